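#' Scoring constants for miRNA-target complementarity
#'
#' The Allen-style penalty convention used by plant target predictors:
#' mismatch 1.0, G:U wobble 0.5, gap 1.0, penalties doubled in the miRNA
#' core (positions 2-13 from the 5' end). At most one gap per duplex.
#'
#' @param mismatch,wobble,gap position penalties.
#' @param core positions (1-based, inclusive range) where penalties double.
#' @return named list of constants.
#' @export
target_scoring <- function(mismatch = 1.0, wobble = 0.5, gap = 1.0,
                           core = c(2, 13)) {
  list(mismatch = mismatch, wobble = wobble, gap = gap, core = core)
}

pos_weight <- function(pos, core) ifelse(pos >= core[1] & pos <= core[2], 2, 1)

base_penalty <- function(m, s, scoring) {
  # m: miRNA base, s: site base; antiparallel pairing
  pen <- rep(scoring$mismatch, length(m))
  pen[(m == "A" & s == "T") | (m == "T" & s == "A") |
        (m == "G" & s == "C") | (m == "C" & s == "G")] <- 0
  pen[(m == "G" & s == "T") | (m == "T" & s == "G")] <- scoring$wobble
  pen
}

#' Score an antiparallel miRNA/target-site duplex
#'
#' The site is the transcript subsequence written 5'->3'; miRNA position
#' `i` pairs the site position `i` counted from the site's 3' end. Site
#' length may differ from the miRNA length by at most one; a single gap
#' (in whichever strand is shorter) is placed where it minimizes the
#' penalty.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target-site sequence (transcript orientation, 5'->3').
#' @param scoring see [target_scoring()].
#' @return one-row tibble: `score`, `n_match`, `n_mismatch`, `n_wobble`,
#'   `n_gap`, and the aligned strings `aln_mirna` (5'->3'), `aln_pairs`,
#'   `aln_site` (3'->5').
#' @export
score_duplex <- function(mirna, site, scoring = target_scoring()) {
  mi <- strsplit(normalize_seq(mirna), "")[[1]]
  st <- strsplit(normalize_seq(site), "")[[1]]
  lm <- length(mi)
  ls <- length(st)
  if (abs(ls - lm) > 1) stop("site length must be within miRNA length ± 1")
  s3 <- rev(st) # site read 3'->5', aligned index-to-index with the miRNA
  core <- scoring$core
  # build candidate alignments as index vectors (NA = gap)
  cands <- list()
  if (ls == lm) {
    cands[[1]] <- list(mi_idx = seq_len(lm), st_idx = seq_len(ls))
  } else if (ls == lm + 1) {
    for (g in seq_len(ls)) {
      st_idx <- seq_len(ls)
      mi_idx <- append(seq_len(lm), NA_integer_, after = g - 1L)
      cands[[length(cands) + 1]] <- list(mi_idx = mi_idx, st_idx = st_idx)
    }
  } else {
    for (g in seq_len(lm)) {
      mi_idx <- seq_len(lm)
      st_idx <- append(seq_len(ls), NA_integer_, after = g - 1L)
      cands[[length(cands) + 1]] <- list(mi_idx = mi_idx, st_idx = st_idx)
    }
  }
  best <- NULL
  best_score <- Inf
  for (cc in cands) {
    mpos <- ifelse(is.na(cc$mi_idx), pmin(cummax(ifelse(is.na(cc$mi_idx), 0L,
                                                        cc$mi_idx)) + 1L, lm),
                   cc$mi_idx)
    w <- pos_weight(mpos, core)
    pen <- numeric(length(mpos))
    gap_col <- is.na(cc$mi_idx) | is.na(cc$st_idx)
    pen[gap_col] <- scoring$gap
    if (any(!gap_col)) {
      pen[!gap_col] <- base_penalty(mi[cc$mi_idx[!gap_col]],
                                    s3[cc$st_idx[!gap_col]], scoring)
    }
    sc <- sum(pen * w)
    if (sc < best_score - 1e-9) {
      best_score <- sc
      best <- list(cc = cc, pen = pen, gap_col = gap_col)
    }
  }
  cc <- best$cc
  mrow <- ifelse(is.na(cc$mi_idx), "-", mi[cc$mi_idx])
  srow <- ifelse(is.na(cc$st_idx), "-", s3[cc$st_idx])
  sym <- ifelse(best$gap_col, " ",
                ifelse(best$pen == 0, "|",
                       ifelse(best$pen == scoring$wobble & scoring$wobble !=
                                scoring$mismatch, "o", " ")))
  tibble::tibble(
    score = best_score,
    n_match = sum(!best$gap_col & best$pen == 0),
    n_mismatch = sum(!best$gap_col & best$pen == scoring$mismatch),
    n_wobble = sum(!best$gap_col & best$pen == scoring$wobble &
                     scoring$wobble != scoring$mismatch),
    n_gap = sum(best$gap_col),
    aln_mirna = paste(mrow, collapse = ""),
    aln_pairs = paste(sym, collapse = ""),
    aln_site = paste(srow, collapse = "")
  )
}

#' Predict target transcripts of a miRNA by complementarity scanning
#'
#' Every window of length `len(miRNA) - 1 .. + 1` in each transcript is
#' scored with the penalty scheme of [target_scoring()]; windows scoring at
#' most `cutoff` are reported, overlapping windows deduplicated to the best
#' site, sorted by score then transcript id.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts transcript reference (see [as_reference()]).
#' @param cutoff maximum penalty score (default 4.0).
#' @param scoring see [target_scoring()].
#' @param mirna_id optional id carried into the output.
#' @return tibble: `mirna_id`, `transcript`, `start`, `end` (0-based
#'   half-open on the transcript), `score`, aligned strings.
#' @export
predict_targets <- function(mirna, transcripts, cutoff = 4.0,
                            scoring = target_scoring(), mirna_id = NA_character_) {
  transcripts <- as_reference(transcripts)
  stopifnot(length(transcripts) > 0)
  mi <- normalize_seq(mirna)
  hits <- list()
  for (tx in names(transcripts)) {
    raw <- .scan_targets_cpp(mi, transcripts[[tx]], cutoff,
                             scoring$mismatch, scoring$wobble, scoring$gap,
                             scoring$core[1], scoring$core[2])
    if (!nrow(raw)) next
    raw <- raw[order(raw$score, raw$start, raw$end - raw$start), ]
    # dedupe overlapping windows: greedy best-first
    taken_s <- integer(0); taken_e <- integer(0)
    keep <- logical(nrow(raw))
    for (i in seq_len(nrow(raw))) {
      s <- raw$start[i]; e <- raw$end[i]
      if (!length(taken_s) || all(e <= taken_s | s >= taken_e)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
    sel <- raw[keep, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      site <- substr(transcripts[[tx]], sel$start[i] + 1L, sel$end[i])
      aln <- score_duplex(mi, site, scoring = scoring)
      hits[[length(hits) + 1]] <- dplyr::bind_cols(
        tibble::tibble(mirna_id = mirna_id, transcript = tx,
                       start = sel$start[i], end = sel$end[i]),
        aln)
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(mirna_id = character(), transcript = character(),
                          start = integer(), end = integer(),
                          score = numeric(), n_match = integer(),
                          n_mismatch = integer(), n_wobble = integer(),
                          n_gap = integer(), aln_mirna = character(),
                          aln_pairs = character(), aln_site = character()))
  }
  out <- dplyr::bind_rows(hits)
  out[order(out$score, out$transcript, out$start), ]
}
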