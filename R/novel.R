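#' Extract precursor candidates around a genome-mapped tag
#'
#' For each combination of 5' and 3' flank lengths, the genomic window
#' spanning the tag plus its flanks (on the tag's strand) is excised, folded
#' and measured. Combinations whose total length would exceed `max_len` are
#' skipped; windows running over a contig end are truncated and flagged.
#'
#' @param locus one-row tibble (or list) with `contig`, `start`, `end`
#'   (0-based half-open) and `strand`, as from [map_to_genome()].
#' @param genome genome reference (see [as_reference()]).
#' @param flanks flank lengths tried on each side (nt).
#' @param max_len maximum precursor length (covers the observed 69-259 nt
#'   range of plant pre-miRNAs, with margin).
#' @param params folding parameters.
#' @return tibble of candidates: window coordinates, `flank5`, `flank3`,
#'   `truncated`, `precursor`, `mature_start`, `mature_end`, `arm`,
#'   `structure`, `mfe`, `gc`, `amfe`, `mfei`.
#' @export
extract_precursor_candidates <- function(locus, genome,
                                         flanks = c(20, 50, 100, 150),
                                         max_len = 300,
                                         params = fold_params()) {
  genome <- as_reference(genome)
  ctg_seq <- genome[[locus$contig]]
  if (is.null(ctg_seq)) stop("contig not in genome: ", locus$contig)
  clen <- nchar(ctg_seq)
  tag_len <- locus$end - locus$start
  out <- list()
  for (f5 in flanks) {
    for (f3 in flanks) {
      if (tag_len + f5 + f3 > max_len) next
      # genome-space flank: on '-' the precursor 5' flank lies 3' in genome
      gl <- if (locus$strand == "+") f5 else f3
      gr <- if (locus$strand == "+") f3 else f5
      ws <- locus$start - gl
      we <- locus$end + gr
      truncated <- ws < 0 || we > clen
      ws <- max(0L, ws)
      we <- min(clen, we)
      prec <- substr(ctg_seq, ws + 1L, we)
      if (locus$strand == "-") prec <- revcomp(prec)
      ms <- if (locus$strand == "+") locus$start - ws + 1L else we - locus$end + 1L
      me <- ms + tag_len - 1L
      if (nchar(prec) < 10) next
      fd <- fold_rna(prec, params = params)
      met <- compute_metrics(fd)
      hp <- decompose_hairpin(fd)
      arm <- NA_character_
      if (hp$is_hairpin) {
        if (me < hp$loop[1]) arm <- "5p" else if (ms > hp$loop[2]) arm <- "3p"
      }
      out[[length(out) + 1]] <- tibble::tibble(
        contig = locus$contig, window_start = ws, window_end = we,
        strand = locus$strand, flank5 = f5, flank3 = f3,
        truncated = truncated, precursor = prec,
        mature_start = ms, mature_end = me, arm = arm,
        structure = fd$structure, mfe = fd$energy,
        gc = met$gc, amfe = met$amfe, mfei = met$mfei)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(contig = character(), window_start = integer(),
                          window_end = integer(), strand = character(),
                          flank5 = integer(), flank3 = integer(),
                          truncated = logical(), precursor = character(),
                          mature_start = integer(), mature_end = integer(),
                          arm = character(), structure = character(),
                          mfe = numeric(), gc = numeric(), amfe = numeric(),
                          mfei = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Call novel miRNAs from unannotated tags
#'
#' A tag (already screened against RNA classes and known miRNAs) is called a
#' novel miRNA when its pooled count strictly exceeds `thresholds$min_reads`
#' and at least one precursor candidate at one of its perfect-match genome
#' loci passes all six criteria. The reported candidate is the passing one
#' with the highest MFEI; every locus with a passing candidate is listed.
#' Ids `cla-miR<n>` are assigned by descending pooled count, ties broken by
#' sequence.
#'
#' @param tags unannotated tag tibble.
#' @param genome genome reference.
#' @param thresholds see [criteria_thresholds()].
#' @param flanks,max_len,params passed to [extract_precursor_candidates()].
#' @return tibble: `id`, `sequence`, `length`, per-library counts, `total`,
#'   best-candidate columns (`contig`, `window_start`, `window_end`,
#'   `strand`, `precursor`, `mature_start`, `mature_end`, `arm`, `structure`,
#'   `mfe`, `mfei`), `n_loci` and a `loci` list-column.
#' @export
call_novel_mirnas <- function(tags, genome, thresholds = criteria_thresholds(),
                              flanks = c(20, 50, 100, 150), max_len = 300,
                              params = fold_params()) {
  libs <- tag_libraries(tags)
  libs <- libs[vapply(tags[libs], is.numeric, logical(1))]
  total <- if (nrow(tags)) rowSums(as.matrix(tags[, libs, drop = FALSE])) else numeric()
  cand_tags <- tags[total > thresholds$min_reads, , drop = FALSE]
  cand_total <- total[total > thresholds$min_reads]
  genome <- as_reference(genome)
  res <- list()
  for (i in seq_len(nrow(cand_tags))) {
    s <- cand_tags$sequence[i]
    loci <- map_to_genome(s, genome)
    if (!nrow(loci)) next
    passing <- list()
    for (k in seq_len(nrow(loci))) {
      cands <- extract_precursor_candidates(loci[k, ], genome,
                                            flanks = flanks,
                                            max_len = max_len,
                                            params = params)
      if (!nrow(cands)) next
      rep_k <- dplyr::bind_rows(lapply(seq_len(nrow(cands)), function(w) {
        evaluate_criteria(cands$precursor[w], cands$structure[w],
                          cands$mature_start[w], cands$mature_end[w],
                          mfe = cands$mfe[w], thresholds = thresholds)
      }))
      ok <- which(rep_k$overall)
      if (length(ok)) {
        passing[[length(passing) + 1]] <-
          dplyr::bind_cols(cands[ok, , drop = FALSE],
                           rep_k[ok, c("mature_paired", "n_stem_pairs")],
                           tibble::tibble(locus_start = loci$start[k],
                                          locus_end = loci$end[k]))
      }
    }
    if (!length(passing)) next
    pass <- dplyr::bind_rows(passing)
    best <- pass[order(-pass$mfei, pass$window_start), ][1, ]
    loci_pass <- unique(pass[, c("contig", "locus_start", "locus_end",
                                 "strand")])
    row <- cand_tags[i, c("sequence", "length", libs), drop = FALSE]
    row$total <- cand_total[i]
    res[[length(res) + 1]] <- dplyr::bind_cols(
      row,
      best[, c("contig", "window_start", "window_end", "strand", "precursor",
               "mature_start", "mature_end", "arm", "structure", "mfe",
               "mfei")],
      tibble::tibble(n_loci = nrow(loci_pass), loci = list(loci_pass)))
  }
  if (!length(res)) {
    out <- tibble::tibble(id = character(), sequence = character(),
                          length = integer(), total = numeric())
    return(out)
  }
  out <- dplyr::bind_rows(res)
  out <- out[order(-out$total, out$sequence), ]
  out <- dplyr::bind_cols(tibble::tibble(id = sprintf("cla-miR%d",
                                                      seq_len(nrow(out)))),
                          out)
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson style shuffle: permutes the sequence while preserving
#' its dinucleotide composition, used to build decoy precursors with the
#' same local composition but scrambled base-pairing potential.
#'
#' @param sequence nucleotide string.
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  b <- strsplit(normalize_seq(sequence), "")[[1]]
  n <- length(b)
  if (n < 3) return(paste(b, collapse = ""))
  # multigraph of dinucleotide edges; walk a random Eulerian trail from b[1]
  edges <- split(seq_len(n - 1), b[seq_len(n - 1)])
  for (try in seq_len(10000L)) {
    shuffled <- lapply(edges, sample)
    # rebuild trail
    ptr <- lapply(shuffled, function(x) 1L)
    out <- character(n)
    out[1] <- b[1]
    cur <- b[1]
    ok <- TRUE
    for (i in 2:n) {
      es <- shuffled[[cur]]
      k <- ptr[[cur]]
      if (is.null(es) || k > length(es)) { ok <- FALSE; break }
      ptr[[cur]] <- k + 1L
      nxt <- b[es[k] + 1L]
      out[i] <- nxt
      cur <- nxt
    }
    if (ok && all(ptr_used(ptr, shuffled))) {
      return(paste(out, collapse = ""))
    }
  }
  stop("dinucleotide shuffle failed to find an Eulerian trail")
}

ptr_used <- function(ptr, shuffled) {
  vapply(names(shuffled), function(v) {
    ptr[[v]] - 1L == length(shuffled[[v]])
  }, logical(1))
}
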