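#' Thresholds for the six novel-miRNA annotation criteria
#'
#' Defaults follow the strict plant-miRNA annotation rules used for hairpin
#' screening: (1) a stem-loop hairpin fold; (2) the mature sequence sits in
#' one arm; (3) stem bulges under 12 nt and more than 18 stem base pairs;
#' (4) mature-region bulges of at most 8 nt and 4 biased errors each, at most
#' 2 biased bulges and 6 errors in the mature region; (5) more than 15 base
#' pairs in the mature region with at least 80% of it inside the stem;
#' (6) negative folding energy with MFEI above 0.9. The pooled read-count
#' filter (strictly greater than `min_reads`, default 50) gates which tags
#' are evaluated at all.
#'
#' Structural terms, computable from the fold alone: an *error* in the mature
#' region is an unpaired mature base; a *biased error* is an unpaired base
#' without an unpaired counterpart on the opposing strand of the loop (the
#' asymmetric excess `|n5 - n3|` of a bulge/internal loop); a *biased bulge*
#' has all its unpaired bases on one strand.
#'
#' @param max_stem_bulge stem bulges must be strictly smaller (nt).
#' @param min_stem_pairs stem pairs must strictly exceed this.
#' @param max_mature_bulge largest allowed bulge overlapping the mature span.
#' @param max_biased_errors_bulge most biased errors allowed in one such bulge.
#' @param max_biased_bulges most biased bulges overlapping the mature span.
#' @param max_mature_errors most unpaired bases in the mature span.
#' @param min_mature_pairs paired mature bases must strictly exceed this.
#' @param min_mature_in_stem minimum fraction of the mature span inside the
#'   stem (arms).
#' @param min_mfei MFEI must strictly exceed this.
#' @param min_reads pooled tag count must strictly exceed this.
#' @return a named list of thresholds.
#' @export
criteria_thresholds <- function(max_stem_bulge = 12,
                                min_stem_pairs = 18,
                                max_mature_bulge = 8,
                                max_biased_errors_bulge = 4,
                                max_biased_bulges = 2,
                                max_mature_errors = 6,
                                min_mature_pairs = 15,
                                min_mature_in_stem = 0.8,
                                min_mfei = 0.9,
                                min_reads = 50) {
  list(max_stem_bulge = max_stem_bulge,
       min_stem_pairs = min_stem_pairs,
       max_mature_bulge = max_mature_bulge,
       max_biased_errors_bulge = max_biased_errors_bulge,
       max_biased_bulges = max_biased_bulges,
       max_mature_errors = max_mature_errors,
       min_mature_pairs = min_mature_pairs,
       min_mature_in_stem = min_mature_in_stem,
       min_mfei = min_mfei,
       min_reads = min_reads)
}

spans_overlap <- function(a1, a2, b1, b2) {
  !is.na(a1) && a1 <= b2 && b1 <= a2
}

#' Evaluate the six annotation criteria on a precursor candidate
#'
#' @param precursor precursor sequence.
#' @param structure dot-bracket structure of the precursor (or a
#'   `clamir_fold` object, in which case `precursor`/`mfe` default from it).
#' @param mature_start,mature_end 1-based inclusive mature span within the
#'   precursor.
#' @param mfe minimum free energy (kcal/mol); defaults to the re-evaluated
#'   energy of `structure` when not given.
#' @param thresholds see [criteria_thresholds()].
#' @return one-row tibble: flags `c1_hairpin` .. `c6_energy` and `overall`
#'   plus the measured quantities (`n_stem_pairs`, `largest_stem_bulge`,
#'   `largest_mature_bulge`, `max_biased_errors_bulge`, `n_biased_bulges`,
#'   `mature_errors`, `mature_paired`, `mature_in_stem`, `mfe`, `mfei`).
#'   When the structure is not a hairpin, `c2`-`c5` and the stem quantities
#'   are `NA` and `overall` is `FALSE`.
#' @export
evaluate_criteria <- function(precursor, structure, mature_start, mature_end,
                              mfe = NULL, thresholds = criteria_thresholds()) {
  if (inherits(structure, "clamir_fold")) {
    if (missing(precursor) || is.null(precursor)) precursor <- structure$sequence
    if (is.null(mfe)) mfe <- structure$energy
    structure <- structure$structure
  }
  n <- nchar(precursor)
  stopifnot(nchar(structure) == n)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end) {
    stop("mature span outside precursor")
  }
  if (is.null(mfe)) mfe <- structure_energy(precursor, structure)
  th <- thresholds
  hp <- decompose_hairpin(structure)
  b <- strsplit(normalize_seq(precursor), "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  met <- compute_metrics(mfe = mfe, length = n, gc = gc)
  mspan <- mature_start:mature_end
  mlen <- length(mspan)
  na_row <- function() tibble::tibble(
    c1_hairpin = FALSE, c2_mature_in_arm = NA, c3_stem = NA, c4_bulges = NA,
    c5_pairing = NA, c6_energy = mfe < 0 && !is.na(met$mfei) &&
      met$mfei > th$min_mfei,
    overall = FALSE,
    n_stem_pairs = NA_integer_, largest_stem_bulge = NA_integer_,
    largest_mature_bulge = NA_integer_, max_biased_errors_bulge = NA_integer_,
    n_biased_bulges = NA_integer_, mature_errors = NA_integer_,
    mature_paired = NA_integer_, mature_in_stem = NA_real_,
    mfe = mfe, mfei = met$mfei)
  if (!hp$is_hairpin) return(na_row())

  paired <- hp$paired
  # c2: mature entirely on one side of the terminal loop
  c2 <- mature_end < hp$loop[1] || mature_start > hp$loop[2]

  # c3: stem geometry
  largest_stem_bulge <- if (nrow(hp$bulges)) max(hp$bulges$size) else 0L
  c3 <- largest_stem_bulge < th$max_stem_bulge &&
    hp$n_stem_pairs > th$min_stem_pairs

  # c4: bulges overlapping the mature span
  overl <- logical(nrow(hp$bulges))
  if (nrow(hp$bulges)) {
    for (k in seq_len(nrow(hp$bulges))) {
      bu <- hp$bulges[k, ]
      overl[k] <-
        (!is.na(bu$start5) &&
           spans_overlap(bu$start5, bu$end5, mature_start, mature_end)) ||
        (!is.na(bu$start3) &&
           spans_overlap(bu$start3, bu$end3, mature_start, mature_end))
    }
  }
  mb <- hp$bulges[overl, , drop = FALSE]
  largest_mature_bulge <- if (nrow(mb)) max(mb$size) else 0L
  max_be <- if (nrow(mb)) max(mb$biased_errors) else 0L
  n_biased <- if (nrow(mb)) sum(mb$biased) else 0L
  mature_errors <- sum(!paired[mspan])
  c4 <- largest_mature_bulge <= th$max_mature_bulge &&
    max_be <= th$max_biased_errors_bulge &&
    n_biased <= th$max_biased_bulges &&
    mature_errors <= th$max_mature_errors

  # c5: mature pairing and stem placement
  mature_paired <- sum(paired[mspan])
  in_stem <- (mspan >= hp$arm5[1] & mspan <= hp$arm5[2]) |
    (mspan >= hp$arm3[1] & mspan <= hp$arm3[2])
  frac_stem <- sum(in_stem) / mlen
  c5 <- mature_paired > th$min_mature_pairs &&
    frac_stem >= th$min_mature_in_stem

  # c6: energy
  c6 <- mfe < 0 && !is.na(met$mfei) && met$mfei > th$min_mfei

  tibble::tibble(
    c1_hairpin = TRUE, c2_mature_in_arm = c2, c3_stem = c3, c4_bulges = c4,
    c5_pairing = c5, c6_energy = c6,
    overall = c2 && c3 && c4 && c5 && c6,
    n_stem_pairs = hp$n_stem_pairs,
    largest_stem_bulge = as.integer(largest_stem_bulge),
    largest_mature_bulge = as.integer(largest_mature_bulge),
    max_biased_errors_bulge = as.integer(max_be),
    n_biased_bulges = as.integer(n_biased),
    mature_errors = as.integer(mature_errors),
    mature_paired = as.integer(mature_paired),
    mature_in_stem = frac_stem,
    mfe = mfe, mfei = met$mfei
  )
}
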