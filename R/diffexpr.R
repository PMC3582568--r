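#' Reads-per-million normalization
#'
#' Each count is scaled by the library's normalization total (the total
#' number of identified miRNA reads in that library) and multiplied by one
#' million. Zero counts are reported as 0 RPM; the pseudocount floor applies
#' only when forming log ratios, never to reported RPM.
#'
#' @param count nonnegative counts.
#' @param total normalization total (> 0).
#' @return RPM values.
#' @examples
#' normalize_rpm(130, 285117) # 455.95
#' @export
normalize_rpm <- function(count, total) {
  stopifnot(all(count >= 0))
  if (any(total <= 0)) stop("normalization total must be > 0")
  count / total * 1e6
}

#' Audic-Claverie test for two tag counts
#'
#' Exact test for comparing a tag's counts `x` and `y` between two libraries
#' of totals `N1` and `N2`, under the sampling model
#' \deqn{p(y | x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' which is the negative binomial with size `x + 1` and success probability
#' `N1 / (N1 + N2)`; tails are therefore computed in log space via the
#' negative binomial distribution function. The two-sided p-value is
#' `min(1, 2 * min(P(K <= y), P(K > y)))`: the lower tail includes the
#' observed `y` and the upper tail excludes it, the unique convention under
#' which the statistic is label-symmetric,
#' `p(x, y, N1, N2) = p(y, x, N2, N1)` (by the negative-binomial duality
#' `P(K' <= x | y, swapped) = P(K > y | x)`).
#'
#' @param x,y observed counts in the two libraries.
#' @param N1,N2 library totals (> 0).
#' @return two-sided p-value(s) in `[0, 1]`; vectorized over `x`/`y`.
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), all(N1 > 0), all(N2 > 0))
  prob <- N1 / (N1 + N2)
  # lower tail: sum_{k <= y} p(k | x); upper: sum_{k > y} p(k | x)
  log_lower <- pnbinom(y, size = x + 1, prob = prob, log.p = TRUE)
  log_upper <- pnbinom(y, size = x + 1, prob = prob,
                       lower.tail = FALSE, log.p = TRUE)
  p <- 2 * exp(pmin(log_lower, log_upper))
  pmin(1, p)
}

#' Fisher exact test on a 2x2 library-count table
#'
#' Two-sided exact test for the table `[[x, N1 - x], [y, N2 - y]]`,
#' two-sided rule: the sum of probabilities of all tables (with the same
#' margins) whose point hypergeometric probability does not exceed the
#' observed one (up to the customary `1e-7` relative slack).
#'
#' @param x,y counts in the two libraries.
#' @param N1,N2 library totals.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(x, y, N1, N2) {
  stopifnot(x >= 0, y >= 0, x <= N1, y <= N2)
  k <- x + y                       # first-column margin
  lo <- max(0, k - N2)
  hi <- min(k, N1)
  support <- lo:hi
  d <- dhyper(support, N1, N2, k)
  obs <- dhyper(x, N1, N2, k)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Pearson chi-squared test on a 2x2 library-count table
#'
#' Chi-squared without continuity correction on `[[x, N1 - x], [y, N2 - y]]`,
#' p-value from the chi-squared distribution with 1 degree of freedom.
#'
#' @param x,y counts in the two libraries.
#' @param N1,N2 library totals.
#' @return two-sided p-value; `NA` (with a warning) when an expected cell
#'   count is zero.
#' @export
chi2_2x2 <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), all(x <= N1), all(y <= N2))
  obs1 <- cbind(x, N1 - x)
  obs2 <- cbind(y, N2 - y)
  n <- N1 + N2
  colsum1 <- x + y
  colsum2 <- n - colsum1
  e1 <- cbind(N1 * colsum1 / n, N1 * colsum2 / n)
  e2 <- cbind(N2 * colsum1 / n, N2 * colsum2 / n)
  bad <- e1[, 1] == 0 | e1[, 2] == 0 | e2[, 1] == 0 | e2[, 2] == 0
  stat <- rowSums((obs1 - e1)^2 / e1) + rowSums((obs2 - e2)^2 / e2)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(bad)) {
    warning("zero expected cell count: chi-squared p undefined")
    p[bad] <- NA_real_
  }
  unname(p)
}

#' Call differentially expressed miRNAs between two libraries
#'
#' Per miRNA: RPM in both libraries, log2 ratio (treatment over control, with
#' an RPM floor substituted for zeros inside the ratio only), the
#' Audic-Claverie, Fisher exact and chi-squared p-values, a significance
#' call and a direction. With the default `gate = "any"` a miRNA is
#' significant when the minimum of the three p-values is below `p_threshold`
#' and `|log2 ratio|` exceeds `fc_threshold`.
#'
#' @param counts tibble with a miRNA id column (`name`/`mirna_id`/`id`) and
#'   one raw count column per library.
#' @param control,treatment library column names.
#' @param totals optional named numeric: per-library normalization totals
#'   (total identified miRNA reads). Default: column sums of `counts`.
#' @param p_threshold p-value threshold (default 0.001).
#' @param fc_threshold threshold on `|log2 ratio|` (default 1.0, i.e.
#'   two-fold).
#' @param gate `"any"` (minimum of the three p-values), `"all"` (maximum),
#'   or one of `"ac"`, `"fisher"`, `"chi2"`.
#' @param rpm_floor RPM substituted for zero inside log ratios (default
#'   0.01).
#' @return a tibble of class `clamir_de`: `id`, `rpm_control`,
#'   `rpm_treatment`, `log2_ratio`, `p_ac`, `p_fisher`, `p_chi2`, `p_gate`,
#'   `significant`, `direction` (+1/-1/0). miRNAs absent from both libraries
#'   are excluded.
#' @export
call_differential <- function(counts, control, treatment, totals = NULL,
                              p_threshold = 0.001, fc_threshold = 1.0,
                              gate = c("any", "all", "ac", "fisher", "chi2"),
                              rpm_floor = 0.01) {
  gate <- match.arg(gate)
  stopifnot(control %in% names(counts), treatment %in% names(counts))
  idcol <- intersect(c("name", "mirna_id", "id"), names(counts))[1]
  if (is.na(idcol)) stop("no miRNA id column (name/mirna_id/id)")
  x <- counts[[control]]
  y <- counts[[treatment]]
  if (is.null(totals)) {
    totals <- c(sum(x), sum(y))
    names(totals) <- c(control, treatment)
  }
  N1 <- unname(totals[control])
  N2 <- unname(totals[treatment])
  keep <- x + y > 0
  dat <- counts[keep, , drop = FALSE]
  if (sum(!keep)) {
    message(sum(!keep), " miRNA(s) absent from both libraries excluded")
  }
  x <- x[keep]; y <- y[keep]
  rpm_c <- normalize_rpm(x, N1)
  rpm_t <- normalize_rpm(y, N2)
  lfc <- log2(pmax(rpm_t, rpm_floor) / pmax(rpm_c, rpm_floor))
  p_ac <- audic_claverie_p(x, y, N1, N2)
  p_fisher <- vapply(seq_along(x),
                     function(i) fisher_exact_2x2(x[i], y[i], N1, N2),
                     numeric(1))
  p_chi2 <- suppressWarnings(chi2_2x2(x, y, N1, N2))
  pm <- cbind(p_ac, p_fisher, p_chi2)
  p_gate <- switch(gate,
                   any = apply(pm, 1, min, na.rm = TRUE),
                   all = apply(pm, 1, max, na.rm = TRUE),
                   ac = p_ac, fisher = p_fisher, chi2 = p_chi2)
  significant <- p_gate < p_threshold & abs(lfc) > fc_threshold
  direction <- ifelse(!significant, 0L, ifelse(lfc > 0, 1L, -1L))
  out <- tibble::tibble(
    id = dat[[idcol]],
    rpm_control = rpm_c, rpm_treatment = rpm_t, log2_ratio = lfc,
    p_ac = p_ac, p_fisher = p_fisher, p_chi2 = p_chi2, p_gate = p_gate,
    significant = significant, direction = direction)
  if ("family" %in% names(dat)) out$family <- dat$family
  attr(out, "control") <- control
  attr(out, "treatment") <- treatment
  attr(out, "totals") <- c(N1, N2)
  attr(out, "p_threshold") <- p_threshold
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("clamir_de", class(out))
  out
}

#' @export
tidy.clamir_de <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential-expression result
#'
#' @param x a `clamir_de` tibble.
#' @param ... unused.
#' @return tibble: `n`, `n_significant`, `n_up`, `n_down`, thresholds.
#' @export
glance.clamir_de <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == 1L),
    n_down = sum(x$direction == -1L),
    p_threshold = attr(x, "p_threshold"),
    fc_threshold = attr(x, "fc_threshold"))
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' @param ct_target_sample,ct_ref_sample target and reference-gene (e.g. U6)
#'   Ct in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator the same in the calibrator
#'   sample.
#' @return fold change `2^-ddCt`.
#' @examples
#' ddct_relative_expression(20, 15, 23, 15) # ddCt = -3 -> 8
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator),
            ct_target_sample > 0, ct_ref_sample > 0,
            ct_target_calibrator > 0, ct_ref_calibrator > 0)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Write a differential-expression table as TSV
#'
#' @param de `clamir_de` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(tidy(de), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
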