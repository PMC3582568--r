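#' Plot read-length distributions
#'
#' Bar chart of raw (or unique) read counts per length, one panel per
#' library, highlighting the 21-24 nt band characteristic of plant small-RNA
#' libraries.
#'
#' @param tags collapsed tag tibble (see [collapse_tags()]).
#' @param libraries libraries to plot (default all).
#' @param measure `"raw"` or `"unique"`.
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(tags, libraries = tag_libraries(tags),
                                     measure = c("raw", "unique")) {
  measure <- match.arg(measure)
  dat <- dplyr::bind_rows(lapply(libraries, function(lib) {
    dplyr::mutate(length_distribution(tags, lib), library = lib)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length,
                                    y = .data[[measure]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~library, scales = "free_y") +
    ggplot2::labs(x = "read length (nt)",
                  y = paste(measure, "reads"),
                  title = "Small-RNA length distribution") +
    ggplot2::theme_minimal()
}

#' Plot RNA-class composition per library
#'
#' Stacked proportion bars of raw reads per annotation class.
#'
#' @param class_totals output of [class_totals()].
#' @return a ggplot object.
#' @export
plot_class_composition <- function(class_totals) {
  dat <- class_totals[class_totals$class != "total", , drop = FALSE]
  long <- tidyr::pivot_longer(dat, dplyr::starts_with("raw_"),
                              names_to = "library", names_prefix = "raw_",
                              values_to = "reads")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library, y = .data$reads,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of clean reads",
                  fill = "class",
                  title = "RNA-class composition") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `clamir_de` tibble from [call_differential()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.clamir_de <- function(object, ...) {
  p_thr <- attr(object, "p_threshold")
  fc_thr <- attr(object, "fc_threshold")
  dat <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_ratio,
                                    y = -log10(pmax(.data$p_gate,
                                                    1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-fc_thr, fc_thr),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ratio (treatment / control)",
                  y = "-log10 p",
                  colour = "significant",
                  title = paste(attr(object, "treatment"), "vs",
                                attr(object, "control"))) +
    ggplot2::theme_minimal()
}

#' Hairpin-profile plot of a folded precursor
#'
#' Per-position pairing profile (paired/unpaired) of a `clamir_fold`, with
#' an optional mature span highlighted.
#'
#' @param object a `clamir_fold` from [fold_rna()].
#' @param mature_start,mature_end optional 1-based inclusive mature span.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.clamir_fold <- function(object, mature_start = NULL,
                                 mature_end = NULL, ...) {
  partner <- dot_bracket_pairs(object$structure)
  n <- nchar(object$structure)
  dat <- tibble::tibble(position = seq_len(n), partner = partner,
                        paired = !is.na(partner))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                         y = ifelse(.data$paired,
                                                    .data$partner,
                                                    .data$position))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$paired), size = 0.8) +
    ggplot2::labs(x = "position", y = "pairing partner",
                  title = sprintf("MFE %.2f kcal/mol", object$energy)) +
    ggplot2::theme_minimal()
  if (!is.null(mature_start) && !is.null(mature_end)) {
    p <- p + ggplot2::annotate("rect", xmin = mature_start,
                               xmax = mature_end, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
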