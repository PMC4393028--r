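# ggplot2 views of the main result tables; every plot function accepts the
# tibble the matching analysis function returned.

#' Plot LD decay
#'
#' Mean r-squared per distance bin against bin midpoint.
#'
#' @param bins Tibble from [bin_ld()].
#' @return A ggplot.
#' @export
plot_ld_decay <- function(bins) {
  ggplot2::ggplot(bins,
                  ggplot2::aes(x = (.data$lo_bp + .data$hi_bp) / 2e6,
                               y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Distance (Mb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot the Ne trajectory
#'
#' Effective population size (or `delta_f` with `what = "delta_f"`) against
#' generations in the past, on a log10 generation axis.
#'
#' @param traj Tibble from [ne_trajectory()].
#' @param what `"ne"` or `"delta_f"`.
#' @return A ggplot.
#' @export
plot_ne_trajectory <- function(traj, what = c("ne", "delta_f")) {
  what <- match.arg(what)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$g, y = .data[[what]])) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Generations ago",
                  y = if (what == "ne") "Effective population size" else
                    expression(Delta * F)) +
    ggplot2::theme_minimal()
}

#' Plot ROH counts per length category
#'
#' @param hist_tab Tibble from [roh_length_histogram()] (optionally
#'   row-bound over thresholds with a `threshold` column).
#' @return A ggplot.
#' @export
plot_roh_lengths <- function(hist_tab) {
  p <- ggplot2::ggplot(hist_tab,
                       ggplot2::aes(x = factor(.data$category,
                                               unique(.data$category)),
                                    y = .data$n))
  if ("threshold" %in% names(hist_tab)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$threshold),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40")
  }
  p + ggplot2::labs(x = "ROH length category", y = "Number of ROHs") +
    ggplot2::theme_minimal()
}

#' Plot selection-scan scores along the genome
#'
#' `-log10 P` per scored core haplotype at the core midpoint, faceted by
#' chromosome, with the significance threshold drawn.
#'
#' @param scored Tibble from [score_rehh()].
#' @param min_score Threshold line (default 3).
#' @return A ggplot.
#' @export
plot_rehh_scores <- function(scored, min_score = 3) {
  dat <- dplyr::filter(scored, .data$scored)
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = (.data$start_bp + .data$end_bp) / 2e6,
                               y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$frequency), size = 0.9) +
    ggplot2::geom_hline(yintercept = min_score, linetype = 2,
                        colour = "red3") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10] ~ P),
                  colour = "Core haplotype\nfrequency") +
    ggplot2::theme_minimal()
}
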