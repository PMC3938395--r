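#' Plot a pair's window-level IBS track
#'
#' Draws P0 (and optionally P2) along the genome for one pair, one facet per
#' chromosome, with identity windows highlighted. Sibling-type pairs show
#' long high-P2 tracts; distant relatives show sparse, short IW runs.
#'
#' @param track A window tibble from [window_ibs()].
#' @param stat Which fraction to draw, `"P0"` or `"P2"`.
#' @return A ggplot object.
#' @export
plot_ibs_track <- function(track, stat = c("P0", "P2")) {
  stat <- match.arg(stat)
  track <- dplyr::mutate(track,
    chrom = factor(.data$chrom, levels = unique(.data$chrom)),
    mb = (.data$start + .data$end) / 2e6
  )
  ggplot2::ggplot(track, ggplot2::aes(x = .data$mb, y = .data[[stat]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_iw), size = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey40"),
      name = "identity window"
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Histogram of per-window P2 for a pair
#'
#' The diagnostic behind the sibling test: full siblings (and twins/self)
#' show a prominent peak in the (0.8, 1] region from IBD2 tracts.
#'
#' @param track A window tibble from [window_ibs()].
#' @param binwidth Histogram bin width on P2 (default 0.01, the width used
#'   by the classifier's peak comparison).
#' @return A ggplot object.
#' @export
plot_p2_hist <- function(track, binwidth = 0.01) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$P2)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#0072B2", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.8, linetype = 2) +
    ggplot2::labs(x = "P2 (fraction of IBS2 sites per window)", y = "windows") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Classifier-statistic distributions by true relationship
#'
#' Boxplots of a chosen pair statistic (default the IW fraction) against the
#' true label of each pair — the monotone decay of IW counts with degree is
#' the core signal the tree thresholds cut.
#'
#' @param calls Classified pairs with a `true_label` column (e.g. from
#'   [relatedness_experiment()] results).
#' @param stat Column to plot (default `n_iw`), shown as a fraction of
#'   `n_windows` when `normalize = TRUE`.
#' @param normalize Divide by `n_windows`?
#' @return A ggplot object.
#' @export
plot_metric_by_class <- function(calls, stat = "n_iw", normalize = TRUE) {
  y <- if (normalize) calls[[stat]] / calls$n_windows else calls[[stat]]
  df <- tibble::tibble(
    true_label = factor(calls$true_label, levels = relationship_levels()),
    y = y
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_label, y = .data$y)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::labs(
      x = "true relationship",
      y = if (normalize) paste0(stat, " / n_windows") else stat
    ) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @export
autoplot.kin_experiment <- function(object, se = NULL, ...) {
  r <- if (is.null(se)) object$results[[1]] else
    object$results[[paste0("se_", se)]]
  plot_metric_by_class(r$calls)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
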