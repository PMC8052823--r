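#' Plot a fitted GC-bias model
#'
#' Panel k-mer counts against GC fraction with the LOESS-predicted
#' single-copy baseline overlaid.
#'
#' @param object A `gc_model`.
#' @param max_points Subsample of panel points to draw (default 5000).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gc_model <- function(object, max_points = 5000, ...) {
  pts <- attr(object, "panel_data")
  if (!is.null(pts) && nrow(pts) > max_points) {
    pts <- pts[seq(1L, nrow(pts), length.out = max_points), ]
  }
  p <- ggplot2::ggplot()
  if (!is.null(pts)) {
    p <- p + ggplot2::geom_jitter(
      data = pts,
      ggplot2::aes(x = .data$gc_frac, y = .data$count),
      width = 0.4 / attr(object, "k"), height = 0,
      alpha = 0.15, size = 0.5
    )
  }
  p +
    ggplot2::geom_line(
      data = as_tibble(object),
      ggplot2::aes(x = .data$gc_frac, y = .data$predicted),
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "k-mer GC fraction", y = "observed count (single-copy k-mers)",
      title = "GC-bias baseline",
      subtitle = sprintf("k = %d, span = %.2f", attr(object, "k"),
                         attr(object, "span"))
    )
}

#' Plot a positional polymorphism landscape
#'
#' Non-consensus nucleotide fraction along the satellite consensus, the
#' per-sample view of the polymorphism landscape.
#'
#' @param object A `poly_matrix`.
#' @param threshold Horizontal reference line (default 0.20, the
#'   variable-site call threshold).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.poly_matrix <- function(object, threshold = 0.20, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$nonconsensus)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "consensus position (1-based)",
      y = "non-consensus nucleotide fraction",
      title = sprintf("Polymorphism landscape: %s",
                      attr(object, "satellite") %||% "satellite"),
      subtitle = sprintf("k = %d, h <= %d", attr(object, "k"),
                         attr(object, "h_max"))
    )
}

#' Plot a variance partition
#'
#' @param object A `variance_partition`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.variance_partition <- function(object, ...) {
  d <- as_tibble(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percent_variance,
                                  y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of variance (sequential SS)", y = NULL,
                  title = sprintf("Variance partition: %s",
                                  attr(object, "response")))
}

#' Copy number against diversity index across samples
#'
#' Scatter of estimated satellite copy number (log scale) versus CDI,
#' the standard view of the size-versus-heterogeneity relationship.
#'
#' @param copy_number Tibble with columns `sample`, `satellite`,
#'   `copies` (e.g. the `copy_number` element of [run_pipeline()]).
#' @param cdi Tibble with columns `sample`, `satellite`, `cdi`.
#' @return A ggplot object.
#' @export
plot_copy_vs_cdi <- function(copy_number, cdi) {
  d <- left_join(copy_number, cdi, by = c("sample", "satellite"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$copies, y = .data$cdi,
                                  colour = .data$satellite)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "estimated copies (log scale)",
                  y = "centromere diversity index",
                  title = "Satellite copy number vs repeat heterogeneity")
}
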