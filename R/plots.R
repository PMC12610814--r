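# ggplot2 graphics for the diagnostic result types.

#' ENC-plot
#'
#' Observed ENC against GC3 with the mutation-only expected curve
#' `2 + GC3 + 29/(GC3^2 + (1-GC3)^2)` overlaid. Genes on the curve are
#' compatible with composition alone; genes below it are candidates for
#' selective constraint.
#'
#' @param x An [enc_plot()] object (or a [cub_profile()] tibble).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enc_plot <- function(x, ...) {
  genes <- if (inherits(x, "enc_plot")) x$genes else x
  curve <- tibble::tibble(gc3 = seq(0.01, 0.99, by = 0.01))
  curve$enc <- pmin(enc_expected(curve$gc3), 61)
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$gc3, y = .data$enc_obs)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$gc3, y = .data$enc),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3", y = "Observed ENC",
                  title = "ENC vs GC3 with mutation-only expectation")
}

#' @rdname autoplot.enc_plot
#' @export
plot_enc <- function(x, ...) autoplot.enc_plot(x, ...)

#' ENC-ratio histogram
#'
#' Frequency distribution of `(expected - observed)/expected` ENC ratios
#' with the mutation window marked.
#'
#' @param x An [enc_plot()] object.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot.
#' @export
plot_enc_ratio <- function(x, binwidth = 0.05) {
  ggplot2::ggplot(x$genes, ggplot2::aes(x = .data$enc_ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-x$window, x$window),
                        linetype = "dashed") +
    ggplot2::labs(x = "ENC ratio (expected - observed)/expected",
                  y = "Genes",
                  title = "ENC-ratio distribution")
}

#' PR2-bias plot
#'
#' Third-position `A3/(A3+T3)` against `G3/(G3+C3)` per gene, with the
#' no-bias center (0.5, 0.5) marked by quadrant lines.
#'
#' @param points A [pr2_points()] tibble.
#' @return A ggplot.
#' @export
plot_pr2 <- function(points) {
  aes_pt <- if ("category" %in% names(points)) {
    ggplot2::aes(x = .data$pr2_x, y = .data$pr2_y, colour = .data$category)
  } else {
    ggplot2::aes(x = .data$pr2_x, y = .data$pr2_y)
  }
  ggplot2::ggplot(dplyr::filter(points, .data$quadrant != "undefined"),
                  aes_pt) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)", title = "PR2 bias")
}

#' Neutrality plot
#'
#' GC12 against GC3 per gene with the OLS fit and the y = x diagonal.
#'
#' @param x A [neutrality()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.neutrality_fit <- function(x, ...) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "black") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "GC3", y = "GC12",
      title = sprintf("Neutrality plot (slope %.2f, r %.2f)", x$slope, x$r)
    )
}

#' @rdname autoplot.neutrality_fit
#' @export
plot_neutrality <- function(x, ...) autoplot.neutrality_fit(x, ...)

#' RSCU heatmap across taxa
#'
#' @param m An [rscu_matrix()].
#' @return A ggplot tile map, codons (grouped by amino acid) x taxa.
#' @export
plot_rscu_matrix <- function(m) {
  long <- tibble::tibble(
    codon = rep(rownames(m), ncol(m)),
    aa = rep(attr(m, "aa"), ncol(m)),
    taxon = rep(colnames(m), each = nrow(m)),
    rscu = as.vector(m)
  )
  long$codon <- factor(long$codon, levels = rev(rownames(m)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$codon,
                                     fill = .data$rscu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "RSCU",
                  title = "RSCU by codon and taxon")
}
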