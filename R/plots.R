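#' Marker-density heat map
#'
#' Per-chromosome binned density (percent of each chromosome's total),
#' the layout used to visualize tag/marker distribution along
#' chromosomes.
#'
#' @param density A [density_track()] tibble.
#' @return A ggplot.
#' @export
plot_marker_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$bin_start / 1e6, y = .data$chrom,
                               fill = .data$pct)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "% of chromosome") +
    ggplot2::labs(x = "Position (Mbp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Depth-bias diagnostics
#'
#' Mean template depth against flanking GC content, with a loess trend.
#'
#' @param profile A [depth_profile()] tibble.
#' @return A ggplot.
#' @export
plot_depth_bias <- function(profile) {
  ggplot2::ggplot(profile[profile$mean_depth > 0, ],
                  ggplot2::aes(x = .data$gc_window, y = .data$mean_depth)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GC of 300 bp adjacent to site",
                  y = "Mean depth (log scale)") +
    ggplot2::theme_minimal()
}

#' Genotype-matrix tile plot
#'
#' @param gm A `dg_genotypes` object.
#' @return A ggplot.
#' @export
plot_genotypes <- function(gm) {
  long <- tidy(gm)
  long$marker_id <- factor(long$marker_id,
                           levels = unique(gm$calls$marker_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker_id, y = .data$sample,
                                     fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(A = "#1b62a5", B = "#c23b22",
                                          H = "#7ac36a", `-` = "grey85")) +
    ggplot2::labs(x = "Marker (physical order)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn build_map Genetic versus physical position, one panel per
#'   chromosome.
#' @param object A `dg_map` object.
#' @param ... Unused.
#' @export
autoplot.dg_map <- function(object, ...) {
  ggplot2::ggplot(object$markers,
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$cM)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "Physical position (Mbp)", y = "Kosambi cM") +
    ggplot2::theme_minimal()
}
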