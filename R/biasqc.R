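#' Build a per-template depth profile
#'
#' Joins per-sample template depths to template metadata (GC of the
#' 300 bp window adjacent to the site; template length = distance from
#' the site to the nearest MseI site on the template's side) and
#' averages depth across samples.
#'
#' @param depths Tibble `template_id`, `sample`, `depth` (e.g. the
#'   `truth_depths` of [sim_reads()], summed over alleles, or collapsed
#'   observations joined to templates).
#' @param templates Template tibble carrying `template_id`, `gc_window`
#'   and (optionally) `template_len`.
#' @return Tibble: `template_id`, `mean_depth`, `gc_window`,
#'   `template_len`.
#' @export
depth_profile <- function(depths, templates) {
  n_samples <- length(unique(depths$sample))
  prof <- depths |>
    dplyr::group_by(.data$template_id) |>
    dplyr::summarize(mean_depth = sum(.data$depth) / n_samples,
                     .groups = "drop")
  cols <- intersect(c("template_id", "gc_window", "template_len"),
                    names(templates))
  full <- templates[, cols] |>
    dplyr::left_join(prof, by = "template_id") |>
    dplyr::mutate(mean_depth = dplyr::coalesce(.data$mean_depth, 0))
  dplyr::relocate(full, "template_id", "mean_depth")
}

#' Depth histogram and fold-range
#'
#' Histogram of per-template mean depths plus the fold-range of
#' sequencing depth, the ratio of the 97.5th to the 2.5th percentile of
#' mean depth among sequenced templates.
#'
#' @param profile A [depth_profile()] tibble.
#' @param bins Number of histogram bins (default 30).
#' @return List: `hist` (tibble `bin_start`, `bin_end`, `n`),
#'   `fold_range`.
#' @export
depth_histogram <- function(profile, bins = 30) {
  if (nrow(profile) < 2) stop("need at least two templates")
  d <- profile$mean_depth
  if (all(d == 0)) stop("all template depths are zero")
  dpos <- d[d > 0]
  q <- quantile(dpos, c(0.025, 0.975))
  fold <- unname(q[2] / q[1])
  breaks <- seq(0, max(d), length.out = bins + 1)
  n <- as.integer(table(cut(d, breaks, include.lowest = TRUE)))
  list(hist = tibble::tibble(bin_start = breaks[-length(breaks)],
                             bin_end = breaks[-1], n = n),
       fold_range = fold)
}

#' GC content versus sequencing depth
#'
#' Mean GC of the flanking window for templates sequenced at high depth
#' (above `high_cut`) versus low depth (within `low_range`), plus the
#' Spearman correlation of depth with GC across all sequenced templates.
#'
#' @param profile A [depth_profile()] tibble.
#' @param high_cut High-depth threshold (default 80).
#' @param low_range Low-depth band, inclusive (default `c(4, 15)`).
#' @return List: `group_means` (tibble `group`, `n`, `mean_gc`), `rho`.
#' @export
gc_vs_depth <- function(profile, high_cut = 80, low_range = c(4, 15)) {
  hi <- profile[profile$mean_depth > high_cut, ]
  lo <- profile[profile$mean_depth >= low_range[1] &
                  profile$mean_depth <= low_range[2], ]
  seqd <- profile[profile$mean_depth > 0, ]
  rho <- if (nrow(seqd) > 2)
    suppressWarnings(cor(seqd$mean_depth, seqd$gc_window,
                         method = "spearman")) else NA_real_
  list(group_means = tibble::tibble(
    group = c(sprintf("high (>%gx)", high_cut),
              sprintf("low (%g-%gx)", low_range[1], low_range[2])),
    n = c(nrow(hi), nrow(lo)),
    mean_gc = c(mean(hi$gc_window), mean(lo$gc_window))),
    rho = rho)
}

#' Template length versus sequencing depth
#'
#' Mean template length (FseI site to nearest MseI site) within depth
#' tiers, and the depth-weighted fraction of sequencing drawn from
#' templates shorter than `short_bp` (i.e. how rarely short templates
#' are actually sequenced). Defaults mirror the double-digest depth
#' tiers (40-72x, 20-40x, 5-20x).
#'
#' @param profile A [depth_profile()] tibble with `template_len`.
#' @param tiers List of `c(lo, hi)` depth bands.
#' @param short_bp Short-template threshold (default 65).
#' @return List: `tiers` (tibble `tier`, `n`, `mean_length`),
#'   `frac_short_sequenced`.
#' @export
length_vs_depth <- function(profile,
                            tiers = list(c(40, 72), c(20, 40), c(5, 20)),
                            short_bp = 65) {
  if (!"template_len" %in% names(profile))
    stop("profile lacks template_len")
  tt <- purrr::map_dfr(tiers, function(t) {
    sel <- profile[profile$mean_depth >= t[1] & profile$mean_depth < t[2], ]
    tibble::tibble(tier = sprintf("%g-%gx", t[1], t[2]), n = nrow(sel),
                   mean_length = mean(sel$template_len))
  })
  seqd <- profile[profile$mean_depth > 0, ]
  list(tiers = tt,
       frac_short_sequenced = sum(seqd$mean_depth[seqd$template_len <
                                                    short_bp]) /
         sum(seqd$mean_depth))
}
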