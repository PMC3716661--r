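#' Kosambi map function
#'
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans, allowing partial
#' crossover interference.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi(0.25) # 25 * log(3) = 27.465 cM
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d Map distance(s) in cM.
#' @return Recombination fraction(s).
#' @export
kosambi_inv <- function(d) 0.5 * tanh(d / 50)

#' Selfed-RIL recombination correction
#'
#' At fixation under selfing, the observed fraction of recombinant lines
#' R relates to the per-meiosis recombination fraction r by
#' R = 2r/(1+2r); `ril_correct()` inverts this (r = R/(2(1-R)),
#' clamped to 0 <= r < 0.5).
#'
#' @param R Observed recombinant fraction(s) among RILs.
#' @return Corrected meiotic recombination fraction(s).
#' @export
ril_correct <- function(R) pmin(pmax(R / (2 * (1 - R)), 0), 0.5 - 1e-9)

#' Expected RIL recombinant fraction from meiotic r
#'
#' @param r Per-meiosis recombination fraction(s).
#' @return Expected observed recombinant fraction(s) among selfed RILs.
#' @export
ril_expect <- function(r) 2 * r / (1 + 2 * r)

rf_pair <- function(ci, cj, min_informative = 20) {
  inf <- ci %in% c("A", "B") & cj %in% c("A", "B")
  n <- sum(inf)
  if (n < min_informative) {
    return(list(n_informative = n, n_recombinant = NA_integer_,
                R_obs = NA_real_, r = NA_real_, lod = NA_real_,
                status = "unknown"))
  }
  rec <- sum(ci[inf] != cj[inf])
  R <- rec / n
  p <- R
  term <- function(p) ifelse(p == 0, 0, p * log10(p / 0.5))
  lod <- n * (term(p) + term(1 - p))
  if (p > 0.5) lod <- 0  # repulsion beyond independence is not linkage
  list(n_informative = n, n_recombinant = rec, R_obs = R,
       r = ril_correct(min(R, 1 - 1e-9)), lod = lod, status = "ok")
}

#' Two-point recombination estimate between two markers
#'
#' Informative lines are homozygous and non-missing at both markers;
#' `R_obs` is the recombinant fraction among them; `r` applies the
#' selfed-RIL correction; the LOD is
#' `n * (p log10(p/0.5) + (1-p) log10((1-p)/0.5))` at `p = R_obs`.
#' Heterozygous calls are excluded (two-point counting with H is
#' ambiguous in selfed RILs).
#'
#' @param gm A `dg_genotypes` object.
#' @param i,j Marker ids (or row indices).
#' @param min_informative Minimum informative lines (default 20); below
#'   it the pair is returned with status `"unknown"`.
#' @return One-row tibble: `marker_i`, `marker_j`, `n_informative`,
#'   `n_recombinant`, `R_obs`, `r`, `lod`, `status`.
#' @export
estimate_rf <- function(gm, i, j, min_informative = 20) {
  m <- calls_matrix(gm)
  if (is.numeric(i)) i <- rownames(m)[i]
  if (is.numeric(j)) j <- rownames(m)[j]
  p <- rf_pair(m[i, ], m[j, ], min_informative)
  tibble::tibble(marker_i = i, marker_j = j,
                 n_informative = p$n_informative,
                 n_recombinant = p$n_recombinant,
                 R_obs = p$R_obs, r = p$r, lod = p$lod, status = p$status)
}

#' Build a genetic map on the physical marker frame
#'
#' Markers are taken in physical order (the frame is not re-optimized;
#' genetic evidence is used to validate it, with deviations surfaced by
#' [detect_misassembly()]). Markers lacking LOD > `lod_min` support
#' against both physical neighbours are set aside; adjacent
#' recombination fractions among the retained markers are RIL-corrected
#' and chained into cumulative Kosambi cM per chromosome. The summary
#' mirrors the standard per-chromosome map table: marker count, total
#' cM, cM/marker, bp/marker, largest interval.
#'
#' @param gm A `dg_genotypes` object.
#' @param lod_min LOD threshold for neighbour support (default 3).
#' @param min_informative Minimum informative lines per pair.
#' @return Object of class `dg_map`: `markers` (tibble with adjacent
#'   `R_obs`, `r_adj`, `lod_adj`, `n_informative`, cumulative `cM`),
#'   `summary`, `set_aside`.
#' @export
build_map <- function(gm, lod_min = 3, min_informative = 20) {
  m <- calls_matrix(gm)
  meta <- gm$calls[, c("marker_id", "chrom", "pos")]
  out <- list(); aside <- character(0)
  for (ch in unique(meta$chrom)) {
    ids <- meta$marker_id[meta$chrom == ch]
    if (length(ids) > 1) {
      sup <- vapply(seq_along(ids), function(k) {
        nb <- c(if (k > 1) ids[k - 1], if (k < length(ids)) ids[k + 1])
        any(vapply(nb, function(x)
          isTRUE(rf_pair(m[ids[k], ], m[x, ], min_informative)$lod > lod_min),
          logical(1)))
      }, logical(1))
      aside <- c(aside, ids[!sup])
      ids <- ids[sup]
    }
    if (length(ids) == 0) next
    pos <- meta$pos[match(ids, meta$marker_id)]
    rr <- rep(NA_real_, length(ids)); RR <- rr; ll <- rr
    nn <- rep(NA_integer_, length(ids))
    if (length(ids) > 1) {
      for (k in 2:length(ids)) {
        p <- rf_pair(m[ids[k - 1], ], m[ids[k], ], min_informative)
        RR[k] <- p$R_obs; rr[k] <- p$r; ll[k] <- p$lod
        nn[k] <- p$n_informative
      }
    }
    seg <- rep(0, length(rr))
    seg[!is.na(rr)] <- kosambi(rr[!is.na(rr)])
    out[[ch]] <- tibble::tibble(
      marker_id = ids, chrom = ch, pos = pos,
      R_obs = RR, r_adj = rr, lod_adj = ll, n_informative = nn,
      interval_cM = seg, cM = cumsum(seg))
  }
  markers <- dplyr::bind_rows(out)
  summary <- markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarize(
      n_markers = dplyr::n(),
      total_cM = max(.data$cM),
      cm_per_marker = max(.data$cM) / dplyr::n(),
      bp_per_marker = (max(.data$pos) - min(.data$pos)) / dplyr::n(),
      largest_interval_cM = max(.data$interval_cM, 0),
      .groups = "drop")
  structure(list(markers = markers, summary = summary,
                 set_aside = aside), class = "dg_map")
}

#' Map-density arithmetic
#'
#' Mean map resolution, total genetic distance over marker count.
#'
#' @param total_cM Total map length (cM).
#' @param n_markers Number of mapped markers.
#' @return cM per marker.
#' @examples
#' map_density(1232.7, 841) # 1.47 cM/marker
#' @export
map_density <- function(total_cM, n_markers) total_cM / n_markers

#' @export
print.dg_map <- function(x, ...) {
  cat(sprintf("Digital genotyping genetic map: %d markers, %.1f cM (%.2f cM/marker)\n",
              nrow(x$markers), sum(x$summary$total_cM),
              map_density(sum(x$summary$total_cM), nrow(x$markers))))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.dg_map <- function(x, ...) x$markers

#' @export
glance.dg_map <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x$markers),
                 n_chromosomes = nrow(x$summary),
                 total_cM = sum(x$summary$total_cM),
                 cm_per_marker = map_density(sum(x$summary$total_cM),
                                             nrow(x$markers)),
                 largest_interval_cM = max(x$summary$largest_interval_cM),
                 n_set_aside = length(x$set_aside))
}
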