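# segment a chromosome's physically ordered markers at adjacencies whose
# recombination fraction exceeds r_unlink
segment_breaks <- function(m, ids, min_informative, r_unlink) {
  if (length(ids) < 2) return(integer(0))
  br <- integer(0)
  for (k in 2:length(ids)) {
    p <- rf_pair(m[ids[k - 1], ], m[ids[k], ], min_informative)
    if (!is.na(p$r) && p$r > r_unlink) br <- c(br, k - 1L)
  }
  br
}

#' Flag genome misassemblies from map/physical discordance
#'
#' A contiguous cluster of markers is flagged as misplaced when it is
#' genetically unlinked from its physical neighbourhood (recombination
#' fraction to the flanking markers above `r_unlink`) while being tightly
#' linked (r below `r_link` at LOD above `lod_min`) to markers on another
#' chromosome or more than `far_bp` away. The genetically supported
#' location is the physical interval flanking the best-linked target
#' marker. Within a flagged cluster the marker order is re-estimated: if
#' reversing the cluster lowers the recombinant count against the target
#' flanks, an inversion is reported.
#'
#' @param gm A `dg_genotypes` object.
#' @param r_link Linkage threshold to the target region (default 0.15).
#' @param r_unlink Unlinkage threshold to physical neighbours
#'   (default 0.3).
#' @param lod_min LOD required for target linkage (default 3).
#' @param far_bp Same-chromosome distance treated as "distant"
#'   (default 10 Mbp).
#' @param max_cluster Largest cluster size considered misplaced
#'   (default 10).
#' @param min_informative Minimum informative lines per pair.
#' @return Tibble of flags: `cluster_markers`, `n_markers`, `chrom`,
#'   `start`, `end` (physical location), `target_chrom`,
#'   `target_start`, `target_end` (genetically supported interval),
#'   `target_r`, `target_lod`, `inverted`.
#' @export
detect_misassembly <- function(gm, r_link = 0.15, r_unlink = 0.3,
                               lod_min = 3, far_bp = 1e7,
                               max_cluster = 10, min_informative = 20) {
  m <- calls_matrix(gm)
  meta <- gm$calls[, c("marker_id", "chrom", "pos")]
  flags <- list()
  for (ch in unique(meta$chrom)) {
    ids <- meta$marker_id[meta$chrom == ch]
    pos <- meta$pos[meta$chrom == ch]
    br <- segment_breaks(m, ids, min_informative, r_unlink)
    if (length(br) == 0) next
    bounds <- c(0, br, length(ids))
    for (s in seq_len(length(bounds) - 1)) {
      lo <- bounds[s] + 1; hi <- bounds[s + 1]
      n_seg <- hi - lo + 1
      if (n_seg > max_cluster) next
      # flanked by breaks on both sides (or a chromosome end + break)
      cluster <- ids[lo:hi]
      others <- meta[meta$chrom != ch |
                       abs(meta$pos - mean(pos[lo:hi])) > far_bp, ]
      if (nrow(others) == 0) next
      best <- NULL
      for (k in seq_len(nrow(others))) {
        p <- rf_pair(m[cluster[1], ], m[others$marker_id[k], ],
                     min_informative)
        if (is.na(p$r)) next
        if (is.null(best) || p$r < best$r)
          best <- c(p, list(target = others$marker_id[k]))
      }
      if (is.null(best) || best$r >= r_link || best$lod <= lod_min) next
      tchrom <- meta$chrom[meta$marker_id == best$target]
      tids <- meta$marker_id[meta$chrom == tchrom]
      tpos <- meta$pos[meta$chrom == tchrom]
      tk <- match(best$target, tids)
      t_start <- if (tk > 1) tpos[tk - 1] else tpos[tk]
      t_end <- if (tk < length(tids)) tpos[tk + 1] else tpos[tk]
      inverted <- FALSE
      if (length(cluster) >= 2) {
        rec_to <- function(id1, id2) {
          p <- rf_pair(m[id1, ], m[id2, ], min_informative)
          if (is.na(p$n_recombinant)) 0L else p$n_recombinant
        }
        left_fl <- if (tk > 1) tids[tk - 1] else tids[tk]
        right_fl <- if (tk < length(tids)) tids[tk + 1] else tids[tk]
        fwd <- rec_to(left_fl, cluster[1]) +
          rec_to(cluster[length(cluster)], right_fl)
        rev_ <- rec_to(left_fl, cluster[length(cluster)]) +
          rec_to(cluster[1], right_fl)
        inverted <- rev_ < fwd
      }
      flags[[length(flags) + 1]] <- tibble::tibble(
        cluster_markers = paste(cluster, collapse = ","),
        n_markers = length(cluster),
        chrom = ch, start = pos[lo], end = pos[hi],
        target_chrom = tchrom, target_start = t_start,
        target_end = t_end, target_r = best$r, target_lod = best$lod,
        inverted = inverted)
    }
  }
  if (length(flags) == 0) {
    return(tibble::tibble(cluster_markers = character(),
                          n_markers = integer(), chrom = character(),
                          start = double(), end = double(),
                          target_chrom = character(),
                          target_start = double(), target_end = double(),
                          target_r = double(), target_lod = double(),
                          inverted = logical()))
  }
  dplyr::bind_rows(flags)
}

#' Place an unanchored supercontig on the genetic map
#'
#' Given segregation data for the markers a supercontig carries, finds
#' the framework interval minimizing total recombinants between contig
#' and framework markers. With no framework marker linked at LOD >
#' `lod_min` the contig is reported unplaced.
#'
#' @param contig_calls Long tibble `marker_id`, `sample`, `call` for the
#'   contig's markers (samples must match `gm`).
#' @param gm Framework `dg_genotypes` object.
#' @param lod_min Required linkage LOD (default 3).
#' @param min_informative Minimum informative lines per pair.
#' @return One-row tibble: `placed`, `chrom`, `start`, `end`,
#'   `best_marker`, `total_recombinants`, `conflict` (TRUE when contig
#'   markers individually support non-adjacent framework positions).
#' @export
place_supercontig <- function(contig_calls, gm, lod_min = 3,
                              min_informative = 20) {
  m <- calls_matrix(gm)
  meta <- gm$calls[, c("marker_id", "chrom", "pos")]
  cw <- contig_calls |>
    dplyr::select("marker_id", "sample", "call") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "call")
  cmat <- as.matrix(cw[, -1]); rownames(cmat) <- cw$marker_id
  cmat <- cmat[, colnames(m), drop = FALSE]

  tot <- setNames(numeric(nrow(m)), rownames(m))
  best_lod <- -Inf
  per_marker_best <- character(nrow(cmat))
  for (ci in seq_len(nrow(cmat))) {
    recs <- vapply(rownames(m), function(fm) {
      p <- rf_pair(cmat[ci, ], m[fm, ], min_informative)
      best_lod <<- max(best_lod, p$lod, na.rm = TRUE)
      if (is.na(p$n_recombinant)) NA_real_ else p$n_recombinant
    }, numeric(1))
    per_marker_best[ci] <- names(which.min(recs))
    recs[is.na(recs)] <- max(recs, na.rm = TRUE) + 1
    tot <- tot + recs
  }
  if (!is.finite(best_lod) || best_lod <= lod_min) {
    return(tibble::tibble(placed = FALSE, chrom = NA_character_,
                          start = NA_real_, end = NA_real_,
                          best_marker = NA_character_,
                          total_recombinants = NA_real_, conflict = FALSE))
  }
  b <- names(which.min(tot))
  bch <- meta$chrom[meta$marker_id == b]
  ids <- meta$marker_id[meta$chrom == bch]
  pos <- meta$pos[meta$chrom == bch]
  k <- match(b, ids)
  start <- if (k > 1) pos[k - 1] else pos[k]
  end <- if (k < length(ids)) pos[k + 1] else pos[k]
  idx_best <- match(per_marker_best, meta$marker_id)
  conflict <- length(unique(per_marker_best)) > 1 &&
    (length(unique(meta$chrom[idx_best])) > 1 ||
       diff(range(match(per_marker_best, ids), na.rm = TRUE)) > 2)
  tibble::tibble(placed = TRUE, chrom = bch, start = start, end = end,
                 best_marker = b, total_recombinants = min(tot),
                 conflict = conflict)
}
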