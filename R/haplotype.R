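#' Segment shared haplotype blocks between accessions
#'
#' For each pair of accessions genotyped on a common ordered marker set,
#' slides a window of `window` markers along each chromosome, scores
#' call identity (missing calls drop out of both numerator and
#' denominator), and merges maximal runs of windows at identity >=
#' `min_identity` into blocks. Block boundaries are reported at the
#' midpoint between the last concordant and the first discordant marker.
#'
#' @param tracks Tibble with `marker_id`, `chrom`, `pos` and one call
#'   column per accession (calls in `{"A","B","H","-"}`), physically
#'   ordered or orderable.
#' @param window Window size in markers (default 5).
#' @param min_identity Minimum within-window identity (default 0.9).
#' @param accessions Optional character vector naming the accession
#'   columns (default: all non-coordinate columns).
#' @return Tibble of blocks: `acc1`, `acc2`, `chrom`, `start`, `end`,
#'   `n_markers`, `identity`.
#' @export
haplotype_blocks <- function(tracks, window = 5, min_identity = 0.9,
                             accessions = NULL) {
  if (is.null(accessions))
    accessions <- setdiff(names(tracks), c("marker_id", "chrom", "pos"))
  if (length(accessions) < 2) stop("need at least two accessions")
  tracks <- dplyr::arrange(tracks, .data$chrom, .data$pos)
  pairs <- utils::combn(accessions, 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    for (ch in unique(tracks$chrom)) {
      tt <- tracks[tracks$chrom == ch, ]
      x <- tt[[pr[1]]]; y <- tt[[pr[2]]]
      inf <- x != "-" & y != "-"
      conc <- inf & x == y
      n <- length(x)
      if (n == 0) next
      w <- min(window, n)
      in_block <- logical(n)
      for (s in seq_len(n - w + 1)) {
        idx <- s:(s + w - 1)
        ninf <- sum(inf[idx])
        if (ninf == 0) next
        if (sum(conc[idx]) / ninf >= min_identity) in_block[idx] <- TRUE
      }
      # trim block ends to concordant markers, then report runs
      r <- rle(in_block)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        idx <- starts[k]:ends[k]
        cidx <- which(conc[idx])
        if (length(cidx) == 0) next
        idx <- idx[min(cidx):max(cidx)]  # trim ends to concordant markers
        first <- min(idx); last <- max(idx)
        start_bp <- if (first > 1)
          (tt$pos[first - 1] + tt$pos[first]) / 2 else tt$pos[first]
        end_bp <- if (last < n)
          (tt$pos[last] + tt$pos[last + 1]) / 2 else tt$pos[last]
        ninf <- sum(inf[idx])
        out[[length(out) + 1]] <- tibble::tibble(
          acc1 = pr[1], acc2 = pr[2], chrom = ch,
          start = start_bp, end = end_bp, n_markers = length(idx),
          identity = if (ninf > 0) sum(conc[idx]) / ninf else NA_real_)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(acc1 = character(), acc2 = character(),
                          chrom = character(), start = double(),
                          end = double(), n_markers = integer(),
                          identity = double()))
  }
  dplyr::bind_rows(out)
}
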