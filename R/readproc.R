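#' Demultiplex reads by barcode and enzyme remnant
#'
#' A read passes only if its first `barcode_len` bases exactly match a
#' registered barcode and the following bases exactly match the enzyme
#' remnant (no mismatch tolerance). The barcode + remnant prefix is
#' removed and `trim3` bases are trimmed from the 3' end. Reads whose
#' remaining genomic portion is shorter than `min_tag_len` are rejected
#' under a distinct counter.
#'
#' @param reads A FASTQ path, a [sim_reads()] result, or a character
#'   vector of read sequences.
#' @param barcodes Tibble with `sample`, `barcode` (equal-length,
#'   distinct barcodes), or a named character vector `sample = barcode`.
#' @param enzyme Enzyme whose remnant is enforced (default "FseI").
#' @param trim3 Bases trimmed from the 3' end (default 1).
#' @param min_tag_len Minimum genomic portion after trimming (default 20).
#' @return List of class `dg_demux`: `observations` (tibble `sample`,
#'   `tag_seq`, one row per passing read), `stats` (tibble with `pass`,
#'   `fail_barcode`, `fail_remnant`, `fail_short`, `total`), and
#'   `per_sample` totals.
#' @export
demultiplex <- function(reads, barcodes, enzyme = "FseI", trim3 = 1,
                        min_tag_len = 20) {
  if (inherits(reads, "dg_simreads")) reads <- reads$reads$read
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    ss <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- as.character(ss)
  }
  if (!is.null(dim(reads))) stop("reads must be sequences, a path or sim output")
  if (!is.character(barcodes)) {
    bc <- setNames(barcodes$barcode, barcodes$sample)
  } else {
    bc <- barcodes
    if (is.null(names(bc))) names(bc) <- paste0("S", seq_along(bc))
  }
  if (length(unique(nchar(bc))) > 1) stop("barcodes must have equal length")
  if (anyDuplicated(bc)) stop("barcodes must be distinct")
  bl <- unique(nchar(bc))
  remnant <- get_enzyme(enzyme)$remnant
  rl <- nchar(remnant)

  n <- length(reads)
  if (n == 0) {
    return(structure(list(
      observations = tibble::tibble(sample = character(),
                                    tag_seq = character()),
      stats = tibble::tibble(pass = 0L, fail_barcode = 0L,
                             fail_remnant = 0L, fail_short = 0L, total = 0L),
      per_sample = tibble::tibble(sample = names(bc), n_reads = 0L)),
      class = "dg_demux"))
  }
  reads <- toupper(reads)
  rb <- substr(reads, 1, bl)
  sample <- names(bc)[match(rb, bc)]
  ok_bc <- !is.na(sample)
  ok_rem <- ok_bc & substr(reads, bl + 1, bl + rl) == remnant
  tag <- substr(reads, bl + rl + 1, nchar(reads) - trim3)
  ok_len <- nchar(tag) >= min_tag_len
  pass <- ok_rem & ok_len
  obs <- tibble::tibble(sample = sample[pass], tag_seq = tag[pass])
  stats <- tibble::tibble(
    pass = sum(pass),
    fail_barcode = sum(!ok_bc),
    fail_remnant = sum(ok_bc & !ok_rem),
    fail_short = sum(ok_rem & !ok_len),
    total = n)
  per_sample <- obs |>
    dplyr::count(.data$sample, name = "n_reads") |>
    tidyr::complete(sample = names(bc), fill = list(n_reads = 0L))
  structure(list(observations = obs, stats = stats,
                 per_sample = per_sample), class = "dg_demux")
}

#' Collapse identical tags to depth counts
#'
#' One record per distinct (sample, tag sequence); depths sum to the
#' input read count. Output is sorted by sample then tag sequence, so it
#' is independent of read order.
#'
#' @param observations Tibble `sample`, `tag_seq` (e.g. from
#'   [demultiplex()]), or a `dg_demux` object.
#' @return Tibble: `sample`, `tag_seq`, `depth`.
#' @export
collapse_tags <- function(observations) {
  if (inherits(observations, "dg_demux"))
    observations <- observations$observations
  observations |>
    dplyr::count(.data$sample, .data$tag_seq, name = "depth") |>
    dplyr::arrange(.data$sample, .data$tag_seq)
}
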