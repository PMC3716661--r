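#' Place tags on a reference by bounded-mismatch seeded search
#'
#' A seed-and-verify short-tag matcher: the reference is indexed by exact
#' `seed_len`-mers; each tag is partitioned into `max_mm + 1` segments
#' (pigeonhole: any placement with at most `max_mm` mismatches leaves at
#' least one segment exact), candidate positions are taken from the first
#' `seed_len` bases of each segment and verified by full-length Hamming
#' comparison. Both strands are searched. On small references the result
#' is identical to an exhaustive Hamming scan.
#'
#' @param tags Tibble with columns `tag_id` and `tag_seq`, or a character
#'   vector of sequences (ids are derived from names or position).
#' @param reference Reference genome (see [as_genome()]).
#' @param seed_len Exact-seed length (default 7, mirroring a BLAST word
#'   size of 7).
#' @param max_mm Maximum mismatches (default 3).
#' @param both_strands Search the reverse complement too (default TRUE).
#' @return Tibble of placements: `tag_id`, `chrom`, `start` (0-based),
#'   `strand` ("+"/"-"), `mismatches`, ordered by tag then mismatches.
#'   Tags with no placement are absent; see [summarize_placements()].
#' @export
place_tags <- function(tags, reference, seed_len = 7, max_mm = 3,
                       both_strands = TRUE) {
  if (is.character(tags)) {
    ids <- if (!is.null(names(tags))) names(tags) else as.character(seq_along(tags))
    tags <- tibble::tibble(tag_id = ids, tag_seq = unname(tags))
  }
  stopifnot(all(c("tag_id", "tag_seq") %in% names(tags)))
  genome <- as_genome(reference)
  if (nrow(tags) == 0) {
    return(tibble::tibble(tag_id = character(), chrom = character(),
                          start = integer(), strand = character(),
                          mismatches = integer()))
  }
  if (any(nchar(tags$tag_seq) < seed_len))
    stop("seed_len exceeds the shortest tag length")
  res <- .place_tags_cpp(toupper(tags$tag_seq), unname(genome),
                         as.integer(seed_len), as.integer(max_mm),
                         isTRUE(both_strands))
  tibble::tibble(
    tag_id = tags$tag_id[res$tag],
    chrom = names(genome)[res$chrom],
    start = as.integer(res$start),
    strand = ifelse(res$strand == 1L, "+", "-"),
    mismatches = res$mismatches) |>
    dplyr::arrange(match(.data$tag_id, tags$tag_id), .data$mismatches,
                   .data$chrom, .data$start)
}

#' Summarize placements to best hit per tag
#'
#' @param placements Output of [place_tags()].
#' @param tag_ids Optional full set of tag ids so unplaced tags appear
#'   with `n_placements = 0`.
#' @return Tibble: `tag_id`, `chrom`, `start`, `strand`, `mismatches`
#'   (best hit), `second_best_mismatches` (NA when single placement),
#'   `n_placements`.
#' @export
summarize_placements <- function(placements, tag_ids = NULL) {
  if (nrow(placements) == 0) {
    s <- tibble::tibble(tag_id = character(), chrom = character(),
                        start = integer(), strand = character(),
                        mismatches = integer(),
                        second_best_mismatches = integer(),
                        n_placements = integer())
    if (!is.null(tag_ids)) {
      s <- tibble::tibble(tag_id = tag_ids, chrom = NA_character_,
                          start = NA_integer_, strand = NA_character_,
                          mismatches = NA_integer_,
                          second_best_mismatches = NA_integer_,
                          n_placements = 0L)
    }
    return(s)
  }
  s <- placements |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::arrange(.data$mismatches, .by_group = TRUE) |>
    dplyr::summarize(
      chrom = dplyr::first(.data$chrom),
      start = dplyr::first(.data$start),
      strand = dplyr::first(.data$strand),
      second_best_mismatches = ifelse(dplyr::n() > 1,
                                      dplyr::nth(.data$mismatches, 2),
                                      NA_integer_),
      n_placements = dplyr::n(),
      mismatches = dplyr::first(.data$mismatches),
      .groups = "drop") |>
    dplyr::relocate("mismatches", .before = "second_best_mismatches")
  if (!is.null(tag_ids)) {
    missing <- setdiff(tag_ids, s$tag_id)
    if (length(missing)) {
      s <- dplyr::bind_rows(s, tibble::tibble(
        tag_id = missing, chrom = NA_character_, start = NA_integer_,
        strand = NA_character_, mismatches = NA_integer_,
        second_best_mismatches = NA_integer_, n_placements = 0L))
    }
    s <- s[match(tag_ids, s$tag_id), ]
  }
  s
}

#' Is a placement unique under the margin rule?
#'
#' Unique means a single placement, or a best placement whose mismatch
#' count beats the second best by at least `margin` (default 2 bp).
#'
#' @param summary Output of [summarize_placements()].
#' @param margin Required mismatch gap.
#' @return Logical vector (NA when unplaced).
#' @export
placement_unique <- function(summary, margin = 2) {
  ifelse(summary$n_placements == 0, NA,
         summary$n_placements == 1 |
           (summary$second_best_mismatches - summary$mismatches) >= margin)
}
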