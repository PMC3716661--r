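#' Anchored comparison of two parental tag sequences
#'
#' Global (end-anchored) alignment with match +2, mismatch -3, linear gap
#' -5; any gap makes the variant an INDEL, otherwise a SNP. The variant
#' offset is the distance (bp, 0-based) of the first difference from the
#' tag's 5' end, i.e. from the restriction site.
#'
#' @param a,b Tag sequences (parent A, parent B).
#' @return List: `identical`, `variant_type` ("SNP"/"INDEL"/NA),
#'   `variant_offset`, `score`.
#' @export
compare_tags <- function(a, b) {
  if (a == b)
    return(list(identical = TRUE, variant_type = NA_character_,
                variant_offset = NA_integer_, score = 2 * nchar(a)))
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  has_gap <- any(pat == "-") || any(sub == "-")
  diffc <- which(pat != sub)[1]
  offset <- sum(pat[seq_len(diffc)] != "-") - 1L
  list(identical = FALSE,
       variant_type = if (has_gap) "INDEL" else "SNP",
       variant_offset = as.integer(offset),
       score = BiocGenerics::score(pa))
}

all_kmers <- function(seqs, k) {
  purrr::map(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Discover polymorphic markers between two parental tag sets
#'
#' Tags sequenced at least `min_depth` times in a parent enter the
#' comparison. Each is placed on the reference by bounded-mismatch search;
#' only uniquely placing tags (margin rule, see [classify_uniqueness()])
#' are used. Parent tags anchored at the same placement (site, side) are
#' compared by anchored global alignment: any difference yields one
#' marker, typed SNP (substitutions only) or INDEL (any gap). Parent-B
#' tags that fail genome-wide placement (indel-shifted tags are searched
#' only by mismatch count) are rescued by seed-sharing against the
#' parent-A catalog and paired through the anchored alignment. Sites seen
#' in only one parent are reported separately as presence/absence
#' candidates and excluded from the marker catalog.
#'
#' @param tags_a,tags_b Collapsed tag tibbles (`tag_seq`, `depth`; a
#'   `sample` column is ignored) for parents A and B.
#' @param reference Reference genome (parent A assembly).
#' @param min_depth Minimum tag depth for discovery (default 3).
#' @param seed_len,max_mm,margin Placement parameters (see [place_tags()]).
#' @param min_rescue_score Minimum anchored-alignment score to accept a
#'   seed-share rescue pairing (default 15; a single 1-3 bp indel plus
#'   a SNP in a fixed-length tag pair scores ~20-25 because the indel
#'   forces a compensating end gap, while unrelated tag pairs score
#'   deeply negative).
#' @return List of class `dg_marker_catalog`: `markers` (tibble:
#'   `marker_id`, `chrom`, `pos`, `side`, `alleleA_seq`, `alleleB_seq`,
#'   `variant_type`, `variant_offset`, `depth_a`, `depth_b`),
#'   `presence_absence`, `stats`.
#' @export
discover_markers <- function(tags_a, tags_b, reference, min_depth = 3,
                             seed_len = 7, max_mm = 3, margin = 2,
                             min_rescue_score = 15) {
  agg <- function(x) x |>
    dplyr::group_by(.data$tag_seq) |>
    dplyr::summarize(depth = sum(.data$depth), .groups = "drop") |>
    dplyr::filter(.data$depth >= min_depth)
  da <- agg(tags_a); db <- agg(tags_b)

  place_parent <- function(d, prefix) {
    if (nrow(d) == 0) {
      return(tibble::tibble(tag_id = character(), tag_seq = character(),
                            depth = integer(), chrom = character(),
                            start = integer(), strand = character(),
                            n_placements = integer(), unique = logical()))
    }
    d$tag_id <- paste0(prefix, seq_len(nrow(d)))
    pl <- place_tags(d[, c("tag_id", "tag_seq")], reference,
                     seed_len = seed_len, max_mm = max_mm)
    s <- summarize_placements(pl, tag_ids = d$tag_id)
    s$unique <- placement_unique(s, margin)
    dplyr::left_join(d, s[, c("tag_id", "chrom", "start", "strand",
                              "n_placements", "unique")], by = "tag_id")
  }
  pa <- place_parent(da, "A")
  pb <- place_parent(db, "B")

  ua <- pa[!is.na(pa$unique) & pa$unique, ]
  ub <- pb[!is.na(pb$unique) & pb$unique, ]
  # one tag per anchor per parent: keep deepest (error tags are shallow)
  dedupe <- function(u) u |>
    dplyr::group_by(.data$chrom, .data$start, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$depth), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  ua <- dedupe(ua); ub <- dedupe(ub)

  paired <- dplyr::inner_join(
    ua[, c("chrom", "start", "strand", "tag_seq", "depth")],
    ub[, c("chrom", "start", "strand", "tag_seq", "depth")],
    by = c("chrom", "start", "strand"), suffix = c("_a", "_b"))

  # rescue unplaced parent-B tags (indel-shifted) by seed sharing
  unplaced_b <- pb[pb$n_placements == 0, ]
  n_rescued <- 0L
  if (nrow(unplaced_b) > 0 && nrow(ua) > 0) {
    a_left <- ua[!paste(ua$chrom, ua$start, ua$strand) %in%
                   paste(paired$chrom, paired$start, paired$strand), ]
    if (nrow(a_left) > 0) {
      akm <- all_kmers(a_left$tag_seq, seed_len)
      akey <- tibble::tibble(
        idx = rep(seq_along(akm), lengths(akm)), kmer = unlist(akm))
      for (i in seq_len(nrow(unplaced_b))) {
        bkm <- all_kmers(unplaced_b$tag_seq[i], seed_len)[[1]]
        hits <- akey[akey$kmer %in% bkm, ] |>
          dplyr::count(.data$idx, sort = TRUE)
        if (nrow(hits) == 0) next
        cand <- utils::head(hits$idx, 3)
        best <- NULL; best_score <- -Inf
        for (j in cand) {
          cmp <- compare_tags(a_left$tag_seq[j], unplaced_b$tag_seq[i])
          if (cmp$score > best_score) { best <- j; best_score <- cmp$score }
        }
        if (best_score >= min_rescue_score) {
          paired <- dplyr::bind_rows(paired, tibble::tibble(
            chrom = a_left$chrom[best], start = a_left$start[best],
            strand = a_left$strand[best],
            tag_seq_a = a_left$tag_seq[best], depth_a = a_left$depth[best],
            tag_seq_b = unplaced_b$tag_seq[i],
            depth_b = unplaced_b$depth[i]))
          n_rescued <- n_rescued + 1L
        }
      }
    }
  }
  paired <- dedupe_pair(paired)

  cmped <- purrr::map(seq_len(nrow(paired)), function(i)
    compare_tags(paired$tag_seq_a[i], paired$tag_seq_b[i]))
  paired$identical <- purrr::map_lgl(cmped, "identical")
  paired$variant_type <- purrr::map_chr(cmped, "variant_type")
  paired$variant_offset <- purrr::map_int(cmped, "variant_offset")

  mk <- paired[!paired$identical, ]
  mk$side <- ifelse(mk$strand == "+", "F", "B")
  mk <- dplyr::arrange(mk, .data$chrom, .data$start)
  mk <- mk |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(marker_id = paste(.data$chrom, .data$side,
                                    dplyr::row_number(), sep = "_")) |>
    dplyr::ungroup()
  markers <- tibble::tibble(
    marker_id = mk$marker_id, chrom = mk$chrom, pos = mk$start,
    side = mk$side, alleleA_seq = mk$tag_seq_a, alleleB_seq = mk$tag_seq_b,
    variant_type = mk$variant_type, variant_offset = mk$variant_offset,
    depth_a = mk$depth_a, depth_b = mk$depth_b)

  pa_key <- paste(paired$chrom, paired$start, paired$strand)
  only_a <- ua[!paste(ua$chrom, ua$start, ua$strand) %in% pa_key, ]
  only_b <- ub[!paste(ub$chrom, ub$start, ub$strand) %in% pa_key, ]
  pres_abs <- dplyr::bind_rows(
    if (nrow(only_a)) tibble::tibble(chrom = only_a$chrom,
                                     pos = only_a$start,
                                     present_in = "A",
                                     tag_seq = only_a$tag_seq,
                                     depth = only_a$depth) else NULL,
    if (nrow(only_b)) tibble::tibble(chrom = only_b$chrom,
                                     pos = only_b$start,
                                     present_in = "B",
                                     tag_seq = only_b$tag_seq,
                                     depth = only_b$depth) else NULL)
  if (is.null(pres_abs)) pres_abs <- tibble::tibble(
    chrom = character(), pos = integer(), present_in = character(),
    tag_seq = character(), depth = integer())

  stats <- tibble::tibble(
    n_tags_a = nrow(da), n_tags_b = nrow(db),
    n_unique_a = nrow(ua), n_unique_b = nrow(ub),
    n_repetitive_a = sum(!pa$unique, na.rm = TRUE),
    n_repetitive_b = sum(!pb$unique, na.rm = TRUE),
    n_multi_site_excluded = sum(!pa$unique, na.rm = TRUE) +
      sum(!pb$unique, na.rm = TRUE),
    n_rescued_indel = n_rescued,
    n_compared = nrow(paired),
    n_monomorphic = sum(paired$identical),
    n_markers = nrow(markers),
    n_presence_absence = nrow(pres_abs))
  structure(list(markers = markers, presence_absence = pres_abs,
                 stats = stats), class = "dg_marker_catalog")
}

dedupe_pair <- function(paired) {
  if (nrow(paired) == 0) return(paired)
  paired |>
    dplyr::group_by(.data$chrom, .data$start, .data$strand) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Per-bin density track
#'
#' Counts features (markers, sites) in fixed-width bins along each
#' chromosome and expresses each bin as a percent of that chromosome's
#' total — the layout used for marker-density heat maps.
#'
#' @param x Tibble with `chrom` and `pos` (or `start`).
#' @param bin_bp Bin width in bp (> 0).
#' @param chrom_lengths Optional named vector of chromosome lengths so
#'   trailing empty bins are included.
#' @return Tibble: `chrom`, `bin_start`, `bin_end`, `n`, `pct`.
#' @export
density_track <- function(x, bin_bp, chrom_lengths = NULL) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  poscol <- if ("pos" %in% names(x)) "pos" else "start"
  ends <- if (!is.null(chrom_lengths)) chrom_lengths else
    tapply(x[[poscol]], x$chrom, max) + 1
  purrr::map_dfr(unique(x$chrom), function(ch) {
    len <- ends[[ch]]
    breaks <- seq(0, ceiling(len / bin_bp) * bin_bp, by = bin_bp)
    pos <- x[[poscol]][x$chrom == ch]
    n <- as.integer(table(cut(pos, breaks, right = FALSE)))
    tibble::tibble(chrom = ch, bin_start = breaks[-length(breaks)],
                   bin_end = breaks[-1], n = n,
                   pct = if (sum(n) > 0) 100 * n / sum(n) else 0)
  })
}

#' @export
print.dg_marker_catalog <- function(x, ...) {
  cat("Digital genotyping marker catalog\n")
  cat(sprintf("  %d markers (%d SNP, %d INDEL), %d monomorphic sites compared\n",
              nrow(x$markers), sum(x$markers$variant_type == "SNP"),
              sum(x$markers$variant_type == "INDEL"),
              x$stats$n_monomorphic))
  cat(sprintf("  %d presence/absence candidates (excluded from catalog)\n",
              x$stats$n_presence_absence))
  invisible(x)
}

#' @export
tidy.dg_marker_catalog <- function(x, ...) x$markers

#' @export
glance.dg_marker_catalog <- function(x, ...) x$stats
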