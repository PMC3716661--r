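#' Genotype-calling policy
#'
#' Two depth-ratio policies for turning per-marker allele counts into
#' genotype calls:
#'
#' * `initial`: fewer than 4 reads is missing; an allele ratio above 4:1
#'   is homozygous for the major allele; 4:1 or less is heterozygous.
#' * `refined`: heterozygous only when both alleles are seen at least 3
#'   times, the ratio is below 15:1 and the total is at least 15 reads;
#'   homozygous when a single allele dominates (minor allele under 3
#'   reads, or ratio at least 15:1) with at least 4 reads total; fewer
#'   than 4 reads, or the ambiguous residue (total 4-14 with both
#'   alleles at 3 or more), is missing.
#'
#' A zero minor count is treated as an infinite ratio.
#'
#' @param name `"initial"` or `"refined"`.
#' @param min_total_missing Depth below which the call is missing.
#' @param hom_ratio Initial-policy homozygous ratio threshold.
#' @param het_min_each Refined: minimum reads per allele for HET.
#' @param het_max_ratio Refined: maximum ratio for HET.
#' @param het_min_total Refined: minimum total reads for HET.
#' @return List of class `dg_policy`.
#' @export
call_policy <- function(name = c("initial", "refined"),
                        min_total_missing = 4, hom_ratio = 4,
                        het_min_each = 3, het_max_ratio = 15,
                        het_min_total = 15) {
  name <- match.arg(name)
  th <- c(min_total_missing, hom_ratio, het_min_each, het_max_ratio,
          het_min_total)
  if (any(th <= 0)) stop("policy thresholds must be positive")
  structure(list(name = name, min_total_missing = min_total_missing,
                 hom_ratio = hom_ratio, het_min_each = het_min_each,
                 het_max_ratio = het_max_ratio,
                 het_min_total = het_min_total), class = "dg_policy")
}

#' Count marker alleles in collapsed sample tags
#'
#' Exact-match lookup of each parental allele sequence in each sample's
#' collapsed tag table; tags at the marker site matching neither allele
#' exactly (placed within `max_mm` mismatches of either allele) are
#' counted as `count_other`. `count_other` is reported but excluded from
#' calling ratios.
#'
#' @param tags Collapsed tags (`sample`, `tag_seq`, `depth`).
#' @param markers Marker catalog ([discover_markers()] result) or its
#'   `markers` tibble.
#' @param max_mm Mismatch bound for the `count_other` search.
#' @param count_other Compute `count_other` (default TRUE; turning it
#'   off skips the near-match search).
#' @return Tibble: `marker_id`, `sample`, `count_a`, `count_b`,
#'   `count_other`, for every marker x sample combination.
#' @export
count_alleles <- function(tags, markers, max_mm = 3, count_other = TRUE) {
  mk <- if (inherits(markers, "dg_marker_catalog")) markers$markers else markers
  samples <- unique(tags$sample)
  exact <- function(allele_col, out) {
    tags |>
      dplyr::inner_join(setNames(mk[, c("marker_id", allele_col)],
                                 c("marker_id", "tag_seq")),
                        by = "tag_seq", relationship = "many-to-many") |>
      dplyr::group_by(.data$marker_id, .data$sample) |>
      dplyr::summarize(!!out := sum(.data$depth), .groups = "drop")
  }
  ca <- exact("alleleA_seq", "count_a")
  cb <- exact("alleleB_seq", "count_b")
  grid <- tidyr::crossing(marker_id = mk$marker_id, sample = samples)
  out <- grid |>
    dplyr::left_join(ca, by = c("marker_id", "sample")) |>
    dplyr::left_join(cb, by = c("marker_id", "sample")) |>
    dplyr::mutate(count_a = dplyr::coalesce(.data$count_a, 0L),
                  count_b = dplyr::coalesce(.data$count_b, 0L),
                  count_other = 0L)
  if (count_other) {
    rest <- tags[!(tags$tag_seq %in% mk$alleleA_seq |
                     tags$tag_seq %in% mk$alleleB_seq), ]
    rest <- rest[nchar(rest$tag_seq) >= 7, ]
    if (nrow(rest) > 0) {
      ref <- c(setNames(mk$alleleA_seq, paste0(mk$marker_id, "|A")),
               setNames(mk$alleleB_seq, paste0(mk$marker_id, "|B")))
      uniq <- unique(rest$tag_seq)
      pl <- place_tags(tibble::tibble(tag_id = uniq, tag_seq = uniq),
                       ref, seed_len = 7, max_mm = max_mm,
                       both_strands = FALSE)
      if (nrow(pl) > 0) {
        best <- pl |>
          dplyr::mutate(marker_id = sub("\\|[AB]$", "", .data$chrom)) |>
          dplyr::group_by(.data$tag_id) |>
          dplyr::arrange(.data$mismatches, .by_group = TRUE) |>
          dplyr::slice(1) |>
          dplyr::ungroup() |>
          dplyr::filter(.data$mismatches >= 1)
        oth <- rest |>
          dplyr::inner_join(best[, c("tag_id", "marker_id")],
                            by = c(tag_seq = "tag_id")) |>
          dplyr::group_by(.data$marker_id, .data$sample) |>
          dplyr::summarize(n_other = sum(.data$depth), .groups = "drop")
        out <- out |>
          dplyr::left_join(oth, by = c("marker_id", "sample")) |>
          dplyr::mutate(count_other = dplyr::coalesce(.data$n_other, 0L),
                        n_other = NULL)
      }
    }
  }
  dplyr::arrange(out, .data$marker_id, .data$sample)
}

#' Call genotypes from allele counts
#'
#' Applies a [call_policy()] to each row. `count_other` is ignored in
#' ratios. Deterministic and total over non-negative counts; ties
#' (equal counts at a homozygous decision) go to allele A.
#'
#' @param counts Tibble with `count_a`, `count_b` (e.g. from
#'   [count_alleles()]).
#' @param policy A [call_policy()].
#' @return `counts` with a `call` column in `{"A","B","H","-"}`.
#' @export
call_genotypes <- function(counts, policy = call_policy("initial")) {
  a <- counts$count_a; b <- counts$count_b
  if (any(a < 0 | b < 0)) stop("negative allele counts")
  tot <- a + b
  major <- pmax(a, b); minor <- pmin(a, b)
  ratio <- ifelse(minor == 0, Inf, major / minor)
  hom <- ifelse(a >= b, "A", "B")
  if (policy$name == "initial") {
    call <- ifelse(tot < policy$min_total_missing, "-",
                   ifelse(ratio > policy$hom_ratio, hom, "H"))
  } else {
    call <- ifelse(
      tot < policy$min_total_missing, "-",
      ifelse(a >= policy$het_min_each & b >= policy$het_min_each &
               ratio < policy$het_max_ratio & tot >= policy$het_min_total,
             "H",
             ifelse(minor < policy$het_min_each |
                      ratio >= policy$het_max_ratio, hom, "-")))
  }
  counts$call <- call
  counts
}

#' Build the segregation matrix
#'
#' Drops markers whose missing fraction reaches `max_missing_frac`
#' (strict reading: a marker missing in exactly 15% of lines is dropped,
#' one just under is kept) and orders markers by physical coordinates.
#'
#' @param calls Long tibble `marker_id`, `sample`, `call`.
#' @param markers Marker catalog or tibble with `marker_id`, `chrom`,
#'   `pos`.
#' @param max_missing_frac Missing-data threshold per marker
#'   (default 0.15).
#' @return Object of class `dg_genotypes`: `calls` (wide tibble:
#'   `marker_id`, `chrom`, `pos`, one column per sample), `samples`,
#'   `dropped` (tibble of removed markers with their missing fractions).
#' @export
build_genotype_matrix <- function(calls, markers,
                                  max_missing_frac = 0.15) {
  mk <- if (inherits(markers, "dg_marker_catalog")) markers$markers else markers
  miss <- calls |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarize(missing_frac = mean(.data$call == "-"),
                     .groups = "drop")
  dropped <- miss[miss$missing_frac >= max_missing_frac, ]
  keep <- calls[!calls$marker_id %in% dropped$marker_id, ]
  wide <- keep |>
    dplyr::select("marker_id", "sample", "call") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "call") |>
    dplyr::left_join(mk[, c("marker_id", "chrom", "pos")],
                     by = "marker_id") |>
    dplyr::relocate("marker_id", "chrom", "pos") |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(list(calls = wide,
                 samples = setdiff(names(wide),
                                   c("marker_id", "chrom", "pos")),
                 dropped = dropped),
            class = "dg_genotypes")
}

calls_matrix <- function(gm) {
  m <- as.matrix(gm$calls[, gm$samples])
  rownames(m) <- gm$calls$marker_id
  m
}

#' Remove markers with identical segregation
#'
#' Among markers whose call vectors are exactly equal (including missing
#' positions), only the one with the smallest physical coordinate is
#' kept. The number removed is attached as attribute `n_removed`.
#'
#' @param gm A `dg_genotypes` object.
#' @return Filtered `dg_genotypes` (attribute `n_removed`).
#' @export
drop_redundant <- function(gm) {
  m <- calls_matrix(gm)
  key <- apply(m, 1, paste, collapse = "")
  ord <- order(gm$calls$chrom, gm$calls$pos)
  first <- !duplicated(key[ord])
  keep_ids <- gm$calls$marker_id[ord][first]
  out <- gm
  out$calls <- gm$calls[gm$calls$marker_id %in% keep_ids, ]
  attr(out, "n_removed") <- nrow(gm$calls) - nrow(out$calls)
  out
}

#' @export
print.dg_genotypes <- function(x, ...) {
  m <- calls_matrix(x)
  cat(sprintf("Digital genotype matrix: %d markers x %d samples\n",
              nrow(m), ncol(m)))
  tab <- table(factor(m, levels = c("A", "B", "H", "-")))
  cat(sprintf("  A %.1f%%  B %.1f%%  H %.1f%%  missing %.1f%%\n",
              100 * tab["A"] / sum(tab), 100 * tab["B"] / sum(tab),
              100 * tab["H"] / sum(tab), 100 * tab["-"] / sum(tab)))
  if (nrow(x$dropped) > 0)
    cat(sprintf("  %d markers dropped for missing data\n", nrow(x$dropped)))
  invisible(x)
}

#' @export
tidy.dg_genotypes <- function(x, ...) {
  x$calls |>
    tidyr::pivot_longer(dplyr::all_of(x$samples), names_to = "sample",
                        values_to = "call")
}

#' @export
glance.dg_genotypes <- function(x, ...) {
  m <- calls_matrix(x)
  tab <- table(factor(m, levels = c("A", "B", "H", "-")))
  tibble::tibble(n_markers = nrow(m), n_samples = ncol(m),
                 prop_a = unname(tab["A"]) / sum(tab),
                 prop_b = unname(tab["B"]) / sum(tab),
                 prop_h = unname(tab["H"]) / sum(tab),
                 prop_missing = unname(tab["-"]) / sum(tab),
                 n_dropped = nrow(x$dropped))
}
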