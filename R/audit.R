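#' Audit genotyping accuracy from homozygous haplotypes
#'
#' Within homozygous haplotype blocks — runs of at least `min_run`
#' consecutive concordant homozygous calls along the physical marker
#' order of a line — only one allele should ever be sequenced. The audit
#' counts reads of the expected (block) allele versus the alternative
#' allele, tabulates how many marker cells saw 0, 1, 2, ... alternative
#' reads, measures concordance of marker pairs derived from the same
#' restriction site (opposite flanks, so physically within two tag
#' lengths), and reports overall genotype-class proportions.
#'
#' @param gm A `dg_genotypes` object.
#' @param counts Allele counts ([count_alleles()] output, with or
#'   without calls).
#' @param min_run Minimum run length defining a homozygous block.
#' @param pair_max_bp Maximum physical separation for a co-site marker
#'   pair (default 2 x 41 bp).
#' @return List of class `dg_audit`: `expected_reads`, `alt_reads`,
#'   `expected_pct`, `alt_histogram` (tibble `n_alt`, `n_cells`),
#'   `n_cells_audited`, `pair_concordance` (both calls homozygous, the
#'   regime the audit is about), `n_pairs_compared`,
#'   `pair_concordance_all` / `n_pairs_compared_all` (any assigned
#'   calls), `class_proportions`.
#' @export
audit_accuracy <- function(gm, counts, min_run = 3, pair_max_bp = 82) {
  m <- calls_matrix(gm)
  meta <- gm$calls[, c("marker_id", "chrom", "pos")]
  cnt <- counts
  cnt$key <- paste(cnt$marker_id, cnt$sample)

  exp_reads <- 0; alt_reads <- 0
  alt_per_cell <- integer(0)
  for (s in colnames(m)) {
    v <- m[, s]
    for (ch in unique(meta$chrom)) {
      idx <- which(meta$chrom == ch)
      calls <- v[idx]
      hom <- calls %in% c("A", "B")
      r <- rle(ifelse(hom, calls, "x"))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (r$values[k] == "x" || r$lengths[k] < min_run) next
        block_ids <- meta$marker_id[idx[starts[k]:ends[k]]]
        cc <- cnt[cnt$key %in% paste(block_ids, s), ]
        if (nrow(cc) == 0) next
        e <- if (r$values[k] == "A") cc$count_a else cc$count_b
        a <- if (r$values[k] == "A") cc$count_b else cc$count_a
        exp_reads <- exp_reads + sum(e)
        alt_reads <- alt_reads + sum(a)
        alt_per_cell <- c(alt_per_cell, a)
      }
    }
  }
  hist <- tibble::tibble(n_alt = sort(unique(alt_per_cell))) |>
    dplyr::mutate(n_cells = vapply(.data$n_alt, function(x)
      sum(alt_per_cell == x), integer(1)))

  # co-site pairs: opposite flanks of one digestion site
  pairs <- meta |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(next_id = dplyr::lead(.data$marker_id),
                  gap = dplyr::lead(.data$pos) - .data$pos) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap), .data$gap <= pair_max_bp)
  n_comp <- 0L; n_agree <- 0L; n_comp_all <- 0L; n_agree_all <- 0L
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      c1 <- m[pairs$marker_id[k], ]
      c2 <- m[pairs$next_id[k], ]
      ok <- c1 != "-" & c2 != "-"
      n_comp_all <- n_comp_all + sum(ok)
      n_agree_all <- n_agree_all + sum(c1[ok] == c2[ok])
      hom <- c1 %in% c("A", "B") & c2 %in% c("A", "B")
      n_comp <- n_comp + sum(hom)
      n_agree <- n_agree + sum(c1[hom] == c2[hom])
    }
  }

  tab <- table(factor(m, levels = c("A", "B", "H", "-")))
  structure(list(
    expected_reads = exp_reads, alt_reads = alt_reads,
    expected_pct = if (exp_reads + alt_reads > 0)
      100 * exp_reads / (exp_reads + alt_reads) else NA_real_,
    alt_histogram = hist,
    n_cells_audited = length(alt_per_cell),
    pair_concordance = if (n_comp > 0) n_agree / n_comp else NA_real_,
    n_pairs_compared = n_comp,
    pair_concordance_all = if (n_comp_all > 0)
      n_agree_all / n_comp_all else NA_real_,
    n_pairs_compared_all = n_comp_all,
    class_proportions = setNames(as.numeric(tab) / sum(tab), names(tab))),
    class = "dg_audit")
}

#' @export
print.dg_audit <- function(x, ...) {
  cat("Allele-assignment audit (homozygous haplotypes)\n")
  cat(sprintf("  expected allele reads: %d, alternative: %d (%.1f%% expected)\n",
              x$expected_reads, x$alt_reads, x$expected_pct))
  cat(sprintf("  co-site pair concordance: %s over %d comparisons\n",
              ifelse(is.na(x$pair_concordance), "NA",
                     sprintf("%.2f%%", 100 * x$pair_concordance)),
              x$n_pairs_compared))
  invisible(x)
}

#' Allele-audit arithmetic
#'
#' Summarizes an alternative-allele histogram: total alternative reads
#' (sum of multiplicity x cell count), total marker cells audited, and
#' the expected-allele percentage out of all reads analyzed.
#'
#' @param n_correct_only Marker cells where only the expected allele was
#'   seen.
#' @param alt_histogram Named numeric vector: names = alternative-read
#'   multiplicities, values = cell counts (e.g. `c("1"=183, "2"=25)`).
#' @param total_reads Total reads analyzed across audited cells.
#' @return Tibble: `n_categories`, `alt_reads`, `expected_pct`.
#' @examples
#' audit_arithmetic(1516, c("1" = 183, "2" = 25, "3" = 3, "4" = 1), 76032)
#' @export
audit_arithmetic <- function(n_correct_only, alt_histogram, total_reads) {
  mult <- as.numeric(names(alt_histogram))
  alt <- sum(mult * alt_histogram)
  tibble::tibble(
    n_categories = n_correct_only + sum(alt_histogram),
    alt_reads = alt,
    expected_pct = 100 * (total_reads - alt) / total_reads)
}

#' Heterozygote-policy validation on a simulated F1
#'
#' Every locus of an F1 is heterozygous, so genotyping an F1 measures the
#' false-homozygote rate of the calling policy directly. Per locus, total
#' depth is negative binomial around `depth_mean` and reads split
#' binomially (1:1) between the alleles; genotypes are then called. The
#' headline statistic is the percentage of assigned (non-missing) calls
#' that are heterozygous.
#'
#' @param n_markers Number of heterozygous loci (default 1200).
#' @param depth_mean Mean per-marker depth (default 41).
#' @param dispersion Negative-binomial dispersion (default 0.2).
#' @param policy A [call_policy()] (default refined).
#' @param seed RNG seed.
#' @param reps Number of replicates.
#' @return Tibble, one row per replicate: `rep`, `pct_h_called` (percent
#'   H among assigned calls), `pct_h_all` (percent H of all loci),
#'   `pct_missing`.
#' @export
f1_het_rate <- function(n_markers = 1200, depth_mean = 41,
                        dispersion = 0.2,
                        policy = call_policy("refined"),
                        seed = 1, reps = 1) {
  purrr::map_dfr(seq_len(reps), function(r) {
    set.seed(substream_seed(seed, paste0("f1rep", r)))
    d <- rnbinom(n_markers, size = 1 / dispersion, mu = depth_mean)
    a <- rbinom(n_markers, d, 0.5)
    calls <- call_genotypes(
      tibble::tibble(count_a = a, count_b = d - a), policy)$call
    tibble::tibble(
      rep = r,
      pct_h_called = 100 * sum(calls == "H") / max(sum(calls != "-"), 1),
      pct_h_all = 100 * mean(calls == "H"),
      pct_missing = 100 * mean(calls == "-"))
  })
}
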