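test_that("zero divergence yields identical parents and no markers", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_len = 40000,
                    snp_rate = 1e-9, knockout_rate = 0)
  par <- sim_parent_genomes(cfg)
  expect_identical(par$genomeA, par$genomeB)
  expect_equal(sum(par$truth$templates$polymorphic), 0L)
})

test_that("polymorphic-tag count matches the binomial expectation", {
  par <- fx_parents_default()
  t <- par$truth$templates
  t <- t[!t$repeat_flank & !t$truncated & !t$knockout_B, ]
  p <- 1 - (1 - par$config$snp_rate)^par$config$read_len
  expected <- nrow(t) * p
  sd3 <- 3 * sqrt(nrow(t) * p * (1 - p))
  expect_lt(abs(sum(t$polymorphic) - expected), sd3)
})

test_that("unique-flank site methylation matches its configured rate", {
  par <- fx_parents_default()
  s <- par$truth$sites[!par$truth$sites$repeat_flank, ]
  p <- par$config$p_meth_unique
  sd3 <- 3 * sqrt(p * (1 - p) / nrow(s))
  expect_lt(abs(mean(s$methylated) - p), sd3)
  srep <- par$truth$sites[par$truth$sites$repeat_flank, ]
  expect_gt(mean(srep$methylated), 0.8)
})

test_that("F1 lines are heterozygous at every variant locus", {
  par <- fx_parents_clean()
  ped <- sim_pedigree(par, par$config, "F1", 3)
  mk <- truth_markers(par)
  gt <- pedigree_genotypes(ped, mk)
  expect_true(all(gt$truth == "H"))
  expect_error(sim_pedigree(par, par$config, "RIL", 0), "n_lines")
})

test_that("RIL residual heterozygosity matches the selfing expectation", {
  par <- fx_parents_clean()
  cfg5 <- par$config
  cfg5$gens_self <- 5
  ped <- sim_pedigree(par, cfg5, "RIL", 137)
  mk <- truth_markers(par)
  gt <- pedigree_genotypes(ped, mk)
  line_het <- tapply(gt$truth == "H", gt$line_id, mean)
  se <- stats::sd(line_het) / sqrt(length(line_het))
  expect_lt(abs(mean(line_het) - 0.5^5), 3 * se + 1e-6)
})

test_that("without crossovers every RIL chromosome is one parental block", {
  par <- fx_parents_clean()
  cfg0 <- par$config
  cfg0$xover_rate <- 0
  ped <- sim_pedigree(par, cfg0, "RIL", 10)
  mk <- truth_markers(par)
  gt <- pedigree_genotypes(ped, mk)
  per_chrom <- tapply(gt$truth, list(gt$line_id, gt$chrom),
                      function(x) length(unique(x)))
  expect_true(all(per_chrom == 1))
})

test_that("error-free reads reproduce the truth flanks exactly", {
  par <- fx_parents_clean()
  sim <- fx_reads_clean()
  tpl <- par$truth$templates
  genomic <- substr(sim$reads$read, 4 + 6 + 1, nchar(sim$reads$read))
  expect_true(all(genomic %in% c(tpl$readA, tpl$readB)))
  # no reads from methylated sites; read conservation vs truth depths
  meth_ids <- tpl$template_id[tpl$methylated]
  expect_false(any(sim$reads$template_id %in% meth_ids))
  expect_equal(nrow(sim$reads), sum(sim$truth_depths$depth))
})

test_that("the same seed produces byte-identical FASTQ", {
  par <- fx_parents_clean()
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(sim_reads(par, NULL, par$config), f1)
  write_fastq(sim_reads(par, NULL, par$config), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("injected error fraction matches the per-base rate", {
  run <- fx_run24()
  reads <- run$sim$reads[!run$sim$reads$is_junk, ]
  L <- run$cfg$read_len + run$cfg$trim3
  p <- 1 - (1 - run$cfg$err_rate)^L
  frac <- mean(reads$n_errors > 0)
  sd3 <- 3 * sqrt(p * (1 - p) / nrow(reads))
  expect_lt(abs(frac - p), sd3)
})

test_that("length weights put ~4-6x more depth on 109 bp than 286 bp templates", {
  ratio <- length_weight(109) / length_weight(286)
  expect_gte(ratio, 4)
  expect_lte(ratio, 6)
  # monotone decline past the optimum; short templates nearly absent
  expect_gt(length_weight(148), length_weight(286))
  expect_lt(length_weight(50), 0.01)
})

test_that("with biases disabled per-site depths are exchangeable", {
  cfg <- sim_config(seed = 13, n_chrom = 1, chrom_len = 60000,
                    gc_beta = 0, site_sd = 0, pool_cv = 0,
                    err_rate = 0, junk_frac = 0)
  par <- sim_parent_genomes(cfg)
  ped <- sim_pedigree(par, cfg, "RIL", 30)
  sim <- sim_reads(par, ped, cfg, include_parents = FALSE)
  d <- sim$truth_depths |>
    dplyr::group_by(.data$template_id, .data$sample) |>
    dplyr::summarize(depth = sum(.data$depth), .groups = "drop")
  pooled <- d$depth
  ids <- unique(d$template_id)[1:5]
  for (id in ids) {
    p <- suppressWarnings(
      stats::ks.test(d$depth[d$template_id == id], pooled))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("duplicate barcodes are rejected", {
  par <- fx_parents_clean()
  expect_error(sim_reads(par, NULL, par$config, barcodes = c("ACGT", "ACGT")),
               "duplicate")
})
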