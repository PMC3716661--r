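cnt <- function(a, b) tibble::tibble(count_a = a, count_b = b)

test_that("the initial depth-ratio policy follows the 4-read / 4:1 rules", {
  pol <- call_policy("initial")
  expect_equal(call_genotypes(cnt(3, 0), pol)$call, "-")   # < 4 reads
  expect_equal(call_genotypes(cnt(10, 2), pol)$call, "A")  # 5:1 > 4:1
  expect_equal(call_genotypes(cnt(8, 4), pol)$call, "H")   # 2:1 <= 4:1
  expect_equal(call_genotypes(cnt(2, 10), pol)$call, "B")
  expect_equal(call_genotypes(cnt(4, 0), pol)$call, "A")   # zero minor = inf
  expect_error(call_genotypes(cnt(-1, 2), pol), "negative")
})

test_that("the refined policy adds the 3-read / 15:1 / 15-total HET rules", {
  pol <- call_policy("refined")
  expect_equal(call_genotypes(cnt(12, 3), pol)$call, "H")  # 4:1, total 15
  expect_equal(call_genotypes(cnt(26, 1), pol)$call, "A")  # skewed 26:1
  expect_equal(call_genotypes(cnt(3, 0), pol)$call, "-")
  expect_equal(call_genotypes(cnt(9, 1), pol)$call, "A")   # minor < 3
  expect_equal(call_genotypes(cnt(6, 5), pol)$call, "-")   # ambiguous 4-14
  expect_equal(call_genotypes(cnt(45, 3), pol)$call, "A")  # 15:1 at depth
  expect_equal(call_genotypes(cnt(44, 3), pol)$call, "H")  # just under 15:1
})

test_that("calling is deterministic and monotone under the initial policy", {
  pol <- call_policy("initial")
  set.seed(8)
  for (i in 1:200) {
    a <- rpois(1, 15); b <- rpois(1, 4)
    call1 <- call_genotypes(cnt(a, b), pol)$call
    expect_identical(call1, call_genotypes(cnt(a, b), pol)$call)
    if (call1 == "A") {
      # more major reads can never flip a homozygote to HET
      expect_equal(call_genotypes(cnt(a + 5, b), pol)$call, "A")
    }
  }
})

test_that("allele counting looks up exact parental sequences plus near-misses", {
  mk <- tibble::tibble(marker_id = "m1", chrom = "c1", pos = 100,
                       alleleA_seq = strrep("A", 33),
                       alleleB_seq = paste0(strrep("A", 16), "C",
                                            strrep("A", 16)))
  err_tag <- paste0("G", strrep("A", 32))  # 1 mismatch off allele A
  tags <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s2"),
    tag_seq = c(mk$alleleA_seq, err_tag, mk$alleleA_seq, mk$alleleB_seq,
                strrep("T", 33)),
    depth = c(40L, 2L, 11L, 9L, 50L))
  out <- count_alleles(tags, mk)
  s1 <- out[out$sample == "s1", ]
  expect_equal(c(s1$count_a, s1$count_b, s1$count_other), c(40L, 0L, 2L))
  s2 <- out[out$sample == "s2", ]
  expect_equal(c(s2$count_a, s2$count_b, s2$count_other), c(11L, 9L, 0L))
})

test_that("markers are dropped at 15% missing data, strictly", {
  mk <- tibble::tibble(marker_id = c("m1", "m2"), chrom = "c1",
                       pos = c(1, 2))
  samples <- sprintf("r%03d", 1:137)
  calls <- tidyr::crossing(marker_id = mk$marker_id, sample = samples)
  calls$call <- "A"
  calls$call[calls$marker_id == "m1"][1:21] <- "-"  # 15.3% -> dropped
  calls$call[calls$marker_id == "m2"][1:20] <- "-"  # 14.6% -> kept
  gm <- build_genotype_matrix(calls, mk, 0.15)
  expect_equal(gm$calls$marker_id, "m2")
  expect_equal(gm$dropped$marker_id, "m1")
})

test_that("redundant markers with identical segregation collapse to one", {
  mk <- tibble::tibble(marker_id = c("m1", "m2", "m3"), chrom = "c1",
                       pos = c(10, 20, 30))
  calls <- tidyr::crossing(marker_id = mk$marker_id,
                           sample = c("s1", "s2", "s3"))
  calls$call <- c("A", "B", "A")[match(calls$sample,
                                       c("s1", "s2", "s3"))]
  calls$call[calls$marker_id == "m3" & calls$sample == "s2"] <- "A"
  gm <- build_genotype_matrix(calls, mk, 0.9)
  gm2 <- drop_redundant(gm)
  expect_equal(attr(gm2, "n_removed"), 1L)
  expect_true(all(c("m1", "m3") %in% gm2$calls$marker_id))  # keep smallest pos
})

test_that("the RIL study reproduces the homozygous-audit signatures", {
  f <- fx_ril()
  calls <- f$calls
  # genotype calls agree with truth where assigned
  assigned <- calls[calls$call != "-", ]
  hom <- assigned[assigned$truth != "H", ]
  expect_gt(mean(hom$call == hom$truth), 0.995)
  # class proportions: A ~ B, H near (1/2)^6
  g <- glance(f$gm)
  expect_lt(abs(g$prop_a - g$prop_b), 0.06)
  expect_lt(abs(g$prop_h - 0.5^6), 0.015)
  aud <- audit_accuracy(f$gm, f$cnt)
  expect_gt(aud$expected_pct, 99)       # ~99.7% expected allele
  expect_gt(aud$pair_concordance, 0.999)
  # the alternative-allele histogram is dominated by single-read cells
  h <- aud$alt_histogram
  expect_equal(h$n_alt[which.max(h$n_cells)], 0L)
  if (nrow(h) > 2) expect_true(all(diff(h$n_cells[h$n_alt > 0]) <= 0))
})

test_that("an error-free study audits perfectly clean", {
  par <- fx_parents_clean()
  cfg <- par$config
  ped <- sim_pedigree(par, cfg, "RIL", 40)
  cntab <- sim_allele_counts(par, ped, cfg)
  calls <- call_genotypes(cntab, call_policy("initial"))
  mk <- truth_markers(par)
  gm <- build_genotype_matrix(calls, mk, 0.15)
  aud <- audit_accuracy(gm, calls)
  expect_equal(aud$alt_reads, 0)
  expect_equal(aud$expected_pct, 100)
  if (aud$n_pairs_compared > 0) expect_equal(aud$pair_concordance, 1)
})

test_that("a simulated F1 is called heterozygous at ~99% of assigned loci", {
  res <- f1_het_rate(n_markers = 1200, depth_mean = 41, dispersion = 0.2,
                     policy = call_policy("refined"), seed = 42, reps = 4)
  expect_gte(mean(res$pct_h_called), 99)
  expect_true(all(res$pct_h_all > 90))
})

test_that("export dialects match the MapMaker and JoinMap grammars", {
  mk <- tibble::tibble(marker_id = c("mA", "mB"), chrom = "c1",
                       pos = c(1, 2))
  calls <- tidyr::crossing(marker_id = mk$marker_id,
                           sample = c("s1", "s2", "s3"))
  calls$call <- c("A", "H", "-", "B", "B", "A")
  gm <- build_genotype_matrix(calls, mk, 0.9)
  f <- tempfile()
  write_mapmaker_raw(gm, f)
  raw <- readLines(f)
  expect_equal(raw[1], "data type ri self")
  expect_equal(raw[2], "3 2 0")
  expect_match(raw[3], "^\\*mA [ABH-]{3}$")
  write_joinmap_loc(gm, f, name = "pop", popt = "RI6")
  loc <- readLines(f)
  expect_equal(loc[1:4], c("name = pop", "popt = RI6", "nloc = 2",
                           "nind = 3"))
  expect_match(loc[7], "^  [abh-]( [abh-]){2}$")
  unlink(f)
})
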