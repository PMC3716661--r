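# construct a dg_genotypes object directly from a call matrix
gm_from_matrix <- function(m, chrom = "c1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 1000
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  calls <- tibble::as_tibble(m)
  calls <- dplyr::bind_cols(
    tibble::tibble(marker_id = rownames(m), chrom = chrom, pos = pos),
    calls)
  structure(list(calls = calls, samples = colnames(m),
                 dropped = tibble::tibble(marker_id = character(),
                                          missing_frac = double())),
            class = "dg_genotypes")
}

test_that("the Kosambi function matches its closed form and bounds", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-10)
  expect_equal(kosambi(0.49), 25 * log(99), tolerance = 1e-10)
  expect_error(kosambi(0.5), "0.5")
  rs <- seq(0.001, 0.499, by = 0.001)
  d <- kosambi(rs)
  expect_true(all(diff(d) > 0))          # monotone increasing
  expect_true(all(d >= 100 * rs))        # at least the additive distance
  expect_equal(kosambi_inv(kosambi(rs)), rs, tolerance = 1e-10)
})

test_that("the selfed-RIL correction round-trips to machine precision", {
  r <- seq(0, 0.499, by = 0.0001)
  expect_equal(ril_expect(ril_correct(ril_expect(r))), ril_expect(r),
               tolerance = 1e-12)
  expect_equal(ril_correct(0.0729927), 0.03937008, tolerance = 1e-6)
})

test_that("two-point estimates reproduce the worked recombination example", {
  # 10 recombinants among 137 informative lines
  m <- matrix("A", nrow = 2, ncol = 137,
              dimnames = list(c("m1", "m2"), NULL))
  m[1, 1:60] <- "B"; m[2, 1:60] <- "B"
  m[2, 1:10] <- ifelse(m[1, 1:10] == "A", "B", "A")
  gm <- gm_from_matrix(m)
  rf <- estimate_rf(gm, "m1", "m2")
  expect_equal(rf$n_informative, 137L)
  expect_equal(rf$n_recombinant, 10L)
  expect_equal(rf$R_obs, 10 / 137, tolerance = 1e-9)
  expect_equal(rf$r, 0.0394, tolerance = 1e-3)
  # identical vectors
  m2 <- m; m2[2, ] <- m2[1, ]
  rf0 <- estimate_rf(gm_from_matrix(m2), "m1", "m2")
  expect_equal(rf0$R_obs, 0)
  expect_equal(rf0$r, 0)
  # independent markers: R ~ 0.5, LOD ~ 0
  set.seed(3)
  m3 <- matrix(sample(c("A", "B"), 2 * 400, TRUE), nrow = 2,
               dimnames = list(c("m1", "m2"), NULL))
  rf5 <- estimate_rf(gm_from_matrix(m3), "m1", "m2")
  expect_lt(abs(rf5$R_obs - 0.5), 0.08)
  expect_lt(rf5$lod, 1)
  # too few informative lines
  m4 <- m[, 1:10]
  expect_equal(estimate_rf(gm_from_matrix(m4), "m1", "m2")$status,
               "unknown")
})

test_that("map intervals chain corrected Kosambi distances", {
  m <- matrix("A", nrow = 2, ncol = 137,
              dimnames = list(c("m1", "m2"), NULL))
  m[1, 1:60] <- "B"; m[2, 1:60] <- "B"
  m[2, 1:10] <- ifelse(m[1, 1:10] == "A", "B", "A")
  map <- build_map(gm_from_matrix(m))
  expect_equal(map$markers$cM,
               c(0, 25 * log(1.0788 / 0.9212)), tolerance = 1e-3)
  g <- glance(map)
  expect_equal(g$cm_per_marker, g$total_cM / g$n_markers)
  # single-marker chromosome maps to zero length
  single <- gm_from_matrix(m[1, , drop = FALSE])
  expect_equal(build_map(single)$summary$total_cM, 0)
})

test_that("adjacent recombination fractions are recovered on the RIL study", {
  f <- fx_ril()
  gm <- drop_redundant(f$gm)
  map <- build_map(gm)
  map_t <- build_map(f$gm_truth)
  # total length within 15% of the truth-genotype map
  expect_lt(abs(sum(map$summary$total_cM) - sum(map_t$summary$total_cM)),
            0.15 * sum(map_t$summary$total_cM))
  # per-interval R within 3 binomial SD of truth for >= 95% of intervals,
  # truth taken over the same marker pairs
  ok <- 0; tot <- 0
  mm <- map$markers
  for (k in seq_len(nrow(mm))) {
    Ro <- mm$R_obs[k]
    if (is.na(Ro) || k == 1 || mm$chrom[k] != mm$chrom[k - 1]) next
    rt <- estimate_rf(f$gm_truth, mm$marker_id[k - 1], mm$marker_id[k])
    Rt <- rt$R_obs
    if (is.na(Rt)) next
    n <- mm$n_informative[k]
    sd3 <- 3 * sqrt(max(Rt * (1 - Rt), 1 / (4 * n)) / n)
    tot <- tot + 1
    if (abs(Ro - Rt) <= sd3 + 1e-9) ok <- ok + 1
  }
  expect_gt(tot, 20)
  expect_gte(ok / tot, 0.95)
  # cumulative cM non-decreasing within chromosomes
  for (ch in unique(map$markers$chrom))
    expect_true(all(diff(map$markers$cM[map$markers$chrom == ch]) >= 0))
})

test_that("translocated and inverted marker clusters are flagged correctly", {
  f <- fx_ril()
  gm <- drop_redundant(f$gm)
  ids2 <- gm$calls$marker_id[gm$calls$chrom == "chr2"]
  moved <- ids2[4:6]
  src_pos <- range(gm$calls$pos[match(c(ids2[3], ids2[7]),
                                      gm$calls$marker_id)])
  # plant a translocation with preserved order
  gmx <- gm
  sel <- match(moved, gmx$calls$marker_id)
  gmx$calls$chrom[sel] <- "chr1"
  gmx$calls$pos[sel] <- 30000 + 1:3
  gmx$calls <- dplyr::arrange(gmx$calls, .data$chrom, .data$pos)
  fl <- detect_misassembly(gmx)
  expect_equal(nrow(fl), 1L)
  expect_setequal(strsplit(fl$cluster_markers, ",")[[1]], moved)
  expect_equal(fl$target_chrom, "chr2")
  expect_lte(fl$target_start, src_pos[2])
  expect_gte(fl$target_end, src_pos[1])
  expect_false(fl$inverted)
  # same translocation with reversed order -> inversion note
  gmy <- gm
  gmy$calls$chrom[sel] <- "chr1"
  gmy$calls$pos[sel] <- 30000 + 3:1
  gmy$calls <- dplyr::arrange(gmy$calls, .data$chrom, .data$pos)
  fly <- detect_misassembly(gmy)
  expect_equal(nrow(fly), 1L)
  expect_true(fly$inverted)
})

test_that("clean simulated populations raise no misassembly flags", {
  par <- fx_parents_clean()
  mk <- truth_markers(par)
  for (seed in 1:20) {
    cfg <- par$config
    cfg$seed <- seed
    ped <- sim_pedigree(par, cfg, "RIL", 100)
    gt <- pedigree_genotypes(ped, mk)
    gt$marker_id <- rep(mk$marker_id, length(ped$lines))
    gt$sample <- gt$line_id
    gt$call <- gt$truth
    gm <- build_genotype_matrix(gt, mk, 1.01)
    expect_equal(nrow(detect_misassembly(gm)), 0L)
  }
})

test_that("supercontigs are placed in the interval their markers came from", {
  f <- fx_ril()
  gm <- drop_redundant(f$gm)
  ids3 <- gm$calls$marker_id[gm$calls$chrom == "chr3"]
  contig <- ids3[6:7]
  flank_pos <- gm$calls$pos[match(c(ids3[4], ids3[9]),
                                  gm$calls$marker_id)]
  gmf <- gm
  gmf$calls <- gmf$calls[!gmf$calls$marker_id %in% contig, ]
  ccalls <- tidy(gm)
  ccalls <- ccalls[ccalls$marker_id %in% contig, ]
  pl <- place_supercontig(ccalls, gmf)
  expect_true(pl$placed)
  expect_equal(pl$chrom, "chr3")
  expect_gte(pl$start, flank_pos[1])
  expect_lte(pl$end, flank_pos[2])
  expect_false(pl$conflict)
  # unlinked contig markers stay unplaced
  set.seed(99)
  rnd <- ccalls
  rnd$call <- sample(c("A", "B"), nrow(rnd), TRUE)
  expect_false(place_supercontig(rnd, gmf)$placed)
  # markers pulled from two chromosomes conflict
  mixed <- tidy(gm)
  mixed <- mixed[mixed$marker_id %in% c(ids3[6],
                                        gm$calls$marker_id[
                                          gm$calls$chrom == "chr1"][5]), ]
  pm <- place_supercontig(mixed, gmf)
  expect_true(pm$conflict)
})

test_that("haplotype blocks recover identity segments and their boundaries", {
  f <- fx_ril()
  gm <- drop_redundant(f$gm)
  m <- gm$calls
  # identical accessions: one full-identity block per chromosome
  tr_same <- tibble::tibble(marker_id = m$marker_id, chrom = m$chrom,
                            pos = m$pos, x = "A", y = "A")
  hb <- haplotype_blocks(tr_same)
  expect_equal(nrow(hb), length(unique(m$chrom)))
  expect_true(all(hb$identity == 1))
  # planted introgression: boundaries within one marker interval of truth
  seg <- m$chrom == "chr1" & m$pos > 120000 & m$pos < 190000
  stopifnot(sum(seg) >= 5)
  y <- ifelse(seg, "A", "B")
  tr <- tibble::tibble(marker_id = m$marker_id, chrom = m$chrom,
                       pos = m$pos, x = "A", y = y)
  hb2 <- haplotype_blocks(tr, window = 5, min_identity = 0.9)
  big <- hb2[which.max(hb2$n_markers), ]
  truth_lo <- min(m$pos[seg]); truth_hi <- max(m$pos[seg])
  prev <- max(c(-Inf, m$pos[m$chrom == "chr1" & m$pos < truth_lo]))
  nxt <- min(c(Inf, m$pos[m$chrom == "chr1" & m$pos > truth_hi]))
  expect_gte(big$start, prev)
  expect_lte(big$start, truth_lo)
  expect_gte(big$end, truth_hi)
  expect_lte(big$end, nxt)
  expect_equal(big$n_markers, sum(seg))
  # unrelated accessions: no sizeable block survives strict identity
  set.seed(31)
  tr3 <- tibble::tibble(marker_id = m$marker_id, chrom = m$chrom,
                        pos = m$pos,
                        x = sample(c("A", "B"), nrow(m), TRUE),
                        y = sample(c("A", "B"), nrow(m), TRUE))
  hb3 <- haplotype_blocks(tr3, window = 5, min_identity = 0.95)
  if (nrow(hb3) > 0) expect_lt(max(hb3$n_markers), 10)
})
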