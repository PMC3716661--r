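test_that("built-in enzymes are palindromic and nested", {
  enz <- dg_enzymes()
  for (i in seq_len(nrow(enz))) {
    rec <- enz$recognition[i]
    expect_identical(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(rec))),
      rec)
    expect_true(grepl(enz$remnant[i], rec, fixed = TRUE))
  }
  # FseI contains NgoMIV contains HpaII
  expect_true(grepl("GCCGGC", "GGCCGGCC", fixed = TRUE))
  expect_true(grepl("CCGG", "GCCGGC", fixed = TRUE))
})

test_that("scan_sites finds nested recognition occurrences at fixed offsets", {
  expect_equal(scan_sites("GGCCGGCC", "FseI")$start, 0L)
  expect_equal(scan_sites("GGCCGGCC", "NgoMIV")$start, 1L)
  expect_equal(scan_sites("GGCCGGCC", "HpaII")$start, 2L)
  expect_equal(nrow(scan_sites("ATATATAT", "FseI")), 0L)
  expect_error(scan_sites("ACGX", "FseI"), "non-nucleotide")
})

test_that("nested-site invariant holds on random sequence (exhaustive oracle)", {
  for (seed in 1:3) {
    g <- random_genome(10000, seed = seed)
    fse <- scan_sites(g, "FseI")$start
    ngo <- scan_sites(g, "NgoMIV")$start
    hpa <- scan_sites(g, "HpaII")$start
    expect_true(all((fse + 1) %in% ngo))
    expect_true(all((fse + 2) %in% hpa))
    expect_lte(length(fse), length(ngo))
    expect_lte(length(ngo), length(hpa))
    # scanner agrees with the independent substring oracle
    expect_identical(hpa, oracle_site_scan(g[[1]], "CCGG"))
    expect_identical(fse, oracle_site_scan(g[[1]], "GGCCGGCC"))
  }
})

test_that("digestion yields two templates per unmethylated site", {
  set.seed(42)
  arm <- function() paste(sample(c("A","C","G","T"), 200, TRUE), collapse = "")
  g <- c(ctg = paste0(arm(), "GGCCGGCC", arm(), "GGCCGGCC", arm(),
                      "GGCCGGCC", arm()))
  g <- c(ctg = gsub("GGCCGGCC", "GGCCGGCC", g[[1]])) # 3 planted sites
  sites <- scan_sites(g, "FseI")
  expect_equal(nrow(sites), 3L)
  tpl <- digest_genome(g, "FseI", read_len = 33)
  expect_equal(nrow(tpl), 6L)
  expect_true(all(nchar(tpl$tag_seq) == 33))
  expect_true(all(!tpl$truncated))
  # all sites masked methylated -> no templates
  meth <- tibble::tibble(chrom = "ctg", start = sites$start,
                         methylated = TRUE)
  expect_equal(nrow(digest_genome(g, "FseI", methylation = meth)), 0L)
  # one site masked -> 4 templates
  meth1 <- meth[1, ]
  expect_equal(nrow(digest_genome(g, "FseI", methylation = meth1)), 4L)
  expect_error(digest_genome(c(x = ""), "FseI"), "empty")
})

test_that("templates at contig ends are truncated and flagged", {
  g <- c(ctg = paste0("GGCCGGCC", strrep("ACGT", 30)))
  tpl <- digest_genome(g, "FseI", read_len = 33)
  expect_equal(nrow(tpl), 2L)
  b <- tpl[tpl$side == "B", ]
  expect_true(b$truncated)
  expect_equal(nchar(b$tag_seq), 0L)
  f <- tpl[tpl$side == "F", ]
  expect_false(f$truncated)
  # left tag is reverse-complemented (reads 5'->3' away from the site)
  g2 <- c(ctg = paste0(strrep("A", 40), "GGCCGGCC", strrep("C", 40)))
  tpl2 <- digest_genome(g2, "FseI", read_len = 33)
  expect_equal(tpl2$tag_seq[tpl2$side == "B"], strrep("T", 33))
  expect_equal(tpl2$tag_seq[tpl2$side == "F"], strrep("C", 33))
})

test_that("gc_window is computed on the available flank", {
  g <- c(ctg = paste0(strrep("A", 100), "GGCCGGCC", strrep("G", 100)))
  tpl <- digest_genome(g, "FseI", read_len = 33)
  expect_equal(tpl$gc_window[tpl$side == "B"], 0)
  expect_equal(tpl$gc_window[tpl$side == "F"], 1)
})

test_that("proximal overlapping templates are reduced to one", {
  tpl <- tibble::tibble(
    chrom = "c1", start = c(0, 10, 20), end = c(33, 43, 53),
    template_id = c("a", "b", "c"))
  out <- filter_proximal(tpl)
  expect_equal(out$template_id, "a")  # three mutually overlapping -> one
  expect_equal(attr(out, "n_removed"), 2L)
  # idempotent
  out2 <- filter_proximal(out)
  expect_equal(out2$template_id, out$template_id)
  expect_equal(attr(out2, "n_removed"), 0L)
  # well-separated templates survive
  far <- tibble::tibble(chrom = "c1", start = c(0, 100), end = c(33, 133),
                        template_id = c("a", "b"))
  expect_equal(nrow(filter_proximal(far)), 2L)
})

test_that("uniqueness follows the 2-mismatch margin rule", {
  set.seed(9)
  base <- paste(sample(c("A","C","G","T"), 33, TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A","C","G","T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  spacer <- function() paste(sample(c("A","C","G","T"), 60, TRUE), collapse = "")
  # copy at 1 mismatch -> repetitive; copy at 2 mismatches -> unique
  g1 <- c(chr = paste0(spacer(), base, spacer(), mut(base, 1), spacer()))
  g2 <- c(chr = paste0(spacer(), base, spacer(), mut(base, 2), spacer()))
  tpl <- tibble::tibble(chrom = "chr", start = 60, end = 93,
                        template_id = "t", tag_seq = base,
                        uniqueness = "unassessed")
  expect_equal(classify_uniqueness(tpl, g1)$uniqueness, "repetitive")
  expect_equal(classify_uniqueness(tpl, g2)$uniqueness, "unique")
  # single occurrence -> unique; absent tag -> unassessed
  g3 <- c(chr = paste0(spacer(), base, spacer()))
  expect_equal(classify_uniqueness(tpl, g3)$uniqueness, "unique")
  foreign <- tpl
  foreign$tag_seq <- mut(base, 10)
  expect_equal(classify_uniqueness(foreign, g3)$uniqueness, "unassessed")
})

test_that("plastid screen counts recognition sites", {
  set.seed(4)
  plastid <- random_genome(20000, seed = 4)
  # remove any accidental FseI occurrence
  while (nrow(scan_sites(plastid, "FseI")) > 0) {
    s <- scan_sites(plastid, "FseI")$start[1]
    substr(plastid[[1]], s + 1, s + 1) <- "T"
  }
  expect_equal(plastid_screen("FseI", plastid), 0L)
  with_sites <- plastid
  clean <- gsub("CCGG", "ATTA", with_sites[[1]], fixed = TRUE)
  with2 <- c(pl = paste0(substr(clean, 1, 5000), "CCGG",
                         substr(clean, 5001, 10000), "CCGG",
                         substr(clean, 10001, nchar(clean))))
  expect_equal(plastid_screen("HpaII", with2), 2L)
})
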