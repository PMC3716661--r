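# Shared simulation fixtures, built once per test run and cached.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_env)) assign(name, builder(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# truth marker table from a parents object: polymorphic, unique-flank,
# usable templates (what discovery should find)
truth_markers <- function(par) {
  t <- par$truth$templates
  t <- t[t$polymorphic & !t$methylated & !t$truncated &
           !t$knockout_B & !t$repeat_flank, ]
  tibble::tibble(marker_id = t$template_id, chrom = t$chrom, pos = t$tstart,
                 template_id = t$template_id,
                 alleleA_seq = t$tagA, alleleB_seq = t$tagB)
}

# clean error-free parents pair on a small genome (round-trip / discovery)
fx_parents_clean <- function() fx("parents_clean", function() {
  cfg <- sim_config(seed = 7, n_chrom = 2, chrom_len = 80000,
                    err_rate = 0, junk_frac = 0, gc_beta = 0, site_sd = 0)
  sim_parent_genomes(cfg)
})

fx_reads_clean <- function() fx("reads_clean", function() {
  par <- fx_parents_clean()
  sim_reads(par, NULL, par$config)
})

# default-bias parents (production protocol) on the default genome
fx_parents_default <- function() fx("parents_default", function() {
  sim_parent_genomes(sim_config(seed = 11))
})

# full RIL study: 137 lines, allele counts, initial-policy matrix
fx_ril <- function() fx("ril", function() {
  par <- fx_parents_default()
  ped <- sim_pedigree(par, par$config, "RIL", 137)
  cnt <- sim_allele_counts(par, ped, par$config)
  mk <- truth_markers(par)
  calls <- call_genotypes(cnt, call_policy("initial"))
  gm <- build_genotype_matrix(calls, mk, 0.15)
  truth_calls <- cnt[, c("marker_id", "sample")]
  truth_calls$call <- cnt$truth
  gmt <- build_genotype_matrix(truth_calls, mk, 1.01)
  list(par = par, ped = ped, cnt = cnt, mk = mk, calls = calls,
       gm = gm, gm_truth = gmt)
})

# 24-sample read-level run with all default biases (smaller genome)
fx_run24 <- function() fx("run24", function() {
  cfg <- sim_config(seed = 3, n_chrom = 2, chrom_len = 150000)
  par <- sim_parent_genomes(cfg)
  ped <- sim_pedigree(par, cfg, "RIL", 24)
  sim <- sim_reads(par, ped, cfg, include_parents = FALSE)
  list(par = par, ped = ped, sim = sim, cfg = cfg)
})

usable_tpl <- function(par) {
  t <- par$truth$templates
  t[!t$methylated & !t$truncated, ]
}

profile_of <- function(sim, par) {
  d <- sim$truth_depths |>
    dplyr::group_by(.data$template_id, .data$sample) |>
    dplyr::summarize(depth = sum(.data$depth), .groups = "drop")
  depth_profile(d, usable_tpl(par))
}

# exhaustive-scan oracle for recognition-site occurrences (independent of
# the package's Biostrings-based scanner)
oracle_site_scan <- function(seq, pattern) {
  w <- nchar(pattern)
  n <- nchar(seq)
  if (n < w) return(integer(0))
  starts <- 1:(n - w + 1)
  which(substring(seq, starts, starts + w - 1) == pattern) - 1L
}

# brute-force bounded-mismatch placement oracle via Biostrings
oracle_place <- function(tag, genome, max_mm = 3) {
  out <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tag)))
      m <- Biostrings::matchPattern(q, subj, max.mismatch = max_mm)
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subj,
                                        starting.at = BiocGenerics::start(m),
                                        with.indels = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = BiocGenerics::start(m) - 1L, strand = strand,
        mismatches = as.integer(mm))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character(), mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start,
                 .data$strand)
}

random_genome <- function(len, n_chrom = 1, seed = 1) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1)),
    paste0("chr", seq_len(n_chrom)))
}
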