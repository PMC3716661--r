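# depth model shared by the read- and count-level simulators.
# sheared protocol (production): depth_mean * w_gc * w_site; templates are
# sheared to a uniform size so length plays no role.
# double_digest protocol (FseI x MseI): multiply by the template-length
# weight scaled so the optimal-length template sits in the top depth tier
# (~1.33 x depth_mean, the geometric centre of the 40-72x band at the
# default depth_mean of 41).
template_mu <- function(templates, config) {
  wgc <- gc_weight(templates$gc_window, config$gc_beta, config$gc0)
  wgc <- wgc / mean(wgc)
  wsite <- if ("site_factor" %in% names(templates))
    templates$site_factor else 1
  mu <- config$depth_mean * wgc * wsite
  if (identical(config$protocol, "double_digest")) {
    wlen <- length_weight(templates$template_len, config$len_profile)
    mu <- mu * 1.33 * wlen / max(wlen)
  }
  mu
}

pool_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

usable_templates <- function(parents) {
  t <- parents$truth$templates
  t[!t$methylated & !t$truncated, ]
}

# multiplicity of each parental allele carried by a sample at each site
allele_mult <- function(sample_type, geno, knockout) {
  if (sample_type == "parentA") {
    mA <- rep(2L, length(knockout)); mB <- rep(0L, length(knockout))
  } else if (sample_type == "parentB") {
    mA <- rep(0L, length(knockout)); mB <- ifelse(knockout, 0L, 2L)
  } else {
    mA <- c(A = 2L, H = 1L, B = 0L)[geno]
    mB <- c(A = 0L, H = 1L, B = 2L)[geno]
    mB[knockout] <- 0L
  }
  list(mA = unname(mA), mB = unname(mB))
}

inject_errors <- function(seqs, err_rate) {
  if (err_rate <= 0 || length(seqs) == 0) return(list(seqs = seqs, nerr = integer(length(seqs))))
  wid <- nchar(seqs)
  nerr <- rbinom(length(seqs), wid, err_rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- sample(length(ch), nerr[i])
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, nerr = nerr)
}

#' Simulate barcoded digital-genotyping reads
#'
#' Generates single-end reads for the two parents and (optionally) a
#' pedigree of lines from the truth templates of
#' [sim_parent_genomes()]. Per template, expected depth is
#' `depth_mean * w_gc * w_len * s_pool`; realized depth is negative
#' binomial; heterozygous sites split depth binomially between the two
#' alleles; methylated sites yield nothing. Each read is
#' `barcode + remnant + (read_len + trim3)` genomic bases; sequencing
#' errors hit the genomic portion at `err_rate` per base, and a
#' `junk_frac` fraction of junk reads (corrupted barcode or remnant) is
#' added.
#'
#' @param parents [sim_parent_genomes()] result.
#' @param pedigree Optional [sim_pedigree()] result.
#' @param config A [sim_config()].
#' @param barcodes Optional character vector, one per sample
#'   (parents first, then lines); generated with [dg_barcodes()] if NULL.
#' @param include_parents Emit reads for the two parents (default TRUE).
#' @return List of class `dg_simreads`: `reads` (tibble: `read_id`,
#'   `sample`, `read`, plus truth columns `template_id`, `allele`,
#'   `n_errors`, `is_junk`), `truth_depths` (per sample x template x
#'   allele), `barcodes` (tibble `sample`, `barcode`), `config`.
#' @export
sim_reads <- function(parents, pedigree = NULL, config = parents$config,
                      barcodes = NULL, include_parents = TRUE) {
  set.seed(substream_seed(config$seed, "reads"))
  tpl <- usable_templates(parents)
  if (nrow(tpl) == 0) stop("no usable templates")
  remnant <- get_enzyme("FseI")$remnant
  samples <- character(0); types <- character(0)
  if (include_parents) {
    samples <- c("parentA", "parentB"); types <- c("parentA", "parentB")
  }
  if (!is.null(pedigree)) {
    ids <- vapply(pedigree$lines, `[[`, character(1), "line_id")
    samples <- c(samples, ids); types <- c(types, rep("line", length(ids)))
  }
  if (length(samples) == 0) stop("nothing to simulate")
  if (is.null(barcodes))
    barcodes <- dg_barcodes(length(samples), config$barcode_len, config$seed)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (length(barcodes) != length(samples))
    stop("need one barcode per sample")

  mu0 <- template_mu(tpl, config)
  spool <- pool_factors(length(samples), config$pool_cv)
  line_lookup <- if (!is.null(pedigree))
    setNames(pedigree$lines, vapply(pedigree$lines, `[[`, character(1),
                                    "line_id")) else list()
  size <- 1 / config$dispersion

  all_reads <- vector("list", length(samples))
  all_depths <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sm <- samples[si]; ty <- types[si]
    geno <- NULL
    if (ty == "line") {
      ln <- line_lookup[[sm]]
      g <- vapply(seq_len(nrow(tpl)), function(i) {
        h <- ln$haps[[tpl$chrom[i]]]
        eval_hap(h$h1, tpl$start[i]) + eval_hap(h$h2, tpl$start[i])
      }, integer(1))
      geno <- c("A", "H", "B")[g - 1L]
    }
    am <- allele_mult(ty, geno, tpl$knockout_B)
    mtot <- am$mA + am$mB
    d <- rnbinom(nrow(tpl), size = size, mu = mu0 * spool[si])
    d[mtot == 0] <- 0L
    nA <- ifelse(am$mA == 0, 0L,
                 ifelse(am$mB == 0, d, rbinom(nrow(tpl), d, 0.5)))
    nB <- d - nA
    nB[am$mB == 0] <- 0L
    keep <- (nA + nB) > 0
    dd <- tibble::tibble(
      sample = sm,
      template_id = rep(tpl$template_id, 2),
      chrom = rep(tpl$chrom, 2), site_start = rep(tpl$start, 2),
      side = rep(tpl$side, 2),
      allele = rep(c("A", "B"), each = nrow(tpl)),
      depth = c(nA, nB))
    all_depths[[si]] <- dd[dd$depth > 0, ]
    idxA <- rep(which(nA > 0), nA[nA > 0])
    idxB <- rep(which(nB > 0), nB[nB > 0])
    gseq <- c(tpl$readA[idxA], tpl$readB[idxB])
    origin <- c(tpl$template_id[idxA], tpl$template_id[idxB])
    alle <- c(rep("A", length(idxA)), rep("B", length(idxB)))
    err <- inject_errors(gseq, config$err_rate)
    all_reads[[si]] <- tibble::tibble(
      sample = sm, template_id = origin, allele = alle,
      n_errors = err$nerr, is_junk = FALSE,
      read = paste0(barcodes[si], remnant, err$seqs))
  }
  reads <- dplyr::bind_rows(all_reads)

  # junk reads: corrupted barcode or remnant, body drawn from real tags
  if (config$junk_frac > 0 && nrow(reads) > 0) {
    n_junk <- round(nrow(reads) * config$junk_frac / (1 - config$junk_frac))
    if (n_junk > 0) {
      body <- sample(c(tpl$readA, tpl$readB[!is.na(tpl$readB)]), n_junk,
                     replace = TRUE)
      jbar <- character(n_junk); jrem <- rep(remnant, n_junk)
      corrupt_bc <- runif(n_junk) < 0.5
      for (i in seq_len(n_junk)) {
        if (corrupt_bc[i]) {
          repeat {
            cand <- paste(sample(c("A", "C", "G", "T"), config$barcode_len,
                                 replace = TRUE), collapse = "")
            if (!cand %in% barcodes) break
          }
          jbar[i] <- cand
        } else {
          jbar[i] <- sample(barcodes, 1)
          at <- sample(nchar(remnant), 1)
          b <- substr(remnant, at, at)
          substr(jrem[i], at, at) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }
      }
      reads <- dplyr::bind_rows(reads, tibble::tibble(
        sample = NA_character_, template_id = NA_character_,
        allele = NA_character_, n_errors = 0L, is_junk = TRUE,
        read = paste0(jbar, jrem, body)))
    }
  }
  reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))
  structure(list(reads = reads,
                 truth_depths = dplyr::bind_rows(all_depths),
                 barcodes = tibble::tibble(sample = samples,
                                           barcode = barcodes,
                                           pool_factor = spool),
                 config = config),
            class = "dg_simreads")
}

#' Write simulated reads as FASTQ
#'
#' Phred+33, constant quality. Same seed upstream implies byte-identical
#' output.
#'
#' @param sim A [sim_reads()] result (or tibble with `read_id`, `read`).
#' @param path Output FASTQ path.
#' @param quality_char Constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path, quality_char = "I") {
  reads <- if (inherits(sim, "dg_simreads")) sim$reads else sim
  lines <- character(4 * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$read
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <-
    vapply(nchar(reads$read), function(n)
      strrep(quality_char, n), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-marker allele counts directly
#'
#' A fast path that skips read strings: for each line and polymorphic
#' template (marker), realized depth is negative binomial around the
#' GC/length/pool-weighted mean; heterozygous genotypes split reads
#' binomially; sequencing error converts an expected-allele read into the
#' alternative allele with probability `err_rate/3` (the variant base
#' must flip to the other parental base) and into an off-catalog sequence
#' ("other") otherwise.
#'
#' @param parents [sim_parent_genomes()] result.
#' @param pedigree [sim_pedigree()] result.
#' @param config A [sim_config()].
#' @param markers Optional marker tibble (defaults to the truth
#'   polymorphic templates) with `marker_id`, `chrom`, `pos`,
#'   `template_id`.
#' @return Tibble: `marker_id`, `sample`, `count_a`, `count_b`,
#'   `count_other`, `truth`.
#' @export
sim_allele_counts <- function(parents, pedigree, config = parents$config,
                              markers = NULL) {
  set.seed(substream_seed(config$seed, "counts"))
  tpl <- usable_templates(parents)
  tpl <- tpl[tpl$polymorphic, ]
  if (!is.null(markers)) tpl <- tpl[tpl$template_id %in% markers$template_id, ]
  if (nrow(tpl) == 0) stop("no polymorphic templates")
  mu0 <- template_mu(tpl, config)
  spool <- pool_factors(length(pedigree$lines), config$pool_cv)
  size <- 1 / config$dispersion
  L <- config$read_len
  p_keep <- (1 - config$err_rate)^L
  p_flip <- (config$err_rate / 3) * (1 - config$err_rate)^(L - 1)
  out <- vector("list", length(pedigree$lines))
  for (si in seq_along(pedigree$lines)) {
    ln <- pedigree$lines[[si]]
    g <- vapply(seq_len(nrow(tpl)), function(i) {
      h <- ln$haps[[tpl$chrom[i]]]
      eval_hap(h$h1, tpl$start[i]) + eval_hap(h$h2, tpl$start[i])
    }, integer(1))
    geno <- c("A", "H", "B")[g - 1L]
    am <- allele_mult("line", geno, tpl$knockout_B)
    d <- rnbinom(nrow(tpl), size = size, mu = mu0 * spool[si])
    d[(am$mA + am$mB) == 0] <- 0L
    nA <- ifelse(am$mA == 0, 0L,
                 ifelse(am$mB == 0, d, rbinom(nrow(tpl), d, 0.5)))
    nB <- d - nA
    nB[am$mB == 0] <- 0L
    okA <- rbinom(nrow(tpl), nA, p_keep)
    okB <- rbinom(nrow(tpl), nB, p_keep)
    flipA <- rbinom(nrow(tpl), nA - okA, p_flip / max(1 - p_keep, 1e-12))
    flipB <- rbinom(nrow(tpl), nB - okB, p_flip / max(1 - p_keep, 1e-12))
    out[[si]] <- tibble::tibble(
      marker_id = tpl$template_id, sample = ln$line_id,
      count_a = okA + flipB, count_b = okB + flipA,
      count_other = (nA - okA - flipA) + (nB - okB - flipB),
      truth = geno)
  }
  dplyr::bind_rows(out)
}
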