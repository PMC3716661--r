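#' Simulation configuration
#'
#' Parameters of the synthetic genome / pedigree / read generator. The
#' defaults emulate the documented behaviour of an FseI digital-genotyping
#' run on a repeat-rich plant genome: ~90% of repeat-flanked sites
#' methylated, ~5-10% of unique-flanked sites methylated, parental
#' divergence of 1 variant per 289 bp in tag space, mean tag depth 41,
#' per-base sequencing error 0.75%, and a ~12% junk-read fraction
#' (matching the ~88% of raw reads carrying an intact barcode + enzyme
#' remnant).
#'
#' @param seed Master RNG seed; every stage draws from a sub-stream
#'   derived from it.
#' @param n_chrom,chrom_len Genome shape (chromosome count, length bp).
#' @param repeat_fraction Fraction of each chromosome occupied by the
#'   central repeat block (pericentromeric analogue).
#' @param site_spacing Mean spacing (bp) of planted FseI sites in unique
#'   sequence.
#' @param p_meth_repeat,p_meth_unique Methylation probability for
#'   repeat-flanked / unique-flanked sites.
#' @param snp_rate Per-bp parental divergence inside tag flanks.
#' @param indel_fraction Fraction of planted variants that are 1-3 bp
#'   indels rather than SNPs.
#' @param knockout_rate Probability a site is destroyed in parent B
#'   (restriction-site mutation), yielding presence/absence candidates.
#' @param gens_self Selfing generations after the F1 (6 = F7 RILs).
#' @param xover_rate Expected crossovers per chromosome per meiosis.
#' @param depth_mean Target mean tag depth per sample.
#' @param dispersion Negative-binomial dispersion of tag depth
#'   (`size = 1/dispersion`).
#' @param gc_beta,gc0 GC bias: depth weight `exp(-gc_beta * max(0, gc - gc0))`.
#' @param site_sd Log-scale SD of the per-template sequence-efficiency
#'   factor (the same templates are sequenced consistently high or low
#'   across samples, beyond what GC alone explains); 0 disables it.
#' @param protocol `"sheared"` (production protocol: templates sheared to
#'   a uniform size, no length bias) or `"double_digest"` (FseI x MseI
#'   fixed-length templates, length bias applied via `len_profile`).
#' @param len_profile Two-column matrix/data.frame of template-length
#'   anchors (length bp, relative weight); interpolated log-linearly.
#'   Used by the double-digest protocol.
#' @param err_rate Per-base sequencing error probability.
#' @param pool_cv Coefficient of variation of per-sample depth factors.
#' @param junk_frac Fraction of emitted reads that are junk (corrupted
#'   barcode or remnant).
#' @param read_len Genomic tag length retained after trimming (bp).
#' @param trim3 Bases trimmed from the 3' end during demultiplexing; reads
#'   carry `read_len + trim3` genomic bases.
#' @param barcode_len Barcode length (nt).
#' @return A list of class `dg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3, chrom_len = 200000,
                       repeat_fraction = 0.33, site_spacing = 1200,
                       p_meth_repeat = 0.90, p_meth_unique = 0.075,
                       snp_rate = 1 / 289, indel_fraction = 0.15,
                       knockout_rate = 0.02,
                       gens_self = 6, xover_rate = 1.2,
                       depth_mean = 41, dispersion = 0.2,
                       gc_beta = 8, gc0 = 0.45, site_sd = 0.75,
                       protocol = c("sheared", "double_digest"),
                       len_profile = default_len_profile(),
                       err_rate = 0.0075, pool_cv = 0.3,
                       junk_frac = 0.12,
                       read_len = 33, trim3 = 1, barcode_len = 4) {
  protocol <- match.arg(protocol)
  probs <- c(p_meth_repeat, p_meth_unique, snp_rate, indel_fraction,
             knockout_rate, err_rate, junk_frac, repeat_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (snp_rate >= 0.1) stop("snp_rate must be below 0.1")
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_len = chrom_len, repeat_fraction = repeat_fraction,
              site_spacing = site_spacing,
              p_meth_repeat = p_meth_repeat, p_meth_unique = p_meth_unique,
              snp_rate = snp_rate, indel_fraction = indel_fraction,
              knockout_rate = knockout_rate, gens_self = gens_self,
              xover_rate = xover_rate, depth_mean = depth_mean,
              dispersion = dispersion, gc_beta = gc_beta, gc0 = gc0,
              site_sd = site_sd, protocol = protocol,
              len_profile = as.data.frame(len_profile),
              err_rate = err_rate, pool_cv = pool_cv,
              junk_frac = junk_frac, read_len = read_len, trim3 = trim3,
              barcode_len = barcode_len)
  structure(cfg, class = "dg_sim_config")
}

#' Default template-length weight anchors
#'
#' Relative sequencing efficiency by template length, anchored to the
#' observed depth tiers (short ~109 bp templates sequenced ~4-6x more
#' often than ~286 bp templates; templates under 65 bp rarely sequenced;
#' 350 bp and longer nearly absent). Interpolation between anchors is
#' linear on log-weight; templates shorter than the first anchor get a
#' hard 0.005 floor (size selection removes them almost entirely).
#'
#' @return Data frame with columns `length`, `weight`.
#' @export
default_len_profile <- function() {
  data.frame(length = c(65, 109, 148, 286, 350),
             weight = c(0.02, 1.0, 0.55, 0.22, 0.02))
}

#' GC depth weight
#'
#' `exp(-gc_beta * max(0, gc - gc0))`: depth is depressed above the GC
#' pivot, reflecting inefficient amplification of GC-rich templates.
#'
#' @param gc GC fraction(s) of the 300 bp window adjacent to the site.
#' @param gc_beta,gc0 Bias strength and pivot.
#' @return Numeric weights.
#' @export
gc_weight <- function(gc, gc_beta = 8, gc0 = 0.45) {
  exp(-gc_beta * pmax(0, gc - gc0))
}

#' Template-length depth weight
#'
#' Log-linear interpolation through the anchor table (see
#' [default_len_profile()]); constant beyond the outermost anchors.
#'
#' @param len Template length(s) bp (site-to-nearest-MseI distance).
#' @param profile Anchor table (`length`, `weight`).
#' @return Numeric weights.
#' @export
length_weight <- function(len, profile = default_len_profile()) {
  lw <- stats::approx(profile$length, log(pmax(profile$weight, 1e-8)),
                      xout = pmin(pmax(len, min(profile$length)),
                                  max(profile$length)))$y
  w <- exp(lw)
  w[len < min(profile$length)] <- 0.005
  w
}

random_seq <- function(len, block = 500) {
  nb <- ceiling(len / block)
  gcs <- runif(nb, 0.25, 0.75)
  chunks <- vapply(seq_len(nb), function(i) {
    n <- min(block, len - (i - 1) * block)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gcs[i]) / 2, gcs[i] / 2,
                          gcs[i] / 2, (1 - gcs[i]) / 2)), collapse = "")
  }, character(1))
  paste(chunks, collapse = "")
}

str_assign <- function(s, start1, replacement) {
  # replace nchar(replacement) bases starting at 1-based start1
  paste0(substr(s, 1, start1 - 1), replacement,
         substr(s, start1 + nchar(replacement), nchar(s)))
}

#' Simulate a pair of parental genomes with truth tables
#'
#' Builds parent A as a multi-chromosome genome with a central repeat
#' block (near-identical copies of a repeat unit carrying an FseI site)
#' and FseI sites planted in the unique arms; assigns per-site methylation
#' (repeat-flanked vs unique-flanked probabilities); then derives parent B
#' by planting SNPs/indels at `snp_rate` within tag flanks and destroying
#' a small fraction of sites (restriction-site knockouts).
#'
#' @param config A [sim_config()].
#' @return List of class `dg_parents`: `genomeA`, `genomeB` (named
#'   character vectors), `methylation` (tibble in parent-A coordinates),
#'   `methylationB`, and `truth` (list with `sites`, `variants`,
#'   `templates`, `repeats`).
#' @export
sim_parent_genomes <- function(config = sim_config()) {
  set.seed(substream_seed(config$seed, "parents"))
  fse <- get_enzyme("FseI")
  chroms <- paste0("chr", seq_len(config$n_chrom))
  L <- config$chrom_len

  rep_unit <- random_seq(600)
  rep_unit <- str_assign(rep_unit, 101, fse$recognition)

  genomeA <- setNames(vector("character", length(chroms)), chroms)
  repeats <- list()
  for (ch in chroms) {
    s <- random_seq(L)
    rep_len <- round(config$repeat_fraction * L)
    rep_start <- round((L - rep_len) / 2)
    n_copies <- floor(rep_len / 600)
    if (n_copies > 0) {
      copies <- vapply(seq_len(n_copies), function(i) {
        u <- strsplit(rep_unit, "")[[1]]
        nmut <- rbinom(1, length(u), 0.01)
        if (nmut > 0) {
          at <- sample(setdiff(seq_along(u), 101:108), nmut)
          u[at] <- vapply(u[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        paste(u, collapse = "")
      }, character(1))
      block <- paste(copies, collapse = "")
      s <- paste0(substr(s, 1, rep_start),
                  block,
                  substr(s, rep_start + nchar(block) + 1, L))
      repeats[[ch]] <- tibble::tibble(chrom = ch, start = rep_start,
                                      end = rep_start + nchar(block))
    }
    # plant unique-arm sites
    arms <- list(c(0, rep_start - 200), c(rep_start + rep_len + 200, L - 200))
    for (arm in arms) {
      if (arm[2] - arm[1] < config$site_spacing) next
      pos <- arm[1] + cumsum(config$site_spacing * runif(100000, 0.7, 1.3))
      pos <- round(pos[pos < arm[2] - 20])
      for (p in pos) s <- str_assign(s, p + 1, fse$recognition)
    }
    genomeA[[ch]] <- s
  }
  repeats <- dplyr::bind_rows(repeats)

  sites <- scan_sites(genomeA, "FseI")
  sites <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(site_index = dplyr::row_number()) |>
    dplyr::ungroup()
  in_rep <- rep(FALSE, nrow(sites))
  if (nrow(repeats) > 0) {
    for (i in seq_len(nrow(repeats))) {
      in_rep <- in_rep | (sites$chrom == repeats$chrom[i] &
                            sites$start >= repeats$start[i] - config$read_len &
                            sites$start < repeats$end[i] + config$read_len)
    }
  }
  sites$repeat_flank <- in_rep
  p_meth <- ifelse(sites$repeat_flank, config$p_meth_repeat,
                   config$p_meth_unique)
  sites$methylated <- runif(nrow(sites)) < p_meth
  sites$knockout_B <- runif(nrow(sites)) < config$knockout_rate

  # plant variants in the tag flanks of unique-arm sites
  flank_w <- config$read_len + config$trim3
  vars <- list()
  usites <- sites[!sites$repeat_flank, ]
  w <- nchar(fse$recognition)
  for (i in seq_len(nrow(usites))) {
    ch <- usites$chrom[i]; s0 <- usites$start[i]
    flank_pos <- c(seq(s0 - flank_w, s0 - 1), seq(s0 + w, s0 + w + flank_w - 1))
    flank_pos <- flank_pos[flank_pos >= 3 & flank_pos < nchar(genomeA[[ch]]) - 3]
    hit <- flank_pos[runif(length(flank_pos)) < config$snp_rate]
    if (length(hit) == 0) next
    vars[[length(vars) + 1]] <- tibble::tibble(chrom = ch, pos = hit,
                                               site_start = s0)
  }
  variants <- if (length(vars)) dplyr::bind_rows(vars) else
    tibble::tibble(chrom = character(), pos = integer(),
                   site_start = integer())
  variants <- dplyr::distinct(variants, .data$chrom, .data$pos,
                              .keep_all = TRUE)
  if (nrow(variants) > 0) {
    # enforce >= 4 bp spacing so indel coordinate shifts stay independent
    variants <- variants |>
      dplyr::arrange(.data$chrom, .data$pos) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::filter(c(TRUE, diff(.data$pos) >= 4)) |>
      dplyr::ungroup()
  }
  if (nrow(variants) > 0) {
    variants$is_indel <- runif(nrow(variants)) < config$indel_fraction
    # deletions must not reach into the recognition site
    ok_indel <- (variants$pos + 3 <= variants$site_start) |
      (variants$pos >= variants$site_start + 8)
    variants$is_indel <- variants$is_indel & ok_indel
    variants$indel_len <- ifelse(variants$is_indel,
                                 sample(1:3, nrow(variants), replace = TRUE), 0L)
    variants$insertion <- variants$is_indel & (runif(nrow(variants)) < 0.5)
    variants$ref <- substr(genomeA[variants$chrom], variants$pos + 1,
                           variants$pos + 1)
    variants$alt <- vapply(seq_len(nrow(variants)), function(i) {
      if (!variants$is_indel[i])
        sample(setdiff(c("A", "C", "G", "T"), variants$ref[i]), 1)
      else if (variants$insertion[i])
        paste0(variants$ref[i],
               paste(sample(c("A", "C", "G", "T"), variants$indel_len[i],
                            replace = TRUE), collapse = ""))
      else variants$ref[i]
    }, character(1))
    variants$type <- ifelse(variants$is_indel, "INDEL", "SNP")
  } else {
    variants$is_indel <- logical(); variants$indel_len <- integer()
    variants$insertion <- logical(); variants$ref <- character()
    variants$alt <- character(); variants$type <- character()
  }

  # knockouts: one substitution in the middle of the recognition site
  kos <- sites[sites$knockout_B, ]
  ko_edits <- tibble::tibble(
    chrom = kos$chrom, pos = kos$start + 3L, delta = 0L,
    replacement = "A", drop = 1L)

  # build genome B by applying edits right-to-left per chromosome
  genomeB <- genomeA
  edits <- dplyr::bind_rows(
    if (nrow(variants)) tibble::tibble(
      chrom = variants$chrom, pos = variants$pos,
      delta = ifelse(!variants$is_indel, 0L,
                     ifelse(variants$insertion, variants$indel_len,
                            -variants$indel_len)),
      replacement = ifelse(variants$is_indel & !variants$insertion,
                           "", variants$alt),
      drop = ifelse(variants$is_indel & !variants$insertion,
                    variants$indel_len + 0L, 1L)) else NULL,
    ko_edits)
  if (!is.null(edits) && nrow(edits) > 0) {
    edits <- dplyr::arrange(edits, .data$chrom, dplyr::desc(.data$pos))
    for (i in seq_len(nrow(edits))) {
      ch <- edits$chrom[i]; p <- edits$pos[i]
      g <- genomeB[[ch]]
      drop <- if (edits$replacement[i] == "") edits$drop[i] else
        max(nchar(edits$replacement[i]) - edits$delta[i], 1L)
      genomeB[[ch]] <- paste0(substr(g, 1, p),
                              edits$replacement[i],
                              substr(g, p + drop + 1, nchar(g)))
    }
    edits <- dplyr::arrange(edits, .data$chrom, .data$pos)
  }

  shiftB <- function(ch, pos) {
    if (is.null(edits) || nrow(edits) == 0) return(pos)
    e <- edits[edits$chrom == ch & edits$delta != 0L, ]
    if (nrow(e) == 0) return(pos)
    vapply(pos, function(p) p + sum(e$delta[e$pos < p]), numeric(1))
  }
  sites$startB <- NA_real_
  for (ch in chroms) {
    idx <- sites$chrom == ch
    sites$startB[idx] <- shiftB(ch, sites$start[idx])
  }

  templates <- build_truth_templates(genomeA, genomeB, sites, config)

  meth <- sites[, c("chrom", "start", "methylated")]
  methB <- tibble::tibble(chrom = sites$chrom,
                          start = as.integer(sites$startB),
                          methylated = sites$methylated)[!sites$knockout_B, ]
  structure(list(genomeA = genomeA, genomeB = genomeB,
                 methylation = meth, methylationB = methB,
                 truth = list(sites = sites, variants = variants,
                              templates = templates, repeats = repeats),
                 config = config),
            class = "dg_parents")
}

# one row per (site, side) with both parental tag sequences, the GC window
# and the FseI-to-nearest-MseI template length
build_truth_templates <- function(genomeA, genomeB, sites, config) {
  fse <- get_enzyme("FseI")
  w <- nchar(fse$recognition)
  rl <- config$read_len + config$trim3
  mse <- scan_sites(genomeA, "MseI")
  tpl <- tidyr::crossing(sites, side = c("B", "F")) |>
    dplyr::arrange(.data$chrom, .data$start, .data$side)
  lenA <- nchar(genomeA)[tpl$chrom]
  tpl$tstart <- ifelse(tpl$side == "F", tpl$start + w, pmax(tpl$start - rl, 0))
  tpl$tend <- ifelse(tpl$side == "F", pmin(tpl$start + w + rl, lenA), tpl$start)
  tpl$truncated <- (tpl$tend - tpl$tstart) < rl
  raw <- substr(genomeA[tpl$chrom], tpl$tstart + 1, tpl$tend)
  tpl$readA <- ifelse(tpl$side == "F", raw, revcomp(raw))
  lenB <- nchar(genomeB)[tpl$chrom]
  bs <- ifelse(tpl$side == "F", tpl$startB + w, pmax(tpl$startB - rl, 0))
  be <- ifelse(tpl$side == "F", pmin(tpl$startB + w + rl, lenB), tpl$startB)
  rawB <- substr(genomeB[tpl$chrom], bs + 1, be)
  tpl$readB <- ifelse(tpl$side == "F", rawB, revcomp(rawB))
  tpl$readB[tpl$knockout_B] <- NA_character_
  tpl$tagA <- substr(tpl$readA, 1, config$read_len)
  tpl$tagB <- substr(tpl$readB, 1, config$read_len)
  # GC of the 300 bp adjacent to the site on the template side
  gws <- ifelse(tpl$side == "F", tpl$start + w, pmax(tpl$start - 300, 0))
  gwe <- ifelse(tpl$side == "F", pmin(tpl$start + w + 300, lenA), tpl$start)
  tpl$gc_window <- gc_fraction(substr(genomeA[tpl$chrom], gws + 1, gwe))
  # distance from site to nearest MseI recognition on the template side
  tpl$template_len <- NA_real_
  for (ch in unique(tpl$chrom)) {
    ms <- mse$start[mse$chrom == ch]
    idx <- which(tpl$chrom == ch)
    for (i in idx) {
      if (tpl$side[i] == "F") {
        d <- ms[ms >= tpl$start[i] + w]
        tpl$template_len[i] <- if (length(d)) min(d) - (tpl$start[i] + w) + 4
        else nchar(genomeA[[ch]]) - tpl$start[i] - w
      } else {
        d <- ms[ms + 4 <= tpl$start[i]]
        tpl$template_len[i] <- if (length(d)) tpl$start[i] - max(d)
        else tpl$start[i]
      }
    }
  }
  tpl$polymorphic <- !is.na(tpl$tagB) & tpl$tagA != tpl$tagB
  tpl$template_id <- paste(tpl$chrom, tpl$side, tpl$site_index, sep = "_")
  # sequence-intrinsic efficiency, fixed per template across all samples
  tpl$site_factor <- if (config$site_sd > 0)
    rlnorm(nrow(tpl), meanlog = -config$site_sd^2 / 2,
           sdlog = config$site_sd) else 1
  tpl[, c("template_id", "chrom", "start", "startB", "site_index", "side",
          "tstart", "tend", "truncated", "methylated", "repeat_flank",
          "knockout_B", "readA", "readB", "tagA", "tagB", "gc_window",
          "template_len", "polymorphic", "site_factor")]
}

eval_hap <- function(h, pos) h$par[findInterval(pos, h$bp) + 1L]

meiosis_gamete <- function(h1, h2, L, rate) {
  k <- rpois(1, rate)
  xs <- sort(runif(k, 0, L))
  first <- sample(1:2, 1)
  src <- list(h1, h2)
  bps <- c(0, xs, L)
  ps <- numeric(0); pv <- integer(0)
  for (i in seq_len(length(bps) - 1)) {
    h <- src[[(i + first) %% 2 + 1]]
    a <- bps[i]; b <- bps[i + 1]
    inner <- h$bp[h$bp > a & h$bp < b]
    ss <- c(a, inner)
    vv <- h$par[findInterval(ss, h$bp) + 1L]
    ps <- c(ps, ss); pv <- c(pv, vv)
  }
  keep <- c(TRUE, pv[-1] != pv[-length(pv)])
  ps <- ps[keep]; pv <- pv[keep]
  list(bp = ps[-1], par = pv)
}

#' Simulate a RIL or F1 pedigree
#'
#' RIL lines descend from an F1 by `gens_self` generations of single-seed
#' descent; each meiosis places Poisson(`xover_rate`) crossovers uniformly
#' (no interference). Residual heterozygous tracts are retained, with
#' expected genome-wide heterozygosity `(1/2)^gens_self`. F1 lines are
#' heterozygous everywhere.
#'
#' @param parents A [sim_parent_genomes()] result (used for chromosome
#'   names/lengths).
#' @param config A [sim_config()].
#' @param design `"RIL"` or `"F1"`.
#' @param n_lines Number of lines.
#' @return List of class `dg_pedigree` with per-line haplotype mosaics.
#' @export
sim_pedigree <- function(parents, config = parents$config,
                         design = c("RIL", "F1"), n_lines = 137) {
  design <- match.arg(design)
  if (n_lines < 1) stop("n_lines must be >= 1")
  set.seed(substream_seed(config$seed, paste0("pedigree", design)))
  chroms <- names(parents$genomeA)
  lens <- nchar(parents$genomeA)
  lines <- purrr::map(seq_len(n_lines), function(l) {
    haps <- purrr::map(chroms, function(ch) {
      h1 <- list(bp = numeric(0), par = 1L)
      h2 <- list(bp = numeric(0), par = 2L)
      if (design == "RIL") {
        for (g in seq_len(config$gens_self)) {
          g1 <- meiosis_gamete(h1, h2, lens[[ch]], config$xover_rate)
          g2 <- meiosis_gamete(h1, h2, lens[[ch]], config$xover_rate)
          h1 <- g1; h2 <- g2
        }
      }
      list(h1 = h1, h2 = h2)
    })
    names(haps) <- chroms
    list(line_id = sprintf("%s%03d", if (design == "RIL") "RIL" else "F1", l),
         haps = haps)
  })
  structure(list(lines = lines, design = design, chrom_len = lens,
                 config = config), class = "dg_pedigree")
}

#' Truth genotypes of a pedigree at given loci
#'
#' @param pedigree A [sim_pedigree()] result.
#' @param loci Tibble with `chrom` and a position column (`start` or `pos`).
#' @return Tibble: `line_id`, locus columns, `truth` in `{"A","H","B"}`.
#' @export
pedigree_genotypes <- function(pedigree, loci) {
  poscol <- if ("pos" %in% names(loci)) "pos" else "start"
  purrr::map_dfr(pedigree$lines, function(ln) {
    g <- vapply(seq_len(nrow(loci)), function(i) {
      h <- ln$haps[[loci$chrom[i]]]
      eval_hap(h$h1, loci[[poscol]][i]) + eval_hap(h$h2, loci[[poscol]][i])
    }, integer(1))
    tibble::tibble(line_id = ln$line_id, chrom = loci$chrom,
                   pos = loci[[poscol]],
                   truth = c("A", "H", "B")[g - 1L])
  })
}

#' Generate a barcode set
#'
#' @param n Number of barcodes.
#' @param len Barcode length (nt).
#' @param seed RNG seed.
#' @return Character vector of distinct barcodes.
#' @export
dg_barcodes <- function(n, len = 4, seed = 1) {
  if (n > 4^len - 1) stop("too many barcodes for this length")
  set.seed(substream_seed(seed, "barcodes"))
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}
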