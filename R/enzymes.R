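#' Built-in restriction enzymes
#'
#' The nested, GC-rich methylation-sensitive set used for digital
#' genotyping — FseI (GGCCGGCC), NgoMIV (GCCGGC), HpaII (CCGG), all sharing
#' the CCGG core so that every FseI site contains an NgoMIV site which
#' contains an HpaII site — plus the methylation-insensitive four-cutter
#' MseI (TTAA) used to generate fixed-length double-digest templates.
#'
#' `remnant` is the recognition-site-derived prefix retained in a read
#' immediately after the sample barcode; demultiplexing requires an exact
#' match to barcode plus remnant.
#'
#' @return A tibble with columns `name`, `recognition`, `cut_offset_top`,
#'   `cut_offset_bottom`, `remnant`, `methylation_sensitive`.
#' @examples
#' dg_enzymes()
#' @export
dg_enzymes <- function() {
  tibble::tibble(
    name = c("FseI", "NgoMIV", "HpaII", "MseI"),
    recognition = c("GGCCGGCC", "GCCGGC", "CCGG", "TTAA"),
    cut_offset_top = c(6L, 1L, 1L, 1L),
    cut_offset_bottom = c(2L, 5L, 3L, 3L),
    remnant = c("CCGGCC", "CCGGC", "CGG", "TAA"),
    methylation_sensitive = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Look up an enzyme definition
#'
#' @param enzyme Enzyme name, or a one-row tibble/list with the fields of
#'   [dg_enzymes()] (for user-supplied enzymes).
#' @return One-row tibble.
#' @export
get_enzyme <- function(enzyme) {
  if (is.character(enzyme)) {
    tab <- dg_enzymes()
    hit <- tab[tab$name == enzyme, ]
    if (nrow(hit) == 0) stop("unknown enzyme: ", enzyme)
    return(hit)
  }
  enzyme <- tibble::as_tibble(as.list(enzyme)[c(
    "name", "recognition", "cut_offset_top", "cut_offset_bottom",
    "remnant", "methylation_sensitive")])
  enzyme
}

#' Scan a sequence for restriction sites
#'
#' Finds all forward-strand occurrences of the recognition sequence,
#' including overlapping ones. All built-in recognition sequences are
#' palindromic, so a forward-strand scan reports each physical site once.
#' IUPAC ambiguity codes in the recognition sequence are honoured.
#'
#' @param seq A single nucleotide string, a named character vector of
#'   chromosomes, a `DNAStringSet`, or a FASTA path.
#' @param enzyme Enzyme name or definition (see [get_enzyme()]).
#' @return Tibble of digestion sites: `chrom`, `start` (0-based),
#'   `end` (half-open), `enzyme`.
#' @examples
#' scan_sites(c(chr1 = "AAGGCCGGCCTT"), "FseI")
#' @export
scan_sites <- function(seq, enzyme) {
  enz <- get_enzyme(enzyme)
  if (is.character(seq) && is.null(names(seq)) && length(seq) == 1 &&
      !file.exists(seq)) {
    seq <- c(seq1 = seq)
  }
  genome <- as_genome(seq)
  check_nucleotide(genome)
  pat <- Biostrings::DNAString(enz$recognition)
  out <- purrr::map_dfr(names(genome), function(chrom) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(genome[[chrom]]),
                                  fixed = FALSE)
    tibble::tibble(chrom = chrom,
                   start = BiocGenerics::start(m) - 1L,
                   end = BiocGenerics::end(m))
  })
  out$enzyme <- enz$name
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Count restriction sites in a plastid genome
#'
#' A count of zero certifies the enzyme as plastid-clean: no reads will be
#' wasted on the high-copy chloroplast genome.
#'
#' @inheritParams scan_sites
#' @param plastid Plastid genome (any form accepted by [as_genome()]).
#' @return Integer site count.
#' @export
plastid_screen <- function(enzyme, plastid) {
  nrow(scan_sites(plastid, enzyme))
}

#' Digest a genome into tag templates
#'
#' Each unmethylated recognition site yields two tag templates, one per
#' genomic flank. Tags are stored in canonical read orientation: 5'->3'
#' away from the site into the fragment, so the left-side ("B") template is
#' the reverse complement of the upstream flank. Methylated sites are
#' blocked entirely and yield no templates.
#'
#' @param genome Genome (see [as_genome()]).
#' @param enzyme Enzyme name or definition.
#' @param methylation Optional tibble (`chrom`, `start`, `methylated`)
#'   giving a per-site methylation mask keyed on recognition-site start;
#'   sites absent from the mask are treated as unmethylated.
#' @param read_len Tag length in bp (default 33; must be >= 20).
#' @param gc_window_bp Width of the flanking window used for GC content
#'   (default 300 bp adjacent to the site on the template's side).
#' @return Tibble of templates: `chrom`, `site_start`, `site_index`,
#'   `side` ("F" = downstream flank, "B" = upstream flank), `start`, `end`
#'   (0-based half-open tag interval), `tag_seq`, `gc_window`, `truncated`,
#'   `template_id`, `uniqueness` (initially "unassessed").
#' @export
digest_genome <- function(genome, enzyme = "FseI", methylation = NULL,
                          read_len = 33, gc_window_bp = 300) {
  if (read_len < 20) stop("read_len must be >= 20")
  genome <- as_genome(genome)
  if (sum(nchar(genome)) == 0) stop("empty genome")
  enz <- get_enzyme(enzyme)
  sites <- scan_sites(genome, enz)
  if (nrow(sites) == 0) return(empty_templates())
  sites <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(site_index = dplyr::row_number()) |>
    dplyr::ungroup()
  if (!is.null(methylation)) {
    sites <- dplyr::left_join(
      sites, methylation[, c("chrom", "start", "methylated")],
      by = c("chrom", "start"))
    sites$methylated[is.na(sites$methylated)] <- FALSE
  } else {
    sites$methylated <- FALSE
  }
  sites <- sites[!sites$methylated, ]
  if (nrow(sites) == 0) return(empty_templates())

  w <- nchar(enz$recognition)
  chrom_len <- nchar(genome)[sites$chrom]
  # F: flank downstream of the site; B: flank upstream, reverse-complemented
  f <- tibble::tibble(
    chrom = sites$chrom, site_start = sites$start,
    site_index = sites$site_index, side = "F",
    start = sites$start + w,
    end = pmin(sites$start + w + read_len, chrom_len))
  b <- tibble::tibble(
    chrom = sites$chrom, site_start = sites$start,
    site_index = sites$site_index, side = "B",
    start = pmax(sites$start - read_len, 0),
    end = sites$start)
  tpl <- dplyr::bind_rows(f, b)
  tpl$truncated <- (tpl$end - tpl$start) < read_len
  raw <- substr(genome[tpl$chrom], tpl$start + 1, tpl$end)
  tpl$tag_seq <- ifelse(tpl$side == "F", raw, revcomp(raw))
  gws <- ifelse(tpl$side == "F", tpl$start, pmax(tpl$end - gc_window_bp, 0))
  gwe <- ifelse(tpl$side == "F",
                pmin(tpl$start + gc_window_bp, chrom_len), tpl$end)
  # window measured from the site edge outward, not from the tag
  gws <- ifelse(tpl$side == "F", tpl$start, gws)
  tpl$gc_window <- gc_fraction(substr(genome[tpl$chrom], gws + 1, gwe))
  tpl$template_id <- paste(tpl$chrom, tpl$side, tpl$site_index, sep = "_")
  tpl$uniqueness <- "unassessed"
  dplyr::arrange(tpl, .data$chrom, .data$site_start, .data$side)
}

empty_templates <- function() {
  tibble::tibble(chrom = character(), site_start = integer(),
                 site_index = integer(), side = character(),
                 start = integer(), end = integer(), truncated = logical(),
                 tag_seq = character(), gc_window = double(),
                 template_id = character(), uniqueness = character())
}

#' Classify tag uniqueness against a reference
#'
#' Places each template's tag on the reference by bounded-mismatch search
#' over both strands (see [place_tags()]) and labels it `unique` when it
#' has exactly one placement, or when the best placement beats the second
#' best by at least `margin` mismatches; otherwise `repetitive`. Tags with
#' no placement at all are `unassessed` (tag/reference mismatch).
#'
#' @param templates Template tibble from [digest_genome()].
#' @param reference Reference genome.
#' @param max_mm Maximum mismatches searched (default 3).
#' @param seed_len Exact-seed length (default 7).
#' @param margin Required best-vs-second-best mismatch gap (default 2).
#' @return `templates` with `uniqueness` filled in.
#' @export
classify_uniqueness <- function(templates, reference, max_mm = 3,
                                seed_len = 7, margin = 2) {
  if (nrow(templates) == 0) return(templates)
  pl <- place_tags(tibble::tibble(tag_id = templates$template_id,
                                  tag_seq = templates$tag_seq),
                   reference, seed_len = seed_len, max_mm = max_mm)
  s <- summarize_placements(pl)
  templates$uniqueness <- NULL
  templates <- dplyr::left_join(
    templates,
    s[, c("tag_id", "n_placements", "mismatches", "second_best_mismatches")],
    by = c(template_id = "tag_id"))
  templates$uniqueness <- dplyr::case_when(
    is.na(templates$n_placements) | templates$n_placements == 0 ~ "unassessed",
    templates$n_placements == 1 ~ "unique",
    templates$second_best_mismatches - templates$mismatches >= margin ~ "unique",
    TRUE ~ "repetitive")
  templates$n_placements <- NULL
  templates$mismatches <- NULL
  templates$second_best_mismatches <- NULL
  templates
}

#' Drop overlapping proximal templates
#'
#' When two restriction sites lie so close that their tag templates cover
#' overlapping genome sequence, only one of the tags is kept (a greedy
#' left-to-right sweep retaining the template with the smaller
#' `(chrom, start)`). The number removed is attached as attribute
#' `n_removed`.
#'
#' @param templates Template tibble with `chrom`, `start`, `end`.
#' @return Filtered tibble (attribute `n_removed` = count dropped).
#' @export
filter_proximal <- function(templates) {
  if (nrow(templates) == 0) {
    attr(templates, "n_removed") <- 0L
    return(templates)
  }
  templates <- dplyr::arrange(templates, .data$chrom, .data$start, .data$end)
  keep <- logical(nrow(templates))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(templates))) {
    if (templates$chrom[i] != last_chrom || templates$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- templates$end[i]
      last_chrom <- templates$chrom[i]
    }
  }
  out <- templates[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Predicted marker yield from tag count, tag length and divergence
#'
#' Expected number of polymorphic tags when `n_tags` unique tags of
#' `tag_len` bp are compared between two genotypes whose divergence in tag
#' space is `divergence` variants per bp: `n_tags * tag_len * divergence`.
#'
#' @param n_tags Number of unique tags compared.
#' @param tag_len Tag length (bp).
#' @param divergence Variants per bp (e.g. 1/500).
#' @return Expected marker count.
#' @examples
#' predict_marker_yield(20000, 33, 1 / 500)
#' @export
predict_marker_yield <- function(n_tags, tag_len, divergence) {
  n_tags * tag_len * divergence
}

#' Observed polymorphism rate in tag space
#'
#' Base pairs of compared tag sequence per observed variant,
#' `floor(n_compared * tag_len / n_polymorphic)`.
#'
#' @param n_compared Tags compared between the two genotypes.
#' @param n_polymorphic Tags containing a SNP or INDEL.
#' @param tag_len Tag length (bp).
#' @return Integer bp-per-variant rate.
#' @examples
#' polymorphism_rate(17151, 1953, 33)
#' @export
polymorphism_rate <- function(n_compared, n_polymorphic, tag_len = 33) {
  if (n_polymorphic <= 0) stop("n_polymorphic must be positive")
  floor(n_compared * tag_len / n_polymorphic)
}

#' Export templates as BED6
#'
#' @param templates Template tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_templates_bed <- function(templates, path) {
  bed <- data.frame(
    chrom = templates$chrom, start = templates$start, end = templates$end,
    name = templates$template_id,
    score = round(templates$gc_window * 1000),
    strand = ifelse(templates$side == "F", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
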