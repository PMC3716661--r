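#' Write a MapMaker/EXP raw file
#'
#' Selfed-RI dialect: a `data type ri self` header, a count line
#' (individuals, loci, traits), then one `*marker` line per locus with
#' genotype symbols `A`, `B`, `H`, `-`.
#'
#' @param gm A `dg_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapmaker_raw <- function(gm, path) {
  m <- calls_matrix(gm)
  lines <- c("data type ri self",
             sprintf("%d %d 0", ncol(m), nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste0("*", rownames(m)[i], " ",
                      paste(m[i, ], collapse = "")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JoinMap loc file
#'
#' RI population dialect: `name`/`popt`/`nloc`/`nind` header followed by
#' one locus block per marker with lower-case codes `a`, `b`, `h`, `-`.
#'
#' @param gm A `dg_genotypes` object.
#' @param path Output path.
#' @param name Population name.
#' @param popt JoinMap population type code (default `RI6`).
#' @return `path`, invisibly.
#' @export
write_joinmap_loc <- function(gm, path, name = "DGpop", popt = "RI6") {
  m <- calls_matrix(gm)
  codes <- matrix(chartr("ABH", "abh", m), nrow = nrow(m))
  lines <- c(sprintf("name = %s", name),
             sprintf("popt = %s", popt),
             sprintf("nloc = %d", nrow(m)),
             sprintf("nind = %d", ncol(m)),
             "")
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, rownames(m)[i],
               paste(" ", paste(codes[i, ], collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genotype matrix as TSV
#'
#' Rows are markers (with chrom/pos), columns are samples.
#'
#' @param gm A `dg_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  utils::write.table(gm$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genetic map as TSV
#'
#' Columns: marker, chromosome, physical bp, cumulative cM.
#'
#' @param map A `dg_map` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(
    map$markers[, c("marker_id", "chrom", "pos", "cM")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
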