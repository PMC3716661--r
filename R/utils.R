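#' Coerce a genome to a named character vector
#'
#' Accepts a named character vector of chromosome sequences, a
#' [Biostrings::DNAStringSet], or a path to a FASTA file (wrapped or
#' unwrapped, multi-record).
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || length(genome) == 0)
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named")
  toupper(genome)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  ss <- Biostrings::DNAStringSet(as_genome(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  bases <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                                       letters = c("G", "C", "A", "T"))
  tot <- rowSums(bases)
  ifelse(tot == 0, NA_real_, (bases[, "G"] + bases[, "C"]) / tot)
}

check_nucleotide <- function(seq, iupac_ok = TRUE) {
  pat <- if (iupac_ok) "^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$" else "^[ACGTNacgtn]*$"
  if (!all(grepl(pat, seq)))
    stop("sequence contains non-nucleotide characters", call. = FALSE)
  invisible(TRUE)
}

# derive a bounded sub-stream seed from a master seed and a stage label
substream_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483587L) + 1L
}
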