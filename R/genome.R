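# Genome container and frame-aware translation.

#' Construct a genome build from named contig sequences
#'
#' @param contigs named character vector of uppercase nucleotide sequences.
#' @return a `genome_build` object (named character vector).
#' @export
genome_build <- function(contigs) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig names must be present and unique")
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(contigs)[bad], collapse = ", "))
  structure(contigs, class = "genome_build")
}

#' Read a genome FASTA into a genome build
#'
#' Multi-contig FASTA; contig names are truncated at the first whitespace,
#' sequences uppercased and restricted to the A/C/G/T/N alphabet.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a `genome_build` object.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(ss)
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genome_build(contigs)
}

#' Write a genome build to FASTA
#' @param genome a `genome_build`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# codon -> amino acid lookup from the standard genetic code; stops are "*"
codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Translate a nucleotide sequence in a fixed frame
#'
#' Translates consecutive codons starting at `offset` until the first stop
#' codon or the end of the sequence. The stop codon is not included in the
#' output. Codons containing `N` (or any non-ACGT character) translate to
#' `X`; such codons never terminate translation.
#'
#' @param seq nucleotide string.
#' @param offset frame offset, one of 0, 1, 2.
#' @param to_stop if `FALSE`, translate through stop codons (rendered `*`)
#'   to the end of the sequence.
#' @return amino-acid string (possibly empty).
#' @export
translate_frame <- function(seq, offset = 0L, to_stop = TRUE) {
  stopifnot(offset %in% 0:2)
  n <- nchar(seq)
  if (n - offset < 3L) return("")
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

# TRUE for codons that are stops under the standard code
is_stop_codon <- function(codon) {
  !is.na(codon_table[codon]) & codon_table[codon] == "*"
}
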