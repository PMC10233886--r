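# Small shared helpers: sequence manipulation, I=L collapsing, TSV I/O.

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @keywords internal
rc <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Collapse isoleucine onto leucine
#'
#' Isoleucine and leucine are isobaric and indistinguishable by mass
#' spectrometry; all peptide-vs-protein containment checks are performed on
#' I-collapsed sequences.
#'
#' @param x character vector of amino-acid sequences.
#' @return character vector with every `I` replaced by `L`.
#' @export
il_collapse <- function(x) chartr("I", "L", x)

# 20-letter amino-acid alphabet (plus X for ambiguous translation products)
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Read a tab-separated table
#' @param path file path.
#' @return data.frame with character columns kept as character.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic per-stage child seed derived from a root seed; kept well below
# .Machine$integer.max for 32-bit safety
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
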