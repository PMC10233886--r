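# Enumeration and classification of non-canonical ORFs on spliced
# transcripts. Categories follow the cryptic-ORF taxonomy: upstream (5'UTR),
# downstream (3'UTR) and out-of-frame ORFs on coding transcripts, plus ORFs
# on noncoding and miscellaneous RNAs.

ORF_CATEGORIES <- c("uORF_5utr", "dORF_3utr", "out_of_frame", "ncRNA", "miscRNA")

orf_id_of <- function(transcript_id, t_start, frame_offset) {
  paste(transcript_id, t_start, frame_offset, sep = ":")
}

#' Enumerate candidate ncORFs on transcripts
#'
#' Scans all three reading frames of each spliced transcript for
#' AUG-initiated ORFs that reach an in-frame stop codon within the
#' transcript. One ORF is reported per (stop codon, frame): the 5'-most AUG.
#' The canonical CDS itself is never returned, and ORFs overlapping the CDS
#' in the canonical frame are discarded (they are canonical isoforms, not
#' ncORFs). Remaining ORFs are classified by [classify_orf()].
#'
#' @param transcripts a `transcript_set`, list of `transcript_model`s, or a
#'   single `transcript_model`.
#' @param genome a `genome_build`.
#' @param min_codons minimum protein length in codons (stop excluded).
#'   Defaults to 30, the usual short-ORF catalogue convention; lower it
#'   (>= 8) when immunopeptide-scale micro-ORFs are of interest.
#' @return data.frame with one row per ORF: `orf_id`, `transcript_id`,
#'   `gene_id`, `gene_name`, `category`, `t_start`, `t_end`, `frame_offset`,
#'   `codon_length`, `protein`.
#' @export
enumerate_orfs <- function(transcripts, genome, min_codons = 30L) {
  stopifnot(min_codons >= 1L)
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  out <- lapply(transcripts, enumerate_orfs_one, genome = genome,
                min_codons = min_codons)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_orf_table()
  rownames(res) <- NULL
  res
}

empty_orf_table <- function() {
  data.frame(orf_id = character(), transcript_id = character(),
             gene_id = character(), gene_name = character(),
             category = character(), t_start = integer(), t_end = integer(),
             frame_offset = integer(), codon_length = integer(),
             protein = character(), stringsAsFactors = FALSE)
}

enumerate_orfs_one <- function(t, genome, min_codons) {
  s <- spliced_sequence(t, genome)
  n <- nchar(s)
  rows <- list()
  for (f in 0:2) {
    if (n - f < 3L) next
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(codon_table[codons]); aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    is_atg <- codons == "ATG"
    open_from <- NA_integer_  # codon index (1-based) of current 5'-most AUG
    for (k in seq_along(codons)) {
      if (is_stop[k]) {
        if (!is.na(open_from)) {
          cl <- k - open_from
          if (cl >= min_codons) {
            t_start <- starts[open_from] - 1L
            t_end <- starts[k] + 2L
            rows[[length(rows) + 1L]] <-
              list(t_start = t_start, t_end = t_end, frame = f,
                   codon_length = cl,
                   protein = paste(aa[seq.int(open_from, k - 1L)], collapse = ""))
          }
          open_from <- NA_integer_
        }
      } else if (is_atg[k] && is.na(open_from)) {
        open_from <- k
      }
    }
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, lapply(rows, function(r) {
    data.frame(orf_id = orf_id_of(t$transcript_id, r$t_start, r$frame),
               transcript_id = t$transcript_id, gene_id = t$gene_id,
               gene_name = t$gene_name, category = NA_character_,
               t_start = r$t_start, t_end = r$t_end, frame_offset = r$frame,
               codon_length = r$codon_length, protein = r$protein,
               stringsAsFactors = FALSE)
  }))
  # never return the canonical CDS itself
  if (!is.null(t$cds_span))
    res <- res[!(res$t_start == t$cds_span[1L] & res$t_end == t$cds_span[2L]), ,
               drop = FALSE]
  res$category <- vapply(seq_len(nrow(res)), function(i)
    classify_orf(res[i, ], t), character(1))
  res <- res[res$category != "discard", , drop = FALSE]
  if (nrow(res) == 0L) return(NULL)
  res
}

#' Classify an ORF relative to its transcript's canonical CDS
#'
#' On a transcript without a CDS the ORF is `ncRNA` (or `miscRNA` for
#' misc_RNA/rRNA biotypes). On a coding transcript: entirely 5' of the CDS
#' -> `uORF_5utr`; entirely 3' of it -> `dORF_3utr`; overlapping it in a
#' shifted frame -> `out_of_frame`; overlapping it in the canonical frame ->
#' `"discard"` (a canonical isoform, not an ncORF).
#'
#' @param orf a list or single-row data.frame with `t_start`, `t_end`.
#' @param t the `transcript_model` the ORF was enumerated on.
#' @return category string, or `"discard"`.
#' @export
classify_orf <- function(orf, t) {
  if (is.null(t$cds_span)) {
    return(if (t$biotype %in% c("misc_RNA", "rRNA")) "miscRNA" else "ncRNA")
  }
  cs <- t$cds_span[1L]; ce <- t$cds_span[2L]
  if (orf$t_end <= cs) return("uORF_5utr")
  if (orf$t_start >= ce) return("dORF_3utr")
  if ((orf$t_start - cs) %% 3L != 0L) return("out_of_frame")
  "discard"
}

#' Collapse ORFs with identical protein sequences
#'
#' One representative is kept per distinct protein string (the
#' lexicographically smallest `orf_id`); the redundancy map records every
#' source ORF per representative.
#'
#' @param orfs ORF table from [enumerate_orfs()].
#' @return list with `representatives` (ORF table subset) and `redundancy`
#'   (data.frame `representative_id`, `orf_id`).
#' @export
deduplicate_orfs <- function(orfs) {
  if (nrow(orfs) == 0L)
    return(list(representatives = orfs,
                redundancy = data.frame(representative_id = character(),
                                        orf_id = character())))
  ord <- order(orfs$protein, orfs$orf_id)
  o <- orfs[ord, , drop = FALSE]
  rep_id <- stats::ave(o$orf_id, o$protein, FUN = function(x) x[1L])
  reps <- o[!duplicated(o$protein), , drop = FALSE]
  list(representatives = reps[order(reps$orf_id), , drop = FALSE],
       redundancy = data.frame(representative_id = rep_id, orf_id = o$orf_id,
                               stringsAsFactors = FALSE))
}

#' FASTA accession for an ncORF protein
#' @param orf_id,category ORF identifier and category.
#' @return accession string `ncorf|<orf_id>|<category>`.
#' @export
orf_accession <- function(orf_id, category) paste("ncorf", orf_id, category, sep = "|")

#' Parse an ncORF FASTA accession
#' @param accession accession string(s) of the form `ncorf|<orf_id>|<category>`.
#' @return data.frame with `orf_id` and `category` (`NA` for non-ncORF
#'   accessions).
#' @export
parse_orf_accession <- function(accession) {
  parts <- strsplit(accession, "|", fixed = TRUE)
  orf_id <- vapply(parts, function(p)
    if (length(p) >= 3L && p[1L] == "ncorf") p[2L] else NA_character_, character(1))
  category <- vapply(parts, function(p)
    if (length(p) >= 3L && p[1L] == "ncorf") p[3L] else NA_character_, character(1))
  data.frame(orf_id = orf_id, category = category, stringsAsFactors = FALSE)
}

#' Write the ORF table and protein FASTA
#'
#' @param orfs ORF table.
#' @param tsv_path,fasta_path output paths (either may be `NULL` to skip).
#' @return invisibly, the ORF table.
#' @export
write_orf_outputs <- function(orfs, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- c("orf_id", "transcript_id", "gene_id", "gene_name", "category",
              "t_start", "t_end", "frame_offset", "codon_length")
    write_tsv_table(orfs[, cols], tsv_path)
  }
  if (!is.null(fasta_path)) {
    ss <- Biostrings::AAStringSet(orfs$protein)
    names(ss) <- orf_accession(orfs$orf_id, orfs$category)
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(orfs)
}
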