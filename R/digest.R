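# Proteogenomic search space: reversed decoys, in-silico tryptic digestion
# (full and semi-specific) and the canonical-overlap exclusion filter.

#' Digestion specification
#'
#' @param enzyme only `"trypsin"` (cleave after K or R, not before P).
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param mode `"full"` (both termini tryptic) or `"semi"` (additionally
#'   every prefix/suffix truncation of a fully-tryptic product, i.e. one
#'   non-tryptic terminus).
#' @param min_len,max_len retained peptide length range.
#' @return a `digest_spec` list.
#' @export
digest_spec <- function(enzyme = "trypsin", missed_cleavages = 2L,
                        mode = c("semi", "full"), min_len = 7L, max_len = 50L) {
  mode <- match.arg(mode)
  stopifnot(enzyme == "trypsin", missed_cleavages >= 0L, min_len <= max_len,
            min_len >= 1L)
  structure(list(enzyme = enzyme, missed_cleavages = as.integer(missed_cleavages),
                 mode = mode, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)), class = "digest_spec")
}

#' In-silico digest of a protein sequence
#'
#' Trypsin rule: cleave after K or R except when the next residue is P. Full
#' mode returns every product with at most `missed_cleavages` internal
#' sites; semi mode additionally returns every prefix/suffix truncation of
#' each fully-tryptic product (one non-tryptic terminus). Products are
#' filtered to `[min_len, max_len]`; peptides containing `X` (ambiguous
#' translation) are dropped because search engines cannot match them.
#'
#' @param sequence amino-acid string (no whitespace).
#' @param spec a [digest_spec()].
#' @return data.frame `peptide`, `start` (0-based offset in `sequence`),
#'   `missed` (internal missed cleavages of the generating product), unique
#'   on (`peptide`, `start`), ordered by `start` then decreasing length.
#' @export
digest <- function(sequence, spec = digest_spec()) {
  stopifnot(nzchar(sequence), !grepl("\\s", sequence))
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1L]]
  after <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  b <- c(0L, after, n)
  nb <- length(b)
  starts <- integer(); ends <- integer(); missed <- integer()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(i + spec$missed_cleavages, nb - 1L)
    for (j in i:jmax) {
      starts <- c(starts, b[i]); ends <- c(ends, b[j + 1L])
      missed <- c(missed, j - i)
    }
  }
  if (spec$mode == "semi") {
    s2 <- integer(); e2 <- integer(); m2 <- integer()
    for (k in seq_along(starts)) {
      a <- starts[k]; z <- ends[k]
      # prefixes (tryptic N-terminus) and suffixes (tryptic C-terminus)
      pe <- seq.int(a + 1L, z)
      s2 <- c(s2, rep(a, length(pe)), seq.int(a, z - 1L))
      e2 <- c(e2, pe, rep(z, z - a))
      m2 <- c(m2, rep(missed[k], 2L * (z - a)))
    }
    starts <- s2; ends <- e2; missed <- m2
  }
  len <- ends - starts
  keep <- len >= spec$min_len & len <= spec$max_len
  starts <- starts[keep]; ends <- ends[keep]; missed <- missed[keep]
  if (!length(starts))
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer(), stringsAsFactors = FALSE))
  pep <- substring(sequence, starts + 1L, ends)
  ok <- !grepl("X", pep, fixed = TRUE)
  out <- data.frame(peptide = pep[ok], start = starts[ok], missed = missed[ok],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$peptide, out$start)), , drop = FALSE]
  out <- out[order(out$start, -nchar(out$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct protein database entries
#'
#' @param accession,sequence character vectors of equal length.
#' @param origin one of `"canonical"`, `"ncorf"`, `"decoy"` (recycled).
#' @param source_accession for decoys, the accession of the mirrored target.
#' @return data.frame with class `protein_db`.
#' @export
protein_db <- function(accession, sequence, origin,
                       source_accession = NA_character_) {
  stopifnot(all(origin %in% c("canonical", "ncorf", "decoy")))
  df <- data.frame(accession = accession, sequence = sequence,
                   origin = origin, source_accession = source_accession,
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_db", "data.frame")
  df
}

#' Reverse-sequence decoys for target entries
#'
#' Whole-sequence character reversal per protein, accession prefixed
#' `rev_`. Reversal of an entry that is already a decoy is an error.
#'
#' @param entries a `protein_db` data.frame of target entries.
#' @return `protein_db` of decoy entries, one per input row.
#' @export
reverse_decoy <- function(entries) {
  if (any(entries$origin == "decoy")) stop("refusing to reverse a decoy entry")
  revseq <- vapply(strsplit(entries$sequence, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  protein_db(paste0("rev_", entries$accession), revseq, "decoy",
             source_accession = entries$accession)
}

#' Build the target-decoy proteogenomic search database
#'
#' Concatenates ncORF and canonical target entries and appends one reversed
#' decoy per target, giving exactly twice the target count. No contaminant
#' entries are added.
#'
#' @param ncorf_db,canonical_db `protein_db` data.frames of targets.
#' @param fasta_path optional path; when given, the database is written as
#'   FASTA in input order (targets then decoys).
#' @return the combined `protein_db`.
#' @export
build_search_database <- function(ncorf_db, canonical_db, fasta_path = NULL) {
  targets <- rbind(ncorf_db, canonical_db)
  dup <- targets$accession[duplicated(targets$accession)]
  if (length(dup))
    stop("duplicate accessions across inputs: ", paste(unique(dup), collapse = ", "))
  db <- rbind(targets, reverse_decoy(targets))
  class(db) <- c("protein_db", "data.frame")
  if (!is.null(fasta_path)) write_protein_fasta(db, fasta_path)
  db
}

#' Read a protein FASTA as database entries
#' @param path FASTA path.
#' @param origin origin label for the entries (decoys recognized by the
#'   `rev_` accession prefix override this).
#' @return a `protein_db`.
#' @export
read_protein_fasta <- function(path, origin = "canonical") {
  ss <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(ss))
  org <- ifelse(startsWith(acc, "rev_"), "decoy", origin)
  protein_db(acc, as.character(ss), org,
             source_accession = ifelse(startsWith(acc, "rev_"),
                                       sub("^rev_", "", acc), NA_character_))
}

#' Write database entries to protein FASTA
#' @param db a `protein_db`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_protein_fasta <- function(db, path) {
  ss <- Biostrings::AAStringSet(db$sequence)
  names(ss) <- db$accession
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Exclude ncORF proteins indistinguishable from canonical sequence space
#'
#' A deterministic stand-in for an alignment-based exclusion of ncORF
#' proteins that collapse into the canonical proteome. An ncORF entry is
#' removed when (a) its full sequence occurs as a substring of any canonical
#' sequence under I=L equivalence, or (b) the fraction of its fully-tryptic
#' peptides (0 missed cleavages) that are also producible from the canonical
#' set strictly exceeds `shared_threshold`. An external aligner's removal
#' list can be supplied to reproduce tool-specific behaviour exactly.
#'
#' @param ncorf_db,canonical_db `protein_db` data.frames.
#' @param spec a [digest_spec()] whose length window is used for the shared
#'   tryptic peptides; mode/missed cleavages are fixed to full/0 here.
#' @param shared_threshold removal threshold on the shared-peptide fraction.
#' @param external_removals optional character vector of ncORF accessions to
#'   remove (reason `"external"`).
#' @return list with `retained` (`protein_db`) and `removed` (data.frame
#'   `accession`, `reason`).
#' @export
canonical_overlap_filter <- function(ncorf_db, canonical_db,
                                     spec = digest_spec(mode = "full",
                                                        missed_cleavages = 0L),
                                     shared_threshold = 0.9,
                                     external_removals = NULL) {
  full0 <- digest_spec(mode = "full", missed_cleavages = 0L,
                       min_len = spec$min_len, max_len = spec$max_len)
  canon_il <- il_collapse(canonical_db$sequence)
  canon_peps <- unique(il_collapse(unlist(
    lapply(canonical_db$sequence, function(s) digest(s, full0)$peptide))))
  removed <- data.frame(accession = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- logical(nrow(ncorf_db))
  for (i in seq_len(nrow(ncorf_db))) {
    acc <- ncorf_db$accession[i]
    if (!is.null(external_removals) && acc %in% external_removals) {
      removed <- rbind(removed, data.frame(accession = acc, reason = "external"))
      next
    }
    seq_il <- il_collapse(ncorf_db$sequence[i])
    if (any(grepl(seq_il, canon_il, fixed = TRUE))) {
      removed <- rbind(removed, data.frame(accession = acc, reason = "substring"))
      next
    }
    peps <- unique(il_collapse(digest(ncorf_db$sequence[i], full0)$peptide))
    if (length(peps)) {
      frac <- mean(peps %in% canon_peps)
      if (frac > shared_threshold) {
        removed <- rbind(removed,
                         data.frame(accession = acc, reason = "shared_peptides"))
        next
      }
    }
    keep[i] <- TRUE
  }
  list(retained = ncorf_db[keep, , drop = FALSE], removed = removed)
}
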