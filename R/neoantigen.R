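# Patient-specific mutated non-canonical proteomes, wildtype elimination,
# retention-time QC, hydrophobicity index and the epitope prioritization
# cascade (binding affinity, RT error, normal-tissue expression).

#' Build per-sample mutated ncORF proteins
#'
#' Eligible variants are those whose protein-altering consequence exists
#' only outside the canonical proteome: canonical-silent variants hitting
#' out-of-frame ncORFs, and variants outside the canonical CDS footprint
#' (UTR/flank/intron/RNA classes) hitting any ncORF. All eligible variants
#' of one sample on one ORF are applied jointly in genomic order on the
#' spliced transcript; frameshifts re-translate to the next stop codon (or
#' transcript end).
#'
#' @param pairs variant x ORF consequence table
#'   ([reannotate_variants()]`$pairs`).
#' @param variants the variant data.frame the pairs were derived from.
#' @param orfs ORF table.
#' @param transcripts `transcript_set`.
#' @param genome `genome_build`.
#' @return data.frame `orf_id`, `sample_id`, `wt_protein`, `mut_protein`,
#'   `variant_ids`, `changed_start`, `changed_end` (0-based half-open
#'   protein coordinates of the altered region). Records whose eligible
#'   variants overlap each other are rejected and reported in the
#'   `rejected` attribute.
#' @export
build_mutated_proteome <- function(pairs, variants, orfs, transcripts, genome) {
  eligible <- pairs$ncorf_class %in% NCORF_ALTERING &
    ((pairs$canonical_class == "silent" & pairs$category == "out_of_frame") |
       pairs$canonical_class %in% CANONICAL_NONCODING)
  el <- pairs[eligible, , drop = FALSE]
  out <- list(); rejected <- list()
  if (nrow(el)) {
    key <- paste(el$sample_id, el$orf_id, sep = "\r")
    for (grp in split(el, key)) {
      orf <- orfs[orfs$orf_id == grp$orf_id[1L], ][1L, ]
      t <- transcripts[[orf$transcript_id]]
      vs <- variants[match(grp$variant_id, variants$variant_id), , drop = FALSE]
      res <- tryCatch(
        apply_variants_to_orf(vs, orf, t, genome),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          orf_id = orf$orf_id, sample_id = grp$sample_id[1L], reason = res,
          stringsAsFactors = FALSE)
        next
      }
      if (res$mut_protein == orf$protein) next  # no net change
      out[[length(out) + 1L]] <- data.frame(
        orf_id = orf$orf_id, sample_id = grp$sample_id[1L],
        wt_protein = orf$protein, mut_protein = res$mut_protein,
        variant_ids = paste(sort(grp$variant_id), collapse = ";"),
        changed_start = res$changed[1L], changed_end = res$changed[2L],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(orf_id = character(), sample_id = character(),
               wt_protein = character(), mut_protein = character(),
               variant_ids = character(), changed_start = integer(),
               changed_end = integer())
  rownames(res) <- NULL
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(orf_id = character(), sample_id = character(),
               reason = character())
  res
}

# Apply a set of variants jointly to one ORF; returns the mutated protein
# and the changed protein interval. Variants must not overlap one another.
apply_variants_to_orf <- function(vs, orf, t, genome) {
  s <- spliced_sequence(t, genome)
  edits <- lapply(seq_len(nrow(vs)), function(i)
    transcript_edit(vs[i, ], t))
  edits <- edits[!vapply(edits, is.null, logical(1))]
  if (!length(edits)) stop("no exonic edit for this ORF")
  starts <- vapply(edits, function(e) e$t_start, integer(1))
  ends <- vapply(edits, function(e) e$t_end, integer(1))
  if (any(starts < orf$t_start))
    stop("variant extends 5' of the ORF start; unsupported")
  ord <- order(starts)
  if (any(ends[ord][-length(ord)] > starts[ord][-1L]))
    stop("conflicting overlapping variants in one sample")
  mut <- s
  for (e in edits[order(-starts)]) {
    mut <- paste0(substr(mut, 1L, e$t_start),
                  e$alt_t,
                  substring(mut, e$t_end + 1L))
  }
  mut_protein <- translate_frame(substring(mut, orf$t_start + 1L), 0L)
  wt_protein <- orf$protein
  changed <- protein_diff_interval(wt_protein, mut_protein)
  list(mut_protein = mut_protein, changed = changed)
}

# transcript-space edit [t_start, t_end) -> alt_t for one variant; NULL when
# the variant has no exonic footprint
transcript_edit <- function(v, t) {
  if (nzchar(v$ref) && nzchar(v$alt)) {  # SNV
    tp <- genomic_to_transcript(t, v$pos0)
    if (is.na(tp)) return(NULL)
    alt_t <- if (t$strand == "+") v$alt else rc(v$alt)
    return(list(t_start = tp, t_end = tp + 1L, alt_t = alt_t))
  }
  if (!nzchar(v$alt)) {  # deletion: exonic deleted positions
    tps <- genomic_to_transcript(t, seq.int(v$pos0, v$pos0 + nchar(v$ref) - 1L))
    tps <- sort(tps[!is.na(tps)])
    if (!length(tps)) return(NULL)
    if (length(tps) != tps[length(tps)] - tps[1L] + 1L)
      stop("deletion discontiguous on the spliced transcript")
    return(list(t_start = tps[1L], t_end = tps[length(tps)] + 1L, alt_t = ""))
  }
  # insertion
  tp0 <- genomic_to_transcript(t, v$pos0)
  if (is.na(tp0)) return(NULL)
  k <- if (t$strand == "+") tp0 + 1L else tp0
  alt_t <- if (t$strand == "+") v$alt else rc(v$alt)
  list(t_start = k, t_end = k, alt_t = alt_t)
}

# 0-based half-open interval of protein positions differing between wt and
# mut (on the mutated protein's coordinates)
protein_diff_interval <- function(wt, mut) {
  if (wt == mut) return(c(NA_integer_, NA_integer_))
  nw <- nchar(wt); nm <- nchar(mut)
  w <- strsplit(wt, "")[[1L]]; m <- strsplit(mut, "")[[1L]]
  k <- min(nw, nm)
  pre <- 0L
  while (pre < k && w[pre + 1L] == m[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < k - pre && w[nw - suf] == m[nm - suf]) suf <- suf + 1L
  c(pre, max(pre + 1L, nm - suf))
}

#' Candidate neoantigen peptides from mutated proteins
#'
#' Digests each mutated protein and keeps products overlapping the changed
#' interval (a peptide that does not span the alteration cannot distinguish
#' mutant from wildtype).
#'
#' @param mutated data.frame from [build_mutated_proteome()].
#' @param spec a [digest_spec()].
#' @return data.frame `peptide`, `orf_id`, `sample_id`, `start`.
#' @export
mutated_peptides <- function(mutated, spec = digest_spec()) {
  rows <- lapply(seq_len(nrow(mutated)), function(i) {
    d <- digest(mutated$mut_protein[i], spec)
    if (!nrow(d)) return(NULL)
    span <- d$start < mutated$changed_end[i] &
      d$start + nchar(d$peptide) > mutated$changed_start[i]
    d <- d[span, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(peptide = d$peptide, orf_id = mutated$orf_id[i],
               sample_id = mutated$sample_id[i], start = d$start,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(peptide = character(), orf_id = character(),
                      sample_id = character(), start = integer())
  res[!duplicated(paste(res$peptide, res$sample_id)), , drop = FALSE]
}

#' Eliminate peptides explainable by wildtype proteins
#'
#' A candidate peptide is removed when it occurs (I=L equivalent) as a
#' substring of any wildtype protein — canonical or unmutated ncORF — so
#' that every retained match is attributable to the somatic alteration.
#'
#' @param peptides data.frame with a `peptide` column (e.g. from
#'   [mutated_peptides()]).
#' @param wildtype_db `protein_db` of all canonical and unmutated ncORF
#'   proteins.
#' @return the retained subset of `peptides`.
#' @export
eliminate_wildtype_matches <- function(peptides, wildtype_db) {
  if (!nrow(peptides)) return(peptides)
  wt_il <- il_collapse(wildtype_db$sequence)
  keep <- vapply(il_collapse(peptides$peptide), function(p)
    !any(grepl(p, wt_il, fixed = TRUE)), logical(1))
  peptides[keep, , drop = FALSE]
}

#' Retention-time error
#'
#' Absolute difference between observed and predicted retention time; the
#' pass flag requires the error to be strictly below `threshold` minutes.
#' Missing values give `NA` error and a `FALSE`-free unset flag (`NA`).
#'
#' @param observed_min,predicted_min numeric vectors (minutes).
#' @param threshold pass threshold in minutes (default 5).
#' @return data.frame `rt_error_min`, `rt_pass`.
#' @export
retention_time_error <- function(observed_min, predicted_min, threshold = 5) {
  err <- abs(observed_min - predicted_min)
  data.frame(rt_error_min = err, rt_pass = err < threshold)
}

#' Additive hydropathy coefficients (Kyte-Doolittle)
#'
#' Per-residue coefficients used by the built-in hydrophobicity index.
#' @format named numeric vector over the 20 amino acids.
#' @export
hydropathy_coefficients <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Built-in hydrophobicity index
#'
#' Sum of per-residue coefficients with a mild length normalization
#' (`1 / (1 + 0.015 * max(0, length - 20))`), mirroring the additive form
#' of reversed-phase retention models. Used for retention-time QC
#' correlation only, never as a hard filter; externally predicted values
#' take precedence when supplied.
#'
#' @param peptide character vector of peptides over the 20-letter alphabet.
#' @param coefficients named numeric per-residue coefficients.
#' @return numeric vector of indices.
#' @export
hydrophobicity_index <- function(peptide, coefficients = hydropathy_coefficients) {
  vapply(peptide, function(p) {
    res <- strsplit(p, "")[[1L]]
    if (length(res) == 0L) return(0)
    if (any(!res %in% names(coefficients)))
      stop("unknown residue(s) in peptide: ", p)
    n <- length(res)
    sum(coefficients[res]) / (1 + 0.015 * max(0L, n - 20L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Prioritize epitope and neoantigen candidates
#'
#' Gate: predicted MHC-I binding affinity at or below `affinity_max` nM
#' (optionally also percentile rank below `rank_max`); support: retention
#' time error strictly below `rt_max` minutes OR normal-tissue median
#' expression strictly below `tpm_max` TPM. The report is
#' `{affinity_pass} AND ({rt_pass} OR {gtex_pass})`, ranked by affinity
#' ascending. Missing RT or expression values leave the respective flag
#' unset (never passing, never disqualifying on their own).
#'
#' @param candidates data.frame with columns `peptide`, `orf_id`,
#'   `sample_id`, `hla_allele`, `affinity_nM`, optional `percentile_rank`,
#'   `rt_observed_min`, `rt_predicted_min`, `gtex_median_tpm`, `mutated`.
#' @param affinity_max high-binder threshold in nM (default 150).
#' @param rt_max retention-time error threshold in minutes (default 5).
#' @param tpm_max normal-tissue expression threshold in TPM (default 1).
#' @param rank_max optional percentile-rank threshold (e.g. 2).
#' @return `candidates` with flag columns (`affinity_pass`, `rt_pass`,
#'   `gtex_pass`, `reported`), report rows first, ranked by affinity.
#' @export
prioritize_epitopes <- function(candidates, affinity_max = 150, rt_max = 5,
                                tpm_max = 1, rank_max = NULL) {
  stopifnot(all(candidates$affinity_nM > 0))
  cand <- candidates
  cand$affinity_pass <- cand$affinity_nM <= affinity_max
  if (!is.null(rank_max) && "percentile_rank" %in% names(cand))
    cand$affinity_pass <- cand$affinity_pass &
      !is.na(cand$percentile_rank) & cand$percentile_rank < rank_max
  if (all(c("rt_observed_min", "rt_predicted_min") %in% names(cand))) {
    rt <- retention_time_error(cand$rt_observed_min, cand$rt_predicted_min,
                               threshold = rt_max)
    cand$rt_error_min <- rt$rt_error_min
    cand$rt_pass <- !is.na(rt$rt_pass) & rt$rt_pass
  } else {
    cand$rt_error_min <- NA_real_
    cand$rt_pass <- FALSE
  }
  if ("gtex_median_tpm" %in% names(cand)) {
    cand$gtex_pass <- !is.na(cand$gtex_median_tpm) &
      cand$gtex_median_tpm < tpm_max
  } else {
    cand$gtex_pass <- FALSE
  }
  cand$reported <- cand$affinity_pass & (cand$rt_pass | cand$gtex_pass)
  cand[order(-cand$reported, cand$affinity_nM, cand$peptide), , drop = FALSE]
}

#' Write per-sample mutated proteome FASTA
#'
#' Accessions follow `ncorf|<orf_id>|mut|<sample_id>`.
#'
#' @param mutated data.frame from [build_mutated_proteome()].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_mutated_proteome <- function(mutated, path) {
  ss <- Biostrings::AAStringSet(mutated$mut_protein)
  names(ss) <- paste("ncorf", mutated$orf_id, "mut", mutated$sample_id,
                     sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
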