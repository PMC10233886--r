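# PSM-level target-decoy FDR, filtering, peptide-to-ORF mapping with
# canonical exclusion, and cohort-level evidence summaries.

PSM_COLUMNS <- c("spectrum_id", "peptide", "score", "probability",
                 "accessions", "sample_id", "cohort", "assay")

#' Read a PSM table
#'
#' Expected TSV columns: `spectrum_id`, `peptide`, `score`, `probability`,
#' `accessions` (semicolon-joined), `sample_id`, `cohort`, `assay`
#' (`proteome` or `immunopeptidome`); an optional logical `validated`
#' column carries external peptide-centric re-validation calls. The decoy
#' flag is derived from the `rev_` accession prefix (a row is a decoy when
#' all its accession hits are decoys).
#'
#' @param path TSV path.
#' @return data.frame of PSM records with an `is_decoy` column.
#' @export
read_psm_table <- function(path) {
  df <- read_tsv_table(path)
  missing <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing))
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "))
  if (!"is_decoy" %in% names(df)) {
    df$is_decoy <- vapply(strsplit(df$accessions, ";", fixed = TRUE),
                          function(a) all(startsWith(a, "rev_")), logical(1))
  }
  df
}

#' Target-decoy q-values at the PSM level
#'
#' Records are ranked by descending score (ties broken by `spectrum_id` for
#' determinism). At each score threshold the FDR estimate is
#' `#decoys / max(1, #targets)` among records at or above the threshold
#' (optionally `(#decoys + 1)` with `plus_one = TRUE`); q-values are the
#' running minimum FDR from the permissive end, so they are monotone
#' non-decreasing with rank, and tied scores share one q-value.
#'
#' @param psms PSM data.frame with `score`, `is_decoy`, `spectrum_id`.
#' @param plus_one use the +1-corrected decoy count.
#' @return `psms` with a `q_value` column appended (input order preserved).
#' @export
compute_fdr <- function(psms, plus_one = FALSE) {
  stopifnot(all(c("score", "is_decoy", "spectrum_id") %in% names(psms)))
  if (anyNA(psms$score)) stop("every PSM must carry a score")
  n <- nrow(psms)
  if (n == 0L) { psms$q_value <- numeric(); return(psms) }
  if (all(psms$is_decoy)) {
    warning("all-decoy PSM input: q-values degenerate to 1")
    psms$q_value <- 1
    return(psms)
  }
  ord <- order(-psms$score, psms$spectrum_id)
  sc <- psms$score[ord]
  d <- cumsum(psms$is_decoy[ord])
  t <- cumsum(!psms$is_decoy[ord])
  # evaluate FDR at the last row of each tie group so ties share a q-value
  last_of_group <- c(sc[-n] != sc[-1L], TRUE)
  idx <- which(last_of_group)
  fdr <- (d[idx] + as.integer(plus_one)) / pmax(1L, t[idx])
  q_grp <- rev(cummin(rev(fdr)))
  grp <- cumsum(c(TRUE, sc[-n] != sc[-1L]))
  q_sorted <- q_grp[grp]
  q <- numeric(n)
  q[ord] <- q_sorted
  psms$q_value <- q
  psms
}

#' Filter PSMs by assay-specific thresholds
#'
#' Proteome-assay records are retained at `q_value <= q_max`;
#' immunopeptidome-assay records at `probability >= p_min` and peptide
#' length within `len_range`. Decoy records are always removed from the
#' retained set, and when a `validated` column is present retained records
#' must have it `TRUE`.
#'
#' @param psms PSM data.frame with `q_value` computed.
#' @param q_max PSM-level FDR threshold for proteome records.
#' @param p_min probability threshold for immunopeptidome records.
#' @param len_range inclusive peptide length range for immunopeptidome
#'   records.
#' @return the retained PSM data.frame.
#' @export
filter_psms <- function(psms, q_max = 0.01, p_min = 0.99,
                        len_range = c(8L, 25L)) {
  stopifnot("q_value" %in% names(psms))
  len <- nchar(psms$peptide)
  keep <- ifelse(psms$assay == "immunopeptidome",
                 !is.na(psms$probability) & psms$probability >= p_min &
                   len >= len_range[1L] & len <= len_range[2L],
                 psms$q_value <= q_max)
  keep <- keep & !psms$is_decoy
  if ("validated" %in% names(psms))
    keep <- keep & !is.na(psms$validated) & as.logical(psms$validated)
  psms[keep, , drop = FALSE]
}

#' Map retained peptides to ncORFs with canonical exclusion
#'
#' Each peptide is assigned to every ncORF protein that contains it under
#' I=L equivalence. Peptides that also occur in any canonical sequence are
#' discarded as non-discriminating; peptides matching nothing are reported
#' as orphans. Evidence is aggregated per ORF with cohort and assay
#' provenance.
#'
#' @param psms retained PSM data.frame (from [filter_psms()]).
#' @param db a `protein_db` containing the ncORF and canonical entries.
#' @param orfs optional ORF table; when given, `gene_id` is attached to the
#'   evidence.
#' @return list with `evidence` (data.frame `orf_id`, `n_peptides`,
#'   `n_cohorts`, `peptides`, `cohorts`, `assays`, and `gene_id` when
#'   available), `peptide_map` (`peptide`, `orf_id`), `canonical_discarded`
#'   and `orphans` (character vectors of peptides).
#' @export
map_peptides_to_ncorfs <- function(psms, db, orfs = NULL) {
  ncorf_db <- db[db$origin == "ncorf", , drop = FALSE]
  canon_il <- il_collapse(db$sequence[db$origin == "canonical"])
  ncorf_il <- il_collapse(ncorf_db$sequence)
  ncorf_ids <- parse_orf_accession(ncorf_db$accession)$orf_id
  ncorf_ids[is.na(ncorf_ids)] <- ncorf_db$accession[is.na(ncorf_ids)]

  peptides <- unique(psms$peptide)
  map <- list(); canonical_discarded <- character(); orphans <- character()
  for (pep in peptides) {
    p_il <- il_collapse(pep)
    if (length(canon_il) && any(grepl(p_il, canon_il, fixed = TRUE))) {
      canonical_discarded <- c(canonical_discarded, pep)
      next
    }
    hit <- grepl(p_il, ncorf_il, fixed = TRUE)
    if (!any(hit)) { orphans <- c(orphans, pep); next }
    map[[length(map) + 1L]] <- data.frame(peptide = pep,
                                          orf_id = unique(ncorf_ids[hit]),
                                          stringsAsFactors = FALSE)
  }
  peptide_map <- if (length(map)) do.call(rbind, map) else
    data.frame(peptide = character(), orf_id = character())
  hits <- merge(peptide_map, psms[, intersect(c("peptide", "cohort", "assay",
                                                "sample_id"), names(psms))],
                by = "peptide")
  evidence <- if (nrow(hits)) {
    do.call(rbind, lapply(split(hits, hits$orf_id), function(h) {
      data.frame(orf_id = h$orf_id[1L],
                 n_peptides = length(unique(h$peptide)),
                 n_cohorts = length(unique(h$cohort)),
                 peptides = paste(sort(unique(h$peptide)), collapse = ";"),
                 cohorts = paste(sort(unique(h$cohort)), collapse = ";"),
                 assays = paste(sort(unique(h$assay)), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(orf_id = character(), n_peptides = integer(),
               n_cohorts = integer(), peptides = character(),
               cohorts = character(), assays = character())
  }
  rownames(evidence) <- NULL
  if (!is.null(orfs) && nrow(evidence))
    evidence$gene_id <- orfs$gene_id[match(evidence$orf_id, orfs$orf_id)]
  list(evidence = evidence, peptide_map = peptide_map,
       canonical_discarded = canonical_discarded, orphans = orphans)
}

#' Flag pervasively translated ORFs
#'
#' ORFs with peptide support in at least `min_cohorts` cohorts (default 8,
#' the pervasive-translation convention) are flagged.
#'
#' @param evidence evidence data.frame from [map_peptides_to_ncorfs()].
#' @param min_cohorts minimum number of supporting cohorts.
#' @return subset of `evidence`, sorted by cohort count descending then
#'   `orf_id`.
#' @export
cohort_pervasiveness <- function(evidence, min_cohorts = 8L) {
  out <- evidence[evidence$n_cohorts >= min_cohorts, , drop = FALSE]
  out[order(-out$n_cohorts, out$orf_id), , drop = FALSE]
}

#' Attach differential-expression classes to ORF evidence
#'
#' A gene is `over`-expressed at p-value below `p_max` and log2 fold change
#' at or above `lfc`, `under`-expressed at p-value below `p_max` and log2
#' fold change at or below `-lfc`, otherwise `none`; genes absent from the
#' table are `none`.
#'
#' @param evidence evidence data.frame carrying `gene_id`.
#' @param de_table data.frame `gene_id`, `log2fc`, `p_value`.
#' @param lfc,p_max thresholds (defaults 1.5 and 0.01).
#' @return `evidence` with a `de_class` column.
#' @export
annotate_differential_expression <- function(evidence, de_table, lfc = 1.5,
                                             p_max = 0.01) {
  stopifnot("gene_id" %in% names(evidence))
  i <- match(evidence$gene_id, de_table$gene_id)
  l2 <- de_table$log2fc[i]; pv <- de_table$p_value[i]
  cls <- rep("none", nrow(evidence))
  cls[!is.na(pv) & pv < p_max & !is.na(l2) & l2 >= lfc] <- "over"
  cls[!is.na(pv) & pv < p_max & !is.na(l2) & l2 <= -lfc] <- "under"
  evidence$de_class <- cls
  evidence
}

#' Two-sample rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test, used for conservation strata,
#' peptide-length and mutation-burden comparisons.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return list with `statistic`, `p_value`, `method`.
#' @export
stratified_rank_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
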