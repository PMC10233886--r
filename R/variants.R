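# Somatic variant ingestion (MAF / VCF), frame-aware projection into ncORFs,
# consequence calling, three-way cross-classification and mutation burden.
#
# Internal variant representation: `pos0` is the 0-based genomic position of
# the first reference base; `ref`/`alt` are nucleotide strings, "" for pure
# insertions/deletions. An insertion with ref "" is placed between pos0 and
# pos0 + 1 (i.e. after the base at pos0).

CANONICAL_NONCODING <- c("utr5", "utr3", "flank5", "flank3", "intron",
                         "splice_region", "rna", "other")
CANONICAL_ALTERING <- c("missense", "stop_gained", "stop_lost", "frameshift",
                        "inframe_indel")
NCORF_ALTERING <- c("missense", "frameshift_ins", "frameshift_del",
                    "inframe_ins", "inframe_del", "stop_gained", "stop_lost")

MAF_CLASS_MAP <- c(
  "5'UTR" = "utr5", "3'UTR" = "utr3", "5'Flank" = "flank5",
  "3'Flank" = "flank3", "Intron" = "intron", "Splice_Region" = "splice_region",
  "RNA" = "rna", "Silent" = "silent", "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "stop_gained", "Nonstop_Mutation" = "stop_lost",
  "Frame_Shift_Del" = "frameshift", "Frame_Shift_Ins" = "frameshift",
  "In_Frame_Del" = "inframe_indel", "In_Frame_Ins" = "inframe_indel")

canonical_class_to_maf <- function(cls, ref, alt) {
  ins <- nchar(ref) < nchar(alt)
  out <- cls
  out[cls == "utr5"] <- "5'UTR"; out[cls == "utr3"] <- "3'UTR"
  out[cls == "flank5"] <- "5'Flank"; out[cls == "flank3"] <- "3'Flank"
  out[cls == "intron"] <- "Intron"; out[cls == "splice_region"] <- "Splice_Region"
  out[cls == "rna"] <- "RNA"; out[cls == "silent"] <- "Silent"
  out[cls == "missense"] <- "Missense_Mutation"
  out[cls == "stop_gained"] <- "Nonsense_Mutation"
  out[cls == "stop_lost"] <- "Nonstop_Mutation"
  out[cls == "frameshift"] <- ifelse(ins[cls == "frameshift"],
                                     "Frame_Shift_Ins", "Frame_Shift_Del")
  out[cls == "inframe_indel"] <- ifelse(ins[cls == "inframe_indel"],
                                        "In_Frame_Ins", "In_Frame_Del")
  out
}

#' Read somatic variants from a GDC-dialect MAF
#'
#' Uses the `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification` and `Tumor_Sample_Barcode`
#' columns (plus an optional `cohort` column). 1-based MAF conventions are
#' converted to the internal 0-based representation: for insertions
#' (`Reference_Allele == "-"`) `Start_Position` is the base before the
#' inserted sequence. Reference alleles are checked against the genome when
#' one is supplied; indels are left-normalized.
#'
#' @param path MAF path (TSV, may contain `#` comment lines).
#' @param genome optional `genome_build` for reference checking and
#'   normalization.
#' @return data.frame `variant_id`, `contig`, `pos0`, `ref`, `alt`,
#'   `sample_id`, `cohort`, `canonical_class`.
#' @export
read_maf <- function(path, genome = NULL) {
  # read everything as character: single-letter alleles like "T" must not
  # collapse to logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if ("Start_Position" %in% names(df))
    df$Start_Position <- as.integer(df$Start_Position)
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("MAF missing column(s): ", paste(missing, collapse = ", "))
  ref <- ifelse(df$Reference_Allele == "-", "", df$Reference_Allele)
  alt <- ifelse(df$Tumor_Seq_Allele2 == "-", "", df$Tumor_Seq_Allele2)
  # SNP/DEL: Start_Position is the first reference base; INS: the base
  # before the inserted sequence (the internal anchor)
  pos0 <- df$Start_Position - 1L
  cls <- if ("Variant_Classification" %in% names(df))
    unname(MAF_CLASS_MAP[df$Variant_Classification]) else NA_character_
  v <- data.frame(
    variant_id = sprintf("%s:%d:%s>%s:%s", df$Chromosome, as.integer(pos0),
                         ifelse(ref == "", "-", ref),
                         ifelse(alt == "", "-", alt), df$Tumor_Sample_Barcode),
    contig = df$Chromosome, pos0 = as.integer(pos0), ref = ref, alt = alt,
    sample_id = df$Tumor_Sample_Barcode,
    cohort = if ("cohort" %in% names(df)) df$cohort else NA_character_,
    canonical_class = cls, stringsAsFactors = FALSE)
  finalize_variants(v, genome)
}

#' Read somatic variants from a VCF 4.x file
#'
#' Minimal site-level reader (CHROM/POS/REF/ALT); sample and cohort labels
#' are taken from optional `SAMPLE=` / `COHORT=` INFO keys. Multi-allelic
#' records must be normalized upstream.
#'
#' @param path VCF path.
#' @param genome optional `genome_build`.
#' @return data.frame in the same shape as [read_maf()] output
#'   (`canonical_class` is `NA`; compute it with
#'   [compute_canonical_class()]).
#' @export
read_vcf_variants <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(finalize_variants(data.frame(
      variant_id = character(), contig = character(), pos0 = integer(),
      ref = character(), alt = character(), sample_id = character(),
      cohort = character(), canonical_class = character()), genome))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, function(x) x[i], character(1))
  alt <- get(5)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records present; normalize the input first")
  info <- vapply(f, function(x) if (length(x) >= 8L) x[8] else ".", character(1))
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0("^.*", key, "="), "",
                    regmatches(info, regexpr(paste0(key, "=[^;]+"), info)))
    out
  }
  ref <- get(4); pos1 <- as.integer(get(2))
  # trim the shared VCF anchor base for indels
  anchored <- nchar(ref) != nchar(alt) &
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  pos0 <- pos1 - 1L
  ref2 <- ref; alt2 <- alt
  ref2[anchored] <- substring(ref[anchored], 2L)
  alt2[anchored] <- substring(alt[anchored], 2L)
  # after trimming, a pure insertion sits after pos0 (the anchor base);
  # a pure deletion starts at pos0 + 1
  pos0[anchored & ref2 == ""] <- pos0[anchored & ref2 == ""]
  pos0[anchored & ref2 != ""] <- pos0[anchored & ref2 != ""] + 1L
  sample_id <- grab("SAMPLE"); cohort <- grab("COHORT")
  v <- data.frame(
    variant_id = sprintf("%s:%d:%s>%s:%s", get(1), pos0,
                         ifelse(ref2 == "", "-", ref2),
                         ifelse(alt2 == "", "-", alt2),
                         ifelse(is.na(sample_id), "NA", sample_id)),
    contig = get(1), pos0 = pos0, ref = ref2, alt = alt2,
    sample_id = sample_id, cohort = cohort,
    canonical_class = NA_character_, stringsAsFactors = FALSE)
  finalize_variants(v, genome)
}

finalize_variants <- function(v, genome) {
  if (!is.null(genome) && nrow(v)) {
    for (i in seq_len(nrow(v))) {
      vi <- left_normalize_variant(v[i, ], genome)
      v$pos0[i] <- vi$pos0; v$ref[i] <- vi$ref; v$alt[i] <- vi$alt
      if (nzchar(v$ref[i])) {
        obs <- substr(genome[[v$contig[i]]], v$pos0[i] + 1L,
                      v$pos0[i] + nchar(v$ref[i]))
        if (obs != v$ref[i])
          stop("reference allele mismatch at ", v$contig[i], ":", v$pos0[i],
               " (expected ", v$ref[i], ", genome has ", obs, ")")
      }
    }
  }
  bad <- v$ref == v$alt
  if (any(bad)) stop("ref equals alt for variant(s): ",
                     paste(v$variant_id[bad], collapse = ", "))
  v
}

# shift pure insertions/deletions to the smallest genomic coordinate with an
# identical haplotype
left_normalize_variant <- function(v, genome) {
  if (nzchar(v$ref) && nzchar(v$alt)) return(v)  # substitution: nothing to do
  ctg <- genome[[v$contig]]
  seqv <- if (nzchar(v$ref)) v$ref else v$alt
  if (nzchar(v$ref)) {
    # deletion of [pos0, pos0+L): shifting left by one preserves the
    # haplotype exactly when the base before the window equals its last base
    while (v$pos0 > 0L &&
           substr(ctg, v$pos0, v$pos0) ==
           substr(seqv, nchar(seqv), nchar(seqv))) {
      seqv <- paste0(substr(ctg, v$pos0, v$pos0),
                     substr(seqv, 1L, nchar(seqv) - 1L))
      v$pos0 <- v$pos0 - 1L
    }
    v$ref <- seqv
  } else {
    # insertion after pos0
    while (v$pos0 > 0L &&
           substr(ctg, v$pos0 + 1L, v$pos0 + 1L) ==
           substr(seqv, nchar(seqv), nchar(seqv))) {
      seqv <- paste0(substr(ctg, v$pos0 + 1L, v$pos0 + 1L),
                     substr(seqv, 1L, nchar(seqv) - 1L))
      v$pos0 <- v$pos0 - 1L
    }
    v$alt <- seqv
  }
  v
}

#' Project a variant into an ORF's local frame
#'
#' @param v single-row variant data.frame.
#' @param orf single-row ORF record.
#' @param t the ORF's `transcript_model`.
#' @return for in-ORF variants, a list with `t_pos` (transcript position of
#'   the first affected base, or insertion point), `codon_index` (0-based)
#'   and `codon_offset` (SNVs only); `NULL` when the variant is intronic or
#'   outside `[t_start, t_end)`.
#' @export
project_variant <- function(v, orf, t) {
  if (v$contig != t$contig) return(NULL)
  if (nzchar(v$ref) && nzchar(v$alt) && nchar(v$ref) == 1L) {
    tp <- genomic_to_transcript(t, v$pos0)
    if (is.na(tp) || tp < orf$t_start || tp >= orf$t_end) return(NULL)
    rel <- tp - orf$t_start
    return(list(t_pos = tp, codon_index = rel %/% 3L, codon_offset = rel %% 3L))
  }
  if (!nzchar(v$alt)) {  # deletion
    tps <- genomic_to_transcript(t, seq.int(v$pos0, v$pos0 + nchar(v$ref) - 1L))
    tps <- tps[!is.na(tps) & tps >= orf$t_start & tps < orf$t_end]
    if (!length(tps)) return(NULL)
    return(list(t_pos = min(tps), codon_index = (min(tps) - orf$t_start) %/% 3L,
                codon_offset = NA_integer_, n_exonic_deleted = length(tps)))
  }
  if (!nzchar(v$ref)) {  # insertion between pos0 and pos0 + 1
    tp0 <- genomic_to_transcript(t, v$pos0)
    if (is.na(tp0)) return(NULL)
    k <- if (t$strand == "+") tp0 + 1L else tp0
    if (k <= orf$t_start || k >= orf$t_end) return(NULL)
    return(list(t_pos = k, codon_index = (k - orf$t_start) %/% 3L,
                codon_offset = NA_integer_))
  }
  stop("multi-nucleotide substitutions are not supported; ",
       "normalize the input first")
}

#' Call the consequence of a variant in one ncORF frame
#'
#' SNVs are classified by comparing the translated codon before and after
#' the edit on the strand-correct spliced ORF sequence: same residue ->
#' `silent`; new stop in the ORF body -> `stop_gained`; a stop codon turned
#' into a sense codon -> `stop_lost`; otherwise `missense`. Indels are
#' classified by the number of affected exonic bases modulo 3
#' (`frameshift_*` vs `inframe_*`).
#'
#' @param v single-row variant data.frame.
#' @param orf single-row ORF record.
#' @param t the ORF's `transcript_model`.
#' @param genome a `genome_build`.
#' @return list with `orf_id`, `ncorf_class` (`"none"` when the variant does
#'   not overlap the ORF) and `protein_change`.
#' @export
call_ncorf_consequence <- function(v, orf, t, genome) {
  if (grepl(",", v$alt, fixed = TRUE))
    stop("multi-allelic record; normalize the input first")
  pr <- project_variant(v, orf, t)
  if (is.null(pr))
    return(list(orf_id = orf$orf_id, ncorf_class = "none", protein_change = ""))
  if (nzchar(v$ref) && nzchar(v$alt) && nchar(v$ref) == nchar(v$alt) &&
      nchar(v$ref) == 1L) {
    s <- spliced_sequence(t, genome)
    ci <- pr$codon_index
    cod_start <- orf$t_start + 3L * ci
    wt_codon <- substr(s, cod_start + 1L, cod_start + 3L)
    alt_t <- if (t$strand == "+") v$alt else rc(v$alt)
    mut_codon <- wt_codon
    substr(mut_codon, pr$codon_offset + 1L, pr$codon_offset + 1L) <- alt_t
    wt_aa <- unname(codon_table[wt_codon]); if (is.na(wt_aa)) wt_aa <- "X"
    mut_aa <- unname(codon_table[mut_codon]); if (is.na(mut_aa)) mut_aa <- "X"
    if (wt_aa == mut_aa)
      return(list(orf_id = orf$orf_id, ncorf_class = "silent",
                  protein_change = ""))
    if (wt_aa == "*")
      return(list(orf_id = orf$orf_id, ncorf_class = "stop_lost",
                  protein_change = sprintf("p.*%d%sext", ci + 1L, mut_aa)))
    if (mut_aa == "*")
      return(list(orf_id = orf$orf_id, ncorf_class = "stop_gained",
                  protein_change = sprintf("p.%s%d*", wt_aa, ci + 1L)))
    return(list(orf_id = orf$orf_id, ncorf_class = "missense",
                protein_change = sprintf("p.%s%d%s", wt_aa, ci + 1L, mut_aa)))
  }
  if (nzchar(v$ref) && nzchar(v$alt))
    stop("multi-nucleotide substitutions are not supported; ",
         "normalize the input first")
  if (!nzchar(v$alt)) {
    m <- pr$n_exonic_deleted
    cls <- if (m %% 3L == 0L) "inframe_del" else "frameshift_del"
    return(list(orf_id = orf$orf_id, ncorf_class = cls,
                protein_change = sprintf("p.%d%s", pr$codon_index + 1L,
                                         if (m %% 3L == 0L) "del" else "fs")))
  }
  m <- nchar(v$alt)
  cls <- if (m %% 3L == 0L) "inframe_ins" else "frameshift_ins"
  list(orf_id = orf$orf_id, ncorf_class = cls,
       protein_change = sprintf("p.%d%s", pr$codon_index + 1L,
                                if (m %% 3L == 0L) "ins" else "fs"))
}

#' Compute a variant's canonical consequence on one transcript
#'
#' Used when the input carries no variant-classification column. Noncoding
#' transcripts give `rna`; intronic positions give `intron`; positions
#' outside the transcript span give `flank5`/`flank3`; exonic positions 5'
#' or 3' of the CDS give `utr5`/`utr3`; in-CDS variants are classified with
#' the same consequence engine as ncORFs (indel classes collapse to
#' `frameshift` / `inframe_indel`).
#'
#' @param v single-row variant data.frame.
#' @param t a `transcript_model`.
#' @param genome a `genome_build`.
#' @return canonical class string.
#' @export
compute_canonical_class <- function(v, t, genome) {
  if (t$biotype != "protein_coding") return("rna")
  span <- range(c(t$exons$start, t$exons$end))
  first_pos <- v$pos0
  if (first_pos < span[1L] || first_pos >= span[2L]) {
    left_flank <- first_pos < span[1L]
    return(if ((t$strand == "+") == left_flank) "flank5" else "flank3")
  }
  cds_orf <- list(orf_id = paste0(t$transcript_id, ":CDS"),
                  t_start = t$cds_span[1L], t_end = t$cds_span[2L])
  res <- call_ncorf_consequence(v, cds_orf, t, genome)
  if (res$ncorf_class != "none") {
    cls <- res$ncorf_class
    cls[cls %in% c("frameshift_ins", "frameshift_del")] <- "frameshift"
    cls[cls %in% c("inframe_ins", "inframe_del")] <- "inframe_indel"
    return(cls)
  }
  tp <- if (nzchar(v$ref)) genomic_to_transcript(t, v$pos0) else {
    tp0 <- genomic_to_transcript(t, v$pos0)
    if (is.na(tp0)) NA_integer_ else if (t$strand == "+") tp0 + 1L else tp0
  }
  if (is.na(tp)) return("intron")
  if (tp < t$cds_span[1L]) "utr5" else "utr3"
}

#' Cross-classify variants into the three overlap groups
#'
#' Group `1_utr_derived`: the canonical annotation is noncoding (UTR, flank,
#' intron, splice region, RNA) and the variant alters an ncORF protein.
#' Group `2_overlap_canonical`: the variant lies in sequence shared by the
#' canonical CDS and an ncORF (canonical class missense/silent or another
#' coding class) and alters the ncORF protein. Group `3_canonical_only`:
#' no overlapping ncORF protein is altered (e.g. silent in the ncORF or a
#' retained stop).
#'
#' @param canonical_class,ncorf_class character vectors (recycled).
#' @return character vector of group labels.
#' @export
cross_classify <- function(canonical_class, ncorf_class) {
  altered <- ncorf_class %in% NCORF_ALTERING
  ifelse(!altered, "3_canonical_only",
         ifelse(canonical_class %in% CANONICAL_NONCODING,
                "1_utr_derived", "2_overlap_canonical"))
}

#' Re-annotate variants against all overlapping ncORFs
#'
#' For every variant, every ncORF whose genomic footprint it overlaps is
#' scored with [call_ncorf_consequence()]; canonical classes are taken from
#' the input when present and computed with [compute_canonical_class()]
#' otherwise. Each variant additionally receives exactly one overlap group
#' via [cross_classify()] (using its most severe ncORF consequence).
#'
#' @param variants variant data.frame ([read_maf()] shape).
#' @param orfs ORF table.
#' @param transcripts `transcript_set`.
#' @param genome `genome_build`.
#' @return list with `pairs` (one row per variant x overlapping ORF:
#'   `variant_id`, `sample_id`, `cohort`, `orf_id`, `category`,
#'   `canonical_class`, `ncorf_class`, `protein_change`, `figure_group`)
#'   and `variants` (per-variant: `variant_id`, `sample_id`, `cohort`,
#'   `canonical_class`, `ncorf_altered`, `figure_group`; `figure_group` is
#'   `NA` for variants overlapping no ncORF).
#' @export
reannotate_variants <- function(variants, orfs, transcripts, genome) {
  pair_rows <- list()
  var_rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cls <- v$canonical_class
    v_pairs <- list()
    for (j in seq_len(nrow(orfs))) {
      orf <- orfs[j, ]
      t <- transcripts[[orf$transcript_id]]
      if (is.null(t) || t$contig != v$contig) next
      res <- call_ncorf_consequence(v, orf, t, genome)
      if (res$ncorf_class == "none") next
      cc <- if (!is.na(cls)) cls else compute_canonical_class(v, t, genome)
      v_pairs[[length(v_pairs) + 1L]] <- data.frame(
        variant_id = v$variant_id, sample_id = v$sample_id, cohort = v$cohort,
        orf_id = orf$orf_id, category = orf$category, canonical_class = cc,
        ncorf_class = res$ncorf_class, protein_change = res$protein_change,
        stringsAsFactors = FALSE)
    }
    if (length(v_pairs)) {
      vp <- do.call(rbind, v_pairs)
      vp$figure_group <- cross_classify(vp$canonical_class, vp$ncorf_class)
      pair_rows[[length(pair_rows) + 1L]] <- vp
      altered <- any(vp$ncorf_class %in% NCORF_ALTERING)
      grp <- if (altered) {
        cc <- vp$canonical_class[vp$ncorf_class %in% NCORF_ALTERING][1L]
        cross_classify(cc, vp$ncorf_class[vp$ncorf_class %in% NCORF_ALTERING][1L])
      } else "3_canonical_only"
      cc_all <- vp$canonical_class[1L]
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        variant_id = v$variant_id, sample_id = v$sample_id, cohort = v$cohort,
        canonical_class = cc_all, ncorf_altered = altered, figure_group = grp,
        stringsAsFactors = FALSE)
    } else {
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        variant_id = v$variant_id, sample_id = v$sample_id, cohort = v$cohort,
        canonical_class = if (!is.na(cls)) cls else NA_character_,
        ncorf_altered = FALSE, figure_group = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(variant_id = character(), sample_id = character(),
               cohort = character(), orf_id = character(),
               category = character(), canonical_class = character(),
               ncorf_class = character(), protein_change = character(),
               figure_group = character())
  vars <- do.call(rbind, var_rows)
  rownames(pairs) <- rownames(vars) <- NULL
  list(pairs = pairs, variants = vars)
}

#' Per-sample mutation burden and cohort comparison
#'
#' Canonical scope counts variants with protein-altering canonical classes;
#' ncORF scope counts variants whose only protein-altering consequence is
#' in an ncORF (canonical class non-altering, ncORF protein altered). Each
#' variant is counted once per sample regardless of how many ORFs it hits.
#'
#' @param variant_summary per-variant data.frame from
#'   [reannotate_variants()]`$variants`.
#' @param region_size_mb surveyed region size in megabases (default 38, a
#'   typical exome target).
#' @return data.frame `sample_id`, `cohort`, `canonical_v_mb`,
#'   `ncorf_only_v_mb`, plus a `comparisons` attribute: per-cohort rank-sum
#'   p-values between the two distributions.
#' @export
mutation_burden <- function(variant_summary, region_size_mb = 38) {
  stopifnot(region_size_mb > 0)
  vs <- variant_summary
  vs$canon_alt <- vs$canonical_class %in% CANONICAL_ALTERING
  vs$ncorf_only <- vs$ncorf_altered & !vs$canon_alt
  samples <- unique(vs[, c("sample_id", "cohort")])
  burden <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    sub <- vs[vs$sample_id == samples$sample_id[i], ]
    data.frame(sample_id = samples$sample_id[i], cohort = samples$cohort[i],
               canonical_v_mb = sum(sub$canon_alt) / region_size_mb,
               ncorf_only_v_mb = sum(sub$ncorf_only) / region_size_mb,
               stringsAsFactors = FALSE)
  }))
  comps <- do.call(rbind, lapply(split(burden, burden$cohort), function(b) {
    p <- if (nrow(b) >= 2L)
      stratified_rank_test(b$canonical_v_mb, b$ncorf_only_v_mb)$p_value
    else NA_real_
    data.frame(cohort = b$cohort[1L], p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(burden) <- rownames(comps) <- NULL
  attr(burden, "comparisons") <- comps
  burden
}
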