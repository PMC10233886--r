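# Independent oracles: deliberately naive re-derivations used to check the
# package implementations. They share only low-level primitives that are
# themselves tested directly (coordinate maps, reverse complement).

GENCODE_TAB <- Biostrings::GENETIC_CODE
oracle_translate <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  out <- character()
  for (p in seq(1L, n - 2L, by = 3L)) {
    aa <- GENCODE_TAB[substr(nt, p, p + 2L)]
    if (is.na(aa)) aa <- "X"
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# Brute-force all-AUG ORF scan: walk every ATG position independently, then
# keep the 5'-most ATG per (stop, frame), drop the canonical CDS and
# same-frame CDS overlaps, classify by interval arithmetic.
oracle_orfs <- function(t, genome, min_codons) {
  s <- spliced_sequence(t, genome)
  n <- nchar(s)
  hits <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    stop_end <- NA_integer_
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) { stop_end <- j + 2L; break }
      j <- j + 3L
    }
    if (is.na(stop_end)) next
    t_start <- i - 1L; t_end <- stop_end
    cl <- (t_end - t_start) %/% 3L - 1L
    if (cl < min_codons) next
    hits[[length(hits) + 1L]] <- data.frame(
      t_start = t_start, t_end = t_end, frame = t_start %% 3L,
      codon_length = cl, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h$t_start), , drop = FALSE]
  h <- h[!duplicated(paste(h$t_end, h$frame)), , drop = FALSE]  # 5'-most AUG
  if (!is.null(t$cds_span)) {
    cs <- t$cds_span[1L]; ce <- t$cds_span[2L]
    h <- h[!(h$t_start == cs & h$t_end == ce), , drop = FALSE]
    overlap <- h$t_end > cs & h$t_start < ce
    same_frame <- (h$t_start - cs) %% 3L == 0L
    h$category <- ifelse(h$t_end <= cs, "uORF_5utr",
                         ifelse(h$t_start >= ce, "dORF_3utr", "out_of_frame"))
    h <- h[!(overlap & same_frame), , drop = FALSE]
  } else {
    h$category <- if (t$biotype %in% c("misc_RNA", "rRNA")) "miscRNA" else "ncRNA"
  }
  if (!nrow(h)) return(NULL)
  h$protein <- vapply(seq_len(nrow(h)), function(k)
    oracle_translate(substr(s, h$t_start[k] + 1L, h$t_end[k] - 3L)),
    character(1))
  h$transcript_id <- t$transcript_id
  h
}

# canonical orf-table key for set comparisons
orf_key <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character())
  sort(paste(df$transcript_id, df$t_start, df$t_end, df$category, df$protein))
}

# Apply a genomic edit to the contig, shift exon coordinates (edits are
# required to fall within a single exon), re-splice and re-translate from
# the ORF start. Returns the mutated protein.
oracle_mut_protein <- function(v, orf, t, genome) {
  ctg <- genome[[t$contig]]
  ref_len <- nchar(v$ref); alt_len <- nchar(v$alt)
  exons <- t$exons
  if (ref_len > 0L && alt_len > 0L) {
    substr(ctg, v$pos0 + 1L, v$pos0 + ref_len) <- v$alt
  } else if (alt_len == 0L) {
    ctg <- paste0(substr(ctg, 1L, v$pos0), substring(ctg, v$pos0 + ref_len + 1L))
    hit <- which(exons$start <= v$pos0 & exons$end >= v$pos0 + ref_len)
    stopifnot(length(hit) == 1L)
    exons$end[hit] <- exons$end[hit] - ref_len
    later <- seq_len(nrow(exons)) > hit
    exons$start[later] <- exons$start[later] - ref_len
    exons$end[later] <- exons$end[later] - ref_len
  } else {
    ctg <- paste0(substr(ctg, 1L, v$pos0 + 1L), v$alt,
                  substring(ctg, v$pos0 + 2L))
    hit <- which(exons$start <= v$pos0 & exons$end > v$pos0 + 1L)
    stopifnot(length(hit) == 1L)
    exons$end[hit] <- exons$end[hit] + alt_len
    later <- seq_len(nrow(exons)) > hit
    exons$start[later] <- exons$start[later] + alt_len
    exons$end[later] <- exons$end[later] + alt_len
  }
  g2 <- genome_build(stats::setNames(ctg, t$contig))
  t2 <- transcript_model(t$transcript_id, t$gene_id, t$gene_name, t$contig,
                         t$strand, exons, cds_span = NULL, biotype = "other")
  s2 <- spliced_sequence(t2, g2)
  oracle_translate(substring(s2, orf$t_start + 1L))
}

# Naive consequence classification from the re-translated proteins
oracle_consequence <- function(v, orf, t, genome) {
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
    wt <- orf$protein
    mut <- oracle_mut_protein(v, orf, t, genome)
    if (mut == wt) return("silent")
    if (nchar(mut) < nchar(wt)) return("stop_gained")
    if (nchar(mut) > nchar(wt)) return("stop_lost")
    return("missense")
  }
  # indels: exonic edit length modulo 3
  if (nchar(v$alt) == 0L) {
    tps <- genomic_to_transcript(t, seq.int(v$pos0, v$pos0 + nchar(v$ref) - 1L))
    m <- sum(!is.na(tps) & tps >= orf$t_start & tps < orf$t_end)
    if (m == 0L) return("none")
    return(if (m %% 3L == 0L) "inframe_del" else "frameshift_del")
  }
  m <- nchar(v$alt)
  if (m %% 3L == 0L) "inframe_ins" else "frameshift_ins"
}

# deletion-exon helper: TRUE when [pos0, pos0+len) sits inside one exon
within_one_exon <- function(t, pos0, len) {
  any(t$exons$start <= pos0 & t$exons$end >= pos0 + len)
}

# random in-ORF variants for the oracle-equivalence checks: SNVs anywhere in
# the ORF, 1-6 nt indels fully inside the ORF body within one exon
random_orf_variants <- function(n, orfs, transcripts, genome, seed) {
  set.seed(seed)
  out <- list()
  guard <- 0L
  while (length(out) < n && guard < n * 50L) {
    guard <- guard + 1L
    orf <- orfs[sample(nrow(orfs), 1L), ]
    t <- transcripts[[orf$transcript_id]]
    kind <- sample(c("snv", "del", "ins"), 1L, prob = c(0.6, 0.2, 0.2))
    if (kind == "snv") {
      tp <- orf$t_start + sample(orf$t_end - orf$t_start, 1L) - 1L
      gp <- transcript_to_genomic(t, tp)
      ref <- substr(genome[[t$contig]], gp + 1L, gp + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      out[[length(out) + 1L]] <- make_variant(t$contig, gp, ref, alt)
    } else if (kind == "del") {
      L <- sample(1:6, 1L)
      span <- orf$t_end - orf$t_start - 3L - L
      if (span < 1L) next
      tp <- orf$t_start + 3L + sample(span, 1L) - 1L
      gps <- sort(transcript_to_genomic(t, seq.int(tp, tp + L - 1L)))
      if (gps[L] - gps[1L] + 1L != L) next   # spans an intron
      if (!within_one_exon(t, gps[1L], L)) next
      ref <- substr(genome[[t$contig]], gps[1L] + 1L, gps[1L] + L)
      out[[length(out) + 1L]] <- make_variant(t$contig, gps[1L], ref, "")
    } else {
      L <- sample(1:6, 1L)
      span <- orf$t_end - orf$t_start - 4L
      if (span < 1L) next
      tp <- orf$t_start + 3L + sample(span, 1L) - 1L  # insertion point k = tp
      # anchor base must sit inside the same exon as the next base
      gp <- transcript_to_genomic(t, tp)
      anchor <- if (t$strand == "+") transcript_to_genomic(t, tp - 1L) else gp
      if (is.na(anchor)) next
      if (!within_one_exon(t, anchor, 2L)) next
      ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      out[[length(out) + 1L]] <- list(v = make_variant(t$contig, anchor, "", ins),
                                      orf_id = orf$orf_id)
      next
    }
    out[[length(out)]] <- list(v = out[[length(out)]], orf_id = orf$orf_id)
  }
  out
}
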