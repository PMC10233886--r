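# Transcript models: strand-aware exon/CDS structure with exact
# genomic <-> transcript coordinate maps. Internal coordinates are 0-based
# half-open everywhere; GTF (1-based closed) is converted at the parse
# boundary only.

BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "misc_RNA", "rRNA", "other")

normalize_biotype <- function(x) {
  if (is.na(x) || !nzchar(x)) return("other")
  if (x == "protein_coding") return("protein_coding")
  if (x %in% c("lncRNA", "lincRNA", "antisense", "processed_transcript")) return("lncRNA")
  if (grepl("pseudogene", x)) return("pseudogene")
  if (x %in% c("misc_RNA", "miscRNA")) return("misc_RNA")
  if (x %in% c("rRNA", "Mt_rRNA")) return("rRNA")
  "other"
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,gene_name identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` columns: 0-based half-open
#'   genomic intervals, non-overlapping, sorted in genomic order.
#' @param cds_span optional length-2 integer vector: transcript coordinates
#'   (0-based half-open, on the spliced transcript) of the CDS including the
#'   stop codon, or `NULL` for noncoding transcripts.
#' @param biotype one of protein_coding, lncRNA, pseudogene, misc_RNA,
#'   rRNA, other.
#' @return a `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name, contig, strand,
                             exons, cds_span = NULL, biotype = "other") {
  stopifnot(strand %in% c("+", "-"), biotype %in% BIOTYPES)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end <= exons$start)) stop("empty exon in ", transcript_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("overlapping exons in ", transcript_id)
  len <- sum(exons$end - exons$start)
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    if (cds_span[1L] < 0L || cds_span[2L] > len || cds_span[2L] <= cds_span[1L])
      stop("cds_span outside transcript in ", transcript_id)
    if ((cds_span[2L] - cds_span[1L]) %% 3L != 0L)
      stop("cds_span length not divisible by 3 in ", transcript_id)
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    contig = contig, strand = strand,
    exons = exons, cds_span = cds_span, biotype = biotype,
    length = len
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), %d nt%s>\n",
              x$transcript_id, x$biotype, x$contig, x$strand,
              nrow(x$exons), x$length,
              if (is.null(x$cds_span)) "" else
                sprintf(", CDS [%d,%d)", x$cds_span[1L], x$cds_span[2L])))
  invisible(x)
}

#' Extract the spliced transcript sequence
#'
#' Exon sequences are concatenated 5' to 3'; minus-strand transcripts are
#' reverse-complemented so position 0 of the result is the transcript 5' end.
#'
#' @param t a `transcript_model`.
#' @param genome a `genome_build` containing `t$contig`.
#' @return nucleotide string of length `sum(exon widths)`.
#' @export
spliced_sequence <- function(t, genome) {
  ctg <- genome[[t$contig]]
  if (is.null(ctg)) stop("contig not in genome: ", t$contig)
  if (any(t$exons$end > nchar(ctg)) || any(t$exons$start < 0L))
    stop("exon out of contig bounds for ", t$transcript_id)
  parts <- substring(ctg, t$exons$start + 1L, t$exons$end)
  s <- paste(parts, collapse = "")
  if (t$strand == "-") s <- rc(s)
  s
}

#' Map genomic positions to spliced-transcript positions
#'
#' @param t a `transcript_model`.
#' @param gpos integer vector of 0-based genomic positions.
#' @return integer vector of 0-based offsets from the transcript 5' end;
#'   `NA` for intronic or out-of-transcript positions.
#' @export
genomic_to_transcript <- function(t, gpos) {
  widths <- t$exons$end - t$exons$start
  cum_before <- cumsum(c(0L, widths))[seq_len(nrow(t$exons))]
  res <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(t$exons))) {
    hit <- !is.na(gpos) & gpos >= t$exons$start[i] & gpos < t$exons$end[i]
    res[hit] <- cum_before[i] + (gpos[hit] - t$exons$start[i])
  }
  if (t$strand == "-") res <- t$length - 1L - res
  res
}

#' Map spliced-transcript positions to genomic positions
#'
#' Inverse of [genomic_to_transcript()]; round-trips for every exonic
#' position.
#'
#' @param t a `transcript_model`.
#' @param tpos integer vector of 0-based transcript positions.
#' @return integer vector of 0-based genomic positions (`NA` outside
#'   `[0, length)`).
#' @export
transcript_to_genomic <- function(t, tpos) {
  widths <- t$exons$end - t$exons$start
  cum_before <- cumsum(c(0L, widths))[seq_len(nrow(t$exons))]
  p <- tpos
  if (t$strand == "-") p <- t$length - 1L - p
  res <- rep(NA_integer_, length(p))
  for (i in seq_len(nrow(t$exons))) {
    hit <- !is.na(p) & p >= cum_before[i] & p < cum_before[i] + widths[i]
    res[hit] <- t$exons$start[i] + (p[hit] - cum_before[i])
  }
  res
}

#' Load transcript models from a GTF annotation
#'
#' Parses Ensembl/GENCODE-dialect GTF (exon and CDS features carrying
#' `transcript_id`), converts 1-based closed intervals to internal 0-based
#' half-open coordinates, and projects CDS features onto spliced-transcript
#' coordinates. The stop codon is considered part of the CDS span: when the
#' annotated CDS excludes it (GENCODE convention) and the next in-frame
#' codon is a stop, the span is extended by 3. Transcripts whose CDS is not
#' contained in their exons, is discontiguous on the spliced transcript, or
#' has no terminal stop codon are rejected and reported; transcripts on
#' contigs absent from `genome` are skipped with a warning.
#'
#' @param gtf_path path to a GTF file.
#' @param genome a `genome_build`.
#' @return a named list of `transcript_model` objects (class
#'   `transcript_set`) with a `rejected` attribute: data.frame of
#'   `transcript_id`, `reason` for rejected transcripts.
#' @export
load_annotation <- function(gtf_path, genome) {
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", gtf_path,
                                          ": ", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!"transcript_id" %in% names(df))
    stop("GTF carries no transcript_id attribute")
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep & !is.na(df$transcript_id), , drop = FALSE]

  bt_col <- intersect(c("transcript_biotype", "transcript_type", "gene_biotype",
                        "gene_type"), names(df))[1]
  models <- list()
  rejected <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  skipped <- character()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    contig <- sub$seqnames[1L]
    if (!contig %in% names(genome)) { skipped <- c(skipped, tid); next }
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) {
      rejected <- rbind(rejected, data.frame(transcript_id = tid,
                                             reason = "no exon features"))
      next
    }
    exons <- data.frame(start = ex$start - 1L, end = ex$end)
    exons <- exons[order(exons$start), , drop = FALSE]
    strand <- sub$strand[1L]
    gene_id <- if ("gene_id" %in% names(sub)) sub$gene_id[1L] else tid
    gene_name <- if ("gene_name" %in% names(sub) && !is.na(sub$gene_name[1L]))
      sub$gene_name[1L] else gene_id
    biotype <- if (!is.na(bt_col)) normalize_biotype(sub[[bt_col]][1L]) else NA

    cds <- sub[sub$type == "CDS", , drop = FALSE]
    res <- tryCatch({
      m0 <- transcript_model(tid, gene_id, gene_name, contig, strand, exons,
                             cds_span = NULL, biotype = "other")
      cds_span <- NULL
      if (nrow(cds) > 0L) {
        cds_span <- project_cds(m0, genome, cds$start - 1L, cds$end)
        bt <- "protein_coding"
      } else {
        bt <- if (is.na(biotype) || biotype == "protein_coding") "other" else biotype
      }
      if (nrow(cds) > 0L && !is.na(biotype) && biotype != "protein_coding")
        bt <- "protein_coding"  # CDS presence wins over a stale biotype tag
      transcript_model(tid, gene_id, gene_name, contig, strand, exons,
                       cds_span = cds_span, biotype = bt)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejected <- rbind(rejected, data.frame(transcript_id = tid, reason = res))
    } else {
      models[[tid]] <- res
    }
  }
  if (length(skipped))
    warning(length(skipped), " transcript(s) on contigs missing from the ",
            "genome were skipped: ", paste(utils::head(skipped, 5L), collapse = ", "))
  structure(models, class = "transcript_set", rejected = rejected)
}

# Project genomic CDS intervals (0-based half-open) to a transcript span,
# checking containment and contiguity, and extending over the stop codon
# when the annotation excludes it.
project_cds <- function(m0, genome, cds_start, cds_end) {
  tpos <- unlist(lapply(seq_along(cds_start), function(i) {
    genomic_to_transcript(m0, seq.int(cds_start[i], cds_end[i] - 1L))
  }))
  if (anyNA(tpos))
    stop("CDS not contained in exons of ", m0$transcript_id)
  lo <- min(tpos); hi <- max(tpos) + 1L
  if (hi - lo != length(tpos))
    stop("CDS discontiguous on spliced transcript of ", m0$transcript_id)
  s <- spliced_sequence(m0, genome)
  len <- hi - lo
  if (len %% 3L != 0L)
    stop("CDS length not divisible by 3 in ", m0$transcript_id)
  last_codon <- substr(s, hi - 2L, hi)
  if (is_stop_codon(last_codon)) return(c(lo, hi))
  nxt <- substr(s, hi + 1L, hi + 3L)
  if (nchar(nxt) == 3L && is_stop_codon(nxt)) return(c(lo, hi + 3L))
  stop("CDS of ", m0$transcript_id, " has no terminal stop codon (incomplete)")
}

#' Write transcript models to a GTF file
#'
#' Emits `exon` and `CDS` features in GENCODE style (1-based closed
#' coordinates; CDS excludes the stop codon) with `gene_id`,
#' `transcript_id`, `gene_name` and `transcript_biotype` attributes.
#'
#' @param transcripts a `transcript_set` or list of `transcript_model`s.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character()
  for (t in transcripts) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
      t$gene_id, t$transcript_id, t$gene_name, t$biotype)
    for (i in seq_len(nrow(t$exons))) {
      lines <- c(lines, paste(t$contig, "crypticorf", "exon",
                              t$exons$start[i] + 1L, t$exons$end[i],
                              ".", t$strand, ".", attrs, sep = "\t"))
    }
    if (!is.null(t$cds_span)) {
      # drop the stop codon (GENCODE convention) before projecting back
      iv <- transcript_interval_to_genomic(t, t$cds_span[1L], t$cds_span[2L] - 3L)
      for (i in seq_len(nrow(iv))) {
        lines <- c(lines, paste(t$contig, "crypticorf", "CDS",
                                iv$start[i] + 1L, iv$end[i],
                                ".", t$strand, ".", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Map a transcript interval [a, b) to a data.frame of genomic intervals
# (0-based half-open), one row per exon piece, in genomic order.
transcript_interval_to_genomic <- function(t, a, b) {
  if (b <= a) return(data.frame(start = integer(), end = integer()))
  gpos <- transcript_to_genomic(t, seq.int(a, b - 1L))
  gpos <- sort(gpos)
  brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
  data.frame(
    start = gpos[brk[-length(brk)] + 1L],
    end = gpos[brk[-1L]] + 1L
  )
}
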