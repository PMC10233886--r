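# hand-built single-exon transcript carrying one ORF: GG ATG TAC AAA TAA GG
toy_orf_setup <- function(strand = "+") {
  s <- "GGATGTACAAATAAGG"
  ctg <- if (strand == "+") s else as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome <- tiny_genome(ctg)
  t <- make_tx(strand = strand, exons = list(0L, nchar(s)))
  orfs <- enumerate_orfs(t, genome, min_codons = 1L)
  list(genome = genome, t = t, orf = orfs[1, ])
}

test_that("MAF and VCF readers agree on the internal representation", {
  genome <- tiny_genome("AACGTACGTACGTACG")
  maf <- tempfile(fileext = ".maf")
  write_tsv_table(data.frame(
    Hugo_Symbol = "G", Chromosome = "chr1",
    Start_Position = c(3L, 5L, 7L), End_Position = c(3L, 6L, 7L),
    Reference_Allele = c("C", "TA", "-"),
    Tumor_Seq_Allele2 = c("T", "-", "GG"),
    Variant_Classification = c("Missense_Mutation", "Frame_Shift_Del", "5'UTR"),
    Tumor_Sample_Barcode = "S1", cohort = "C01"), maf)
  v <- read_maf(maf, genome)
  expect_equal(v$pos0, c(2L, 4L, 6L))
  expect_equal(v$ref, c("C", "TA", ""))
  expect_equal(v$alt, c("T", "", "GG"))
  expect_equal(v$canonical_class, c("missense", "frameshift", "utr5"))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t3\t.\tC\tT\t.\t.\tSAMPLE=S1",
               "chr1\t4\t.\tGTA\tG\t.\t.\tSAMPLE=S1",
               "chr1\t7\t.\tC\tCGG\t.\t.\tSAMPLE=S1"), vcf)
  vv <- read_vcf_variants(vcf, genome)
  expect_equal(vv$pos0, c(2L, 4L, 6L))
  expect_equal(vv$ref, c("C", "TA", ""))
  expect_equal(vv$alt, c("T", "", "GG"))
  # multi-allelic records are refused
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t3\t.\tC\tT,G\t.\t.\t."), vcf)
  expect_error(read_vcf_variants(vcf, genome), "multi-allelic")
})

test_that("reference mismatches are a hard error and indels left-normalize", {
  genome <- tiny_genome("AACGTTTTACGT")
  maf <- tempfile(fileext = ".maf")
  write_tsv_table(data.frame(
    Hugo_Symbol = "G", Chromosome = "chr1", Start_Position = 3L,
    End_Position = 3L, Reference_Allele = "G", Tumor_Seq_Allele2 = "A",
    Variant_Classification = "Silent", Tumor_Sample_Barcode = "S1"), maf)
  expect_error(read_maf(maf, genome), "mismatch")
  # deletion of one T in the TTTT run shifts to the run start (pos0 4)
  write_tsv_table(data.frame(
    Hugo_Symbol = "G", Chromosome = "chr1", Start_Position = 8L,
    End_Position = 8L, Reference_Allele = "T", Tumor_Seq_Allele2 = "-",
    Variant_Classification = "Frame_Shift_Del", Tumor_Sample_Barcode = "S1"),
    maf)
  v <- read_maf(maf, genome)
  expect_equal(v$pos0, 4L)
  expect_equal(v$ref, "T")
})

test_that("projection locates codons and rejects out-of-ORF positions", {
  x <- toy_orf_setup("+")
  # first base of the start codon: codon 0, offset 0
  v <- make_variant("chr1", 2L, "A", "C")
  pr <- project_variant(v, x$orf, x$t)
  expect_equal(pr$codon_index, 0L)
  expect_equal(pr$codon_offset, 0L)
  # one nt 5' of t_start: none
  expect_null(project_variant(make_variant("chr1", 1L, "G", "C"), x$orf, x$t))
  # last base of the stop codon is still inside
  pr2 <- project_variant(make_variant("chr1", 13L, "A", "C"), x$orf, x$t)
  expect_equal(pr2$codon_index, 3L)
})

test_that("SNV consequences follow the genetic code on both strands", {
  for (strand in c("+", "-")) {
    x <- toy_orf_setup(strand)
    L <- 16L
    gpos <- function(tp) if (strand == "+") tp else L - 1L - tp
    base_at <- function(tp) substr("GGATGTACAAATAAGG", tp + 1L, tp + 1L)
    tx_alt <- function(a) if (strand == "+") a else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
    # TAC -> TAA at codon 1 offset 2: stop gained
    v <- make_variant("chr1", gpos(7L), tx_alt(base_at(7L)), tx_alt("A"))
    expect_equal(call_ncorf_consequence(v, x$orf, x$t, x$genome)$ncorf_class,
                 "stop_gained")
    # TAC -> TAT: silent
    v2 <- make_variant("chr1", gpos(7L), tx_alt(base_at(7L)), tx_alt("T"))
    expect_equal(call_ncorf_consequence(v2, x$orf, x$t, x$genome)$ncorf_class,
                 "silent")
    # TAC -> TGC: missense with protein_change notation
    v3 <- make_variant("chr1", gpos(6L), tx_alt(base_at(6L)), tx_alt("G"))
    res <- call_ncorf_consequence(v3, x$orf, x$t, x$genome)
    expect_equal(res$ncorf_class, "missense")
    expect_equal(res$protein_change, "p.Y2C")
    # stop codon TAA -> TAC: stop lost
    v4 <- make_variant("chr1", gpos(13L), tx_alt(base_at(13L)), tx_alt("C"))
    expect_equal(call_ncorf_consequence(v4, x$orf, x$t, x$genome)$ncorf_class,
                 "stop_lost")
  }
})

test_that("indel consequences classify by exonic length modulo 3", {
  x <- toy_orf_setup("+")
  # 2-nt deletion inside the ORF: frameshift
  v <- make_variant("chr1", 6L, "AC", "")
  expect_equal(call_ncorf_consequence(v, x$orf, x$t, x$genome)$ncorf_class,
               "frameshift_del")
  # 3-nt deletion: in-frame
  v2 <- make_variant("chr1", 6L, "ACA", "")
  expect_equal(call_ncorf_consequence(v2, x$orf, x$t, x$genome)$ncorf_class,
               "inframe_del")
  # 1-nt insertion inside the ORF: frameshift
  v3 <- make_variant("chr1", 6L, "", "G")
  expect_equal(call_ncorf_consequence(v3, x$orf, x$t, x$genome)$ncorf_class,
               "frameshift_ins")
  # deletion entirely outside the ORF: none
  v4 <- make_variant("chr1", 14L, "GG", "")
  expect_equal(call_ncorf_consequence(v4, x$orf, x$t, x$genome)$ncorf_class,
               "none")
})

test_that("consequence calls match the re-translation oracle on random variants", {
  sim <- shared_sim()
  ref <- sim$ref
  cases <- random_orf_variants(250, ref$planted, ref$transcripts, ref$genome,
                               seed = 77)
  expect_gte(length(cases), 200)
  for (cs in cases) {
    orf <- ref$planted[ref$planted$orf_id == cs$orf_id, ]
    t <- ref$transcripts[[orf$transcript_id]]
    got <- call_ncorf_consequence(cs$v, orf, t, ref$genome)$ncorf_class
    want <- oracle_consequence(cs$v, orf, t, ref$genome)
    expect_equal(got, want)
  }
})

test_that("canonical classes are computed when the MAF column is absent", {
  sim <- shared_sim()
  ref <- sim$ref
  sv <- simulate_variants(sim$cfg, ref$planted, ref$transcripts, ref$genome)
  n <- min(nrow(sv$maf), 120L)
  for (i in seq_len(n)) {
    row <- sv$maf[i, ]
    ref_a <- ifelse(row$Reference_Allele == "-", "", row$Reference_Allele)
    alt_a <- ifelse(row$Tumor_Seq_Allele2 == "-", "", row$Tumor_Seq_Allele2)
    v <- make_variant(row$Chromosome, row$Start_Position - 1L, ref_a, alt_a)
    tid <- row$Hugo_Symbol
    t <- ref$transcripts[[tid]]
    want <- sv$manifest$canonical_class[i]
    expect_equal(compute_canonical_class(v, t, ref$genome), want)
  }
})

test_that("cross-classification assigns exactly one group per variant", {
  expect_equal(cross_classify("utr5", "missense"), "1_utr_derived")
  expect_equal(cross_classify("silent", "missense"), "2_overlap_canonical")
  expect_equal(cross_classify("silent", "silent"), "3_canonical_only")
  expect_equal(cross_classify("missense", "frameshift_del"),
               "2_overlap_canonical")
  sim <- shared_sim()
  ref <- sim$ref
  sv <- simulate_variants(sim$cfg, ref$planted, ref$transcripts, ref$genome)
  f <- tempfile(fileext = ".maf"); write_tsv_table(sv$maf, f)
  vars <- read_maf(f, ref$genome)
  ra <- reannotate_variants(vars, ref$planted, ref$transcripts, ref$genome)
  ov <- ra$variants[!is.na(ra$variants$figure_group), ]
  expect_true(all(ov$figure_group %in%
                    c("1_utr_derived", "2_overlap_canonical", "3_canonical_only")))
  # group tallies sum to the overlapping-variant total, and the altering
  # per-class tallies sum to the protein-altering total
  expect_equal(sum(table(ov$figure_group)), nrow(ov))
  altering <- ra$pairs[ra$pairs$ncorf_class != "none", ]
  per_var <- tapply(altering$ncorf_class %in%
                      c("missense", "frameshift_ins", "frameshift_del",
                        "inframe_ins", "inframe_del", "stop_gained",
                        "stop_lost"),
                    altering$variant_id, any)
  expect_equal(sum(per_var), sum(ov$ncorf_altered))
})

test_that("strand symmetry: minus-strand consequences equal the plus-strand oracle", {
  sim <- shared_sim()
  ref <- sim$ref
  minus_tx <- names(ref$transcripts)[vapply(ref$transcripts,
                                            function(t) t$strand == "-",
                                            logical(1))]
  orfs <- ref$planted[ref$planted$transcript_id %in% minus_tx, ]
  cases <- random_orf_variants(60, orfs, ref$transcripts, ref$genome, seed = 5)
  for (cs in cases) {
    orf <- ref$planted[ref$planted$orf_id == cs$orf_id, ]
    t <- ref$transcripts[[orf$transcript_id]]
    expect_equal(call_ncorf_consequence(cs$v, orf, t, ref$genome)$ncorf_class,
                 oracle_consequence(cs$v, orf, t, ref$genome))
  }
})

test_that("mutation burden normalizes per megabase and separates scopes", {
  vs <- data.frame(
    variant_id = sprintf("v%02d", 1:40),
    sample_id = "S1", cohort = "C01",
    canonical_class = c(rep("missense", 38), rep("utr5", 2)),
    ncorf_altered = c(rep(FALSE, 38), TRUE, TRUE),
    figure_group = NA_character_, stringsAsFactors = FALSE)
  b <- mutation_burden(vs, region_size_mb = 38)
  expect_equal(b$canonical_v_mb, 1.0)
  expect_equal(b$ncorf_only_v_mb, 2 / 38)
  # zero qualifying variants give zero burden
  vs0 <- vs[vs$canonical_class == "utr5", ]
  vs0$ncorf_altered <- FALSE
  b0 <- mutation_burden(vs0)
  expect_equal(b0$canonical_v_mb, 0)
  expect_equal(b0$ncorf_only_v_mb, 0)
})

test_that("a planted rate difference is detected by the rank-sum comparison", {
  # ncORF-only variants planted at half the canonical rate across samples
  set.seed(13)
  hits <- replicate(25, {
    canon <- rpois(40, 60); nco <- rpois(40, 30)
    stratified_rank_test(canon / 38, nco / 38)$p_value < 0.01
  })
  expect_gte(mean(hits), 0.9)
})
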