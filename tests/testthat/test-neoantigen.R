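ncorf_wildtype_db <- function(ref) {
  rbind(protein_db(orf_accession(ref$planted$orf_id, ref$planted$category),
                   ref$planted$protein, "ncorf"),
        ref$canonical_db)
}

sim_mutated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_sim()
      ref <- sim$ref
      sv <- simulate_variants(sim$cfg, ref$planted, ref$transcripts, ref$genome)
      f <- tempfile(fileext = ".maf"); write_tsv_table(sv$maf, f)
      vars <- read_maf(f, ref$genome)
      ra <- reannotate_variants(vars, ref$planted, ref$transcripts, ref$genome)
      mut <- build_mutated_proteome(ra$pairs, vars, ref$planted,
                                    ref$transcripts, ref$genome)
      cache <<- list(sim = sim, vars = vars, ra = ra, mut = mut)
    }
    cache
  }
})

test_that("a single eligible missense changes exactly one residue", {
  x <- sim_mutated()
  ra <- x$ra; mut <- x$mut
  single <- mut[!grepl(";", mut$variant_ids), ]
  mis <- merge(single, ra$pairs[ra$pairs$ncorf_class == "missense", ],
               by.x = c("orf_id", "variant_ids"),
               by.y = c("orf_id", "variant_id"))
  expect_gt(nrow(mis), 0)
  for (i in seq_len(min(nrow(mis), 40L))) {
    wt <- strsplit(mis$wt_protein[i], "")[[1]]
    mu <- strsplit(mis$mut_protein[i], "")[[1]]
    expect_equal(length(wt), length(mu))
    expect_equal(sum(wt != mu), 1L)
    expect_equal(mis$changed_end[i] - mis$changed_start[i], 1L)
  }
})

test_that("canonical-missense variants over an ncORF are not eligible", {
  x <- sim_mutated()
  pairs <- x$ra$pairs
  can_mis <- pairs[pairs$canonical_class == "missense" &
                     pairs$ncorf_class == "missense", ]
  expect_gt(nrow(can_mis), 0)
  keys <- paste(can_mis$variant_id, can_mis$orf_id)
  for (i in seq_len(nrow(x$mut))) {
    vids <- strsplit(x$mut$variant_ids[i], ";")[[1]]
    expect_false(any(paste(vids, x$mut$orf_id[i]) %in% keys))
  }
})

test_that("frameshifts diverge from the edit position to a new stop (oracle)", {
  x <- sim_mutated()
  sim <- x$sim; ref <- sim$ref
  fs <- merge(x$mut[!grepl(";", x$mut$variant_ids), ],
              x$ra$pairs[grepl("frameshift", x$ra$pairs$ncorf_class), ],
              by.x = c("orf_id", "variant_ids"),
              by.y = c("orf_id", "variant_id"))
  expect_gt(nrow(fs), 0)
  for (i in seq_len(min(nrow(fs), 25L))) {
    orf <- ref$planted[ref$planted$orf_id == fs$orf_id[i], ]
    t <- ref$transcripts[[orf$transcript_id]]
    v <- x$vars[x$vars$variant_id == fs$variant_ids[i], ]
    expect_equal(fs$mut_protein[i], oracle_mut_protein(v, orf, t, ref$genome))
    expect_true(fs$mut_protein[i] != fs$wt_protein[i])
  }
})

test_that("co-occurring eligible variants apply jointly and conflicts reject", {
  sim <- shared_sim()
  ref <- sim$ref
  # construct two SNVs in one uORF for one sample
  orf <- ref$planted[ref$planted$category == "uORF_5utr", ][1, ]
  t <- ref$transcripts[[orf$transcript_id]]
  mk_snv <- function(tp) {
    gp <- transcript_to_genomic(t, tp)
    refb <- substr(ref$genome[[t$contig]], gp + 1L, gp + 1L)
    altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
    make_variant(t$contig, gp, refb, altb, sample_id = "SX")
  }
  v1 <- mk_snv(orf$t_start + 4L)
  v2 <- mk_snv(orf$t_start + 10L)
  vars <- rbind(v1, v2)
  ra <- reannotate_variants(vars, orf, ref$transcripts, ref$genome)
  mut <- build_mutated_proteome(ra$pairs, vars, ref$planted, ref$transcripts,
                                ref$genome)
  if (nrow(mut) == 1L) {
    expect_equal(mut$variant_ids,
                 paste(sort(c(v1$variant_id, v2$variant_id)), collapse = ";"))
  }
  # overlapping deletions in the same sample are rejected, not merged
  gp <- transcript_to_genomic(t, orf$t_start + 4L)
  gs <- sort(transcript_to_genomic(t, orf$t_start + 4:9))
  if (gs[6] - gs[1] == 5L) {
    d1 <- make_variant(t$contig, gs[1], substr(ref$genome[[t$contig]],
                                               gs[1] + 1, gs[1] + 4), "",
                       sample_id = "SY")
    d2 <- make_variant(t$contig, gs[3], substr(ref$genome[[t$contig]],
                                               gs[3] + 1, gs[3] + 4), "",
                       sample_id = "SY")
    vars2 <- rbind(d1, d2)
    ra2 <- reannotate_variants(vars2, orf, ref$transcripts, ref$genome)
    mut2 <- build_mutated_proteome(ra2$pairs, vars2, ref$planted,
                                   ref$transcripts, ref$genome)
    expect_equal(nrow(mut2), 0L)
    expect_gt(nrow(attr(mut2, "rejected")), 0L)
  }
})

test_that("wildtype elimination is exhaustive and keeps change-spanning peptides", {
  x <- sim_mutated()
  ref <- x$sim$ref
  wt <- ncorf_wildtype_db(ref)
  spec <- digest_spec(mode = "semi", missed_cleavages = 2L, min_len = 8L,
                      max_len = 25L)
  cand <- mutated_peptides(x$mut, spec)
  expect_gt(nrow(cand), 0)
  kept <- eliminate_wildtype_matches(cand, wt)
  wt_il <- il_collapse(wt$sequence)
  for (pep in unique(kept$peptide))
    expect_false(any(grepl(il_collapse(pep), wt_il, fixed = TRUE)))
  # direct example: a peptide identical to a wildtype tryptic peptide dies
  wt_pep <- digest(ref$canonical_db$sequence[1],
                   digest_spec(mode = "full", missed_cleavages = 0L,
                               min_len = 8L, max_len = 25L))$peptide[1]
  fake <- data.frame(peptide = wt_pep, orf_id = "x", sample_id = "s",
                     start = 0L, stringsAsFactors = FALSE)
  expect_equal(nrow(eliminate_wildtype_matches(fake, wt)), 0L)
  # every candidate spans the changed interval of its mutated protein
  m <- merge(cand, x$mut, by = c("orf_id", "sample_id"))
  expect_true(all(m$start < m$changed_end &
                    m$start + nchar(m$peptide) > m$changed_start))
})

test_that("retention-time error is the absolute difference with strict pass", {
  r <- retention_time_error(c(10, 10, 7), c(12.5, 15, 7))
  expect_equal(r$rt_error_min, c(2.5, 5, 0))
  expect_equal(r$rt_pass, c(TRUE, FALSE, TRUE))  # 5.0 fails the strict bound
  rna <- retention_time_error(NA_real_, 10)
  expect_true(is.na(rna$rt_pass))
})

test_that("hydrophobicity index is additive with length normalization", {
  zero <- stats::setNames(rep(0, 20), names(hydropathy_coefficients))
  expect_equal(hydrophobicity_index("ACDEFG", zero), 0)
  # appending a positive-coefficient residue increases the index
  expect_gt(hydrophobicity_index("AAAI"), hydrophobicity_index("AAA"))
  expect_error(hydrophobicity_index("AB?"), "unknown")
  # self-consistency: RT generated from the same coefficients correlates
  set.seed(31)
  peps <- vapply(1:120, function(i)
    paste(sample(names(hydropathy_coefficients), sample(8:15, 1),
                 replace = TRUE), collapse = ""), character(1))
  hi <- hydrophobicity_index(peps)
  rt <- 20 + 1.5 * hi + rnorm(120, 0, 0.4)
  expect_gt(stats::cor(hi, rt), 0.95)
})

test_that("epitope cascade equals its set-algebra definition and is monotone", {
  sim <- shared_sim()
  ref <- sim$ref
  orfs <- ref$planted
  epi <- simulate_epitope_tables(sim$cfg, orfs)
  pr <- prioritize_epitopes(epi$candidates)
  aff <- pr$affinity_nM <= 150
  rt <- !is.na(pr$rt_error_min) & pr$rt_error_min < 5
  gtex <- !is.na(pr$gtex_median_tpm) & pr$gtex_median_tpm < 1
  expect_equal(pr$reported, aff & (rt | gtex))
  # planted intent recovered exactly
  m <- merge(pr, epi$intent[, c("candidate_id", "intend_reported")],
             by = "candidate_id")
  expect_equal(m$reported, m$intend_reported)
  # tightening any threshold never enlarges the report
  base_n <- sum(pr$reported)
  for (args in list(list(affinity_max = 50), list(rt_max = 2),
                    list(tpm_max = 0.2))) {
    n <- sum(do.call(prioritize_epitopes, c(list(epi$candidates), args))$reported)
    expect_lte(n, base_n)
  }
  # rule table: affinity gate dominates; GTEx rescues an RT failure
  cand <- data.frame(peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"),
                     orf_id = "o", sample_id = "s", hla_allele = "HLA-A*02:01",
                     affinity_nM = c(8.91, 200, 100),
                     rt_observed_min = c(10, 10, 16),
                     rt_predicted_min = c(12, 10, 10),
                     gtex_median_tpm = c(10, 0.5, 0.5),
                     stringsAsFactors = FALSE)
  out <- prioritize_epitopes(cand)
  expect_equal(out$reported[match(cand$peptide, out$peptide)],
               c(TRUE, FALSE, TRUE))
  # optional percentile-rank gate
  cand$percentile_rank <- c(0.5, 0.5, 3)
  out2 <- prioritize_epitopes(cand, rank_max = 2)
  expect_equal(out2$reported[match(cand$peptide, out2$peptide)],
               c(TRUE, FALSE, FALSE))
})

test_that("mutated proteome FASTA carries per-sample accessions", {
  x <- sim_mutated()
  f <- tempfile(fileext = ".fa")
  write_mutated_proteome(x$mut[1:5, ], f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(as.character(back[[1]]), x$mut$mut_protein[1])
  expect_match(names(back)[1], "^ncorf\\|.*\\|mut\\|")
})
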