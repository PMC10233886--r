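mk_psms <- function(score, is_decoy, assay = "proteome",
                    probability = NA_real_, peptide = NULL) {
  n <- length(score)
  data.frame(spectrum_id = sprintf("s%03d", seq_len(n)),
             peptide = if (is.null(peptide)) strrep("PEPTIDEK", 1) else peptide,
             score = score, probability = probability,
             accessions = ifelse(is_decoy, "rev_x", "x"),
             sample_id = "S1", cohort = "C01", assay = assay,
             is_decoy = is_decoy, stringsAsFactors = FALSE)
}

test_that("q-values count decoys over targets with monotonization", {
  # scores T:10 T:9 D:8 T:7 -> FDR at 7 is 1/3
  p <- mk_psms(c(10, 9, 8, 7), c(FALSE, FALSE, TRUE, FALSE))
  q <- compute_fdr(p)
  expect_equal(q$q_value[q$score == 7], 1 / 3)
  expect_equal(q$q_value[q$score == 10], 0)
  # no decoys: all q-values zero
  q2 <- compute_fdr(mk_psms(c(5, 4, 3), rep(FALSE, 3)))
  expect_equal(q2$q_value, rep(0, 3))
  # all decoys: degenerate, q = 1 with a warning
  expect_warning(q3 <- compute_fdr(mk_psms(c(5, 4), c(TRUE, TRUE))), "decoy")
  expect_equal(q3$q_value, c(1, 1))
  # tied scores share one q-value
  q4 <- compute_fdr(mk_psms(c(5, 5, 5, 5), c(FALSE, TRUE, FALSE, FALSE)))
  expect_equal(length(unique(q4$q_value)), 1L)
  # +1 correction is uniformly more conservative
  q5 <- compute_fdr(p, plus_one = TRUE)
  expect_true(all(q5$q_value >= q$q_value))
  expect_equal(q5$q_value[q5$score == 9], 0.5)
})

test_that("q-values are monotone in score and filtering is monotone in q_max", {
  set.seed(8)
  p <- mk_psms(c(rnorm(300, 3), rnorm(300, 0)), rep(c(FALSE, TRUE), each = 300))
  q <- compute_fdr(p)
  ord <- order(-q$score)
  expect_true(all(diff(q$q_value[ord]) >= -1e-12))
  n_strict <- nrow(filter_psms(q, q_max = 0.01))
  n_loose <- nrow(filter_psms(q, q_max = 0.05))
  expect_lte(n_strict, n_loose)
})

test_that("assay-specific filters apply probability, length and q thresholds", {
  imm <- mk_psms(c(5, 5, 5), rep(FALSE, 3), assay = "immunopeptidome",
                 probability = c(0.995, 0.995, 0.98),
                 peptide = c(strrep("A", 9), strrep("A", 26), strrep("A", 9)))
  imm$q_value <- 0
  kept <- filter_psms(imm)
  expect_equal(kept$spectrum_id, "s001")  # length 26 and p 0.98 removed
  pro <- mk_psms(c(5, 5), c(FALSE, FALSE))
  pro$q_value <- c(0.01, 0.011)
  expect_equal(nrow(filter_psms(pro, q_max = 0.01)), 1L)
  # decoys never survive
  dec <- mk_psms(5, TRUE); dec$q_value <- 0
  expect_equal(nrow(filter_psms(dec)), 0L)
  # external validation column gates retention when present
  val <- mk_psms(c(5, 5), c(FALSE, FALSE)); val$q_value <- 0
  val$validated <- c(TRUE, FALSE)
  expect_equal(nrow(filter_psms(val)), 1L)
})

test_that("peptide mapping discards canonical-contained peptides under I=L", {
  db <- rbind(
    protein_db(orf_accession("T1:0:0", "ncRNA"), "MAKVLGLWDDDK", "ncorf"),
    protein_db("canon|G1", "MPPKVIGLPPR", "canonical"))
  psms <- mk_psms(c(5, 5), c(FALSE, FALSE),
                  peptide = c("KVLGL", "LWDDDK"))
  # KVLGL occurs in canonical KVIGL under I=L -> discarded
  mp <- map_peptides_to_ncorfs(psms, db)
  expect_equal(mp$canonical_discarded, "KVLGL")
  expect_equal(mp$peptide_map$peptide, "LWDDDK")
  expect_equal(mp$peptide_map$orf_id, "T1:0:0")
  expect_equal(mp$evidence$n_peptides, 1L)
  # a peptide matching nothing lands in the orphan report
  psms2 <- mk_psms(5, FALSE, peptide = "WWWWWWWW")
  mp2 <- map_peptides_to_ncorfs(psms2, db)
  expect_equal(mp2$orphans, "WWWWWWWW")
  expect_equal(nrow(mp2$evidence), 0L)
})

test_that("planted peptides recover exactly their source ORFs", {
  sim <- shared_sim()
  ref <- sim$ref
  psm <- simulate_psm_tables(sim$cfg, ref$planted, ref$canonical_db)
  orfdb <- protein_db(orf_accession(ref$planted$orf_id, ref$planted$category),
                      ref$planted$protein, "ncorf")
  db <- build_search_database(orfdb, ref$canonical_db)
  retained <- filter_psms(compute_fdr(psm$psms))
  mp <- map_peptides_to_ncorfs(retained, db, ref$planted)
  # every retained mapped peptide is absent from all canonical sequences
  canon_il <- il_collapse(ref$canonical_db$sequence)
  for (pep in unique(mp$peptide_map$peptide))
    expect_false(any(grepl(il_collapse(pep), canon_il, fixed = TRUE)))
  # every true planted peptide that survived filtering maps to its ORF
  truthy <- psm$true_peptides[!is.na(psm$true_peptides$orf_id), ]
  truthy <- truthy[truthy$peptide %in% retained$peptide, ]
  mkey <- paste(mp$peptide_map$peptide, mp$peptide_map$orf_id)
  expect_true(all(paste(truthy$peptide, truthy$orf_id) %in% mkey))
})

test_that("pervasiveness flagging is exact on planted cohorts and monotone", {
  sim <- shared_sim()
  ref <- sim$ref
  psm <- simulate_psm_tables(sim$cfg, ref$planted, ref$canonical_db)
  orfdb <- protein_db(orf_accession(ref$planted$orf_id, ref$planted$category),
                      ref$planted$protein, "ncorf")
  db <- build_search_database(orfdb, ref$canonical_db)
  mp <- map_peptides_to_ncorfs(filter_psms(compute_fdr(psm$psms)), db)
  flagged <- cohort_pervasiveness(mp$evidence, min_cohorts = 8L)
  expect_setequal(flagged$orf_id, psm$pervasive_orfs)
  # boundary: 7 cohorts is not pervasive at min 8
  ev <- data.frame(orf_id = c("a", "b"), n_peptides = 1L, n_cohorts = c(8L, 7L),
                   peptides = "p", cohorts = "x", assays = "proteome")
  expect_equal(cohort_pervasiveness(ev, 8L)$orf_id, "a")
  # monotone: raising min_cohorts never adds ORFs
  for (k in 1:10) {
    a <- cohort_pervasiveness(mp$evidence, k)$orf_id
    b <- cohort_pervasiveness(mp$evidence, k + 1L)$orf_id
    expect_true(all(b %in% a))
  }
})

test_that("differential-expression classes use strict p and inclusive fold-change", {
  ev <- data.frame(orf_id = letters[1:4], gene_id = c("g1", "g2", "g3", "g4"))
  de <- data.frame(gene_id = c("g1", "g2", "g3"),
                   log2fc = c(1.6, -1.5, 2.0), p_value = c(0.005, 0.005, 0.02))
  out <- annotate_differential_expression(ev, de)
  expect_equal(out$de_class, c("over", "under", "none", "none"))
})

test_that("rank-sum comparison matches exact small-sample behaviour", {
  r <- stratified_rank_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)         # minimal rank-sum statistic
  expect_equal(r$p_value, 2 / choose(6, 3))    # two-sided exact p = 0.1
  same <- stratified_rank_test(1:20, 1:20)
  expect_gt(same$p_value, 0.9)
  expect_error(stratified_rank_test(numeric(), 1:3), "nonempty")
  # a 1-SD shift at n = 200 per group is essentially always detected
  set.seed(21)
  hits <- mean(replicate(30, {
    stratified_rank_test(rnorm(200), rnorm(200, 1))$p_value < 0.001
  }))
  expect_gte(hits, 0.95)
})

test_that("PSM table I/O round-trips with derived decoy flags", {
  sim <- shared_sim()
  psm <- simulate_psm_tables(sim$cfg, sim$ref$planted, sim$ref$canonical_db)
  f <- tempfile(fileext = ".tsv")
  write_tsv_table(psm$psms[, setdiff(names(psm$psms), "is_decoy")], f)
  back <- read_psm_table(f)
  expect_equal(nrow(back), nrow(psm$psms))
  expect_equal(back$is_decoy, psm$psms$is_decoy)
})
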