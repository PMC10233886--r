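#!/usr/bin/env Rscript
# Step 6: build per-sample mutated ncORF proteomes from eligible variants
# (canonical-silent hits on out-of-frame ORFs; UTR/noncoding hits on any
# ORF), eliminate wildtype-explainable peptides, and run the epitope
# prioritization cascade: MHC-I affinity <= 150 nM AND (retention-time
# error < 5 min OR normal-tissue median expression < 1 TPM).

suppressPackageStartupMessages(library(crypticorf))

genome <- read_genome("results/simdata/genome.fa")
tx <- load_annotation("results/simdata/annotation.gtf", genome)
orf_fa <- read_protein_fasta("results/ncorfs.fa", origin = "ncorf")
orfs <- read_tsv_table("results/ncorfs.tsv")
orfs$protein <- orf_fa$sequence[match(orf_accession(orfs$orf_id, orfs$category),
                                      orf_fa$accession)]
canonical_db <- read_protein_fasta("results/simdata/canonical.fa",
                                   origin = "canonical")

vars <- read_maf("results/simdata/variants.maf", genome)
ra <- reannotate_variants(vars, orfs, tx, genome)
mut <- build_mutated_proteome(ra$pairs, vars, orfs, tx, genome)
write_mutated_proteome(mut, "results/mutated_proteome.fa")
cat(sprintf("Mutated ncORF proteins: %d across %d samples\n",
            nrow(mut), length(unique(mut$sample_id))))

spec <- digest_spec(mode = "semi", missed_cleavages = 2L, min_len = 8L,
                    max_len = 25L)
cand <- mutated_peptides(mut, spec)
wt_db <- rbind(orf_fa, canonical_db)
neo <- eliminate_wildtype_matches(cand, wt_db)
write_tsv_table(neo, "results/neoantigen_peptides.tsv")
cat(sprintf("Candidate mutated peptides: %d; %d retained after wildtype elimination\n",
            nrow(cand), nrow(neo)))

epi <- read_tsv_table("results/simdata/epitope_candidates.tsv")
report <- prioritize_epitopes(epi, affinity_max = 150, rt_max = 5, tpm_max = 1)
write_tsv_table(report, "results/epitope_report.tsv")
rep <- report[report$reported, ]
cat(sprintf("Epitope candidates: %d; reported: %d\n", nrow(report), nrow(rep)))
cat(sprintf("  affinity pass: %d; RT pass: %d; GTEx pass: %d\n",
            sum(report$affinity_pass), sum(report$rt_pass),
            sum(report$gtex_pass)))
cat("Top reported candidates by affinity:\n")
print(utils::head(rep[, c("peptide", "hla_allele", "affinity_nM",
                          "rt_error_min", "gtex_median_tpm")], 5))
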