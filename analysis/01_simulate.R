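#!/usr/bin/env Rscript
# Step 1: generate the synthetic study data (genome, annotation, canonical
# proteome, PSM tables, somatic MAF, epitope candidate tables) with planted
# ground truth. All downstream steps read from results/simdata.

suppressPackageStartupMessages(library(crypticorf))

seed <- as.integer(Sys.getenv("CRYPTICORF_SEED", "1"))
out <- "results/simdata"

cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg, out)

cat("Synthetic study generated under", out, "\n")
cat(sprintf("  transcripts: %d (%d noncoding)\n", cfg$n_transcripts,
            round(cfg$n_transcripts * cfg$fraction_noncoding)))
cat(sprintf("  planted ncORFs: %d\n", nrow(sim$ref$planted)))
print(table(sim$ref$planted$category))
cat(sprintf("  PSMs: %d (%d decoys), cohorts: %d\n", nrow(sim$psm$psms),
            sum(sim$psm$psms$is_decoy), cfg$n_cohorts))
cat(sprintf("  planted pervasive ORFs: %d\n", length(sim$psm$pervasive_orfs)))
cat(sprintf("  somatic variants: %d\n", nrow(sim$variants$maf)))
cat(sprintf("  epitope candidates: %d\n", nrow(sim$epitopes$candidates)))
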