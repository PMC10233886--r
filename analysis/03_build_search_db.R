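#!/usr/bin/env Rscript
# Step 3: drop ncORF proteins indistinguishable from canonical sequence
# space, then build the target-decoy proteogenomic search database
# (ncORF + canonical targets, one reversed decoy each, no contaminants).

suppressPackageStartupMessages(library(crypticorf))

orfs <- read_tsv_table("results/ncorfs.tsv")
ncorf_db <- read_protein_fasta("results/ncorfs.fa", origin = "ncorf")
canonical_db <- read_protein_fasta("results/simdata/canonical.fa",
                                   origin = "canonical")

flt <- canonical_overlap_filter(ncorf_db, canonical_db)
write_tsv_table(flt$removed, "results/ncorf_removals.tsv")

db <- build_search_database(flt$retained, canonical_db,
                            fasta_path = "results/search_db.fa")

cat(sprintf("Canonical-overlap filter removed %d of %d ncORF proteins\n",
            nrow(flt$removed), nrow(ncorf_db)))
if (nrow(flt$removed)) print(table(flt$removed$reason))
cat(sprintf("Search database: %d entries (%d targets + %d reversed decoys)\n",
            nrow(db), sum(db$origin != "decoy"), sum(db$origin == "decoy")))
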