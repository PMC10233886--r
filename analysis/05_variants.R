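#!/usr/bin/env Rscript
# Step 5: re-annotate somatic variants in non-canonical reading frames.
# Every variant is projected into every overlapping ncORF, classified
# (missense / frameshift / stop gained / stop lost / silent), then
# cross-classified into the three overlap groups: (1) canonical-noncoding
# variants altering an ncORF, (2) variants in sequence shared by CDS and
# ncORF, (3) variants with no ncORF protein change. Per-sample mutation
# burden compares canonical-altering vs ncORF-only variants.

suppressPackageStartupMessages(library(crypticorf))

genome <- read_genome("results/simdata/genome.fa")
tx <- load_annotation("results/simdata/annotation.gtf", genome)
orfs <- read_tsv_table("results/ncorfs.tsv")
orfs$protein <- read_protein_fasta("results/ncorfs.fa")$sequence[
  match(orf_accession(orfs$orf_id, orfs$category),
        read_protein_fasta("results/ncorfs.fa")$accession)]

vars <- read_maf("results/simdata/variants.maf", genome)
ra <- reannotate_variants(vars, orfs, tx, genome)
write_tsv_table(ra$pairs, "results/variant_consequences.tsv")
write_tsv_table(ra$variants, "results/variant_summary.tsv")

ov <- ra$variants[!is.na(ra$variants$figure_group), ]
cat(sprintf("%d of %d variants overlap at least one ncORF\n",
            nrow(ov), nrow(vars)))
cat("Overlap groups:\n"); print(table(ov$figure_group))
alt <- ra$pairs[ra$pairs$ncorf_class != "none", ]
cat("Per-class ncORF consequences (variant x ORF pairs):\n")
print(table(alt$ncorf_class))
cat(sprintf("Protein-altering in an ncORF: %d variants; class tallies sum: %s\n",
            sum(ov$ncorf_altered),
            nrow(ov) - sum(ov$figure_group == "3_canonical_only")))

burden <- mutation_burden(ra$variants, region_size_mb = 38)
write_tsv_table(burden, "results/mutation_burden.tsv")
comp <- attr(burden, "comparisons")
cat("Mutation burden (v/Mb), canonical vs ncORF-only, per cohort rank-sum p:\n")
print(comp)
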