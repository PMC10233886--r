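Package: crypticorf
Title: Proteogenomic Discovery of Non-Canonical ORF Peptides, Neoantigens
    and Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates and classifies non-canonical open reading frames
    (upstream, downstream, out-of-frame and noncoding-RNA ORFs) from genome
    and transcript annotations, builds target-decoy proteogenomic search
    databases with in-silico tryptic digestion, filters peptide-spectrum
    matches by target-decoy false discovery rate and probability thresholds,
    re-annotates somatic variants in non-canonical reading frames, generates
    patient-specific mutated non-canonical proteomes for neoantigen
    discovery, and prioritizes MHC-bound epitope candidates by binding
    affinity, retention-time error and normal-tissue expression. Includes a
    synthetic-data generator with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
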