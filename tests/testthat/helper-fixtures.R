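# In-code fixtures shared across test files.

# single-contig genome from a raw sequence
tiny_genome <- function(seq, name = "chr1") genome_build(stats::setNames(seq, name))

# quick transcript constructor with exons given as a 2-column matrix-like list
make_tx <- function(id = "T1", contig = "chr1", strand = "+", exons,
                    cds_span = NULL, biotype = if (is.null(cds_span)) "lncRNA"
                    else "protein_coding") {
  transcript_model(id, paste0("G_", id), paste0("g_", id), contig, strand,
                   data.frame(start = exons[[1]], end = exons[[2]]),
                   cds_span = cds_span, biotype = biotype)
}

# one-row variant data.frame in the internal representation
make_variant <- function(contig, pos0, ref, alt, sample_id = "S1",
                         cohort = "C01", canonical_class = NA_character_) {
  data.frame(variant_id = sprintf("%s:%d:%s>%s:%s", contig, pos0,
                                  ifelse(ref == "", "-", ref),
                                  ifelse(alt == "", "-", alt), sample_id),
             contig = contig, pos0 = as.integer(pos0), ref = ref, alt = alt,
             sample_id = sample_id, cohort = cohort,
             canonical_class = canonical_class, stringsAsFactors = FALSE)
}

# shared small simulated reference (built once per test run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42)
      cache <<- list(cfg = cfg, ref = simulate_reference(cfg))
    }
    cache
  }
})
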