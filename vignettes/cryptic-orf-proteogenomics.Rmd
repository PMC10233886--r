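---
title: "Methods: non-canonical ORF proteogenomics with crypticorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-canonical ORF proteogenomics with crypticorf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticorf)
```

# Scope and model

`crypticorf` re-implements a cancer proteogenomics workflow around a single
object of interest: the **non-canonical ORF (ncORF)** — an AUG-initiated
reading frame that reaches an in-frame stop codon but lies outside the
annotated coding sequence. On protein-coding transcripts these are upstream
ORFs (entirely 5′ of the CDS), downstream ORFs (entirely 3′ of it) and
out-of-frame ORFs (overlapping the CDS in a shifted frame, encoding a
protein unrelated to the canonical one); on noncoding transcripts every ORF
is non-canonical. The pipeline asks three questions of such ORFs: is there
mass-spectrometric peptide evidence they are translated; do somatic
mutations alter their proteins even when silent or noncoding in the
canonical frame; and do their peptides (mutated or not) look like MHC-I
ligands worth nominating as immunotherapy targets.

## Coordinates and translation

All internal coordinates are 0-based half-open, on both the genome and the
spliced transcript; GTF (1-based closed) and MAF/VCF (1-based) are
converted exactly once, at the parse boundary. Minus-strand transcripts are
handled by a single pair of maps (`genomic_to_transcript`,
`transcript_to_genomic`) that are inverse bijections on exonic positions —
a property the test suite asserts over every exonic base of simulated
transcripts. The stop codon is considered part of the CDS span; when an
annotation excludes it (GENCODE convention) the parser extends the span by
one codon after verifying the next in-frame codon is a stop. Transcripts
with an annotated but incomplete CDS (no terminal stop, discontiguous
projection, CDS outside exons) are rejected and reported rather than
guessed at. Codons containing `N` translate to `X`, and peptides containing
`X` are excluded from digestion products, because a search engine cannot
match an ambiguous residue.

## ORF enumeration and classification

Enumeration scans the three frames of the spliced transcript and emits one
ORF per (stop codon, frame): the 5′-most AUG, i.e. the longest variant.
This avoids a combinatorial explosion of nested AUGs while preserving the
between-start-and-stop interval definition; alternative-AUG isoforms are an
explicit non-goal, as are near-cognate (CUG/GUG) starts, ribosome-profiling
integration, Kozak-context scoring (accepted as an optional external
annotation instead) and novel junction discovery. The canonical CDS itself
is never emitted, and ORFs overlapping the CDS in the canonical frame are
discarded as canonical isoforms. An ORF that starts in a UTR but runs into
the CDS out of frame is classified `out_of_frame`: overlap with canonical
sequence, not start position, is the property that matters downstream
(shared peptides, variant cross-classification). The default minimum length
is 30 codons — the usual short-ORF catalogue convention — configurable down
to 8 for immunopeptide-scale ORFs; the synthetic workflow and tests run at
8–10 because planted ORFs are deliberately short (10–26 codons).

Correctness is established by oracle equivalence: an independent
brute-force scan that walks every AUG position and applies the
5′-most-per-(stop, frame) rule must produce an identical ORF set on 200
random transcripts (300–3,000 nt, GC 0.30–0.60) and on every planted
reference transcript.

## Search space

The search database is targets plus per-protein whole-sequence reversed
decoys (`rev_` prefix), giving exactly 2× the target count, with no
contaminant entries. Digestion follows the trypsin rule (cleave after K or
R, not before P); semi-specific mode adds every prefix/suffix truncation of
each fully-tryptic product, so the semi set provably contains the full set,
and 0-missed full products concatenate back to the parent protein — both
asserted structurally on 1,000 random proteins.

ncORF proteins indistinguishable from canonical sequence space are removed
before searching. Where the original workflow used an aligner E-value
cutoff, this package uses a deterministic, parameter-explicit filter: drop
an ncORF if (a) its full sequence is an I=L-equivalent substring of a
canonical protein, or (b) more than 90 % of its fully-tryptic peptides are
also producible from the canonical set. E-values depend on the tool and
database size; the filter preserves the step's purpose (removing ncORFs
whose peptide evidence could never be discriminating) while being exactly
testable at boundary cases (9/10 shared peptides retained, 10/10 removed).
An external aligner's removal list can be supplied verbatim for users who
want tool-faithful behaviour. Isoleucine and leucine are treated as
identical in *all* peptide-vs-protein comparisons because they are isobaric
in MS.

## PSM filtering and evidence

The FDR estimator at score threshold t is `#decoys ≥ t / max(1, #targets ≥ t)`,
monotonized into q-values from the permissive end; ties share a q-value and
sorting is made deterministic by breaking score ties on spectrum id. The
+1-corrected decoy count is available as a switch; both estimators are
standard and the choice is deliberately exposed rather than hidden.
Upstream engine internals (search scoring, the semi-parametric probability
mixture, peptide-centric re-validation) are not re-implemented: scores and
probabilities are input columns, and an optional `validated` column gates
retention when present — preserving each tool's position in the pipeline
without cloning it.

Per-assay defaults mirror the two acquisition regimes: whole-proteome PSMs
are filtered at q ≤ 0.01; immunopeptidome PSMs (no enzyme, MHC-eluted) at
probability ≥ 0.99 and 8–25 aa. Retained peptides are mapped to every ncORF
containing them (I=L), peptides also contained in any canonical protein are
discarded as non-discriminating, and evidence is aggregated per ORF with
cohort/assay provenance. Pervasive translation is support in ≥ 8 cohorts;
the flag is monotone in the threshold. DE annotation uses p < 0.01 with
log2FC ≥ 1.5 (over) or ≤ −1.5 (under), inclusive at the fold-change bound.
Group comparisons (conservation strata, peptide lengths, mutation burden)
use the two-sided Wilcoxon rank-sum test via `stats::wilcox.test`.

The FDR calibration check runs the generator's two-component score model —
true targets N(4, 1), false targets and decoys N(0, 1), 10,000 PSMs at 50 %
decoys — over 20 seeds and requires the realized false-target fraction
among q ≤ 0.01 acceptances to average ≤ 0.02. With decoys twice as numerous
as false targets the estimator is conservative by about that factor;
measured values sit near 0.005.

## Variant re-annotation

Variants are read from GDC-dialect MAF (or minimally from VCF 4.x),
checked against the reference genome (a mismatch is a hard error, not a
warning), and pure indels are left-normalized so positions are identical
across input dialects. An SNV's consequence in an ORF is called by codon
arithmetic on the strand-correct spliced sequence: same residue → silent;
stop codon gained → `stop_gained`; a stop codon turned sense → `stop_lost`;
otherwise missense. Indels are classified by the number of *exonic*
affected bases modulo 3 — a deletion straddling an intron boundary shifts
the frame only by its exonic part. Splice-site re-splicing is out of scope:
variants are projected only where they fall in exonic sequence.

Every variant × overlapping-ORF pair is emitted, and each variant receives
exactly one overlap group: (1) canonical-noncoding (UTR, flank, intron,
splice region, RNA) but ncORF-altering; (2) in sequence shared by the CDS
and an ncORF, ncORF-altering; (3) no ncORF protein change. The partition
identity — groups are exhaustive and mutually exclusive, and per-class
tallies (missense + frameshift + stop gained/lost) sum to the
protein-altering total — is asserted on every synthetic run. The
consequence caller itself is checked against a naive oracle that applies
the edit to the genome, shifts exon coordinates, re-splices and re-diffs
the translated proteins, on 1,000 random SNVs and 1–6 nt indels across both
strands.

Mutation burden divides per-sample protein-altering variant counts by a
surveyed-region size whose default is 38 Mb — a typical exome target size,
made an explicit parameter because burden denominators are usually silently
tool-defined. The ncORF scope counts variants whose *only* protein-altering
consequence is non-canonical, counting each variant once regardless of how
many ORFs it hits.

## Mutated proteomes and the epitope cascade

Eligibility for the mutated proteome is exactly the blind spot of
canonical-frame neoantigen pipelines: canonical-silent variants hitting
out-of-frame ORFs, and variants outside the canonical CDS footprint hitting
any ORF. All eligible variants of one sample on one ORF are applied jointly
on the spliced transcript (rejecting overlapping edits rather than
guessing an order), and frameshifts re-translate to the next stop. A
candidate peptide must span the changed interval, and is discarded if it
occurs — I=L equivalent — anywhere in the wildtype space (canonical plus
unmutated ncORF proteins); the test suite re-verifies this by brute-force
substring scan on every run.

Prioritization is a gate plus a support disjunction: predicted MHC-I
affinity ≤ 150 nM (the conventional high-binder cutoff; an optional
percentile-rank < 2 gate is available), then retention-time error < 5 min
(strict) OR normal-tissue median expression < 1 TPM. Missing RT or
expression values leave the corresponding flag unset: a candidate with no
RT measurement can still be rescued by the expression route but never
passes on RT. Binding affinities, RT predictions and expression medians are
pluggable input tables — trained predictor internals are out of scope. The
built-in hydrophobicity index (per-residue hydropathy coefficients summed
with a mild length normalization, `1/(1 + 0.015·max(0, L − 20))`) exists
only for RT-vs-hydrophobicity QC correlation, never as a filter, and an
external prediction column takes precedence.

## The synthetic study design

The generator's defaults are the fixed conditions every planted-truth check
runs under: 48 transcripts (a quarter noncoding) on 4 contigs, both
strands, 1–3 exons each; 5′UTRs of 96–150 nt, CDSs of 60–100 codons, 3′UTRs
of 120–200 nt; one planted ORF per eligible category slot (uORF, dORF,
out-of-frame per coding transcript; one per noncoding transcript) of 10–26
codons; 10 cohorts × 5 samples; the N(4,1)/N(0,1) score mixture with 10,000
PSMs and probabilities as a logistic transform of score; 8 pervasive ORFs;
a variant model of 189 variants across 10 verified consequence cells; 47
epitope candidates cycling through all 8 filter-intent combinations; 1 min
of RT noise. These sizes keep the full suite and the acceptance script
within a few minutes on one CPU while leaving every check statistically
meaningful.

Plants are constructed, not hoped for: each planted ORF is written as
`TAA · AUG · body · stop` in its frame, the leading in-frame stop
guaranteeing the planted AUG is the 5′-most of its (stop, frame) group, so
recovery of the exact planted coordinates is a valid expectation.
Out-of-frame plants are resampled until they introduce no canonical-frame
stop, keeping the annotated CDS translatable end-to-end. Background ORFs
arising in random sequence are allowed and expected — recovery checks use
superset semantics for counts and exact membership for planted ids. Variant
plants are verified closed-loop: a candidate edit is emitted only after the
package's own consequence caller (on the left-normalized form) reproduces
the requested canonical and non-canonical classes. One root seed derives
fixed-offset child seeds per generator so stages are reproducible
independently.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: spectra (no mzML/MGF; scores and probabilities
are drawn, not computed from peaks), real score distributions (which are
neither Gaussian nor homoscedastic), homology structure (random sequence
under-represents shared peptides between paralogous ORFs, so the
canonical-overlap filter removes nothing here), genuine splice-site
variants, quantification, and the scale of a real ORF catalogue. The
pipeline's headline quantities on real cohorts depend on those inputs; the
tests establish the machinery's exactness, not biological effect sizes.

## Numerical and degenerate-input choices

q-values on an all-decoy table degenerate to 1 with a warning rather than
erroring; empty variant models produce a valid empty MAF; a digest whose
products all fall outside the length window returns an empty table;
multi-allelic variant records are refused with instructions to normalize
upstream, as are multi-nucleotide substitutions (out of scope).
Deduplication breaks ties by lexicographically smallest ORF id; FDR sorting
breaks score ties by spectrum id; thresholds are strict or inclusive
exactly as documented (q ≤, probability ≥, RT error <, affinity ≤,
expression <, fold-change ≥) and boundary cases are pinned by tests
(RT error of exactly 5 min fails; 9/10 shared peptides is retained).

## Known limitations

Single transcript-per-gene reasoning: the figure-group assignment uses the
canonical class of the variant's annotation (or the ORF's own transcript),
which is unambiguous in the synthetic design but could differ per isoform
in a real multi-isoform annotation. Peptide→ORF mapping is exact substring
matching; it does not model modified residues. The VCF reader is
site-level only. Mutated-proteome construction rejects variants extending
5′ of the ORF start rather than re-locating the start codon.
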