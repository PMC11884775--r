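---
title: "Refining an NLRome with enrichment sequencing evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining an NLRome with enrichment sequencing evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlromer)
```

## The problem

Plant genomes carry hundreds of nucleotide-binding leucine-rich repeat
receptors (NLRs), the intracellular immune receptors that underlie most
cloned disease-resistance genes. NLR loci are long, repetitive,
clustered, and fast-evolving — exactly the genes that automated
annotation pipelines miss, truncate, or merge. An annotation error at an
NLR locus is costly: it hides candidate resistance genes from mapping
and cloning work.

Resistance gene enrichment sequencing (RenSeq) offers an independent
line of evidence. Hybridization baits tiled over known NLR sequences
capture NLR-derived DNA fragments before short-read sequencing, so true
NLR loci show deep, sharply bounded read coverage against a shallow
genome-wide background. Overlaying that coverage with motif-based NLR
locus predictions and with the genome's existing gene models turns
annotation auditing into a tractable, largely automatic procedure:
wherever prediction and coverage agree but the annotation does not,
something is wrong, and the region can be re-annotated de novo.

`nlromer` implements that procedure end to end, with every stage
exchangeable for an external tool through standard file formats.

## Pipeline model

The pipeline classifies each predicted, coverage-supported NLR locus
into one of four categories and repairs the last three:

* **ok** — an annotated gene's CDS covers ≥ `ok_cds_fraction` (default
  0.8) of the locus;
* **missing** — no annotated CDS overlaps the locus;
* **misannotated** — overlap exists but below the threshold (truncated
  or frame-shifted models fall here);
* **fused** — a single gene model's CDS overlaps two or more loci.
  Fused takes precedence over the other categories for every locus under
  the same gene, because the repair (splitting one model into several)
  differs fundamentally from re-predicting a single model.

The 0.8 threshold operationalizes "correctly annotated": a model missing
≥ 20% of its motif-supported locus is worth re-predicting, while
boundary jitter of a few percent is not. Coverage support is defined per
locus as ≥ `min_cov_fraction` (default 0.5) of locus bases inside a
high-coverage region; loci without support are reported but excluded
from repair, mirroring the practice of only trusting calls with solid
enrichment signal. Both thresholds are configurable and recorded in the
run manifest.

### Coverage

Depth is *span-based*: each primary alignment contributes its full CIGAR
reference span, which reproduces what a coverage display shows and is
deterministic; secondary and supplementary records are excluded, and no
mapping-quality floor is applied by default. The region caller emits
maximal runs of bases with depth ≥ `min_depth` (default 50), merges runs
separated by ≤ `merge_gap` bases (default 200, bridging short dips from
repeat-masked or diverged stretches), and discards merged runs shorter
than `min_run_length` (default 100, suppressing isolated spikes). The
depth floor and the 1 kb extraction flank are the published working
criteria; the run-length floor and merge gap are this package's
reproducible stand-ins for what is otherwise a manual inspection step.

### Locus prediction

The scanner works on six-frame translations (standard code, stops as
`*`, ambiguous codons as `X`) with a set of ~12 degenerate consensus
motifs covering the NB-ARC core (P-loop, Kinase-2, RNBS-B on the
P-loop side; GLPL and MHD on the C-terminal side), two TIR motifs, a
double-unit LRR repeat (`L..L.L..N.L` twice), and an EDVID-like CC
motif. This is a deliberately simplified, fully documented motif set —
not a reproduction of MEME-derived motif libraries — and the adapter
`read_nlr_annotator()` accepts an external predictor's output under the
same locus contract whenever higher sensitivity is needed.

Same-sequence, same-strand hits within `max_gap` (default 10 kb,
a typical NLR gene span) are single-linkage clustered; the locus is the
hull of its hits. Opposite-strand hits never cluster, so nested or
head-to-head loci are reported separately. Completeness follows a
two-sided NB-ARC rule: *complete* requires a P-loop-side and a
GLPL/MHD-side motif in the same reading frame; both sides present only
across different frames is flagged *pseudogene-like* (a frameshift
indicator); anything else is *partial*. This three-way flag approximates
(but does not reproduce) the taxonomy of external locus predictors.

### Repair

Problem regions (non-ok, coverage-supported loci, flanked by 1 kb,
merged) are sliced from the genome and re-annotated. The internal
predictor finds all maximal ORFs — first ATG after the previous in-frame
stop, through the next stop — of ≥ 300 nt in all six frames, suppressing
ORFs nested inside a longer same-strand ORF. It is intronless *by
design*: spliced prediction is delegated to an external tool through a
command-template adapter, and the synthetic genome plants intronless
genes so the whole pipeline is testable without external software.
"Longest isoform" is measured by total CDS length (protein-level
downstream analyses care about the longest protein, not the longest
transcript span), with ties broken by the lexicographically smallest
transcript id.

Novel candidates are translated and kept only if they carry at least one
canonical NLR domain signature; a novel model sharing > 50% reciprocal
CDS overlap with a kept model is rejected as a duplicate. The refined
annotation is the kept originals plus the surviving novel models;
non-NLR genes are never touched.

### Classification

Domain hits come either from an InterProScan TSV (accessions mapped to
the controlled vocabulary via a shipped Pfam table; unknown accessions
become OTHER, never an error) or from the internal consensus scanner,
which recognizes the same cassettes the synthetic generator plants and
emits pseudo e-values well below threshold for exact matches. All hits
are filtered at e-value < 1e-5 — the documented threshold for C-JID and
integrated-domain detection, applied uniformly to canonical hits as
well for consistency (configurable).

A protein is **full** iff it has an N-terminal signaling domain (TIR, CC
or RPW8), NB-ARC, and LRR; class is assigned with N-terminal precedence
TIR > RPW8 > CC (TIR is the strongest signature; RPW8 is kept distinct
from generic CC in the three-class scheme). Completeness depends on
domain *presence*, not order, but the ordered N→C domain string is
reported so order anomalies stay auditable. TIR-only means the
category set is exactly {TIR}. OTHER-category hits on a protein that
also carries NB-ARC or TIR are integrated-domain (NLR-ID) candidates,
with copy counts from disjoint hits. NB-ARC subsequences (best hit per
protein) are exported as the standard input for NB-ARC-based phylogeny,
which is itself out of scope.

The summary layer reports totals, full/partial, TNL/CNL/RNL, TIR-only,
C-JID and NLR-ID counts and a per-chromosome table; sequence names not
matching `^[AC][0-9]{2}$` (the *B. napus* A01..C09 style; configurable)
are pooled as "scaffolds". C-JID prevalence can be expressed per TIR
containing protein by the caller; the per-protein flags make either
denominator available.

### Bait tiling

Capture targets are preprocessed with the N rule — every maximal N run
of 1–10 nt becomes Ts (length preserved), longer runs split the target —
and tiled with 80-nt probes at 3× density. Probe offsets lie on the
phase-rounded grid `round(i * probe_length / tiling_factor)`
(0, 27, 53, 80, ... for 80/3). Because the grid repeats exactly every
`probe_length` bases, every base at least one probe length from both
segment ends is covered by *exactly* `tiling_factor` probes — the
defining property of k× tiling — with one end-anchored probe appended
when the grid does not already reach the segment end. A uniform 27-nt
step cannot achieve this (3 × 27 ≠ 80); the phase-rounded grid is this
package's explicit tiling contract, since vendors do not publish their
offsets. Repeat softmasking and thermodynamic filtering are out of
scope, so bait *counts* over real target sets are not comparable to
vendor numbers.

## The synthetic study

`synth_config()` defaults define the study conditions used throughout
the tests and the acceptance script:

* 2 Mb genome over four sequences (`A01`, `A09`, `C09`,
  `scaffold00001`) at 37.6% background GC — the GC content typical of
  crucifer NLR capture targets;
* 40 planted intronless NLR genes: 20 TNL (8 with C-JID), 8 CNL, 4 RNL
  and 8 partial (TIR-only, TIR+NB-ARC, NB-ARC+LRR), four proteins
  carrying integrated domains (one with three tandem copies of a
  galactose-oxidase cassette);
* corruption rates 0.3 / 0.2 / 0.1 for missing / truncated (random
  30–60% codon-aligned prefix) / fused models;
* 150 bp paired reads, insert ~N(350, 50²) truncated at 300 nt, ~100×
  depth over planted-gene neighborhoods (± 500 bp), ~2× background,
  0.1% substitution errors, and a truth SAM so coverage can be computed
  without an aligner.

Planted proteins are assembled from fixed amino-acid cassette blocks
that contain literal instances of the scanner's motifs, reverse
translated with one fixed AT-leaning codon per amino acid, framed by an
in-frame upstream stop so each gene is a maximal ORF, and rejected and
redrawn if random linkers ever create spurious domain hits. Two layout
choices matter and are deliberate:

* single genes sit ≥ 12 kb apart — beyond the 10 kb clustering gap — so
  each planted gene yields exactly one predicted locus; designated
  fusion pairs are placed head-to-head (opposite strands, a common
  layout of real paired NLRs) 0.4–1.2 kb apart, so the pair's loci stay
  distinct while an erroneous fused model spans both;
* single-domain partial genes (TIR-only) carry two cassette copies with
  the length filler between them, so the motif hull spans most of the
  CDS — as the single large TIR domain does in real TIR-only proteins.
  With a 30-aa cassette confined to the N-terminus, prefix truncation
  would be invisible to locus/CDS overlap, which is a property of the
  fixture rather than of real data.

Randomness uses stage-derived seeds (`seed` for genome and placement,
`seed + 1` for corruption, `seed + 2` for reads) with a documented draw
order — categories first, one uniform per gene in manifest order, then
truncation fractions — so stages are independently re-runnable and every
output is byte-reproducible.

What the generator does **not** emulate: introns and alternative
splicing, segmental duplications and pseudogene clusters, indel and
quality-score error structure, PCR duplicates, capture-efficiency
biochemistry, and repeat-driven multi-mapping. Passing the synthetic
suite therefore demonstrates the pipeline's logic — category assignment,
region extraction, exact ORF recovery, classification arithmetic — not
performance on real repeat-rich NLR clusters, where the external
aligner/predictor adapters carry the load.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed internally (the GenomicRanges
  convention); GFF3/BED/SAM conversions happen only in readers and
  writers, so no off-by-one drift can accumulate mid-pipeline.
* The region caller merges before applying the run-length floor, so two
  ≥ 50× runs bridged by a short dip count as one region.
* Strict inequality at thresholds: depth ≥ 50 passes, e-value must be
  < 1e-5, uniform depth 49 yields nothing.
* Empty inputs yield empty, well-typed outputs everywhere (no-alignment
  depth tracks are all zero; an all-ok reconciliation extracts nothing;
  an empty bait set reports `NA` mean GC).
* Isoform ties use lexicographic transcript-id order; locus ids are
  position-sorted; all tables are emitted in deterministic order.
* Proteins that fail translation (internal stops in a broken real-world
  model) are skipped with a warning rather than aborting the cohort.

## Validation strategy

Each fast implementation is tested against an independent brute-force
oracle: per-base depth against a nested-loop count, the region caller
against a linear per-base scan with the same merge contract, motif
clustering against an O(n²) transitive-closure oracle, six-frame
translation against an independent translation routine, CIGAR reference
spans against a hand-written CIGAR walk, and the end-to-end pipeline
against the generator's truth manifest (category confusion, exact CDS
recovery, zero background calls). Classification algebra — full =
TNL + CNL + RNL, full + partial = total, TIR-only ⇒ partial — is
property-tested over a thousand random architectures. The cohort-level
classifier is additionally exercised on a bundled per-gene composition
table for the refined Westar canola NLRome; that table is a synthetic
reconstruction consistent with the published cohort's marginal counts
(715 NLRs; 287 full = 232 TNL + 39 CNL + 16 RNL; 138 TIR-only; 199
C-JID; 69 NLR-IDs over 49 domain types; 75/68/9 NLRs on C09/A09/A10),
not a redistribution of deposited data — so it validates the
classification and aggregation machinery, not the underlying biology.

## Known limitations

* The internal ORF predictor cannot recover spliced genes; use the
  external-predictor adapter for real genomes.
* The motif set trades sensitivity for transparency; diverged NLRs
  (notably CC-NLRs with degenerate EDVID motifs) may need an external
  locus predictor.
* Span-based depth ignores deletions and soft-clips inside alignments;
  depth near structural variants can differ from base-accurate piling.
* The fused category requires both constituent loci to be individually
  predicted; two NLRs merged by the locus predictor itself are
  indistinguishable from one.
* Bait counts are not vendor-comparable (no repeat masking or
  thermodynamic filtering).
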