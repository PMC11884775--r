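# nlromer

Refining a plant genome's NLRome — its complete complement of
nucleotide-binding leucine-rich repeat receptors (NLRs) — by reconciling
three independent evidence tracks:

1. **RenSeq read depth.** Resistance gene enrichment sequencing captures
   NLR-derived fragments with tiled 80-nt baits before Illumina
   sequencing, so true NLR loci show deep coverage (the working criterion
   is ≥ 50×) against a shallow background.
2. **Motif-predicted NLR loci.** Six-frame translation of the genome is
   scanned with degenerate consensus motifs for the NB-ARC core (P-loop
   `GG[VM]GKTT`, Kinase-2, RNBS-B, GLPL, MHD), TIR, LRR and EDVID-like CC
   signatures; same-strand hits within 10 kb are clustered into candidate
   loci, and a locus is *complete* when a P-loop-side and a GLPL/MHD-side
   NB-ARC motif co-occur in one reading frame.
3. **The existing annotation.** Each predicted, coverage-supported locus
   is compared against annotated CDS and assigned one of the three
   classical misannotation categories — **missing** (no gene model),
   **misannotated** (the model covers < 80% of the locus, e.g. a
   truncated CDS), or **fused** (one model spans ≥ 2 loci) — or **ok**.

Non-ok loci are extracted with 1 kb flanks, genes are re-predicted de
novo inside those regions (an intronless ORF predictor is built in; an
external predictor such as AUGUSTUS can be wrapped), the longest isoform
is kept, candidates without an NLR domain signature are dropped, and the
surviving models replace the faulty ones. The refined proteins are then
classified NLRtracker-style by ordered domain composition:
**full** = N-terminal signaling domain (TIR / CC / RPW8) + NB-ARC + LRR,
with class TNL / CNL / RNL by N-terminal precedence TIR > RPW8 > CC;
everything else is **partial** (including TIR-only receptors). C-JID
domains and integrated decoy domains (NLR-IDs, e-value < 1e-5) are
flagged, and counts are aggregated per chromosome with non-chromosome
sequences pooled as "scaffolds".

Every stage reads and writes standard formats (FASTA, GFF3, SAM, BED,
bedGraph, InterProScan-style TSV), so real aligner output, NLR-Annotator
predictions, or InterProScan tables can replace the built-in components
at any stage boundary. A fully seeded synthetic-data generator (genome
with planted NLR genes of known architecture, corrupted annotation,
enriched paired reads with a truth SAM) makes the whole pipeline testable
without external data.

## Worked example

Run the full pipeline on the default synthetic study (2 Mb genome, 40
planted NLRs — 20 TNL, 8 CNL, 4 RNL, 8 partial — corrupted with rates
0.3/0.2/0.1 for missing/truncated/fused, ~100× on-target enrichment):

```r
library(nlromer)
res <- run_nlrome(nlrome_config(seed = 42L), out_dir = "nlrome_out")
res$summary
#> <nlrome_summary> 40 NLRs: 32 full (20 TNL / 8 CNL / 4 RNL), 8 partial
#>   TIR-only 3 | C-JID 8 | NLR-ID 4 over 4 domain types
#>   per chromosome: A01=14 A09=9 C09=10 scaffolds=7

table(res$records$category)
#>        fused misannotated      missing           ok
#>            2           10           16           12
```

The reconciliation table shows how the corrupted annotation was
diagnosed: 12 models were already correct, 16 planted genes had no model
at all, 10 were truncated below the 80% locus-coverage threshold, and 2
loci were hidden inside one fused model. After re-prediction the refined
annotation contains the 12 kept models plus 28 novel NLR models — all 40
planted genes, each with an exactly recovered CDS — and the
classification recovers the planted architecture mix:

```r
head(res$calls[, c("protein_id", "domain_string", "completeness", "nlr_class")], 3)
#>                protein_id     domain_string completeness nlr_class
#> 1 A01:116653-119138_g1.t1 TIR-NBARC-LRR-LRR         full       TNL
#> 2 A01:199031-201516_g1.t1 TIR-NBARC-LRR-LRR         full       TNL
#> 3 A01:227642-230127_g1.t1 TIR-NBARC-LRR-LRR         full       TNL
```

All intermediates land in `out_dir`: the depth bedGraph, ≥ 50× regions
(BED), predicted loci (BED), the reconciliation TSV, problem-region
FASTA, refined GFF3, proteins and NB-ARC domains (FASTA, the standard
input for NB-ARC phylogenies), architecture calls (TSV), the summary
(JSON) and a run manifest with config, checksums and per-stage counts.
Reruns with the same config and seed are byte-identical.

Capture-bait design for a target set uses the same package:
`replace_n_runs()` applies the N-replacement rule (N-runs of 1–10 nt
become Ts, longer runs split the target) and `tile_baits()` lays 80-nt
probes so every interior base is covered by exactly 3 probes.

## Scope

The package does not run BWA-MEM2, AUGUSTUS, InterProScan or IQ-TREE2
itself and does not build phylogenies; it consumes or produces their
standard interchange files through the adapters described above.
See `vignettes/nlrome-refinement.Rmd` for the methods account.
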