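# viranet

Comparative genomics of NAD⁺/ADP-ribose-network protein domains across viral
genomes, as a tested, reusable R pipeline.

Large surveys of the virus world repeatedly find that domains processing
NAD⁺ and ADP-ribose derivatives — Macro, NADAR, SLOG, Nudix,
ADP-ribosyltransferases (ART), ARG, the NAD⁺-salvage enzymes NadV/NadM,
sirtuins — concentrate in viruses with large genomes and intricate
life-history strategies, cluster into conserved gene neighborhoods (operons),
and co-occur more often than chance. viranet packages the computational
skeleton of such a survey for anyone who wants to run it on their own genome
collection or study its statistical behavior:

* **dataset I/O** — a genome collection as metadata TSV + GFF3 (CDS) +
  protein FASTA, with validation and taxid-based proteome de-duplication
  (one genome per taxid, keeping the largest proteome);
* **profile search** — position-specific scoring profiles from seed
  alignments; ungapped window scanning (C++ inner loops); empirical E-values
  calibrated on background decoys; iterative profile inclusion at
  E ≤ 0.01 with monotone growth of the included set;
* **clustering** — BLASTCLUST-style single linkage on bit-score density
  (bit = (λ·raw − ln K)/ln 2 over Smith–Waterman local alignments) with
  coverage criteria, plus evidence-based cluster merging (reciprocal best
  hits, shared annotations, shared genome context) with an audit log;
* **genome context** — domain architectures by greedy overlap resolution;
  gene neighborhoods bounded by a 100-nt inter-gene distance cutoff;
  conserved (anchor, partner) contexts filtered by support and distinct
  taxa; contextual-absence queries for counter-system prediction;
* **survey statistics** — genome-size prevalence curves, size-class
  fractions (small < 25 kb, medium 100–180 kb, jumbo ≥ 180 kb), per-1000
  morphology rates, Pearson χ² enrichment, pairwise co-occurrence under the
  fixed-margin hypergeometric null with Benjamini–Hochberg correction, and
  Euler-style exclusive set counts;
* **synthetic genomes** — a generator with planted ground truth
  (size-dependent carriage `logit p = a + b·log10 L`, morphology shifts,
  operon-structured gene layout, planted neighborhoods, latent-factor
  co-occurrence), so every stage is testable without downloading anything.

## Worked example

```r
library(viranet)

sim <- generate_collection(generator_config(n_genomes = 60, seed = 42))
sim$collection
#> Collection: 60 genomes, 2282 proteins
#>   na_class: dsDNA=36 dsRNA=1 ssDNA=8 ssRNA_neg=5 ssRNA_pos=10

prof <- builtin_profiles("Macro")$Macro
res <- iterative_search(prof, sim$collection, seed = 42)
head(res$hits, 3)
#>   protein_id ali_start ali_end    score     e_value iteration
#>  G00010_p012        75     134 361.5671 0.008333303         1
#>  G00018_p107         6      65 341.8592 0.008333303         1
#>  G00027_p073       119     178 360.0814 0.008333303         1
```

All 20 planted Macro segments are recovered (scores ≈ 340–360 half-bits sit
far above the background decoy maximum; the E-value 0.0083 is the empirical
floor `database_size/(n_decoys + 1)` at this calibration size). Genome-level
positives then stratify by size class:

```r
pos <- unique(sim$collection$proteins$genome_id[
  match(res$hits$protein_id, sim$collection$proteins$protein_id)])
class_prevalence(sim$collection$genomes, pos)
#>      class  n n_positive  fraction
#>      small 35          4 0.1142857
#>     medium  5          4 0.8000000
#>      jumbo  0          0        NA
#>  unclassed 20          8 0.4000000
```

— the planted size gradient (carriage rising with log genome length) is
visible even at 60 genomes: 11% of small genomes carry the domain versus 80%
of medium ones. `run_pipeline(pipeline_config(...), "rundir")` chains
simulate → dedup → scan → cluster → context → stats into one reproducible run
with a manifest of file digests; `inst/scripts/viranet.R` wraps the same
functions for shell use.

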