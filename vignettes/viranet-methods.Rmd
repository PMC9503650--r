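---
title: "Methods: surveying metabolite-network domains across viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying metabolite-network domains across viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

viranet implements a desk-scale version of the comparative-genomics procedure
used to map NAD^+^/ADP-ribose-network protein domains (Macro, NADAR, SLOG,
Nudix, ART, ARG, NadV, NadM, sirtuins, ...) across large collections of viral
genomes: de-duplicate proteomes, detect domain families with iterative
profile searches, group sequences into families, mine conserved gene
neighborhoods, and quantify prevalence, enrichment and co-occurrence. This
vignette explains the models and the numerical choices, and what the
synthetic benchmark does and does not establish.

## The data model and de-duplication

A collection is a genome metadata table (id, taxid, length, nucleic-acid
class, host superkingdom, phage morphology) plus a protein table (1-based
inclusive genomic coordinates, strand, amino-acid sequence). On disk this is
a TSV, a GFF3 restricted to CDS features, and a protein FASTA; reading after
writing is the identity on every field. Public viral genome sets contain many
near-identical entries per taxon, so `deduplicate_by_taxid()` keeps exactly
one genome per taxid — the one with the most CDS features. The tie-break
(larger genome, then lexicographically smallest id) is our own deterministic
rule; proteome size means CDS count, not residue count.

## Profile search

Domain detection uses position-specific scoring profiles built from seed
alignments. Columns with more than 50% gaps are dropped; per match column the
emission probability of residue $a$ is

$$ e_i(a) = \frac{c_i(a) + \tau\, b(a)}{n_i + \tau} $$

with observed counts $c_i$, background $b$ (fixed standard database residue
composition, so that calibration is stable), and pseudocount weight
$\tau = 1$ by default. Scores are half-bit log-odds
$s_i(a) = 2\log_2 (e_i(a)/b(a))$; unknown residues (X) score 0.

Scanning is an **ungapped sliding window**: the hit score is the maximum over
offsets of the summed per-column log-odds, so a hit span always has the
profile length. This is a deliberate simplification of gapped local profile
search: the surveyed procedure delegates detection to mature search tools,
and the property actually under test here — the iterative inclusion logic —
is independent of whether the per-protein score comes from a gapped or
ungapped alignment. The inner loops are in C++ with long-double accumulation
so R-side oracles agree bitwise.

Significance is empirical rather than Karlin–Altschul: `calibrate_null()`
scans `n_decoys` i.i.d. background proteins of a fixed length and sets

$$ E(s) = N_\mathrm{db}\,\frac{k(s) + 1}{n_\mathrm{decoys} + 1} $$

where $k(s)$ counts decoy best-scores at least $s$. The +1 smoothing keeps
E-values positive; with $n_\mathrm{decoys} = 1999$ the null probability of
$E \le N_\mathrm{db}\,q$ is exactly $q$ for $q \in \{0.001, 0.01, 0.1\}$,
which the test suite verifies on fresh decoys against a 99% binomial
interval. Decoy length defaults to the median database protein length; the
default decoy count adapts to
$\max(1999,\ \lceil 1.2\,N_\mathrm{db}/E_\mathrm{incl}\rceil)$ so that the
inclusion threshold sits above the resolution floor
$N_\mathrm{db}/(n_\mathrm{decoys}+1)$.

`iterative_search()` mirrors iterative profile-inclusion searching: scan all
proteins, include every hit with $E \le 0.01$ (the standard inclusion
threshold), add the matched ungapped segments to the alignment with uniform
weight, rebuild the profile, recalibrate, repeat. The included set only ever
grows, which guarantees termination within `max_iter` (default 5; iteration
counts per family are not standardized in practice, and five suffices for
every fixture here — non-convergence at the cap is flagged, not hidden).
Borderline hits with $0.01 < E \le 0.1$ are reported in a separate candidate
tier rather than being confirmed by reciprocal searches against an external
database, which a self-contained package cannot do.

## Clustering into families

`cluster_proteins()` re-implements the logic of classic bit-score-density
clustering (BLASTCLUST): Smith–Waterman local alignment with affine gaps
(BLOSUM62, gap open 11, extend 1), raw scores converted to bits with the
published gapped constants $\lambda = 0.267$, $K = 0.041$, an edge when
bit-score density (bits per aligned column, default $\ge 0.8$) and coverage
(default $\ge 0.6$ of **both** sequences; a "shorter"-sequence mode is
available) pass, and single-linkage connected components. The original
thresholds were set empirically per family and are unpublished, so ours are
defaults to be tuned per dataset — they are configuration, not constants.
Alignment itself is delegated to Biostrings; the package owns the edge
criterion, determinism (cluster ids ordered by smallest member), and the
merging layer.

`merge_clusters()` merges small clusters into larger ones on independent
evidence: (a) representatives that are reciprocal best hits at
$E \le 10^{-3}$ (search-space E-value $mn\,2^{-\mathrm{bit}}$), (b) at least
half of both clusters' members carrying the same profile annotation, or
(c) identical conserved-context signatures. Structure-based merging evidence
is out of scope. Every merge is recorded with its evidence class in an audit
log.

In the end-to-end pipeline, clustering operates on the matched domain
segments rather than whole proteins: multidomain fusion proteins would
otherwise chain unrelated families into a single single-linkage component.

## Gene neighborhoods and conserved contexts

A neighborhood is the run of genes around an anchor, up to five genes per
side, truncated at the first inter-gene gap over 100 nt — an operon proxy.
The gap between consecutive genes is `next.start − prev.end − 1` on 1-based
inclusive coordinates; overlapping genes give a negative value that is
treated as 0 and passes the filter. The 100-nt cutoff is applied to every
internal gap, not only the anchor-adjacent ones (the looser reading would
admit neighborhoods spanning operon boundaries). Anchors on the minus strand
are canonicalized by flipping member order and relative strands; the flip is
an involution, which the tests check.

`mine_contexts()` aggregates (anchor family, partner family) pairs over
neighborhoods and keeps pairs supported by at least `min_support = 3`
distinct genomes spanning at least `min_taxa = 2` distinct taxids. The taxid
requirement is our operationalization of filtering by "phyletic patterns" —
support concentrated in one clonal cluster is discounted; the original
criterion is not given as a formula. Orientation is called same-strand or
opposite when at least 80% of supporting instances agree (our threshold;
no standard value exists). `absence_query()` inverts the logic for
counter-system prediction: it reports loci where a target family (for
example a predicted deconjugase) has **no** genomically coupled member of a
partner set (for example ARTs or sirtuins), listing what is present instead.

## Survey statistics

* `prevalence_curve()`: fraction of genomes of length ≥ t carrying at least
  one network domain, per threshold — the size-dependence display, with
  landmark rises near 17.5 kb (RNA viruses) and 60 kb (DNA viruses) kept as
  configuration.
* `class_prevalence()`: per size class — small (< 25 kb), medium
  (100–180 kb), jumbo (≥ 180 kb). The 25–100 kb gap is reported as
  "unclassed" rather than silently absorbed, because the class definitions
  leave it undefined.
* `per_1000()`: carriage per 1000 genomes by phage morphology (myo-, sipho-,
  podovirus); genomes of unknown morphology are excluded from morphology
  analyses and counted separately.
* `enrichment_test()`: uncorrected Pearson chi-square on r×c tables, with a
  warning plus Fisher's exact p for 2×2 tables when an expected count drops
  below 5.
* `cooccurrence()`: per family pair, the 2×2 genome contingency, expected
  overlap $n_a n_b / N$, odds ratio, and one-sided hypergeometric p-values
  for enrichment and depletion. "Expected by chance" is operationalized as
  the fixed-margin hypergeometric null; Benjamini–Hochberg q-values are
  computed separately per direction (the choice of correction is ours).
  `euler_counts()` gives exclusive subset counts for up to four families.

## The synthetic generator

No accession list for the original GenBank snapshot is available, so the
package ships a generator whose defaults emulate the survey's qualitative
structure, with complete truth tables (per-genome families, per-protein
domain spans, planted adjacencies):

* **Carriage model.** Family $f$ is carried by a genome of length $L$ with
  probability $\mathrm{logit}^{-1}(a_f + b_f \log_{10} L + \delta_f\,
  \mathbb{1}[\text{myovirus}] + \rho z)$. Defaults place the per-family rise
  midpoints at 70–200 kb for DNA genomes (slope 2.7/decade) so that carriage
  of ≥ 1 family echoes the observed gradient (rare below 25 kb, ~70% around
  100–180 kb, higher still beyond), and at ~22 kb with slope 8 for the
  RNA-capable families (Macro, NADAR, Nudix), echoing the sharp RNA-virus
  rise near 17.5 kb. ART carries a +1.5 log-odds myovirus shift. The shared
  standard-normal $z$ per genome with $\rho = 0.8$ induces the positive
  pairwise co-occurrence of Macro/NADAR/SLOG/Nudix. A step model with fixed
  per-size-class probabilities replaces the logistic for calibration
  experiments.
* **Genome layout.** Gene lengths are gamma (shape 4, scale 75 codons,
  minimum 80); gaps are 0–60 nt within operons and 150–500 nt between them,
  with operon breaks at probability 0.25 and one strand per operon. These
  are chosen as typical phage gene/operon scales, not fitted values.
* **Domain emission.** A carried family contributes its 60-residue synthetic
  consensus mutated to `identity_target` (default 0.9; replacements drawn
  from background excluding the original residue, so expected identity equals
  the target), spliced into a background protein. Scanner recall is thereby a
  controlled function of identity. The seed alignments are synthetic:
  deterministic functions of the family name, carrying no biological signal.
* **Contexts and polyproteins.** Planted anchor/partner pairs (for example
  NADAR–NadM, NadM–NadV, terminase-adjacent ART) are inserted as adjacent
  same-strand genes with gaps ≤ 60 nt, in DNA genomes only; RNA-class genomes
  instead stack their carried domains into one polyprotein-style gene. Both
  choices mirror how the surveyed domains occur — phage operons versus RNA
  viral polyproteins — and keep adjacency truth meaningful.
* **Determinism.** One seed drives everything; equal seeds give byte-identical
  TSV/GFF3/FASTA output. The pipeline fans a single global seed out to
  per-stage substreams so stages can be re-run independently.

What passing tests on this generator **do not** show: performance on real
annotation noise (frameshifts, missed ORFs, contaminant contigs), real
sequence divergence structure (synthetic families are i.i.d.-background
consensi, far easier to separate than real superfamilies), taxon sampling
bias, or the original survey's actual percentages, which depend on a
database snapshot that was never deposited.

## Problem sizes and numerical choices

The test suite and acceptance script run the statistics at deliberately
modest sizes chosen as the package's own benchmark conditions: 1000–5000
decoys per calibration check, 1200 genomes × 100 seeds for class-prevalence
recovery, 900 genomes × 1000 replicates for the chi-square type-I rate,
300 genomes × 20 seeds for context mining, and a 120-genome end-to-end
determinism run.

The context-mining benchmark deserves its own note. Pair-support counting is
detection, not inference: any family pair whose incidental same-operon rate
λ approaches the support floor will be reported. Under the default survey
configuration, a near-universal anchor family (terminase is present in
virtually every tailed phage) accumulates incidental adjacencies with every
other family well past support 5 across 300 genomes — which is exactly why
the real procedure pairs neighborhood counts with phyletic filtering and
curation. The benchmark therefore gives every family a flat 10% carriage
(no size, morphology or co-occurrence structure). With ~4-gene operons the
chance that two random annotated genes share a neighborhood is ≈ 15%, and
context planting inflates partner families' carriage by up to 60%, so the
incidental pair-support rate is λ ≈ 0.2–0.5 per pair — safely below the
`min_support = 5` floor — while planted contexts reach support ≈ 13. Truth
is the per-genome transitive
closure of planted adjacencies (a chained anchor–partner–partner neighborhood
plants all three pairwise associations), compared as unordered family pairs
pooled over seeds.
Degenerate inputs are defined, not special-cased: empty collections
round-trip, genomes with zero proteins keep their metadata row, proteins
shorter than a profile score −∞, and contingency tables with a zero margin
are an error rather than a silent NaN.

Known limitations: ungapped scanning misses domains split by long insertions;
empirical E-values are exchangeable-null estimates, so their resolution is
bounded by the decoy count; all-vs-all clustering is quadratic and meant for
thousands, not millions, of sequences; and the phyletic filter reduces to a
taxid count, which under-filters datasets whose taxids are all distinct.
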