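---
title: "Methods: k-mer presence/absence population genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer presence/absence population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions they rest on, the tunable parameters that
matter, and the choices made where the design was genuinely open. The
numerical claims made here are exactly those computed by the test suite and
`scripts/acceptance.R`; nothing beyond what those scripts verify is
asserted.

## The pipeline in one paragraph

A panel of diploid accessions (wild relatives of a crop, in the motivating
use case a three-lineage *Aegilops tauschii* panel) is reduced to a binary
matrix: one row per canonical 51-mer, one column per accession, entry 1 if
the accession's sequence data contains the k-mer. Everything downstream
consumes that matrix or the companion SNP genotype matrix: redundancy QC by
identity-by-state, a UPGMA phylogeny with bootstrap supports, PCA,
three-set Venn partition of the k-mer space by lineage, sliding-window
Weir–Cockerham F~ST~, LD decay, correlation-prefiltered association mapping
with a nested-model likelihood-ratio test, anchoring of de novo scaffolds to
a reference by their longest alignment hit, and painting of a hexaploid-like
chromosome in 100-kb windows by lineage-specific k-mer content.

## Canonical k-mers and the presence/absence matrix

k-mers are counted on canonical forms: the lexicographic minimum of the
k-mer and its reverse complement. The upstream counting tool used for the
original data operates on reads from both strands, and presence calls must
not depend on which strand an assembly happens to report, so
strand-collapsed counting is the only defensible default; `k` is required
odd so no k-mer is its own reverse complement. Internally k-mers are
2-bit-packed 128-bit integers whose numeric order equals the string order,
so matrix row order is reproducible across routes.

Two filters define matrix membership:

* **Within accession:** k-mers with multiplicity below `min_count`
  (default 2) are discarded immediately. This is an error filter for
  raw-read input; on assembled or simulated consensus sequences every
  genomic k-mer occurs once, so `min_count = 1` is the correct setting
  there (the coverage-robustness test exercises exactly this distinction).
* **Across the panel:** rows with occupancy below 2 or equal to n − 1 are
  removed, per the stated construction rule. The rule leaves occupancy = n
  unstated; such rows are removed here too, because a constant row carries
  no information for any downstream stage and breaks the Pearson prefilter
  (zero variance). This is the single deliberate extension of the printed
  rule, and it is what makes "an all-identical panel yields an empty
  matrix" a testable property.

k-mers spanning a non-ACGT character are skipped and counted, never fatal:
real read sets contain Ns and a pipeline that throws on them is unusable.

## The synthetic panel: what it emulates, and what it does not

Every stage is tested against generated panels with a complete truth
ledger. The generator's world:

* **Three-level star phylogeny.** One random ancestor; lineage founders
  derived by independent per-base substitution at `divergence` (default
  0.01); *subpopulation* founders within each lineage at `sub_divergence`
  (default `divergence/3`); accessions descend from subpopulation founders.
  Substitution is the only mutation type, so ancestor, donor and accession
  coordinates coincide and the genotype truth is exact by construction.
* **Shared segregating variation.** `within_diversity` (default 0.005) is
  the per-base probability that a position segregates within a lineage; the
  derived allele's carrier count is drawn from the neutral 1/i frequency
  spectrum and carriers are a uniform subset. Two earlier, simpler designs
  were rejected after measurement, and the reasoning matters: with only
  accession-private mutations (no shared polymorphism), the post-filter
  k-mer space contains nothing but lineage axes and the planted causal
  block — at the scale of the end-to-end test the causal block literally
  became the panel's second principal component (|r| = 0.99 with the
  carrier indicator) and the PCA covariates absorbed the signal they are
  meant to leave alone. Shared polymorphism plus subpopulation structure
  restores the property every real diversity panel has: the top principal
  axes are genome-wide structure, not any single locus. A 2-lineage panel
  with 2 subpopulations each has exactly three strong structure axes,
  matching the default 3 PCA covariates.
* **Biallelic sites.** Each position has one predetermined alternative
  allele; every substitution event at that position produces it. This
  guarantees biallelic truth sites (the genotype container's invariant)
  at the cost of ignoring triallelic sites, which the QC stage would skip
  anyway.
* **Causal haplotype.** The configured interval of the ancestor is mutated
  at `sub_rate` (default 0.01) and written verbatim into every carrier,
  replacing whatever variation the carrier had there. Carriers therefore
  share the haplotype as an exact substring (string-search testable) and
  non-carriers cannot contain it. Carriers are drawn *stratified by
  subpopulation* at the configured fraction, so the planted variant is
  unconfounded with structure by construction; with a simple random draw,
  sampling fluctuation at n = 60 can correlate the carrier set with a
  subpopulation axis strongly enough that the phenotype effect leaks into
  structure-patterned k-mers genome-wide. Structure-confounded signal is a
  separate, deliberate scenario driven by `lineage_shift` in the phenotype
  model (and tested as such).
* **Diploidy as overlay.** Each accession is one consensus sequence; a
  `het_fraction` of genotype calls are flipped to heterozygous in the
  truth matrix only. k-mer stages consume one sequence set per accession,
  which mirrors how consensus assemblies and reads are used in practice;
  heterozygosity matters only to the QC stage, which reads the matrix.
* **Reads.** `shred_reads` emits error-free uniform reads at a target
  coverage (an optional substitution rate exists for exercising the
  `min_count` filter). No quality strings, no indels, no coverage bias.

What a green test therefore establishes: the *computations* are correct on
a panel whose statistical skeleton (differentiated lineages, hierarchical
substructure, segregating diversity, a planted causal locus) matches the
motivating study's world at desk scale. What it does not establish:
behavior under sequencing error models, indels and structural variation,
reference bias, demographic realism (migration, selection, recombination
graphs), or gigabase genome scale.

## Quality control

Pairwise identity-by-state uses up to 100 SNPs per 4-Mb window, sampled
uniformly per window (windows with fewer sites contribute all of them).
Identity of a pair is the percentage of co-called sites with identical
call states; heterozygous is its own state, the conservative reading of
comparing called genotypes, and sites missing in either member leave the
denominator so missingness cannot inflate identity. Pairs above 99.5%
identity are redundant; the redundancy graph's connected components each
retain exactly one accession. The retained representative is the member
with the fewest missing calls (ties: lexicographic id) — the original
procedure does not state its choice, so the deterministic, data-preserving
rule is used. Accessions whose heterozygous fraction of biallelic calls
exceeds 0.1 are dropped as residually heterogeneous before redundancy
resolution.

## Population structure

* **Distance.** Hamming proportion on presence/absence columns. The
  original tree is described only as built from k-mer presence/absence;
  Hamming is the simplest metric consistent with that, and Jaccard is
  available behind a flag for panels where shared absence is uninformative.
* **UPGMA.** Size-weighted average-linkage agglomeration; node height is
  half the merge distance, so trees are ultrametric by construction (and
  tested to be). Tied merges pick the lexicographically smallest
  accession-id pair — determinism is worth more than any particular tie
  outcome. The independent oracle in the tests is `hclust(method =
  "average")`.
* **Bootstraps.** Rows resampled with replacement; a node's support is the
  percentage of replicate trees containing its clade (default 100
  replicates).
* **PCA.** Column-centered presence decomposed by `prcomp` on a
  fixed-seed 100,000-row sample; each component's largest-magnitude
  loading is made positive so scores are reproducible.
* **F~ST~.** Weir & Cockerham (1984) per-site variance components a, b, c;
  windows (default 1 Mb, step 100 kb) report both the ratio-of-sums
  ("weighted") estimator — matching the windowed weighted output of the
  VCF tooling named in the original methods — and the mean of per-site
  ratios for transparency. Monomorphic sites contribute nothing to either.
* **LD.** Composite r² from 0/1/2 dosages (phase is never produced by this
  pipeline, and composite LD is standard for predominantly selfing,
  homozygous panels), binned by distance up to 5 Mb; the decay distance is
  the midpoint of the first bin whose mean r² drops below 0.1. Dense
  chromosomes are thinned to a site cap before pairing to bound the
  O(sites²) cost; the cap and seed are exposed.

## Association core

The prefilter computes each row's Pearson correlation with the phenotype
and keeps |r| strictly above the threshold (default 0.2). It is a
computational sieve, not a test; its soundness on unstructured panels
(every causal k-mer passes when effect/noise ≥ 2 and carrier frequency is
in [0.2, 0.8]) is a tested property.

The association score is −log10 of the p-value of a likelihood-ratio test
between nested Gaussian linear models: null = intercept + leading PCA
scores (default 3), full = null + the k-mer's presence indicator. With the
variance profiled out the statistic is n·ln(RSS₀/RSS₁), compared to χ²₁.
Numerical policy: p below 1e−300 is reported as score 300 (perfect
separation would otherwise produce −log10(0)); a presence vector collinear
with the covariates scores 0 with a degeneracy flag rather than a spurious
large value. Null calibration (KS uniformity of p-values over permuted
phenotypes) is part of the acceptance suite. Accessions with missing
phenotype are dropped pairwise per run and the PCA covariates are
recomputed on the retained accession set, keeping covariates aligned with
the tested sample.

The multiple-testing threshold divides the total number of tested k-mers
by k (a single substitution alters k overlapping k-mers — the brute-force
window count in the acceptance suite verifies exactly 51 for k = 51)
to get an effective variant count, then applies Bonferroni:
−log10(α / (N/k)). For N = 5×10⁹ and 3×10⁹ at α = 0.05 this rounds to 9.3
and 9.1; comparisons use the raw value, rounding is for reporting.

Placement is exact canonical match of each candidate k-mer on a target
sequence set (reference chromosomes, or a relevant accession's assembly —
the latter is what makes presence-positive haplotype k-mers mappable at
all, since they are absent from the reference by construction). Plot
coordinates: blocks are 0-based half-open `[x·B, (x+1)·B)` internally with
B = 10 kb, emitted 1-based; a k-mer at 1-based position p belongs to block
`(p − 1) div B`. In anchored mode the x axis is the scaffold order by
anchor position. Records above the report floor (default 6) are aggregated
per (block, score rounded to one decimal, direction) with a k-mer count
per dot.

## Anchoring

Per scaffold, the alignment record with the largest block length (PAF
column 11) wins and donates its target start as the anchor — the literal
reading of ordering by "longest hits"; mapping quality is ignored because
it is aligner-specific. Ties break by target name then target start, making
the result invariant to record order (a tested property). Scaffolds with no
hits are unplaced, excluded from plots with a logged count, never an error.
The built-in exact-match seed-and-extend aligner exists so tests and
synthetic pipelines need no external aligner; real assemblies should be
aligned externally and loaded as PAF.

## Lineage painting

A k-mer of the target subgenome is *usable* when it occurs at exactly one
locus across the designated chromosomes (computed over the subgenome only),
optionally intersected with the union of landrace k-mer sets to mask recent
alien introgressions. Each 100-kb window is assigned by the stated
thresholds against the nominal 100,000 k-mers per window: below 20%
usable-and-panel-present k-mers → unassigned; otherwise the lineage whose
specific count exceeds every other lineage's by at least 10 (0.01% of
100,000) wins, else the window stays unresolved. A window's k-mers are
those whose forward-strand window starts inside it, so each k-mer counts
exactly once. Trailing partial windows get thresholds scaled by their
actual window count and a `partial` flag — the alternative (evaluating
them against full-window thresholds) would systematically unassign every
chromosome end.

## Open questions, resolved

* Whether the original counting ran strand-canonically is not stated;
  canonical counting is adopted as a documented decision (see above).
* The UPGMA distance metric is not stated; Hamming is the default,
  Jaccard a flag.
* Whether prefilter and regression use identical accession subsets under
  missing phenotypes is not stated; pairwise-complete handling with
  recomputed covariates is the documented choice.
* The 20% usable floor's conjunctive reading ("usable as well as present")
  is implemented: the floor applies to k-mers that are both usable and
  present in at least one panel accession.
* The generator makes no attempt to match any particular site-frequency
  spectrum beyond the neutral 1/i shape of within-lineage variants.

## Known limitations

Desk-scale by design: dense matrices (raw storage, one byte per cell) and
in-memory counting cap practical panels at tens of accessions times a few
megabases — the regime every test and the acceptance report run in. No
external-memory counting, no probabilistic sketches, no mixed-model GWAS,
no binary-trait variant, no gap-tolerant internal alignment, and no
inference about hybridization timing from painting output.
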