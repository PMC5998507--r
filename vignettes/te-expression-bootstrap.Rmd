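---
title: "Weighted bootstrap analysis of TE-associated gene expression"
author: "teboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted bootstrap analysis of TE-associated gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teboot)
```

## The question and the estimator

Transposable elements (TEs) carry regulatory sequence, so an insertion in or
near a gene can change that gene's expression.  Testing this association
genome-wide is confounded twice over: almost every gene contains TEs of
several classes at once, so genes carrying a focal element differ from the
rest in their whole TE composition, and TE content correlates with gene
length.  `teboot` implements a matched weighted bootstrap that addresses
both.

Insertions are classified by age from their percent identity to the
consensus: recent, species-specific insertions (*ss*) at identity >= 94
(boundary inclusive), older non-species-specific insertions (*ns*) below.
Genes are flanked by 1 kb on both sides and intersected with the TE
annotation under 0-based half-open semantics (>= 1 bp shared counts as
overlap), giving each gene a profile of counts per (class, age) element over
the four classes DNA, ERV/LTR, LINE and SINE.  For a focal element, the
*test pool* is all genes carrying it and the *reference pool* all genes
lacking it (which may carry other classes, the same class at the other age,
or no TE at all; genes carrying the focal class at both ages sit in the test
pool — they do contain the focal element — and their count is reported for
sensitivity checks).

Each bootstrap iteration draws `n = min(1000, pool sizes)` genes uniformly
with replacement from the test pool and the same number from the reference
pool with matching weights (below).  Two statistics are computed per
iteration:

* the difference in median log2(TPM), after omitting genes with zero TPM
  from each set (TPM = transcripts per million);
* the difference in the proportions of genes detected as expressed
  (TPM > 0 by default), computed on all sampled genes including zeros.

Over `B = 5000` iterations this yields, per statistic, a point estimate
(mean of the iteration statistics; the median is reported alongside), a
percentile confidence interval, and a two-sided p-value from the level at
which the interval first touches zero, with an add-one continuity
correction so p is never 0.  Pools below 600 genes are skipped rather than
tested.

## Matching weights

Test genes are sampled uniformly.  A reference gene in stratum *s* gets
weight proportional to `f_test(s) / f_ref(s)`, the ratio of the stratum's
frequency in the test pool to its frequency in the reference pool, so that
the weighted reference draw reproduces the test pool's stratum distribution
in expectation.  A stratum is the set of *co-occurring TE classes other
than the focal class*, crossed with the gene's length bin (gene lengths,
flanks excluded, are split into 10 equal-frequency bins within the gene
universe under analysis, ties broken by stable gene-ID order).  Classes
rather than (class, age) elements define the stratum: with four classes and
ten bins there are at most 80 strata, so the frequency ratios stay
estimable; a stratum over the eight class-age elements would fragment into
hundreds of near-empty cells whose noisy ratios concentrate the weights and
collapse the effective reference sample size.  Strata present in the test
pool but absent from the reference pool cannot be matched; their mass is
dropped from the target distribution with a recorded warning, and the
effective reference size `1 / sum(w^2)` is attached to the weights as a
diagnostic.

A calibration caveat follows directly from the construction: the percentile
interval reflects resampling noise at the drawn set size `n`, while the
pools themselves are finite.  The test side is safe because `n` never
exceeds the test pool.  On the reference side the relevant quantity is the
effective size under the weights; when it falls well below `n`, intervals
become anticonservative.  The weights diagnostic makes this visible, and
the synthetic study conditions below were chosen so the precondition holds.

## Family-wise error control and FDR

A family is one (species, gene universe, age group) analysis: `m = n_tissues
x n_classes` tests (24 for six tissues and four classes).  Confidence
intervals are taken at level `1 - alpha/m` with `alpha = 0.05`, so declaring
a comparison significant when its CI excludes zero controls the family-wise
error rate at `alpha`.  The family is counted over tests, not statistics;
the proportion-expressed statistic forms its own family.  Benjamini-Hochberg
FDR across all p-values of a fit (per statistic) is reported as a secondary
significance flag.

## What the synthetic generator emulates

The generator (`simulation_config()` / `simulate_te_dataset()`) stands in
for the real inputs — genome annotations, repeat calls with per-insertion
identity, and multi-species TPM tables — and plants known effects so every
downstream stage is testable.  Its defaults are the package's study
conditions:

* **Genes**: log-normal lengths (meanlog 9.5, sdlog 1.2, i.e. a ~13 kb
  median with a broad spread), placed without overlap on 5 chromosomes;
  lengths, baselines and tissue effects are shared across species so
  ortholog groups behave like orthologs.
* **TE landscape**: per-gene class counts are Poisson with expected
  insertions per gene of DNA 1.5, ERV/LTR 2, LINE 3, SINE 3, scaled by a
  shared gamma frailty (dispersion 1.5) and by the square root of relative
  gene length.  The frailty makes class counts positively correlated within
  a gene, reproducing the empirical situation in which most genes carry
  several TE classes, genes with a single TE are a minority and TE-free
  genes are rare; the tempered length scaling makes long genes TE-richer
  without making composition a near-deterministic function of length.
  A fraction `ss_fraction = 0.3` of insertions draws identity uniformly
  from [94, 100], the rest from [50, 94).  Insertions are placed uniformly
  within the gene extent plus 1 kb flanks, with a 5 percent intergenic
  background.
* **Expression**: log2(TPM) is baseline N(3, 2) per gene, plus per-(gene,
  tissue) effects (sd 1) shared across species, per-(gene, species) effects
  (sd 0.5) and sample noise (sd 0.5); the tissue term dominating the
  species term reproduces tissue-led sample clustering.  A gene is
  unexpressed (exact TPM = 0) with probability 0.1 per sample, giving the
  zero-omission filter genuine zeros to act on.  Planted effects add a
  configured delta to log2(TPM) for every gene whose profile contains the
  targeted (class, age) element, in the targeted (species, tissue) sample
  only; carrier status is determined by the same flank/intersect/classify
  code used in analysis, so the returned truth table is exact.
* **Rounding**: TPM is rounded to 3 decimals and identity to 2 at
  generation, so all tables round-trip bit-exactly through the TSV
  writers/readers.

Features of real data the generator does not emulate: sequence content,
nested or fragmented insertions, positional effects within the gene (the
analysis uses presence/absence only), library-size artefacts, batch
structure across studies, and correlated dropout.  Passing tests therefore
demonstrate the statistical machinery — matching, calibration, error
control, recovery — under a clean generative model, not robustness to
real-data artefacts.

## Numerical and design choices

* Internal coordinates are uniformly 0-based half-open; GFF3/GTF converters
  handle the 1-based inclusive representation, and flanks are symmetric and
  strand-agnostic (1 kb each side makes the strand reading immaterial).
* Percentile CIs use type-7 quantiles (linear interpolation between order
  statistics).  With fewer than `2m/alpha` iterations the tail quantiles are
  unresolvable and the interval falls back to the sample range with a
  warning.
* "Median difference" is the difference of per-set medians (the sets are
  unpaired).  Iterations in which one set has no expressed gene yield a
  missing median difference and are excluded from that statistic's CI, with
  the used count reported.
* Sampling is with replacement (a true bootstrap); without-replacement
  draws are available for sensitivity analyses via the pure-R engine.
* The bootstrap inner loop runs in compiled code using R's RNG; a pure-R
  engine mirrors it draw for draw and is asserted identical under the same
  seed, so results are reproducible and engine-independent.
* Clustering operates on log2(TPM + 1) — the pseudocount keeps unexpressed
  genes in the sample vectors, unlike the bootstrap statistic which omits
  zeros — with Euclidean distance by default and 1 − Spearman correlation
  as an option, UPGMA cut at k = 5 and Ward.D2 cut at k = 7 by default, and
  per-gene-centred PCA.
* Degenerate inputs: all-equal gene lengths collapse to one length bin with
  a warning; empty pools or pools under the 600-gene floor produce skipped
  results (grey heatmap cells), never errors; constant expression matrices
  give zero-variance PCA.

## Problem sizes used in the checks

The packaged checks run the full chain at desk scale: null calibration uses
200 simulated datasets of 3000 genes with 24 tests each at B = 1000;
effect recovery uses 100 replicates per planted shift (−0.5 and +1.0 on
log2 TPM) at the same size; the matching property is verified on a
20-stratum instance at B = 5000; intersection, BH and quantile routines are
compared against brute-force oracles at 10^3-scale.  B = 5000 remains the
analysis default.

## Limitations

Association, not causation: planted-effect recovery shows the estimator
works when the generative assumptions hold; in real data, unmodelled
confounders correlated with TE presence (GC content, chromatin context,
recombination) are not adjusted for.  The matching scheme balances
co-occurring TE classes and length only.  Comparisons whose test pool is
small are skipped entirely rather than tested at reduced power, and the
percentile interval's calibration degrades if the weights concentrate
(watch the `n_effective` diagnostic).
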