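---
title: "Detecting miRNA-target antagonism patterns in paired expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA-target antagonism patterns in paired expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirantag)
```

## The antagonism pattern

MicroRNAs silence genes post-transcriptionally. When a miRNA actively
degrades a target mRNA, the pair's joint expression across samples often does
not look linearly anti-correlated: other regulators, copy-number changes and
noise modulate the mRNA, so the only robust signature is an *exclusion* — the
high-miRNA/high-mRNA corner of the scatter is depleted, leaving a
triangular-shaped cloud. `mirantag` scores exactly this signature. It is a
non-linear measure of dependence tailored to small clinical cohorts (tens of
samples), where mutual-information estimators are unreliable and Pearson
correlation misses the triangular shape.

## The statistic

Expression of each feature is z-scored across samples (sample mean, $n-1$
standard deviation) so miRNA and mRNA intensities from different platforms
are comparable. For a pair with z-scores $(x_i, y_i)$, $i = 1..N$, and an
anti-diagonal line $x + y = b$, let

$$F_{\mathrm{obs}}(b) = \frac{1}{N}\,\#\{\,i : x_i + y_i < b\,\}$$

be the fraction of samples strictly below the line — the empirical CDF of the
sums. Let $\bar F_{\mathrm{null}}(b)$ be the mean of the same quantity over
$S$ random re-pairings of $y$ against $x$ (default $S = 100$): the value
multisets are preserved but the association is destroyed. The antagonism
coefficient is the one-sided Kolmogorov–Smirnov-type supremum

$$A = \max_b\,\bigl[F_{\mathrm{obs}}(b) - \bar F_{\mathrm{null}}(b)\bigr],$$

with $b^\*$ the maximizing intercept. A triangular cloud concentrates
observed sums at low values relative to random re-pairings, producing a large
$A$. Significance is assessed by a permutation test: the coefficient is
recomputed for $M$ random re-pairings (default $M = 1000$), each with its own
fresh shuffle null, and

$$PV = \frac{1 + \#\{\,m : A_m \ge A\,\}}{1 + M}.$$

Across all miRNA × gene pairs, p-values are Benjamini–Hochberg adjusted and
edges retained at an FDR threshold (default 2%).

### Numerical and design choices

* **One-sided statistic.** The biological signal is a *depletion* of high
  sums (the high/high corner), so only positive excesses of
  $F_{\mathrm{obs}}$ over the null are scored. The maximum is never negative:
  at the largest observed sum both CDFs equal 1.
* **Exhaustive intercept search, exactly.** $F_{\mathrm{obs}} - \bar
  F_{\mathrm{null}}$ is a difference of step functions. Between observed
  breakpoints $F_{\mathrm{obs}}$ is flat and $\bar F_{\mathrm{null}}$ is
  non-decreasing, so the supremum over all real $b$ is attained just above an
  *observed* sum; the implementation evaluates exactly those candidates (ties
  resolve to the smallest $b$). Tests verify exact equality with a
  brute-force search over the union of all observed and null breakpoints.
* **Null re-pairings.** Each shuffle draws one uniform permutation
  (unbiased Fisher–Yates) and re-pairs $y$ against $x$. Shuffling both
  vectors, as one may equally describe the null, composes two permutations
  into one uniform permutation — the same null distribution at twice the RNG
  cost — so one draw is used.
* **Strict inequality, ties toward "not below".** The count uses
  $x_i + y_i < b$, making $F_{\mathrm{obs}}$ a proper left-continuous CDF of
  the sums.
* **Add-one smoothing.** The permutation p-value uses $(1+r)/(1+M)$ rather
  than $r/M$. Zero p-values would break BH adjustment downstream; the price
  is a floor of $1/(M+1)$, which also makes "FDR threshold 0 yields no
  edges" an exact invariant.
* **Degenerate inputs.** Constant expression vectors cannot be z-scored;
  they are rejected in `zscore()` and dropped (with a message) before a
  scan. Pairs need at least 3 samples.
* **Reproducibility.** All permutation draws replicate base R's
  `sample.int()` stream exactly, so any C++ result can be replayed in plain
  R. Scans derive one RNG substream per pair from `(seed, row, column)` via
  `derive_seed()`; results are independent of evaluation order and any
  single pair can be recomputed in isolation. The scan is serial — with
  per-pair substreams this already guarantees the "identical to serial"
  contract a parallel implementation would have to meet, and the package
  targets single-CPU batch use.

## The synthetic-data generator

`simulate_pair(n, noise_fraction, seed)` draws `n - round(noise_fraction *
n)` "signal" points uniformly from the triangle $\{x, y \ge 0,\; x + y \le
1\}$ and the remaining points uniformly from the complementary triangle
$\{x + y > 1,\; x, y \le 1\}$, by rejection from the unit square (exactly
uniform, no transform subtleties). The noise *count* is fixed per dataset,
not Bernoulli per point, so the stated fraction holds exactly in every draw.
`null_mode = TRUE` draws uniformly on the whole square, destroying the
pattern — used to calibrate the null distribution of p-values.

Simulated pairs are z-scored before scoring, the same transform applied to
real data, so the benchmark exercises the identical scoring pathway.

What the generator does *not* emulate: platform-specific noise (additive
Gaussian measurement error, batch effects), heavy-tailed expression
distributions, or correlated backgrounds. Passing benchmarks therefore
demonstrate the detector's operating characteristic on the idealized
triangular geometry, not its false-discovery behaviour on any particular
array platform.

A structural property worth knowing: at `noise_fraction = 0.5` the two
triangles carry equal uniform mass, which *is* the uniform distribution on
the unit square — x and y are then exactly independent, and the mean of any
valid permutation p-value is close to 1/2. Mean p-values at 50% noise should
be read as "no signal", not as partial detection.

## Power benchmark

`run_benchmark()` maps mean permutation p-value over a (sample size × noise)
grid. With 200 datasets per cell, 500 permutation rounds and 100 null
shuffles (the sizes used by the package's acceptance tests and
`scripts/acceptance.R`), clean triangular data are detected (mean p ≤ 0.05)
from roughly 50 samples upward at 10% noise, while 20 samples never reach
significance at any noise level; the mean p-value is monotone in both grid
directions up to Monte-Carlo error. Each cell consumes RNG substreams
derived from `(seed, cell, replicate)`; a failed replicate marks its cell
`NA` rather than being silently averaged.

The planted-recovery suite embeds one clean triangular pair (n = 60) among
29 independent Gaussian pairs and requires it to rank first. Ranking a field
of 30 needs p-value resolution finer than the field size — with $M$ rounds
the p-value floor is $1/(M+1)$ and coarse grids produce floor ties — so
recovery is scored at $M = 500$ with ties broken by coefficient magnitude
and then lexicographically by pair id.

## Correlation baseline

`loo_corrected_pearson()` implements the comparison method: the Pearson
coefficient is recomputed $n$ times leaving out one sample; a sample whose
removal shifts the coefficient by at least twice the standard deviation of
the leave-one-out replicates from their mean is an outlier; the coefficient
is recomputed once (no iteration) on the remaining samples, with the
two-sided t-transform p-value at the effective $n$. Spread below $10^{-12}$
(perfectly linear data) flags nothing; if every sample were flagged the
correction refuses and returns the raw coefficient with a flag. Both a raw
p-value threshold and an FDR cutoff are exposed, since network-size matching
between methods may be done either way; the negative-correlation component
is selectable for comparison with silencing-type links.

## Network and hubs

Edges are pairs with BH q-value at or below the threshold. Connectivity is
plain degree; miRNA hubs and target hubs are called separately against a
network rebuilt by the *same* pipeline on sample-shuffled expression
(`shuffle_samples()` permutes the mRNA matrix's sample assignment). The hub
cutoff default is 0.75 × the maximal connectivity of the randomized network
("max75"): of the two readings of a "75th percentile of the maximal value"
rule, this is the one in which the maximal value is not vacuous; the
alternative — the 75th percentile of the randomized connectivity
distribution — is available as `rule = "percentile75"`. Ranked method
comparison uses cumulative-hit curves against a validated-interaction list,
merging methods by best rank per pair.

## Seed enrichment

From each mature miRNA's first eight 5' nucleotides, all contiguous 6-, 7-
and 8-mer windows are reverse-complemented into DNA-alphabet match strings
(at most 3, 2 and 1 distinct strings). Occurrences in predicted targets'
3'UTRs are counted with overlaps (sliding window, step 1) and summed raw
over all predicted pairs. The default seed region starts at position 1;
`offset = 1` shifts to positions 2–9 for the canonical convention that
discounts the first nucleotide. The null permutes the miRNA labels across
the edge list — preserving every UTR (hence composition and length) and each
miRNA's link count — and the observed count is referred to a normal with the
shuffled counts' mean and SD, one-sided. When all miRNAs share a seed the
statistic is permutation-invariant (SD 0); this is reported as degenerate
and non-significant rather than as a division error. Genes with several UTR
isoforms contribute their longest.

## Gene-set validation

Per-miRNA target sets are tested per category with the upper-tail
hypergeometric test. The universe is the set of genes that entered the scan
(not the genome): enrichment is claimed relative to what the method could
have predicted. No multiple-testing correction is applied inside the GO
scoring by default — the negative control is structural instead: target
labels are permuted (miRNA degrees preserved) and the fraction of
category tests reaching the real-data threshold is reported, which should
collapse to the chance level. The default significance threshold is 0.001
(configurable). GO-graph propagation to ancestor terms is deliberately not
performed. Target sets can additionally be intersected with seed evidence
(`combined_target_sets()`), keeping only predicted targets whose UTR carries
at least one seed match for the predicting miRNA.

## Data filtering and I/O

Expression TSVs (feature id column, sample header) are validated cell by
cell; duplicate feature ids collapse by mean with a warning; rows with
missing values are dropped with a message. The variance filter keeps
features whose across-sample IQR *strictly* exceeds the median IQR of all
features — strictness makes the rule deterministic under ties — with an
optional low-abundance median-quantile floor (the platform-specific
detection-p-value filter of array pipelines is out of scope).
`run_full_pipeline()` chains filter → scan → BH → network → hubs → optional
seed and gene-set stages, writes a JSON manifest (seed, parameters, version,
per-stage counts), aborts naming the failed stage, and removes partial
outputs. All randomness flows from one master seed through named substreams
recorded in the manifest; reruns are byte-identical. A thin command-line
wrapper with verbs `simulate`, `benchmark`, `detect`, `correlate`,
`network`, `seeds`, `enrich` and `run` ships in `inst/cli/mirantag.R`.

## Problem sizes used by the test suite

The package's acceptance-style checks use: 200 datasets per benchmark cell
with 500 permutation rounds and 100 null shuffles; 200 replicates for type-I
error and p-value-uniformity checks (M = 200 and 100 respectively, 50 null
shuffles); 100 repetitions of the 30-pair planted-recovery scan at M = 500;
exhaustive brute-force oracles at n ≤ 12. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances (e.g. ±0.03
around a 0.05 rejection rate).

## Known limitations

* The statistic detects association, not causality: indirect regulation and
  co-regulation produce the same triangular signature.
* Power is modest below ~40 samples by construction of the permutation test;
  this matches the detector's intended use on cohort-scale data.
* The shuffle-null and permutation loops make the scan O(miRNAs × genes ×
  M × S × n); genome-scale scans are batch jobs, not interactive calls.
* Seed counting treats all UTR positions equally; no context scoring,
  conservation or thermodynamics.
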