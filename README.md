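# mirantag

Inference of microRNA–target interactions from paired miRNA and mRNA
expression profiles by **antagonism pattern detection**: a non-linear,
permutation-calibrated statistic that recognizes the triangular
joint-expression shape left behind when a miRNA silences a target. Where a
linear method asks "do miRNA and mRNA move in opposite directions?", the
antagonism statistic asks "is the simultaneously-high corner of the scatter
statistically depleted?" — the signature expected when silencing is real but
modulated by other regulators, genomic alterations and noise, as in tumor
cohorts.

The package is aimed at systems-biology analyses of matched miRNA/mRNA
expression from the same samples (typically a few dozen clinical specimens),
where mutual information is unreliable and Pearson correlation misses
non-linear exclusion patterns.

## The statistic

For a pair with z-scored expression $(x_i, y_i)$, $i = 1..N$, and the
anti-diagonal line $x + y = b$, let
$F_{\mathrm{obs}}(b) = \#\{i: x_i + y_i < b\}/N$ and let
$\bar F_{\mathrm{null}}(b)$ be its mean over $S$ random re-pairings of the
two vectors (value multisets preserved, association destroyed; default
$S = 100$). The antagonism coefficient is the one-sided
Kolmogorov–Smirnov-type supremum

$$A = \max_b \left[ F_{\mathrm{obs}}(b) - \bar F_{\mathrm{null}}(b) \right],$$

attained at the best intercept $b^\*$, and its significance is the
permutation p-value $PV = (1 + \#\{A_m \ge A\})/(1 + M)$ over $M$ random
re-pairings (default $M = 1000$), each rescored with a fresh shuffle null.
Pair families are Benjamini–Hochberg adjusted; edges at FDR ≤ 2% (default)
form a bipartite miRNA–gene network analyzed for hub regulators against a
sample-shuffled randomized network. Predicted target sets are validated by
miRNA seed-match enrichment in 3'UTRs (against miRNA-label shuffles that
preserve UTR composition and node degrees) and by hypergeometric gene-set
enrichment with a label-shuffle negative control.

A triangular-data simulator with controlled noise drives a power benchmark
(mean p-value over a sample-size × noise grid), and a leave-one-out-corrected
Pearson baseline supports method comparison via cumulative-hit curves.

## Worked example

```r
library(mirantag)

# one synthetic miRNA/mRNA pair: 60 samples, 10% of points violating the
# triangle constraint
sp <- simulate_pair(n_samples = 60, noise_fraction = 0.1, seed = 42)
pair <- standardized_pair(sp$x, sp$y,
                          mirna_id = "hsa-miR-sim", gene_id = "GENE_SIM")
set.seed(42)
antagonism_pvalue(pair, n_permutations = 1000, n_null_shuffles = 100)
#>      mirna_id  gene_id coefficient best_intercept      pvalue
#> 1 hsa-miR-sim GENE_SIM      0.1465       1.024324 0.001998002
```

The coefficient 0.147 says the fraction of samples below the line
$x + y = b^\* = 1.02$ (on the z-score sum scale) exceeds its
random-re-pairing expectation by 14.7 percentage points at the best
intercept; only 1 of 1000 random re-pairings scored as high, giving the
smoothed permutation p-value 0.002.

Scanning a small paired expression set (the planted pair above embedded
among independent features) ranks the true pair first and flags it at
FDR ≤ 5%:

```r
mi <- matrix(rnorm(3 * 60), nrow = 3,
             dimnames = list(paste0("miR-", 1:3), paste0("S", 1:60)))
mg <- matrix(rnorm(4 * 60), nrow = 4,
             dimnames = list(paste0("gene", 1:4), paste0("S", 1:60)))
mi[1, ] <- sp$x; mg[1, ] <- sp$y
expr <- paired_expression_set(mi, mg)
scores <- scan_all_pairs(expr, n_permutations = 500,
                         n_null_shuffles = 100, seed = 7, fdr_q = 0.05)
head(rank_predictions(scores), 4)
#>   mirna_id gene_id coefficient pvalue qvalue significant
#> 1    miR-1   gene1      0.1517 0.0020  0.024        TRUE
#> 2    miR-2   gene4      0.1082 0.0359  0.216       FALSE
#> 3    miR-2   gene3      0.0875 0.1896  0.723       FALSE
#> 4    miR-1   gene2      0.0738 0.4232  0.723       FALSE
```

Downstream steps follow the same grammar: `build_network()` →
`detect_hubs()`, `seed_enrichment()`, `mirna_target_enrichment()` /
`randomized_go_control()`, or everything at once via `run_full_pipeline()`.
A command-line wrapper with verbs `simulate`, `benchmark`, `detect`,
`correlate`, `network`, `seeds`, `enrich` and `run` is installed at
`inst/cli/mirantag.R`.

See the vignette (`vignettes/antagonism-detection.Rmd`) for the model,
the simulator's semantics, numerical choices and limitations.

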