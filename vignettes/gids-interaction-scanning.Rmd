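---
title: "Scanning for gene-gene interactions with the generalized index of dissimilarity"
author: "gidscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for gene-gene interactions with the generalized index of dissimilarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gidscan)
```

## The association model

A k-SNP combination partitions samples into the $3^k$ multi-locus genotype
cells of additive minor-allele coding; a multi-class phenotype partitions
them into $J$ outcome classes. Cross-tabulating gives counts $n_{ij}$ with
marginals $n_{i\cdot}$, $n_{\cdot j}$, total $n$, and independence
expectations $E_{ij} = n_{i\cdot} n_{\cdot j}/n$. The generalized index of
dissimilarity

$$\mathrm{GIDS} \;=\; \frac{\tfrac12 \sum_{j}\sum_{i} |n_{ij} - E_{ij}|}
{\sum_j n\,P_{\cdot j}(1-P_{\cdot j})}, \qquad P_{\cdot j}=n_{\cdot j}/n,$$

measures how unevenly the outcome classes distribute over genotype cells.
The denominator is the maximum the numerator can attain for the observed
class margins, so $\mathrm{GIDS}\in[0,1]$, with 0 exactly at independence
and 1 when every genotype cell is pure.

Three identities anchor the measure to classical MDR practice, and the test
suite verifies them numerically on random tables:

* for $J=2$, GIDS equals the classical index of dissimilarity
  $\mathrm{IDS} = \tfrac12\sum_i |n_{i1}/n_{\cdot 1} - n_{i2}/n_{\cdot 2}|$;
* under the conventional risk rule — genotype row $i$ is HIGH when
  $n_i^{case}/n_i^{control} \ge n^{case}/n^{control}$ — the pooled
  classifier's balanced accuracy satisfies $\mathrm{IDS} = 2\,\mathrm{BA}-1$;
* hence GIDS generalizes balanced accuracy to arbitrary $J$ while never
  constructing a confusion matrix, which is exactly what makes multi-class
  and composite phenotypes (e.g. the nine joint blood-pressure states)
  analyzable.

The risk comparison is evaluated as the integer cross-product
$n_i^{case} n^{control} \ge n_i^{control} n^{case}$: exact in integer
arithmetic, defined when a row has no controls, and ties go to HIGH, the
conventional reading of the $\ge$ rule. Empty genotype rows contribute
$|0-0|=0$ to the numerator and are retained so row indexing is stable.
Samples missing a genotype at a scanned SNP are excluded listwise for that
combination only, and the excluded count travels with the table.

## Scanning and permutation inference

`scan_order()` scores every one of the $\binom{p}{k}$ combinations (GIDS by
default; the raw Pearson $\chi^2$ statistic is available as a ranking
baseline — as a deviation-from-expectation measure it is the natural
comparator, but its unnormalized maximum grows with $J$). Results are sorted
descending with deterministic tie-breaking (lexicographically smallest SNP
tuple), so ranks are reproducible.

Significance uses a max-statistic permutation scheme: the phenotype vector
is permuted against the fixed genotype rows — equivalent to permuting the
whole dataset's genotype-phenotype linkage while preserving any structure
among genotypes — the full scan is repeated, and the maximum score is
recorded. The $B$ maxima form the order-specific null distribution, and

$$p = \frac{1 + \#\{b : \max_b \ge \mathrm{obs}\}}{B + 1}.$$

The add-one rule is used because it yields a valid p-value (never zero,
ties counted against the observation); we deliberately expose only this one
formula rather than the asymptotically equivalent $r/B$. Because the
maximum is taken over all combinations of the order, the p-value is already
multiplicity-adjusted within that order, and p-values are comparable across
orders — `select_best_model()` builds one null per order (never shared,
since $\max$ over $\binom{p}{k}$ combinations depends on $k$) and reports
the smallest-p model, breaking ties toward the smaller order and then the
larger score. Permutations are drawn sequentially from R's RNG given a
single seed, so every result is bit-reproducible.

## What the simulators emulate

**Categorical phenotypes.** `simulate_genotypes()` draws independent SNPs
under Hardy-Weinberg equilibrium, $g \sim \mathrm{Binomial}(2, \mathrm{MAF})$
— the field's default when linkage disequilibrium is not under study.
`penetrance_from_odds()` turns class prevalences $v_j$ and a $3^k \times J$
odds-ratio pattern into cell-wise class probabilities by the multinomial
tilt $p_{j|i} \propto OR_{ij} \, v_j$. This construction is our own device:
it is the simplest map that leaves penetrance equal to prevalence when all
odds ratios are 1, approaches a point mass as an odds ratio grows, and
row-normalizes exactly. Because row normalization perturbs the marginals, an
optional iterative proportional fitting pass (`match_prevalence = TRUE`)
rescales class weights until the genotype-averaged class frequencies match
$v_j$ to within $10^{-6}$. The shipped strong-effect scenario
(`scenario_strong_categorical()`, also available as a YAML config under
`inst/extdata/`) uses a cyclic pattern — the favored class of cell $(i,j)$
is $(i+j) \bmod 3$ with odds ratio 4, prevalences $0.3/0.4/0.3$, $n = 400$,
$p = 20$, MAF 0.5 — chosen as a representative strong two-way interaction
whose favored class varies over cells rather than along either margin.

**Quantitative phenotypes.** `quant_penetrance_model()` implements the
mixture law in which a $3\times3$ mean table $f_{ij}$ dictates each cell's
distribution:

$$y \mid (i,j) \sim \begin{cases}
N(f_{ij}, \sigma_L^2) & f_{ij} < \bar f\\[2pt]
\tfrac12 N(f_{ij}-\alpha, \sigma_H^2) + \tfrac12 N(f_{ij}+\alpha, \sigma_H^2)
 & f_{ij} \ge \bar f
\end{cases}$$

so above-average cells are bimodal with mean $f_{ij}$ and variance
$\sigma_H^2 + \alpha^2$. The reference mean $\bar f$ is the
genotype-frequency-weighted average of the cell means (the population mean
the branch comparison implies); the unweighted 9-cell average is available
via `fbar = "unweighted"`. Defaults $\sigma_L = \sigma_H = 1$ and
$\alpha = 0.4$ sit at the center of the study grid
($\sigma \in \{0.8, 1.0, 1.2\}$), $\alpha$ small enough that the mixture
components overlap. Since the original 70 penetrance tables behind the
published heritability grid are not distributed with their source,
`quant_model_from_heritability()` rescales a user-chosen pattern (default: a
checkerboard $(i+j) \bmod 2$, a pure interaction) so that
$h^2 = \mathrm{Var}_G / (\mathrm{Var}_G + \mathrm{Var}_E)$ hits the target
exactly, where $\mathrm{Var}_G$ is the weighted variance of cell means and
$\mathrm{Var}_E$ the weighted within-cell variance; scaling preserves branch
membership, so the solution is closed-form.

**Categorization.** `categorize_trait()` cuts a quantitative trait at
thresholds placed from its sample mean and SD: $(\mu)$ for $J=2$,
$(\mu \pm 0.43\,\sigma)$ for $J=3$, $(\mu - 0.67\,\sigma,\ \mu,\
\mu + 0.67\,\sigma)$ for $J=4$ — the standard-normal cut points giving
near-equal class areas. A value exactly at a threshold joins the upper
class, a convention applied uniformly across $J$ (we read the lone
asymmetric rendering of the $J=3$ thresholds in the source design as a typo
for the symmetric pair). **Null data** use the same mixture law with a flat
mean table, hence a phenotype independent of every SNP by construction.

The simulators deliberately omit linkage disequilibrium, covariates and
population structure. Passing tests therefore certify the method's
calibration and power under independent-SNP, randomly-mating conditions —
not robustness to confounding or correlated markers, which real GWAS data
exhibit.

## Study harnesses and problem sizes

`run_study()` replicates a scenario, scans at orders 1-3 and scores
single-locus (either causal SNP top-ranked), two-locus (exact causal pair)
and three-locus (triple containing the pair) hit ratios — top-1 comparison,
set-wise, as no ranking threshold is part of the design. `type1_study()`
generates null datasets, categorizes each trait into $J$ classes, and
reports the fraction of max-GIDS permutation p-values at or below $\alpha$.

The packaged studies use 100 replicates for power, and 200 null datasets
with $B = 200$ permutations per type-I-error estimate (the full-scale design
uses $B = 1000$ for one-decimal accuracy; the smaller $B$ widens the
per-replicate p-value grid to $1/201$, which is still fine at
$\alpha = 0.05$, and the acceptance band is the exact binomial 99% interval
for 200 replicates). MAFs alternate 0.2/0.4 across replicates so estimates
average over the study's allele-frequency grid, matching how the published
averages pool conditions.

```{r, eval = FALSE}
ts <- type1_study(J = 3, replicates = 200, B = 200, seed = 1)
ts$percent   # empirical type-I error, percent, at alpha = 0.05
```

## Numerical and design notes

* All measures operate on plain count matrices or the `gids_table`
  container; GIDS errors out when all mass sits in one class (zero
  denominator) rather than returning a conventional value.
* The exhaustive scan's tabulation loop is compiled (Rcpp); the R-level
  per-table path is retained and the two are asserted equal in the test
  suite, including on the full 190-pair, $n=400$ design.
* Seeds: every stochastic entry point takes one integer seed; internally,
  child seeds for replicates and per-order nulls are drawn up front from
  the seeded stream, so runs are reproducible end to end and replicates are
  independent.
* `compose_phenotypes()` encodes multiple categorical traits as one
  mixed-radix composite class (row-major over components), which is how the
  nine-class blood-pressure phenotype arises from two three-band traits;
  `classify_blood_pressure()` hard-codes the JNC7 bands, boundaries
  belonging to the upper band.
* Known limitations: the exhaustive scan is meant for candidate panels
  (hundreds of SNPs); genome-wide use needs the permutation loop
  distributed. BA is only defined for $J = 2$ by construction; for $J > 2$
  GIDS is the measure.
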