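# gidscan

Gene–gene interaction (epistasis) scanning for phenotypes with **any number
of outcome classes**, built on the generalized index of dissimilarity (GIDS).

## The problem

Multifactor dimensionality reduction (MDR) and its relatives find interacting
SNP pairs by pooling the 3^k multi-locus genotype cells of a k-SNP
combination into high/low risk classes and scoring the resulting case–control
classifier with balanced accuracy (BA). That construction needs a binary
phenotype: with three or more outcome classes there is no longer a single
well-defined risk threshold per genotype cell. Yet multi-class phenotypes are
everywhere — ordinal disease stages, categorized quantitative traits, or
composite traits such as the nine joint systolic/diastolic blood-pressure
states of the JNC7 classification.

`gidscan` scores a k-locus genotype × J-class phenotype contingency table
`n_ij` directly, with no risk statuses at all, using the generalized index of
dissimilarity:

```
        (1/2) Σ_j Σ_i | n_ij − E_ij |
GIDS = ───────────────────────────────,   E_ij = n_i. n_.j / n,  P_.j = n_.j / n
          Σ_j n P_.j (1 − P_.j)
```

GIDS is 0 under exact independence and 1 at maximal unevenness. For J = 2 it
reduces to the classical index of dissimilarity
`IDS = (1/2) Σ_i |n_i1/n_.1 − n_i2/n_.2|`, which is analytically equivalent
to MDR's balanced accuracy through `IDS = 2·BA − 1` — so GIDS is a
generalized balanced accuracy that happens to need no dichotomization.

The package provides:

* **Measures** — GIDS, IDS, BA (with the conventional cross-product risk
  rule), and a Pearson χ² baseline, all on the same table container.
* **Scanning** — exhaustive scoring of all C(p, k) combinations, max-statistic
  permutation null distributions (phenotype permuted against fixed genotype
  rows, maximum score recorded per permutation), multiplicity-adjusted
  p-values `p = (1 + #{null ≥ obs}) / (B + 1)`, and best-model selection
  across interaction orders by smallest p-value.
* **Simulators** — Hardy–Weinberg genotypes; penetrance-driven categorical
  phenotypes (penetrances built from prevalences and odds-ratio patterns); a
  Gaussian-mixture quantitative trait whose cell distribution depends on a
  3×3 mean table (`N(f_ij, σ_L²)` below the average cell mean, an
  equal-weight mixture `½N(f_ij ± α, σ_H²)` at or above it), with a
  heritability-targeted model builder; mean/SD-based categorization of
  quantitative traits into 2/3/4 classes; null datasets; the nine-class
  JNC7 blood-pressure classifier and general composite-phenotype encoding.
* **Evaluation** — single/two/three-locus hit ratios over replicated scans
  and empirical type-I error of the permutation test on null data.
* **CLI** — a thin `Rscript` front end (`inst/cli/gidscan.R`) with
  `simulate`, `scan`, `best-model`, `evaluate` and `bp-classify`
  subcommands driven by YAML scenario configs.

## Worked example

Simulate the shipped strong-effect three-class scenario (400 samples, 20
SNPs at MAF 0.5, causal pair (1, 2), prevalences 0.3/0.4/0.3) and scan it:

```r
library(gidscan)

scenario <- scenario_strong_categorical()
ds   <- simulate_scenario(scenario, seed = 2026)
scan <- scan_order(ds$genotypes, ds$phenotype, k = 2)
head(scan, 3)
#>   snp1 snp2      gids rank
#> 1    1    2 0.4919868    1
#> 2   11   15 0.1933296    2
#> 3    2   11 0.1871789    3
```

The causal pair tops the 190 pairs with GIDS 0.49, well clear of the best
background pair (0.19). Comparing interaction orders with per-order
permutation nulls (B = 199):

```r
select_best_model(ds$genotypes, ds$phenotype, orders = 1:3, B = 199, seed = 2026)
#> Best interaction model across orders (gids):
#>  order  snps      gids p_value
#>      1     1 0.1295868   0.050
#>      2   1,2 0.4919868   0.005
#>      3 1,2,4 0.5202193   0.005
#> best: order 2, SNPs (1,2), gids = 0.4920, p = 0.005
```

The order-3 triple necessarily contains the causal pair and reaches the same
minimal p-value; the tie rule (smaller order first) correctly reports the
two-way model. Composite blood-pressure classes for three subjects:

```r
classify_blood_pressure(c(115, 130, 145), c(85, 95, 75))
#>   class           label
#> 1     2 prehypertension
#> 2     6    hypertension
#> 3     7    hypertension
```

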