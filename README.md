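# ifnburden

Quantitative pipeline for candidate-gene studies of type I
interferon-driven autoimmunity — the setting where ultra-rare variants in a
regulator of endosomal Toll-like receptor signalling (such as UNC93B1 in
systemic and chilblain lupus) are screened in a patient cohort, scored for
predicted deleteriousness, and followed up with blood interferon-signature
measurements, NF-κB luciferase reporter assays, and structural
free-energy predictions.

The package is aimed at genetics and immunology groups who have the
standard raw tables of such a study (cohort variant calls with population
reference counts, predictor score tables, RT-qPCR Ct and NanoString count
tables, dual-luciferase plate readings, per-model ΔΔG values) and want the
downstream statistics to be exact, scripted and reproducible. A
synthetic-data generator with planted ground truth exercises every stage
offline.

## What it computes

- **Qualifying-variant filter and carrier gene-burden test.** Variants
  qualify when protein-altering with population allele frequency strictly
  below 10⁻⁵ (and, optionally, combined damage score ≥ 0.7). With *k*
  carrier kindreds of *n* and background carrier probability *p₀*, the
  test reports fold enrichment (k/n)/p₀ and the exact one-sided binomial
  tail p = P(X ≥ k), X ~ Bin(n, p₀), summed in log space. A
  Hardy–Weinberg product form 1 − Π(1 − cᵢ), cᵢ = 2pᵢ(1−pᵢ) + pᵢ²,
  derives p₀ from a reference variant table.
- **Combined VEP damage score.** Per predictor, the fraction of the gene's
  reference missense variants predicted less damaging (mid-rank ties),
  averaged over available predictors; seven-predictor catalog with
  per-predictor scale orientation included.
- **Interferon-signature scores.** Six-gene qPCR score (2^(−ΔCt) against
  the mean housekeeping Ct, per-gene folds versus control medians, median
  of six folds, positive strictly above 2.46) and 24-probe NanoString
  score (calibrator/background/reference-probe normalization, median of 24
  folds, threshold recomputed as control mean + 2 SD).
- **Dual-luciferase reporter statistics.** RLU = Firefly/Renilla, fold
  stimulated over matched unstimulated wells, normalization to wild type
  per experiment; one-way ANOVA, Monte Carlo Dunnett comparisons versus
  wild type, and the Šidák closed form.
- **ΔΔG box statistics.** Per variant × complex: median, interpolated
  quartiles, 1.5 IQR whiskers, and a stabilizing/neutral/destabilizing
  call with a configurable tolerance.

## Worked example

The five ultra-rare UNC93B1 missense substitutions of the motivating
cohort, with their reference allele counts and damage scores, ship as a
built-in example:

```r
library(ifnburden)
ex <- unc93b1_example_cohort()
qual <- select_qualifying(ex$variants, filter_criteria(), ex$damage_scores)
cc <- cohort_carrier_count(ex$genotypes[, qual$protein_change])
burden_test(cc$k, cc$n, ex$background_carrier_freq)
#> Carrier gene-burden test (binomial)
#>   cohort carriers:     5 / 63 (7.9%)
#>   background carriers: 0.004
#>   fold enrichment:     19.8
#>   one-sided p-value:   5.93e-06
```

All five variants pass the MAF < 10⁻⁵ and damage ≥ 0.7 filters; 5 of 63
kindreds is a 7.9% cohort carrier frequency, a 19.8-fold enrichment over
the 0.4% reference background, significant at p ≈ 5.9 × 10⁻⁶.

A reporter experiment, simulated with a planted 3× gain-of-signal
construct and analysed end to end:

```r
sim <- simulate_reporter_plate(plate_sim_spec(
  constructs = c("EV", "WT", "GOF"),
  effect_multiplier = c(EV = 0.2, WT = 1, GOF = 3),
  replicate_cv = 0.1, n_experiments = 4, seed = 42))
reporter_assay(sim$wells, n_mc = 1e5, seed = 1)
#> Dual-luciferase reporter analysis (fold stimulated, relative to WT)
#>   EV         0.207 +/- 0.023 (n = 4)
#>   GOF        3.05 +/- 0.21 (n = 4)
#>   WT         1 +/- 0 (n = 4)
#> One-way ANOVA: F(2, 9) = 148, p = 1.3e-07
#> Dunnett vs WT (Monte Carlo):
#>   EV - WT          diff -0.793  adj. p = 0.00209
#>   GOF - WT         diff +2.05  adj. p = 7.55e-07
```

The estimates recover the planted multipliers (0.2, 1, 3) within noise and
both constructs differ from wild type after Dunnett adjustment.

A command-line wrapper over the same functions is installed at
`inst/scripts/ifnburden` with subcommands `simulate`, `burden`,
`damage-score`, `ifn-score`, `reporter` and `ddg-summary`; each run writes
TSV/JSON results plus a `provenance.json` recording inputs, thresholds,
seed and package version.

See `vignettes/ifnburden-methods.Rmd` for the statistical conventions and
their rationale.

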