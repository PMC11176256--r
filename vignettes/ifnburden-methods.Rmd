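---
title: "Methods: burden testing, damage scores, interferon signatures, and reporter statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden testing, damage scores, interferon signatures, and reporter statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnburden)
```

`ifnburden` implements the quantitative backbone of a candidate-gene study
of type I interferon-driven autoimmunity: screening a cohort for ultra-rare
qualifying variants in one gene and testing carrier enrichment against a
population reference, scoring variant deleteriousness by percentile
normalization across variant-effect predictors, quantifying the blood
interferon signature by two assay-specific scores, analysing dual-luciferase
TLR-signalling reporter assays, and summarizing predicted folding-energy
changes from structural models. This vignette records the statistical model
behind each stage, the conventions chosen where the field leaves them open,
and what the synthetic-data generator does and does not emulate.

## The carrier gene-burden test

The cohort unit is the **kindred**: a kindred carries if any member bears at
least one qualifying allele, and it counts once regardless of zygosity or of
how many qualifying variants segregate in it. With `k` carrier kindreds of
`n`, the test compares the carrier frequency `k/n` against a fixed
background carrier probability `p0` using the exact one-sided binomial
upper tail

$$ p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, p_0), $$

computed by direct summation of point masses on the log scale, so tails far
below the double-precision underflow of the naive product remain exact
(the suite checks agreement with brute-force summation to $10^{-10}$
relative error for all `n` up to 200). Fold enrichment is `(k/n)/p0`.
"Gene burden test" names a family of procedures rather than one test; the
exact binomial carrier test against a fixed background was chosen because
it needs only the published background carrier frequency, is exact at small
`k`, and reproduces the worked example's printed numbers
(`burden_test(5, 63, 0.004)` gives `p = 5.9e-6` and 19.8-fold enrichment).
A Fisher-exact alternative against observed reference carrier counts is
available via `method = "fisher"` for users who have the reference counts
rather than a probability. The discrete test is conservative: under null
simulation its rejection rate at $\alpha = 0.05$ sits below nominal.

Qualifying variants are protein-altering (missense, in-frame and
out-of-frame indels, stop gains) with population allele frequency
**strictly** below `max_maf` (default $10^{-5}$); a variant absent from the
reference is encoded as allele count 0 over a valid allele number, i.e.
frequency 0, never as an undefined ratio. Because all qualifying alleles
are ultra-rare alternates, the minor-allele frequency is the alternate
frequency itself and no folding logic is applied. When combined damage
scores are supplied the filter additionally requires score
$\ge$ `min_damage_score` (default 0.7, inclusive), and a qualifying variant
without a score is an error rather than a silent pass.

The cumulative background carrier frequency from a reference variant table
uses Hardy–Weinberg per-variant carrier probabilities
$c_i = 2p_i(1-p_i) + p_i^2$ combined through the product form
$p_0 = 1 - \prod_i (1 - c_i)$, which is exact for independent loci and
reduces to $\sum_i 2 p_i$ in the rare limit. Published background
frequencies (such as the 0.4% used in the worked example) can instead be
passed directly as `p0`. One documented quirk of the motivating study: its
concluding text rounds the cohort carrier frequency to "~6%", while the
counts it prints (5 of 63 kindreds) give 7.9%; the package reports 7.9% and
leaves the discrepancy to the reader.

## The combined VEP damage score

For each predictor, the variant's raw score is converted to the fraction of
the gene's reference missense variants predicted to be **less damaging**,
after orienting the predictor's native scale so that larger means more
damaging (the default catalog flags DeepSequence and ESM-1v as
lower-is-more-damaging, the [0,1]-scaled meta-predictors as
higher-is-more-damaging). Exact ties count one half (mid-rank), so a
background member scores 0.5 against its own distribution; whether the
original procedure used strict-less or mid-rank counting is not decidable
from published descriptions, and mid-rank was chosen as the unbiased
standard rank convention. The combined score is the unweighted mean over
the predictors for which both a raw score and a background exist; missing
predictors are excluded rather than imputed, with `n_used` reported.
The score is invariant to any strictly increasing transform applied
jointly to a predictor's raw score and background, monotone in the oriented
raw score, and converges to the planted quantile of a continuous background
as the background grows (checked at background size $10^4$ within 0.02).
Classification as damaging uses an inclusive threshold, 0.7 by default.
The package never runs the predictors; raw scores are inputs.

## Interferon-signature scores

**qPCR (6 genes).** Technical replicates are averaged on the Ct scale.
Relative expression is $2^{-\Delta Ct}$ with
$\Delta Ct = Ct_\mathrm{gene} - \tfrac12(Ct_{HPRT1} + Ct_{18S})$; the
arithmetic mean of the two housekeeping Ct values (equivalently the
geometric mean of their expression) is the standard $\Delta\Delta Ct$
choice where the combination rule is unstated. Per-gene fold changes are
taken against the median of the healthy controls, and the score is the
exact median of the six folds (even-length medians are the mean of the two
central order statistics). Positivity is strict: score > 2.46, a threshold
derived once from a reference control cohort and carried as panel
configuration, not recomputed.

**NanoString (24 probes).** Normalization is one defensible reading of
"normalized relative to the internal positive and negative calibrators, the
three reference probes, and the control samples": (1) the per-sample mean
of the negative calibrators is subtracted from every count and floored at
1; (2) each sample is scaled by the ratio of the grand geometric mean of
positive-calibrator levels to its own positive-calibrator geometric mean;
(3) the same geometric-mean ratio over the three reference probes, computed
after steps 1–2, is applied. A uniform multiplicative distortion of a
sample — calibrators included — cancels exactly when background is zero.
Scores are per-probe folds against control medians, summarized by the
median over the 24 probes; the positivity threshold is recomputed from the
supplied controls as mean + 2 SD of the control scores with the sample
(n−1) SD. The reference cohort of record (27 controls) yielded 2.75 (2.758
at higher precision); both are carried as documented constants, and the
threshold is otherwise cohort-specific by construction. Median-based
scoring tolerates corruption of a minority of genes (2 of 6, 11 of 24)
without moving when the remaining folds are constant.

## Dual-luciferase reporter statistics

Per well, RLU = Firefly/Renilla removes transfection-efficiency and lysis
variation. Replicate wells are averaged at the RLU stage (duplicate-well
plating is the norm), the fold stimulated of a construct within an
experiment is mean stimulated RLU over mean matched unstimulated RLU, and
folds are normalized to the wild-type fold of the same experiment, making
WT exactly 1 per experiment. The whole chain is invariant to rescaling all
Firefly values of an experiment, or all Renilla values, by constants.

Statistics operate on per-experiment relative folds (one observation per
construct per experiment) — the resolution at which independent biological
replicates exist; well-level analysis would treat technical replicates as
independent. One-way ANOVA uses the standard pooled-variance F test.
Many-to-one comparisons against WT use Dunnett's construction: pooled
variance, shared control, and the null distribution of the familywise
maximum |t| — here sampled by seeded Monte Carlo (group means as scaled
normals, the pooled variance as a scaled chi-square, 10^5 draws by
default) rather than multivariate-t quadrature. Monte Carlo keeps the
implementation transparent and directly checkable against a brute-force
resampling oracle (the suite also cross-checks against the multivariate-t
implementation in `multcomp`); adjusted p-values are floored at the
unadjusted two-sided p so sampling noise can never make adjustment appear
to strengthen evidence. The Šidák closed form `1 − (1 − p)^m` is provided
as the named pairwise correction; routine omnibus alternatives (two-way
ANOVA, rank tests, mixed models) are deliberately out of scope.

## Folding-energy summaries

Per-model ΔΔG values (kcal/mol) are grouped by variant × complex and
summarized as box statistics: quartiles by linear interpolation of order
statistics (the common plotting default; with five models the quartiles sit
on the second and fourth values), whiskers at the most extreme data points
within 1.5 IQR of the quartiles. Direction calls use a symmetric tolerance
band (default 0.5 kcal/mol): median below −tol is stabilizing, above +tol
destabilizing, otherwise neutral. The band is an artifact convention —
source studies describe direction qualitatively — and is exposed as a
parameter. A tolerant parser for FoldX `Dif_*.fxout` difference tables is
included; running the structure tools themselves is out of scope.

## The synthetic-data generator

Each generator draws from an independent substream derived from one global
seed, so outputs are byte-identical under a fixed seed and adding a
generator never perturbs another's stream; the caller's RNG state is left
untouched. Ground truth (carrier kindreds, injected folds, effect
multipliers, planted ΔΔG means) is emitted alongside the data — as a YAML
sidecar on disk — never inferred from it.

Noise shapes are the simplest that make each normalization non-trivial:
Gaussian noise on the Ct scale (with a per-sample loading offset common to
all genes, which the housekeeping normalization must cancel); log-normal
count noise plus per-sample multiplicative calibrator distortion and
additive background for NanoString; unit-mean log-normal luminescence noise
at a stated CV for plates, with per-experiment baseline and
stimulation-fold variability so WT normalization matters. Noise-free
settings are exactly deterministic (the qPCR loading offset is suppressed
at `ct_noise_sd = 0`), giving sharp degenerate tests. Default condition
sizes mirror the motivating study: 63 kindreds, 29 qPCR and 27 NanoString
controls, 3–4 reporter experiments in duplicate wells, five structural
models.

What the generator does **not** emulate bounds what green tests show about
real data: no linkage or population structure (cohort carriers are
independent Bernoulli draws and reference loci independent), no
amplification-efficiency differences between qPCR targets, no
probe-specific NanoString hybridization kinetics or RCC file structure, no
plate-position effects or dose–response shape, and Gaussian ΔΔG spread
rather than FoldX's actual model-to-model error structure. Passing
recovery tests demonstrates that the estimators invert the generative model
they target, not that these assay artefacts are absent in practice.

## Numerical choices and problem sizes

Binomial tails are summed in log space; percentile scores use exact
counting, not interpolation; even-length medians average the two central
order statistics; background-subtracted NanoString counts are floored at 1
to keep folds defined; Dunnett Monte Carlo uses a fixed, user-visible seed.
The test suite and the bundled `scripts/acceptance.R` size their
simulations for desk-scale runs as the package's own verification
conditions: 100 simulated patients for qPCR fold recovery, 2,000 null
cohorts for type-I calibration, background size 10^4 for percentile
convergence, 2×10^5 Monte Carlo draws for the Dunnett oracle comparison,
and 50 experiments for reporter-bias checks. Patient-level published
quantities (individual interferon scores, per-variant reporter folds) are
not reproducible from public information and are used only as interface
fixtures and plausible magnitudes.
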