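---
title: "Methods: classifying deviation from polygenic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying deviation from polygenic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydev)
```

## The problem

A polygenic score $PS_i = \sum_j \beta_j G_{ij}$ predicts a quantitative
phenotype from common-variant dosages. Most people land near their
prediction; a small minority do not, and those individuals are interesting
precisely because something outside the additive common-variant model — a
rare large-effect variant, a medical condition, a strong environmental
exposure — may explain the gap. polydev classifies individuals as
*deviators* (phenotype improbably far from prediction), *aligned*
(consistent with the additive model; the comparison group for enrichment
testing), or *intermediate*, and then quantifies what distinguishes the
deviator groups.

All classifiers consume the same object: per-individual standardized pairs
$(z_{PS}, z_{pheno})$. The phenotype is residualised on its covariates
(age, sex, assessment centre, medication as appropriate), optionally
rank-inverse normalised, and scaled to mean 0, SD 1; the score is treated
the same way with leading principal components as covariates. The
adjustment order is residualise, then RINT, then standardize.

## The four classifiers

**Mahalanobis (primary).** A null cohort is simulated under the additive
polygenic model at the cohort's observed variance explained, and the
2×2 covariance $\Sigma$ of the simulated standardized pairs is estimated
from it — calibration never touches the observed data. Each observed pair
gets $D^2 = (x-\mu)^\top \Sigma^{-1} (x-\mu)$, converted to the upper tail
of $\chi^2_{2}$ (equal to $e^{-D^2/2}$). A deviator must satisfy both
$p < \alpha$ (default $\alpha = 0.001$; a Bonferroni mode uses $0.05/n$)
and $|z| > 2$, where $z$ is the standardized residual from regressing the
score on the phenotype over the full cohort. The joint rule exists because
a large $D^2$ can also arise from an individual who is extreme in *both*
coordinates in a mutually consistent way — tall with a tall score — which
is exactly what the additive model predicts, not a deviation from it.

**Regression residuals.** Deviators are individuals with $|z| > k$
($k = 2$ or $3$) for the same standardized residual $z$. Under a bivariate
normal null the $k=2$ rule flags $2\Phi(-2) \approx 4.55\%$ of the cohort,
which makes it the most liberal method here.

**Rank-matched empirical p-values.** $B$ null cohorts are simulated; in
each, phenotypes are stored in order of score rank. An observed phenotype
$y$ at score rank $k$ is compared with the $B$ stored phenotypes at the
same rank; with $r$ the count at least as extreme (two-sided about the
per-rank null median by default), the empirical p-value is
$(r+1)/(B+1)$, with floor exactly $1/(B+1)$. This makes no use of the
chi-squared approximation and so tolerates non-normal phenotypes better.

**Score-centile Tukey fences.** Individuals are cut into 100 equal-count
score bins; within each bin, phenotypes outside
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ ($k = 1.5$ or $3$) are
deviators. Fully non-parametric: no assumption on either marginal.

Deviators are split into low/high groups by the sign of the standardized
phenotype (below the mean = lower than predicted); a residual-sign
alternative is available via `direction_rule = "residual"`, because the
phenotype-sign rule classifies by overall phenotype rather than by the
direction of the *discrepancy*, which can differ for individuals whose
score is itself below the mean. The aligned group, $|z| < 1$, is shared by
all methods so enrichment comparisons are always against the same people.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.001 | Mahalanobis / rank-method p threshold (unitless) |
| `z_dev` | 2 | residual magnitude required of Mahalanobis deviators (SD) |
| `z_aligned` | 1 | residual magnitude bounding the aligned group (SD) |
| `k` | 2 | residual-method threshold (SD) |
| `k_iqr` | 1.5 | fence multiplier (IQR units) |
| `bins` | 100 | score bins for the centile method |
| `B` | 1000–10000 | replicate cohorts behind the empirical p |
| `target_r2` | 0.316 | simulated variance explained (height-like; 0.167 for an LDL-C-like trait) |

## The regression-direction choice

The shared residual $z$ comes from regressing the *score on the phenotype*
by default; `regression = "phenotype_on_score"` selects the transpose.
The two are not symmetric. With correlation $\rho$ between standardized
score and phenotype, a phenotype displaced by $\Delta$ SD moves the
score-on-phenotype residual by only $\rho\Delta/\sqrt{1-\rho^2}$, but the
phenotype-on-score residual by $\Delta/\sqrt{1-\rho^2}$. At
$\rho \approx 0.56$ (height-like) a 4 SD phenotypic displacement therefore
shifts the default $z$ by about 2.5 — so an appreciable fraction of true
deviators sits below the $|z| > 2$ gate — while the transposed residual
shifts by about 4.6 and gates almost nobody out. The default follows the
convention that the score is the response, which treats score–phenotype
pairs symmetrically with the calibration simulation; users chasing maximal
sensitivity to phenotypic outliers should prefer the transposed direction,
and the acceptance script reports the measured sensitivity of the default
under the packaged study conditions.

## What the synthetic generator emulates — and what it does not

`simulate_null_cohort()` draws dosages per variant as Binomial(2, $f_j$)
under Hardy–Weinberg with frequencies uniform on a configurable range,
effects standard normal, and phenotype
$\sqrt{r^2}\,z_{PS} + \sqrt{1-r^2}\,\varepsilon$. That reproduces the
features the classifiers are calibrated against: a score built from many
small contributions, a controlled variance explained, and joint normality
in the null. `generate_synthetic_study()` plants deviators by adding
$\pm$`shift_sd` to the pre-standardisation phenotype, and can add an
LDL-C-like right skew ($x \mapsto e^{0.5x}$, magnitude chosen only to make
the non-parametric methods earn their keep) and a two-sex structure with
sex-specific variance explained.

The generator deliberately omits linkage disequilibrium, ascertainment and
selection, non-additive architecture, score-weight uncertainty, and
population structure. Passing tests therefore demonstrate correctness of
the statistical machinery under the additive model, not robustness to the
full messiness of biobank data; in particular the false-positive rates
measured here are best-case.

Planted deviators are a stand-in for rare large-effect carriers and strong
environmental causes. A planted shift is added to, not substituted for,
the environmental noise, so a plant whose noise term happens to cancel the
shift is genuinely unremarkable phenotypically — no method, at any
threshold, can find it, and recovery rates below 100% at `shift_sd = 4`
are a property of the data-generating process, not a defect of a
classifier.

## Numerical choices

- RINT uses the Blom offset: $\Phi^{-1}((r - 3/8)/(n + 1/4))$, average
  ranks for ties.
- Standardisation uses the sample SD ($n-1$ denominator) throughout.
- Quartiles interpolate linearly between order statistics
  (`quantile(type = 7)`).
- Score ties in ranking are broken by a seeded random permutation, so
  repeated runs are reproducible.
- $2\times 2$ odds ratios use the cross-product, with the
  Haldane–Anscombe 0.5 added to every cell when any cell is zero; CIs are
  Wald on the log scale; Fisher's exact p and the conditional-MLE OR are
  available by flag since no single estimator is canonical.
- Continuous enrichment outcomes are RINTed by default so effects read in
  SD units; nominal p-values are reported without multiplicity correction
  (a Bonferroni column is trivial for callers to add and deliberately not
  imposed).
- Logistic fits that hit separation or fail to converge return a flagged
  result with `NA` estimate rather than a spurious number.
- The rank-null store materialises a $B \times n$ matrix and refuses
  (with advice) above a 4 GiB cap; extremity counting runs in column
  chunks so no second matrix of that size is ever allocated.
- All randomness flows from one root seed expanded into per-stage child
  seeds, recorded in the run manifest.

## Problem sizes

The packaged demonstration (`run_demo()`) uses $n = 10{,}000$ individuals,
$m = 200$ variants, $B = 2000$ replicates and 50 planted deviators; the
test suite calibrates null behaviour at $n$ up to $10^5$ (bivariate-normal
fast path) and $2\times 10^4$ (genotype-level path), with $B$ up to 1000.
These sizes give sampling error comfortably inside the tolerances being
checked while keeping a full run in tens of seconds; the simulator scales
to biobank-size cohorts ($1.6\times 10^5 \times 3198$ variants) if asked.

## Known limitations

- Allele harmonisation is out of scope: dosages must already count the
  weight table's effect allele.
- The Mahalanobis p-value assumes joint normality of the standardized
  pairs; for skewed phenotypes use RINT adjustment or the rank/centile
  methods.
- The aligned/deviator boundary treats $z$ thresholds as crisp; no
  uncertainty in the score weights is propagated.
- Sex-stratified runs re-standardize and re-calibrate within stratum,
  which assumes each stratum is large enough for stable covariance
  estimation (a few thousand individuals).
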