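---
title: "Methods: chemometric analysis of apple cultivar composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric analysis of apple cultivar composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomochem)
```

# Scope

`pomochem` implements the statistical pipeline of a targeted
metabolite-profiling study of fruit cultivars: replicate-level analyte
tables with structural non-detects, antioxidant assay mathematics,
correlation-matrix PCA with per-variable contributions, Pearson correlation
screening, a small feed-forward neural network relating phenolic composition
to antioxidant endpoints, and Yoon's connection-weight interpretation of the
trained network. The packaged worked example transcribes the summary tables
of a published survey of seven conventional apple cultivars (Gala, Red
Jonaprince, Red Delicious, Fuji, Granny Smith, Idared, Golden Delicious):
15 phenolic compounds, 10 organic acids and phosphate, 6 sugars and sugar
alcohols, and three assay endpoints (total phenolic content as gallic acid
equivalents, DPPH IC50, FRAP as ascorbic acid equivalents), each as
mean ± SD over n = 3 replicates.

# Data model

Measurements live in long format: one row per
(cultivar, analyte, replicate) with a detection flag. A non-detect ("n.d.")
is a *structural* absence — the compound was not observed in any replicate of
that cultivar — and is carried without a numeric value until an explicit
policy converts it.

**Non-detect policy.** The default enters non-detects as concentration 0
when building analysis matrices. This is not merely convenient: with the
worked-example tables, the printed correlation between *p*-coumaric acid and
DPPH IC50 (r = −0.853, p = 0.015) is reproduced only if the one cultivar
with undetected *p*-coumaric acid ('Granny Smith') enters as 0 in an n = 7
correlation; the package treats that consistency check as fixing the
convention. An `exclude` policy is available for workflows where imputed
zeros would bias summaries.

**Summaries.** Per-group means use the sample SD (n − 1 denominator),
matching the mean ± SD convention of triplicate assay tables. A group
reduced to a single value yields sd = 0 with a warning rather than an error,
so toy fixtures stay usable.

**Significance letters.** Per analyte, a one-way ANOVA across cultivars is
followed by Tukey HSD at α = 0.05 and a compact letter display built by the
insert-and-absorb algorithm: cultivars share a letter iff their Tukey
comparison is not significant. Tukey HSD is an assumption — the source
tables do not name their post hoc test — and letters are ordered so "a"
attaches to the smallest mean, ties broken by cultivar name.

# Assay mathematics

Percent DPPH scavenging is
`100 − (A_sample − A_correction) · 100 / A_control`; the correction well
blanks the sample's own colour. Values outside [0, 100] are reported as-is
(with a warning), because clamping raw assay arithmetic hides pipetting and
blank problems; clamping happens only internally when bracketing 50% for
IC50 interpolation.

IC50 defaults to log-linear interpolation between the two tested
concentrations bracketing 50% inhibition, the robust choice for a
five-concentration ladder. A four-parameter logistic fit
(`minpack.lm::nlsLM`) is available; on noiseless Hill data with slope 1 the
two agree within 3%. Calibration for GAE/AAE quantification is unweighted
ordinary least squares — no weighting scheme is assumed.

**Precision of a 5-point IC50.** Near the midpoint the logistic rises at
25·ln(10) ≈ 57.6 percentage points per decade of concentration, so
inhibition noise of σ percentage points maps to roughly σ/57.6 decades of
IC50 uncertainty per reading. At σ = 2 pp this is ~8% of the IC50 for a
single series; the package's property tests therefore assert recovery
within 15% (single series) and within 10% (triplicate-averaged series, the
usual assay design) for ≥90% of seeds — bounds computed from the simulation
itself. Tighter claims would require more replicates or a steeper curve,
not a better estimator: the Cramér–Rao bound for an ideal estimator with
known slope and asymptotes already sits near these figures.

# PCA and correlation conventions

PCA is performed on the **correlation matrix** (equivalently, z-scored
columns). This is forced by the data: phenolics are mg/kg, sugars g/kg, and
covariance PCA would let chlorogenic acid and malic acid dominate by scale
alone. Eigenvalues then sum to the number of variables p, and the explained
fraction of component j is λ_j/p.

The contribution of variable i to component j is
`100 · loading_ij² / λ_j` with the loading's sign reported separately as the
direction of influence — the standard "contribution based on correlations".
Contributions sum to 100 within each component. Component signs are fixed
by making the largest-magnitude loading in each component positive;
ordination signs are otherwise arbitrary.

**Rows are cultivar means, not replicates** (7 rows), because the
ordinations this reproduces plot exactly one point per cultivar; a
replicate-level variant (21 simulated rows) is available behind the
pipeline's `pca_unit` flag. Variables undetected everywhere (hydroxybenzoic
acid, procyanidin B1, galactose in the worked example) are dropped before
standardization — a column of zeros has no variance and no place in a
correlation matrix. On the worked-example tables the 13-phenolic matrix
puts 65.4% of total variance in the first two components and the 15-variable
acid/sugar matrix 78.4% in the first three, matching the published analysis.

Pearson correlations take their two-sided p from
`t = r·√(n−2)/√(1−r²)` with n − 2 degrees of freedom. The choice of n is a
modelling decision made explicit: phenolics-vs-assay correlations use the 7
cultivar means (n = 7), while inter-assay correlations in the source were
computed at replicate level (n = 21). Both conventions are exposed; the
package's tests verify that the printed p-values (0.015 at n = 7, 0.011 at
n = 21) discriminate between them.

# The neural network

The regression model is a single-hidden-layer perceptron,
`Y = f1(W2ᵀ · f2(W1ᵀ · X + B1) + B2)`, with 12 phenolic inputs, 11 hidden
neurons and 2 outputs (DPPH IC50, FRAP) in the worked example. Weight
matrices are stored input-major (rows = source layer), the orientation in
which trained weight tables are printed and exchanged.

Choices the source leaves open, fixed here:

* **Transfer functions**: tanh (hidden), identity (output). The connection
  weight sensitivity analysis below is independent of this choice by
  construction, so the reproduction surface is unaffected.
* **Normalization**: min-max to [0, 1] per variable, fitted on training
  data, invertible; constant columns map to 0.5.
* **Training**: sum-of-squared-error loss minimized by BFGS with an
  analytic backpropagation gradient, restarted from `restarts` uniform
  random initializations in [−0.5, 0.5]; the restart with the lowest
  training SSE wins. The default `restarts = 100` preserves the multi-start
  protocol at desk scale (the original search used far more); tests and the
  pipeline demonstration use 2–10 restarts, which the overparameterized
  21-sample problem does not need more of.
* **Training unit**: replicate scale (21 samples), because 7 cultivar means
  cannot meaningfully constrain a 179-parameter network even for
  interpolation reporting.

A 12-11-2 network has ~4× more parameters than a 21-sample training set has
targets, so training r² ≈ 1.000 is **interpolation, not generalization** —
the package reports it as the source does, but the vignette's caution
stands: such a model describes the fitted sample only.

# Yoon's connection-weight sensitivity

For input i and output j the raw influence is
`S_ij = Σ_k W1[i,k] · W2[k,j]` (sum over hidden neurons; biases excluded),
and the signed relative importance is `RI_ij = 100 · S_ij / Σ_i |S_ij|`.
Two conventions deserve note:

* The **denominator uses absolute values** of the per-input sums. A signed
  denominator would over-scale whenever positive and negative influences
  partially cancel; with the packaged weight tables only the absolute-sum
  convention reproduces the published percentages (e.g. phloridzin −26.99%
  on DPPH), which settles the reading.
* The hidden-unit index runs over the n hidden neurons; printed index
  ranges starting at 0 are read as typographical.

The measure depends only on W1 and W2 — never on biases, transfer functions
or normalizers — which the tests assert both by construction and by varying
the stored identifiers. It is scale-covariant in the right way: scaling an
output's W2 column by c > 0 leaves its RI column unchanged, and flipping
its sign flips every sign in the column.

# Synthetic data: what it does and does not emulate

The generators exist so every downstream stage is testable without any
external data:

* `simulate_replicates()` draws triplicates from Normal(mean, sd)
  **truncated at zero by redraw** (not clipping, which would pile mass at 0
  and bias means); non-detect groups stay structurally absent.
* `simulate_dose_response()` uses a Hill curve with default slope 1 — the
  source does not model curve shape — plus truncated noise.
* `simulate_training_set()` draws the 12 phenolic inputs uniformly within
  each compound's empirical range (cultivar means ± 2 SD, floored at 0) and
  maps them through a known affine `generative_map()` whose coefficient
  signs follow the observed correlation directions, sized so each input
  spans ~120 µg/mL of DPPH IC50 and ~40 mg AAE/kg of FRAP across its range,
  with noise ≈ 5% of each output's observed range. Defaults were fixed once
  from those descriptive statistics. 21 samples mirror the 7 × 3 design.

Deliberately **not** modelled: between-orchard or seasonal variance,
correlation among analytes within a cultivar (replicates are drawn
independently per analyte), heteroscedastic instrument noise, and
limit-of-detection censoring between 0 and the reporting limit. Passing
tests therefore certify the arithmetic and the statistical conventions, not
the field realism of the generator.

# Numerical choices and degenerate inputs

* Correlation-matrix eigenvalues are clipped at 0 to absorb −1e−16
  round-off on rank-deficient matrices (7 samples give rank ≤ 6).
* Constant columns: dropped with a recorded reason before standardization;
  reaching PCA with one is an error, not a silent fix.
* Letter-display ties (equal means) break by cultivar name; ranking ties in
  the sensitivity report keep input order (stable sort).
* Weight-table round-trips are exact at the printed 3-decimal precision.
* Problem sizes in the test suite — 20 training seeds, 3 restarts, 100
  dose-response seeds, 10 000-draw moment checks — were chosen as the
  smallest sizes at which the asserted properties are stable.

# Known limitations

* The IC50 precision analysis above: five-point ladders at realistic noise
  do not support errors much below ~8% per single series; consumers needing
  tighter IC50s should average replicate series or extend the ladder.
* Compact letters are only as good as the ANOVA assumptions; with n = 3 and
  occasionally large SDs (shikimic acid in the worked example) the Tukey
  machinery is fragile, which is why the letter-reproduction test is framed
  over a majority of simulation seeds rather than every seed.
* The network's r² = 1.000 is an interpolation statement; no validation
  split exists in the reproduced design, and none is added.
* Units are metadata: nothing converts between fresh-weight bases, and
  mixing bases in one matrix is legal only because standardization removes
  scale.
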