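---
title: "Methods: descriptive CYP activity models and CBC-IVIVE clearance extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptive CYP activity models and CBC-IVIVE clearance extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypivive)
```

## The problem

Hepatic drug clearance in vivo (CL_H) is largely set by the activities of a
handful of cytochrome P450 (CYP) isoforms. Those activities vary several-fold
between individuals, and measuring all of them in liver tissue is costly.
Because CYP activities are correlated — shared regulation, shared redox
partners, correlated expression — the activities of some isoforms can be
predicted from others. `cypivive` implements a three-stage workflow on this
idea:

1. **Kinetics** — summarise each measured CYP's probe-substrate incubation
   series as Michaelis–Menten parameters (V_max, K_m) and intrinsic
   clearance CL_int = V_max/K_m;
2. **Descriptive models** — predict V_max and CL_int of CYP2A6, 2C8, 2D6,
   2E1 and 3A4/5 from the same parameter of the measured CYP1A2, 2B6, 2C9
   and 2C19, by a registry of linear models;
3. **CBC-IVIVE** — scale CL_int to whole-liver, unbound-in-blood units and
   convert to CL_H with a bias-corrected well-stirred model.

A synthetic cohort generator reproduces the statistical shape of the
105-donor human-liver-microsome cohort behind the shipped registry, so every
stage is exercised end to end by code alone.

## Michaelis–Menten fitting

`mm_fit()` minimises unweighted squared error of v = V_max·S/(K_m+S) with
bounded Levenberg–Marquardt (`minpack.lm::nlsLM`): V_max ∈ (0, 10·max(v)],
K_m ∈ (0, 10·max(S)], started at V_max₀ = max(v) and K_m₀ = the substrate
concentration nearest half-maximal observed velocity. Replicate velocities
at identical S are averaged before fitting (the default convention when a
series contains replicate incubations). No weighting scheme is applied —
with 6–8 points per series and multiplicative noise of a few percent,
weighting choices move estimates far less than assay noise does.

Two numerical choices deserve note:

* **Degenerate surfaces.** A fully saturated series (all S ≫ K_m, flat
  velocities) has its least-squares optimum on the K_m → 0 boundary, where
  the LM step can fail outright. `mm_fit()` then falls back to profiling:
  conditional on K_m, the optimal V_max is the closed-form linear solution,
  so the SSE is profiled over a log-spaced K_m grid and refined by
  one-dimensional optimisation. The `converged` flag is `FALSE` whenever the
  optimiser failed or an estimate sits on a box bound, so boundary behaviour
  is never silent.
* **Identity by construction.** `clint` is always computed as `vmax/km`
  (units: (pmol/min/mg)/(µmol/L) = µl/min/mg), never fitted separately, so
  the ratio identity holds exactly in every result.

## Stepwise descriptive models

`stepwise_fit()` follows the classic SPSS convention: at each iteration the
candidate with the smallest partial-F p-value enters if p ≤ `p_enter`
(default 0.05); entered terms with partial-F p ≥ `p_remove` (default 0.10)
are then removed one at a time, worst first; the loop stops when neither
step changes the model, with a guard at 2·|candidates| iterations (and
`p_remove > p_enter` is enforced, which rules out entry/removal cycles). An
intercept-only model is a legitimate outcome. Partial-F p-values are taken
from the coefficient t-tests of the embedding `lm` fit, which are identical
to single-term partial F tests; the test suite checks the selected sets
against an independent re-implementation built on explicit normal-equation
algebra.

The shipped registry (`published_models()`) holds the eleven published
models: five for V_max and five for CL_int (responses 2A6, 2C8, 2D6, 2E1,
3A4/5) plus one K_m model (3A4/5). Three design points:

* **Parameter homogeneity.** V_max models use predictor V_max values,
  CL_int models predictor CL_int values: each kinetic parameter forms its
  own dataset.
* **K_m by ratio, not regression.** `predict_cohort()` deliberately ignores
  the registry's K_m regression and derives K_m = V_max/CL_int
  (`derive_km()`). The ratio keeps the three predicted parameters mutually
  consistent, is defined for all five responses, and cannot go negative —
  the lone K_m regression (negative slope in 1A2) can.
* **No clamping.** A linear model can return a negative activity for
  extreme inputs. Predictions are returned unclamped with a structured
  warning; silently clamping would distort every quantity downstream. Only
  at the clearance-extrapolation boundary are negative CL_int values floored
  at zero (again with a warning), because a negative whole-organ clearance
  is physically meaningless.

Subjects missing a required predictor are dropped per response with a
logged count. `model_stats()` provides the F and adjusted-R² identities
used to validate registry entries: F = (R²/k)/((1−R²)/(n−k−1)),
R²_adj = 1−(1−R²)(n−1)/(n−k−1).

`minimal_predictor_set()` answers "which CYPs must actually be measured":
the smallest set M such that every response has a model whose predictors lie
in M, found by exhaustive subset enumeration (the universe is at most ten
CYPs, so 2¹⁰ subsets; ties break lexicographically). On the published V_max
and CL_int families it returns {1A2, 2B6, 2C9, 2C19}.

Prediction intervals (`prediction_interval()`) are standard new-observation
intervals of the underlying `lm`; they require the training data and are
therefore available only for models fitted in-session, not for the published
registry (whose individual-level data are not distributed).

## CBC-IVIVE clearance

The scaling and clearance equations are

* Q_H = 0.245 · cardiac output (ml/min),
* LW = (12.5 · BW + 536.4) · 1.001 (g, via liver volume and density),
* X = CL_int · MPPGL · LW · (f_u,p / R_B) / 1000 (ml/min),
* CL_H = CC · Q_H · X / (Q_H + X).

**Absolute flow units.** Some statements of the scaling multiply by LW/BW,
i.e. liver weight per kilogram body weight. In a well-stirred balance X must
be commensurable with Q_H, which is in absolute ml/min; dividing by BW would
produce ml/min/kg against ml/min and misstate clearances by a factor of
~60–70. The default therefore uses absolute flow (LW in g, no BW division),
which reproduces the published clearance magnitudes; `per_bw = TRUE` exposes
the literal per-kilogram variant for auditability. A unit audit is part of
the test suite: CL_int = 1 µl/min/mg, MPPGL = 1000 mg/g, LW = 1000 g,
f_u,p/R_B = 1 gives exactly 1000 ml/min.

The drug table (`published_drugs()`) fixes the probe-drug-to-CYP map
(coumarin→2A6, paclitaxel→2C8, dextromethorphan→2D6, chlorzoxazone→2E1,
midazolam→3A4/5) and each drug's CC, f_u,p, R_B and literature-observed
clearance. CC is the empirical bias-correction of conventional IVIVE and is
treated as a given constant per drug.

## Accuracy statistics

AFE and IFE are geometric-mean fold-errors against the observed report
means: AFE = 10^((1/N)·Σ log₁₀(predicted mean / observed mean_r)), IFE the
per-subject analogue. Both reduce to a plain ratio against a single pooled
mean when only one report is available, so the functions accept either a
vector of report means or one pooled value. The 2-fold window is the
*closed* interval [0.5, 2]: the convention is symmetric on the log scale and
reciprocal-invariant, and boundary cases are counted in (the open/closed
choice moves results only when a ratio is exactly 0.5 or 2).

Distribution comparisons use the Mann–Whitney U test (exact enumeration for
untied samples with min(n) ≤ 8, otherwise the tie-corrected normal
approximation without continuity correction), Pearson's χ² on 2×2
concordance tables (no continuity correction by default, matching the
"Pearson Chi-Square" convention; Yates correction available), and a
normality screen running both Shapiro–Wilk and the Lilliefors variant of
Kolmogorov–Smirnov (`nortest::lillie.test`, i.e. the KS test with estimated
parameters, as statistical packages report it). A constant sample is
reported with p = 0 by convention — degenerate, treated as non-normal.
Rank-based comparisons are the default downstream because microsomal
activity distributions are strongly right-skewed and typically fail both
tests.

## The synthetic cohort generator

`generate_cohort()` emulates the reference cohort's statistical structure;
its defaults *are* the study conditions and are not meant to be tuned:

* **Demographics.** Female fraction 0.648; age groups at the published
  prevalences; smoking and drinking at 12/101 with four missing values,
  mirroring the reference table's incomplete covariates.
* **Marginals.** Body weight (median 64.0, range 30.0–92.0 kg), MPPGL
  (39.6, 9.9–127.9 mg/g) and the four measured CYPs' V_max and CL_int
  (published medians/ranges) are truncated lognormals: the simplest
  positive, right-skewed family, consistent with the non-normality of the
  real data. With only a median and range published, sdlog comes from a 99%
  central-span heuristic, sdlog = (log max − log min)/(2·z₀.₉₉₅), and
  meanlog is root-found so the *truncated* median equals the published
  median exactly in distribution — necessary because several medians sit far
  off the geometric centre of their range (CL_int of 2C19: median 1.91 in
  0.01–7.46).
* **Physiology.** Q_H is 0.245 × cardiac output, with cardiac output drawn
  from gender-specific truncated normals (female N(4930, 250), male
  N(5150, 400) ml/min, truncated to the range implied by the published Q_H
  range). The reference values behind the published cardiac outputs are not
  distributed, so these two distributions were calibrated once,
  analytically, to put the mixture median of Q_H at 1259.3 ml/min; the
  published Q_H range (1205.4–1629.3, median barely above the minimum)
  implies exactly this strongly right-skewed shape. Liver weight is always
  derived from body weight through the liver-weight model.
* **Correlation.** Cross-CYP correlation is induced solely by the published
  linear backbone: each predicted CYP's V_max and CL_int is its registry
  model evaluated on the drawn driver activities plus independent Gaussian
  noise, with the noise variance set from the empirical variance of the
  linear predictor so the population R² equals the model's published R².
  K_m is V_max/CL_int throughout, so the kinetic identity holds for every
  subject by construction. No residual correlation beyond the backbone is
  modelled, because none is documented.
* **Positivity.** Additive Gaussian noise can push an activity below zero;
  such draws are redrawn (up to 100 times, then the calibration is declared
  infeasible). This truncation is not free: it raises the conditional mean
  of low-linear-predictor subjects and thereby *attenuates* the realised
  regression slopes relative to the generative coefficients. For the
  CL_int(2C8)~CL_int(2C9) pair the expected OLS slope at n = 10,000 is
  ≈ 0.82 against the generative 0.862; the attenuation is reproduced
  exactly by the analytic truncated-normal mean
  E[y|x] = lin + σ·φ(lin/σ)/Φ(lin/σ), which is what the tests check against.
  For backbones with weak R² and wide-range lognormal predictors (the 2A6
  V_max model), a quarter or more of draws are redrawn, the attenuation is
  large, and stepwise refits recover the generative coefficient within
  their own confidence intervals noticeably less often than the nominal
  rate. This is an inherent property of "linear backbone + additive noise +
  positivity" generation, worth keeping in mind when interpreting recovery
  experiments.

What passing tests on this generator do **not** show about real data: real
activity distributions need not be lognormal, real cross-CYP correlation is
not exhausted by the published models (the backbone enforces exactly the
published R², no more structure), genotype, smoking and disease effects are
absent, and measured-vs-predicted comparisons on synthetic cohorts inherit
the generator's assumptions. The generator validates the *pipeline*, not the
biology.

`generate_kinetic_curves()` produces incubation series on each probe's
published concentration span (serial dilutions, 6–8 points, e.g.
0.39–50 µM for midazolam) with multiplicative Gaussian noise (default CV
5%), for round-trip tests of the kinetic fitter.

## Recovery experiments and problem sizes

The suite's cohort-level checks use n = 10,000 draws for calibration
(medians within 3%, R² within 0.03) and 200 seeded replicates of n = 105
cohorts for stepwise recovery — sizes at which Monte-Carlo error is small
relative to the tolerances while the whole suite stays quick. The recovery
experiment asks, per published single-predictor model: how often does
stepwise selection return exactly the true predictor set, and how often does
the fitted 95% CI cover the generative coefficient? Three forces cap these
rates below ideal: the power of the p ≤ 0.05 entry test at the published
effect sizes (population R² of 0.041 gives ≈ 55% power at n = 105 — no
selection procedure honouring the entry threshold can do better), spurious
entries among the three null candidates (≈ 14% of replicates admit at least
one), and the positivity-truncation slope attenuation described above. The
strong-signal models (R² ≥ 0.17) recover their predictor in essentially
every replicate.

## Known limitations

* The published registry carries no training data, so prediction intervals
  and refitting are only available for models fitted in-session.
* Atypical kinetics (Hill, substrate inhibition, multi-enzyme curves) are
  out of scope for the fitter; only the hyperbolic model is supported.
* The CBC-IVIVE chain covers hepatic, CYP-mediated clearance only — no
  renal or biliary routes, no parallel-tube or dispersion liver models, no
  drug–drug interaction scaling.
* Fold-error accuracy against observed clearances treats the literature
  report means as fixed references; report-level variability enters only
  through the geometric mean.
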