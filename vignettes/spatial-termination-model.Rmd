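---
title: "Bayesian spatial logistic regression for areal survey data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian spatial logistic regression for areal survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

National household surveys of reproductive health record binary outcomes
(here: whether an ever-married woman of reproductive age has ever had a
pregnancy terminated) together with individual socio-demographic covariates,
a district of residence, and a sampling weight. Two scientific questions
drive the analysis: which individual characteristics are associated with the
outcome, and whether residual geographic structure remains after adjusting
for them — that is, whether women in neighbouring districts are more alike
than covariates explain, and which districts carry significantly elevated
residual risk.

`spatlogit` implements the full workflow for this design: a survey-weighted
Bayesian logistic regression with district-level spatial random effects,
nonlinear age effects, model selection by WAIC, multicollinearity screening
by GVIF, prior-sensitivity sweeps, and exceedance-probability risk maps,
together with a synthetic-data generator that provides ground truth for
every stage.

## The model

For individual $i$ in district $j$,

$$\mathrm{logit}(p_{ij}) = \mathbf{Z}_{ij}^T\boldsymbol\beta
  + s(t_{ij}) + \phi(t'_{ij}) + b_j + h_j,$$

where $\mathbf{Z}$ collects the categorical covariates in reference-cell
coding (plus the intercept), $t$ is age at survey time, $t'$ is age at first
cohabitation, $b_j$ is a spatially structured district effect and $h_j$ an
unstructured one (the BYM convolution). The components:

* **Fixed effects.** $\beta_k \sim N(0, 10^6)$, vague by construction.
* **Nonlinear age effects.** $s(\cdot)$ and $\phi(\cdot)$ are random-walk
  smooths over the ranked, binned covariate values ("knots"): RW1 penalizes
  first differences of consecutive knot effects, RW2 second differences.
  Ages are floor-binned (1-year bins by default, capped at 60 knots; ties
  share a knot); spacing between knots is ignored, i.e. a unit-spacing walk.
  Each smooth has a precision $\tau_s$.
* **Spatial effect.** $b$ has an intrinsic CAR (Besag) prior: conditionally,
  $b_j \mid b_{-j} \sim N(\bar b_j, \sigma_b^2/m_j)$ with $\bar b_j$ the
  mean over the $m_j$ adjacent districts. This is the conditional-variance
  parameterization — no marginal (Riebler-type) rescaling. Two districts are
  adjacent when they share a boundary.
* **Unstructured effect.** $h_j \sim N(0, \sigma_h^2)$ i.i.d.
* **Variance components.** Each precision $\tau = 1/\sigma^2$ carries a
  Gamma$(a_1 = 1, a_2 = 10^{-5})$ prior by default (an essentially flat
  exponential on the precision). For sensitivity analyses the prior can be
  placed on the sd scale instead: half-normal, half-Cauchy, half-$t$,
  uniform, or penalized-complexity (exponential on $\sigma$ with rate
  $-\log\alpha/u$).
* **Survey weights.** The log-likelihood of record $i$ is multiplied by its
  sampling weight $w_i$ (pseudo-likelihood). Weights are normalized to mean
  1 by default so the weighted likelihood carries the same effective sample
  size as the unweighted one; `normalize_weights = FALSE` disables this.

### Identifiability

The ICAR prior and both RW priors are improper (rank-deficient): constants
(and, for RW2, linear trends) are unpenalized, and would be confounded with
the intercept. The package resolves this with hard sum-to-zero constraints:
each draw of $b$ and of each smooth is centered, with the removed level
transferred to the intercept, so the linear predictor is unchanged and every
stored draw of $b$ sums to zero exactly. The IID effect $h$ is proper and
stays unconstrained.

## Inference: Pólya-Gamma Gibbs sampling

The posterior is sampled by a blocked Gibbs sampler built on Pólya-Gamma
augmentation: given $\omega_i \sim \mathrm{PG}(w_i, \eta_i)$, every Gaussian
block ($\beta$, each smooth, $b$, $h$) has a conjugate multivariate-normal
full conditional, and the precisions are conjugate gamma draws (or
Metropolis steps on $\log\sigma$ for sd-scale prior families). This targets
the same posterior a Laplace-approximation engine would approximate, without
inheriting any particular approximation's error characteristics.

Implementation points that matter in practice:

* $\mathrm{PG}(1, z)$ (the unit-weight case) is drawn exactly with Devroye's
  alternating-series rejection sampler. $\mathrm{PG}(w, z)$ for non-integer
  weights uses the sum-of-gammas series truncated at 40 terms with the
  dropped tail replaced by its analytic mean; the samplers are validated
  against the closed-form mean $\mathbb{E}[\mathrm{PG}(b,z)] = b\tanh(z/2)/(2z)$.
* The conditional update $\tau \mid \text{field}$ mixes very slowly between
  the "field ≈ 0, $\sigma$ tiny" and "field active" regimes — with weak
  spatial signal the chain can sit in the degenerate mode for thousands of
  iterations. The sampler therefore adds a joint **scale move** after every
  variance update: propose $(x, \tau) \to (cx, \tau/c^2)$ with
  $\log c \sim N(0, 0.4^2)$, which leaves the GMRF quadratic form invariant
  and is accepted by an exact Metropolis ratio involving only the weighted
  Bernoulli likelihood and the prior. This is the rescaling analogue of
  ancillarity-sufficiency interweaving and removes the sticky-mode
  behaviour.
* Chains are seeded deterministically (chain $c$ uses
  `seed + 1000 * (c-1)`); fixed seed and chain count give bit-identical
  draws. Split-chain $\widehat R$ and a Geyer-style effective sample size
  are reported per parameter.

The posterior summaries are means, sds, and equal-tailed 95% intervals —
matching the reporting conventions of the study design this package
addresses (posterior means, "95% CI").

## Model selection

WAIC is computed from the weighted pointwise log predictive density matrix
$ld_{si} = w_i \log \mathrm{Bern}(y_i \mid p_i^{(s)})$ as

$$\mathrm{lppd} = \sum_i \log \tfrac1S \sum_s e^{ld_{si}},\qquad
  p_D = \sum_i \mathrm{var}_s(ld_{si}),\qquad
  \mathrm{WAIC} = -2(\mathrm{lppd} - p_D).$$

The deviance-scale convention is used deliberately: reported WAIC magnitudes
in this literature (tens of thousands at $n \approx 18{,}000$) are on the
deviance scale, so "LPD + penalty" formulations are read as $-2\cdot$lppd.
Smaller is better; models within 2 units are treated as fitting similarly.

Three selection tools share this machinery, all running candidate fits at
identical sampler settings and a seed schedule derived from one master seed:

* `structure_ladder()` fits NO / IID / CAR / CAR+IID and picks the best by
  the 2-unit rule with a parsimony tie-break (fewest effective parameters
  among similar fits).
* `backward_select()` repeatedly removes the covariate whose removal gives
  the lowest WAIC, accepting the removal when the reduced model fits
  similarly to or better than the current one (WAIC below current + 2).
  The rationale: a 1-df null covariate lowers WAIC by only ≈ 1 in
  expectation when dropped, so demanding a strict 2-unit *improvement*
  would never drop anything; the similar-fit reading — equal predictive
  accuracy with fewer parameters wins — both drops null covariates and
  retains informative ones, which is the behaviour a manual backward search
  guided by the 2-unit rule-of-thumb would produce.
* `sensitivity_sweep()` refits one model under each precision-prior family
  and tabulates the variance-component posteriors and WAICs;
  `linearity_comparison()` pairs fixed-effect odds ratios under linear
  versus RW1 age treatments (the misspecification report).

## Diagnostics and risk mapping

* `compute_gvif()` implements the generalized variance inflation factor
  $\mathrm{GVIF} = \det(R_{11})\det(R_{22})/\det(R)$ on the correlation
  matrix of the pooled dummy design (unweighted — screening happens before
  the weighted model), reported on the $\mathrm{GVIF}^{1/(2\,df)}$ scale
  against the 1.58 rule-of-thumb cutoff ($\sqrt{2.5}$). Rank-deficient
  designs yield infinite GVIF with the collinear covariate set identified.
  The implementation is cross-checked against `car::vif` in the test suite.
* `exceedance()` reports $q_j = P(e^{b_j} > 1) = P(b_j > 0)$ as the
  fraction of posterior draws above zero; districts with $q_j > 0.90$
  (strict) are flagged as significantly elevated.
* `district_risk_map()` adds posterior mean/sd of $b_j$ and the mean/sd of
  per-record posterior predictive probabilities within each district;
  districts without records keep their $b$ summaries and carry NA
  probability fields.
* `descriptive_table()` produces the frequency / column-% / row-% table
  with medians and IQRs for continuous covariates, unweighted by default
  (a weighted variant is available), percentages rounded to 2 decimals.

## The synthetic-data generator

`simulate_survey()` is first-class, tested code: it generates the exact
structure the model assumes, so every downstream stage can be validated
against known truth. Its defaults *are* the emulated study conditions:

* 64 districts (8×8 rook lattice — same cardinality and a connected,
  desk-scale stand-in for a national district map; arbitrary graphs are
  accepted via edge lists or GeoJSON).
* Prevalence calibrated to 19.44% through the intercept (the generator
  solves for the intercept given the covariate mix and effect sizes).
* Covariate mixes at the survey's descriptive proportions (65.4% rural,
  31.5% working, near-uniform wealth quintiles, 94.2% married, parity
  peaking at two children), with effects at the study's adjusted
  odds-ratio scale (working 1.19, richest 1.26, widowed 0.41, ...).
* Age at first cohabitation on a 0.25-year grid in [10, 35] (gamma-shaped,
  median ≈ 16); age at survey = cohabitation age + uniform duration,
  truncated to [15, 49].
* A rise-then-plateau age-at-survey effect (0.2 log-odds per year up to age
  25, flat after) and a decline-then-plateau cohabitation-age effect
  (−0.08/yr to age 22). The rise amplitude (≈ 2 log-odds in total) reflects
  a strong risk-time effect, consistent with the reported magnitude of the
  nonlinear survey-age component being an order of magnitude larger than
  the cohabitation-age component; both smooths are centered over the
  realized ages.
* $\sigma_b = 0.44$, $\sigma_h = 0.25$ (log-odds scale); the ICAR field is
  drawn exactly by eigendecomposition of the precision on the sum-to-zero
  subspace.
* Stratified weights emulate unequal selection: inverse synthetic selection
  probabilities (varying by district and urban residence), clamped to
  [0.3, 3] and rescaled to mean 1. The dispersion is a free choice — the
  emulated survey does not publish its weight distribution. Only the
  resulting weights are emulated, not the two-stage cluster mechanics, so
  design-based variance estimation is out of scope by construction.

What passing tests on these data do **not** show: robustness to informative
missingness, to misspecified adjacency, to cluster-level dependence beyond
the district effects, or to outcome misreporting — none of which the
generator produces.

## Numerical and design choices

* **Problem sizes in the test suite.** Parameter recovery runs 20 replicates
  of the 64-district × 300-record design; the model-selection behaviour
  suite runs 10 replicates × 4 structures at 80 records/district; the
  nonlinearity recovery runs one 192,000-record fit with 2-year knot bins —
  the knot resolution matched to the per-knot information the experiment
  needs. These sizes were chosen as the smallest designs at which the
  studied effects are statistically decisive.
* **Small-field shrinkage.** With weak spatial signal relative to the
  per-district noise, the posterior for $\sigma_b$ genuinely concentrates
  near zero (the gamma(1, 1e-5) prior places substantial mass on tiny
  $\sigma$); this is correct behaviour on null data and a caution when
  hunting single hot-spots in small graphs.
* **Degenerate inputs.** Disconnected graphs are rejected for CAR/ICAR
  work (no silent per-component handling); constant smooth covariates
  collapse to the intercept with a warning; missing values are excluded
  listwise with the exclusion count reported.
* **Ties and ordering.** Design columns follow the declared covariate and
  category order; knots are the sorted unique bins; the ladder's tie-break
  is the effective parameter count. The CAR-vs-CAR+IID distinction is not
  identified when the truth has $\sigma_h = 0$ — their WAICs tie to within
  Monte-Carlo noise, and either label is an acceptable selection.
* **Repository shape.** The package is organised as an analysis compendium:
  the numbered scripts under `analysis/` narrate the workflow (simulate →
  screen → select → fit → sensitivity → map) and write their tables under
  `results/`; all computation lives in the package functions, and
  `run_pipeline()` executes the same sequence from a single YAML config
  with a manifest and resumability. No shell CLI is shipped — the scripts,
  functions, and this vignette are the interface.

## Known limitations

* The GeoJSON reader derives adjacency from exactly shared polygon edge
  segments (after coordinate rounding). Well-noded administrative boundary
  files satisfy this; sliver polygons or mismatched digitizations need a
  full geometry engine and are out of scope.
* The pseudo-likelihood treats weights as likelihood exponents; it does not
  produce design-based standard errors.
* WAIC is the only predictive criterion implemented (no DIC,
  cross-validation, or Bayes factors).
* Interaction terms are not supported in the design builder.
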