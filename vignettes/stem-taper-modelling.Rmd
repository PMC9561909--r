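---
title: "Stem taper modelling with stand-density effects: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem taper modelling with stand-density effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemtaper)
```

## The problem

A stem taper equation predicts over-bark diameter $d$ (cm) at any height
$h$ (m) along a tree bole from diameter at breast height $D$ (cm, at
1.3 m) and total height $H$ (m). Accurate taper curves underpin
merchantable-volume estimation, bucking optimisation and growth-and-yield
work in plantation forestry. This package implements the
variable-exponent family of taper equations, in which a single continuous
function covers the neiloid butt, the paraboloid mid-stem and the conic
tip by letting the exponent of a taper ratio vary along the stem, and
asks how stand density — trees per hectare ($S_d$), basal area ($BA$,
m²/ha) or canopy density ($C_d$) — modifies the stem form, and which
estimation technique (pooled nonlinear least squares, tree-level
nonlinear mixed effects, or nonlinear quantile regression) best exploits
stem-analysis data.

## The core model

The Kozak (2004) Model II form is the package's centrepiece:

$$d = b_1 D^{b_2} H^{b_3} Z^{E}, \qquad
  Z = \frac{1 - T^{1/3}}{1 - X^{1/3}},$$

with relative height $T = h/H$, relative breast height $X = 1.3/H$,
$Q = 1 - T^{1/3}$ and

$$E = b_4 T^4 + b_5 e^{-D/H} + b_6 Z^{0.1} + b_7/D + b_8 H^{Q} + b_9 Z
      \;+\; b_{10}\, g(\text{density}).$$

Two structural identities follow directly and are enforced by tests at
machine precision: at breast height $Z = 1$ exactly, so
$d(1.3) = b_1 D^{b_2} H^{b_3}$ whatever the exponent coefficients; at
the tip $Z = 0$, so $d(H) = 0$ whenever $E > 0$ there.

The density term $g$ takes one of eight forms ($b_{10} BA$,
$b_{10} C_d$, $b_{10} S_d$, $b_{10}/S_d$, $b_{10}/S_d^2$,
$b_{10}/\sqrt{S_d}$, $b_{10}/\ln S_d$, $b_{10}/S_d^{1/3}$); the
reciprocal form $b_{10}/S_d$ is the canonical default. Twelve classical
base forms are registered alongside (`list_models()`), spanning the
Kozak 1988/2002/2004 lineages, Bi's trigonometric form, polynomial-
exponent forms, and two dimensionally compatible Sharma–Zhang-type
forms. Several of the non-Kozak entries circulate in typographically
inconsistent variants in the applied literature; each registry entry
therefore records the exact algebra adopted (`taper_model(key)$formula`),
flags entries where transcription involved a judgement call, and records
in `tip_zero` whether its adopted algebra forces a zero tip under the
entry's reference coefficients. One eight-parameter entry has a negative
tip exponent at its reference coefficients (the predicted tip diameter
diverges rather than vanishing); it is kept, flagged, because the
comparison workflow needs runnable competitors, not because the form is
recommended. The `b10 * Sd` density variant similarly loses its
guaranteed zero tip at moderate densities.

## Estimation engines

**Nonlinear least squares** (`fit_taper_nls()`) pools all section
measurements and minimises the residual sum of squares by
Levenberg–Marquardt iteration (via `minpack.lm`), with approximate
standard errors from $s^2 (J^\top J)^{-1}$. Defaults: relative-RSS
tolerance 1e-10, gradient tolerance 1e-8, 500-iteration cap, start
values at the registry's published reference coefficients. An inflection
parameter $p$, where a form has one, is treated as estimable inside
(0, 1) — its published value is a start, not a constant. The
log-likelihood reported everywhere is the concentrated Gaussian value
$\ln L = -(n/2)[\ln 2\pi + \ln(\mathrm{RSS}/n) + 1]$, so information
criteria decrease as fit improves.

**Tree-level nonlinear mixed effects** (`fit_taper_nlme()`). Random
effects $u_j \sim N(0, \mathbf D)$ perturb one or two selected
coefficients additively ($\beta + u_j$), grouped by tree — the tree is
the natural unit because the eleven sections of one stem are strongly
dependent. The marginal likelihood integrates $u_j$ out per tree by a
Laplace approximation around the posterior mode; the mode search is a
damped Gauss–Newton iteration vectorised across all trees at once, with
analytic coefficient gradients for the Kozak-2004 family and central
finite differences otherwise. The Gauss–Newton Hessian
$J^\top J/\sigma^2 + \mathbf D^{-1}$ enters the Laplace determinant; it
is exact whenever the model is linear in $u$, which is what makes the
closed-form linear-mixed-model oracle test exact to 1e-8. The outer
optimisation runs over the fixed effects (preconditioned by their
approximate NLS standard-error scales — the variable-exponent
coefficients are highly collinear and unscaled steps crawl along the
likelihood ridge), a log-Cholesky parameterisation of $\mathbf D$ (so
every iterate is symmetric positive definite by construction), and
$\log\sigma$. Tolerances: 1e-9 on the inner modes, 1e-6 relative
log-likelihood outer, 300 outer iterations. Variance collapse
($\sigma_k^2 \to 0$) is reported as a boundary fit, not an error. The
within-tree covariance is $\sigma^2 I$ by default — no variance function
or correlation structure is fitted, because the workflow this package
reproduces reports only a scalar residual variance; the machinery keeps
the general $\sigma^2 G^{1/2} \Gamma G^{1/2}$ form conceptually in view
but deliberately does not expose unused structure. The
information-criterion parameter count is
$\lambda = p + q(q+1)/2 + 1$ (fixed effects, free covariance components,
residual variance); NLS fits count $\lambda = p + 1$ so the two engines
are compared on the same convention.

`rank_placements()` fits every requested placement of one or two random
effects (all 55 subsets of ten coefficients by default,
`enumerate_random_subsets()`), keeps non-converged rows flagged rather
than dropping them, and marks the converged minimum-AIC row, with ties
broken by BIC and then by parsimony.

**Nonlinear quantile regression** (`fit_taper_quantile()`). The
$\tau$-th quantile surface minimises the check (pinball) loss
$\sum_i \rho_\tau(d_i - f_i)$. The kink is handled by smoothing
continuation: the convex surrogate
$\tau r + \delta \log(1 + e^{-r/\delta})$ converges to the check loss as
$\delta \to 0$, so BFGS minimises it at $\delta = 0.1, 0.01, 0.001$ cm
(each stage warm-started), and a Nelder–Mead polish then runs on the
exact loss. The returned point is never worse, in exact loss, than its
start — an explicit contract checked at run time. `quantile_sweep()`
fits the nine-level grid $\tau = 0.1, \dots, 0.9$, warm-starting each
level from its neighbour, and diagnoses quantile crossing (a lower-$\tau$
surface exceeding a higher-$\tau$ one) by counting violations over all
section rows and ordered level pairs; crossings are reported, never
corrected.

## Evaluation statistics

`fit_statistics()` computes MAB, RMSE, MPB, signed Bias, $R^2$, adjusted
$R^2$, the concentrated Gaussian log-likelihood, AIC and BIC. Two
conventions deserve notice. RMSE uses an $n-1$ denominator — kept for
comparability with the taper literature that defines it so; tools using
$n$ will differ by a factor $\sqrt{(n-1)/n}$. MAB and MPB are
absolute-deviation statistics (strictly positive for imperfect fits)
while Bias is signed; the BIC sample size is the number of section
observations, not trees. `error_by_height_class()` summarises errors in
left-open, right-closed relative-height bins (the upper stem is
$0.7 < T \le 1$), retaining empty bins with $n = 0$.

## The synthetic generator

No stem-analysis archive accompanies the study design this package
emulates, so `simulate_taper_data()` is a first-class module, not a test
fixture. Its defaults are the study conditions: 132 plots × 3
destructively sampled trees, diameters at 5, 10, 15, 20, 30, 40, 50, 60,
70, 80 and 90 % of total height, generating coefficients equal to the
supported fit of the density-augmented model
(b₁…b₁₀ = 0.9913, 0.9227, 0.0688, 0.6625, −0.7874, 0.5001, 2.4607,
0.0099, −0.0785, 0.3470 with the $1/S_d$ form), tree-level random
effects on $b_6$ and $b_8$, and residual SD $\sqrt{0.5791}$ cm.

Distributional choices the design leaves open were fixed once:

* **DBH** is drawn from a normal truncated to 15.1–28.8 cm whose
  pre-truncation parameters (μ₀ = 20.027, σ₀ = 4.895) were calibrated by
  root-finding so the *truncated* marginal has mean 21.0 and SD 3.4 cm —
  naively plugging the target moments into the parent normal would
  shrink the sample SD by ~13 %.
* **Height** follows a Chapman–Richards-type curve
  $H = 1.3 + 19.65\,(1 - e^{-0.09 D})^{1.235}\,\varepsilon$ with
  lognormal $\varepsilon$ (τ = 0.141), clamped to 10.4–22.8 m; the
  constants were calibrated once against the DBH distribution so the H
  marginal approximates mean 17.2, SD 2.5 m.
* **Stand covariates**: $S_d \sim U(90, 2580)$ trees/ha; BA and $C_d$
  are monotone noisy maps of $S_d$ into 10.6–67.7 m²/ha and 0.2–0.9.
  $C_d$ is treated as a fraction; the printed dispersion statistics for
  canopy density in the source tables are only consistent with a percent
  scale and are not reproduced.
* **Random-effect scales** default to SDs of 0.02 on $b_6$ and 0.002 on
  $b_8$ (≈ 4 % and 20 % of the coefficient magnitudes, uncorrelated).
  The printed variance components of the reference mixed fit could not
  be used as truth: they include a negative "variance", an evident
  erratum, so plausible scales relative to the coefficients were chosen
  instead and documented here.
* Negative section draws are truncated at zero rather than redrawn
  (rare: they occur only near the tip at the default noise scale).
  No breast-height section row is emitted by default — the measurement
  protocol lists only relative heights — but `include_dbh_section = TRUE`
  adds one for calibration exercises.

What the generator does **not** emulate: bark thickness, stem
irregularities (sweep, forks, buttressing), measurement error in $D$ and
$H$ themselves, spatial structure among plots, and any density effect
beyond the single exponent term. Tests passing on this generator
therefore certify the estimators and workflow, not the biology of any
particular plantation.

## Identifiability: what recovery tests can and cannot show

Two quantitative limitations emerged from the package's own recovery
experiments, and they are properties of the model at this design, not of
the estimators.

First, the exponent terms $H^Q$, $Z$, $1/D$ and the density term are
strongly collinear over the realistic covariate ranges. At 132 trees the
likelihood surface has a long flat ridge: the fitted *surface* recovers
the generating surface to well under 0.1 cm RMSE (the acceptance script
computes this), while individual coefficients along the ridge — $b_8$,
$b_9$, $b_{10}$ especially — can sit far from their generating values
with little likelihood cost. Coefficient-wise recovery assertions at
tight relative tolerances are therefore expected to fail at this design
size even for a correct estimator, and the same trade-off redistributes
random-effect variance between $u_6$ and $u_8$ (with a compensating
negative covariance). A well-identified control — a random effect on the
overall scale coefficient $b_1$ — recovers its variance closely, which
is the relevant evidence that the machinery itself is sound.

Second, the $1/S_d$ density term at its supported magnitude
($b_{10} = 0.347$) moves the exponent by at most
$0.347/90 \approx 3.9\times10^{-3}$ and varies between plots by a few
$10^{-4}$, i.e. a few hundredths of a centimetre of diameter — two
orders of magnitude below the residual SD of 0.76 cm. Synthetic data
generated at these exact conditions therefore cannot discriminate the
density forms: the base model typically wins the AIC comparison by
exactly the parameter penalty, and the null-calibration check (no
spurious preference under a zero density effect) is the meaningful one.
On real data, apparent density effects of practical size must come from
somewhere other than a term of this magnitude — a caution worth carrying
into applications.

## Problem sizes used by the test suite

The suite exercises the estimators at the full 396-tree design where the
quantity under test depends on it (generator design reproduction,
quantile coverage at ~4,356 sections, noiseless NLS recovery) and at
reduced designs elsewhere (30–132 trees for mixed fits; a four-candidate
placement search over five seeds), sizes chosen so the whole suite runs
comfortably on a single CPU while keeping every Monte-Carlo tolerance at
its stated value.

## Known limitations

* Only tree-level grouping is supported; plot-within-stand nesting is
  out of scope.
* The Laplace approximation is first-order; no adaptive quadrature.
* Quantile fits are local minimisers of a non-convex objective (the
  model is nonlinear in its parameters); the continuation schedule and
  never-worse-than-start contract are pragmatic safeguards, not global
  guarantees.
* Volume integration and merchantable-height inversion are deliberately
  not provided.
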