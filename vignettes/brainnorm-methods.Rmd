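---
title: "Distributional normative models of brain morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional normative models of brain morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainnorm)
```

## The model

brainnorm fits, independently for every region x hemisphere x metric, a
four-parameter distributional regression of the base-10 log of the
measure. Log transformation puts metrics of different dimensionality
(thickness in mm, areas in mm^2, volumes in mm^3) on a common scale, so
the same model machinery applies to all of them; the folding components
K, I, and S are already logarithmic quantities and are modelled as-is.

The response follows the sinh-arcsinh (SHASH) location-scale family of
Jones & Pewsey: with $z = (y - \mu)/\sigma$,

$$Z \;=\; \sinh\!\big(\tau \,\mathrm{asinh}(z) - \nu\big) \;\sim\; N(0, 1).$$

$\nu$ controls skew (0 = symmetric) and $\tau > 0$ tail weight (1 =
normal); at $\nu = 0,\ \tau = 1$ the family is exactly Gaussian. The
family was chosen because it covers skew and kurtosis with two
interpretable parameters and its quantiles are closed-form through the
normal CDF, which makes centile computation exact and fast. A Gaussian
family is available behind the same interface (`bn_family("normal")`);
it both demonstrates that the family is pluggable and serves as the
reduction used in several tests. A Box–Cox-type power-exponential family
would be a natural third option; we chose the Gaussian as the second
implementation because it is simultaneously the reduction the SHASH
family must reproduce exactly, so one implementation does double duty.

Each distribution parameter has its own additive predictor, mirroring
standard growth-chart practice:

* **location** $\mu$: intercept + cubic B-spline in age + sex (fixed
  effect) + site (random intercept);
* **scale** $\log\sigma$: same structure (log link keeps
  $\sigma > 0$);
* **skew** $\nu$: intercept + age spline + sex;
* **tail weight** $\log\tau$: intercept + age spline.

Site enters mean and scale but not skew or kurtosis; sex enters
everything except the tail weight.

## Fitting

Fitting is cyclic penalised Newton scoring in the Rigby–Stasinopoulos
style: each submodel in turn is updated against working responses
$z_i = \eta_i + u_i / w_i$, where $u_i = \partial \ell_i / \partial
\eta_i$ is the analytic score and $w_i$ a finite-difference observed
information (floored, with a squared-score fallback where the curvature
is locally non-positive). The penalised update solves
$(X^\top W X + S)\beta = X^\top W z$ with $S$ holding the spline
difference penalty and the site ridge.

* **Age smooth**: cubic B-splines with 10 interior knots at age
  quantiles and a second-order difference penalty; the basis carries a
  sum-to-zero constraint (QR projection) so the intercept stays
  identifiable. Outside the training age range the smooth is continued
  as a constant and predictions warn about extrapolation.
* **Smoothing parameters**: chosen per submodel by GAIC with penalty
  weight 2 over a log-spaced grid, once, during an initial
  hyperparameter phase (5 outer iterations); re-optimising every
  iteration buys little and breaks monotonicity guarantees.
* **Site effect**: random intercepts realised as ridge-penalised site
  dummies; the shrinkage variance is profiled by an EM moment update
  ($\hat\tau^2 = \overline{b_j^2 + V_{jj}}$) during the hyperparameter
  phase and then frozen. With fewer than 10 sites a message notes that
  fixed effects are often advised at that level count; with a single
  site the dummy block is dropped and the effect absorbed into the
  intercept, with a warning.
* **Convergence**: after the hyperparameter phase every accepted step
  must not decrease the penalised log-likelihood (step halving), so the
  trace is monotone; the fit stops when the relative change falls below
  1e-6 (default), and a fit that exhausts `max_iter` is returned with
  `converged = FALSE` and a warning — never silently. Skew and tail
  weight are held at their neutral values for the first two iterations
  so location and scale stabilise first.

Coefficient uncertainty is summarised by the curvature of the penalised
likelihood at convergence ($({X^\top W X + S})^{-1}$), the usual
Bayesian covariance of penalised regression; it is kept in memory
(`model$vcov`) and its diagonal is serialised with the model.

### A known identifiability limitation

In the SHASH family a small location shift can be traded against a small
skew change with almost no likelihood cost. Predictions, z-scores, and
centiles are unaffected (the combination is identified), but
coefficient-level uncertainty in the $\mu$ submodel is underestimated by
the block-wise covariance: in simulations the sex coefficient's error SD
was about twice its reported SE under SHASH, while the Gaussian family
was calibrated. For this reason the parameter-recovery analyses
(`scripts/acceptance.R`, and the corresponding tests) fit the Gaussian
family — the generator's noise is Gaussian, so this is also the matched
family — and recovery is assessed per generating coefficient: the age
slope (via the fitted mean difference over ages 25–75), the sex offset,
and the five centred site offsets must each lie within 2 SEs of their
estimate, aggregated over 50 replicates with a 90% pass requirement.

## Harmonising unseen sites and scoring

Scoring a new site requires healthy controls from that site. Their
residuals against the reference-site prediction give the site offset
(their mean); the scoring SD follows the 30-control rule: the SD of
those residuals when $n \ge 30$, otherwise the unweighted mean of the
per-site residual SDs stored in the model (an HC-count-weighted mean is
available as an option). The rule's rationale is quantified by
`sd_rule_probability()`: the sample SD of $n = 30$ normal draws lies
within 10% of the truth with probability 0.552 and within 25% with
probability 0.944 (chi-square closed form; the Monte-Carlo route in the
acceptance script agrees within its standard error). The reference site
defaults to the training site with the most controls. Patients never
contribute to offset or SD estimation. Multiple unseen sites in one
upload are harmonised independently.

Z-scores are $(y - \mu_{ref} - \text{offset})/sd$. Centiles map each
value through the family CDF of the distribution whose **mean** equals
$\mu_{ref} + \text{offset}$ and whose **SD** equals the scoring SD, with
skew and kurtosis predicted at the subject's own age (and sex for
skew). Solving location and scale from the two moments — rather than
plugging the offset and SD in as the location and scale parameters —
matters: the offset is a mean and the SD rule estimates an SD, but for
a skewed, kurtotic family the location parameter is not the mean and
the scale is not the SD. Without the moment matching, sampling noise in
the fitted $\hat\nu, \hat\tau$ propagated into systematic 1–3 point
centile coverage errors in held-out calibration runs; with it, coverage
at the 5/10/50/90/95th centiles is within a few tenths of a point.
Centiles are clipped to [0.01, 99.99] with a flag.

## Quality control

Residuals about the fitted location (own-site effects included) are
flagged beyond 5 median absolute deviations; the MAD uses the normal
consistency constant 1.4826 by default, with `constant = 1` one switch
away since "five MADs" can be read either way. A zero MAD (degenerate
scale) flags nothing and warns. Exclusion is listwise: a subject flagged
in any model is removed from all models, so every normative model trains
on the identical reference set and model statistics remain comparable.
QC is a single fit–flag–refit pass by default; image-level and visual QC
are out of scope.

## Group statistics and lateralisation

`group_abnormality()` summarises patient z-scores per region in two
modes. Case–control mode is classical Cohen's d between patient and
uploaded-control z-scores. Normative mode compares patients against the
normative reference population directly; since reference z-scores are 0
with unit SD by construction, we use the one-sample standardised mean
$d = \bar z_p / s_{z_p}$. This definition is deliberately simple and
documented as swappable; an alternative (pooled d against held-out
normative scores) would differ mainly through the patient-SD estimate.

`lateralize()` computes $\Delta z = z_{left} - z_{right}$ per subject
(the left-minus-right convention is fixed) and calls the hemisphere that
is more abnormal given the metric's abnormal direction — for
atrophy-like metrics lower values are abnormal, so $\Delta z < 0$
implicates the left hemisphere. A subject "exceeds 2 SD" when
$|\Delta z - \overline{\Delta z}_{ctrl}| > 2\,SD(\Delta z_{ctrl})$,
i.e. against the empirical control delta distribution rather than the
theoretical $\sqrt 2$ — the empirical choice is robust to
interhemispheric correlation, which shrinks the control delta SD well
below $\sqrt 2$.

## The synthetic cohort generator

`simulate_cohort()` draws subjects with uniform age over 5–95 years
(the normative support), balanced sex, and multinomial site assignment,
and generates per region and hemisphere

$$y = b_r + f(\text{age}) + \beta_{sex}[male] + \delta_{site} +
  \varepsilon,\qquad \varepsilon \sim
  \mathrm{SHASH}\big(0,\ \sigma(\text{age})\, s_{site},\ \nu,\ \tau\big).$$

Defaults, chosen once as plausible study conditions and then left alone:

* median age trajectory through control points at ages 5/20/65/95 with
  log10-thickness values for 2.9/2.65/2.5/2.2 mm, monotone (Hyman)
  interpolation — decline steeper in early and late life and gentle in
  mid-life;
* sex offset 0.01 log10 units; noise SD 0.02 log10 units (about 5% on
  the raw scale), optionally linear in age; Gaussian noise by default
  ($\nu = 0, \tau = 1$), with skew/kurtosis available through the
  config;
* per-site mean shifts with SD 0.02 log10 units and multiplicative
  scale factors with log-SD 0.15; 5 sites and 2000 subjects in the
  standard testing configuration;
* left and right values share a Gaussian-copula noise correlation of
  0.8, reflecting the strong interhemispheric correlation of real
  morphometry (this narrows the control $\Delta z$ distribution, which
  is what makes hemispheric lateralisation informative at all).

`inject_disease()` relabels a seeded subset of subjects and shifts the
targeted regions (optionally one hemisphere) by a stated multiple of the
generator's noise SD, recording everything in a ground-truth attribute,
so effect-size recovery can be checked exactly.

What the generator does **not** emulate: covariance between
neighbouring regions, FreeSurfer's measurement error structure,
realistic demographic imbalance across sites, or longitudinal sessions.
Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the stated generating process, not that
real cortical data meet its assumptions.

## Problem sizes and numerical choices

The test suite and acceptance script use training cohorts of 2000
subjects across 5 sites, unseen-site cohorts of 4000 (2000 for the site
adjustment, 2000 held out) pooled over four independent regional
models, 50 replicates for parameter recovery, and 100,000 Monte-Carlo
replicates for the SD-rule probabilities — sizes at which the
calibration bands (|mean z| < 0.05, |SD − 1| < 0.05, centile coverage
within 1.5 points) are comfortably wider than the residual sampling
noise. Ages slightly inside the training support are used for unseen
cohorts so boundary extrapolation does not enter calibration checks.
Degenerate inputs (a single site, a single sex, all-equal residuals,
non-positive morphometry before the log, subjects missing from either
table) are either handled with an explicit warning or rejected with an
error naming the offender; ties in the lateralisation delta are called
indeterminate rather than broken arbitrarily.

## Serialisation and sessions

Model sets serialise to versioned JSON (family id, spline bases,
coefficients, SEs, site tables, diagnostics) and reload bit-for-bit for
prediction without refitting, so pre-trained models can ship with a
repository. Subjects with multiple sessions keep their first session by
sort order with a warning; longitudinal modelling is future work.

## Known limitations

* Coefficient SEs under the SHASH family understate location-submodel
  uncertainty (see above); use the Gaussian family when coefficient
  inference is the goal and the data are near-symmetric.
* The age smooth extrapolates as a constant outside the training range.
* Scoring requires healthy controls from every unseen site; there is no
  ComBat-style harmonisation without them.
* K, I, S are computed at hemisphere level only; regional folding
  components are not yet derived.
* No multiple-comparison correction is applied to regional effect-size
  maps; they are descriptive, as effect sizes, not tests.
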