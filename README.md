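# brainnorm

Normative ("growth chart") modelling of regional brain morphometry with
multi-site harmonisation, individual z-scores/centiles, and group-level
abnormality mapping.

## The problem

Regional brain measures (cortical thickness, surface area, volume, and
the independent folding components K, I, S) vary strongly with age, sex,
and — in multi-site studies — with scanner and protocol. To decide
whether one patient's precentral thickness is abnormal, or whether a
small clinical cohort shows real thinning, those covariates must be
removed first. brainnorm fits distributional normative models to a large
healthy reference cohort and then scores new, unseen subjects against
them, harmonising each new scanning site through its own healthy
controls. It is aimed at researchers working with FreeSurfer-style
regional tables who need individual deviation scores and regional effect
sizes without building the statistical machinery themselves.

## The model

For every region x hemisphere x metric, the base-10 log of the measure
`y` follows a four-parameter sinh-arcsinh (SHASH) distribution whose
parameters each get their own additive predictor:

    mu    = f_mu(age)    + beta_mu  * sex + u_site,     u_site ~ N(0, tau^2)
    log sigma = f_s(age) + beta_s   * sex + v_site
    nu    = f_nu(age)    + beta_nu  * sex
    log tau   = f_t(age)

with cubic B-spline age smooths (second-order difference penalty,
smoothing chosen by GAIC), ridge-shrunk random site intercepts, and
`Z = sinh(tau * asinh((y - mu)/sigma) - nu) ~ N(0,1)`, so centiles come
in closed form through the normal CDF. At `nu = 0, tau = 1` the family
reduces exactly to the Gaussian.

An unseen site is harmonised by the mean residual of its healthy
controls relative to the reference site; the scoring SD comes from those
controls when there are at least 30 of them, otherwise from the average
residual SD across the normative sites (a sample of 30 gives roughly a
55% chance of estimating an SD within 10% and 95% within 25% — the
package computes these probabilities by Monte Carlo and chi-square).
Then for each subject

    z = (y - mu_ref(age, sex) - offset) / sd_site

and the centile is the family CDF with site mean/SD and the skew and
kurtosis predicted at the subject's age.

The folding components are the orthogonal combinations of
`x = log10 At, y = log10 T^2, z = log10 Ae` (total pial area, average
thickness, exposed area): `K = x + y/4 - 5z/4` (tension),
`I = x + y + z` (isometric size), `S = 3x/2 - 9y/4 + 3z/4` (shape).
Isometric rescaling changes I but not K or S.

## Worked example

```r
library(brainnorm)

# a seeded multi-site healthy cohort with known ground truth
cohort <- simulate_cohort(sim_config(n_subjects = 1500, n_sites = 4, seed = 42))
model  <- fit_normative(cohort, c("bankssts", "left", "thickness_mm"))
model
#> normative model (shash): left bankssts thickness_mm
#>   n = 1500, sites = 4, reference site = site04
#>   converged = TRUE in 22 iterations; R^2 = 0.586

# harmonise an unseen site through its healthy controls, then score
new_site <- simulate_cohort(sim_config(n_subjects = 120, n_sites = 1,
                                       seed = 7, age_range = c(18, 80)))
new_site$meta$site <- "my_hospital"
adj <- estimate_site_adjustment(model, new_site)
adj
#> site adjustment for 'my_hospital': offset = 0.01316, sd = 0.02625
#> (unseen_hc, n_hc = 120)

z    <- compute_zscores(model, adj, new_site)
cent <- compute_centiles(model, adj, new_site)
head(cbind(z[c("subject_id", "region", "z")], centile = cent$centile), 4)
#>   subject_id   region          z   centile
#> 1  sub-00001 bankssts -1.1745773 11.755704
#> 2  sub-00002 bankssts -1.6175386  5.352366
#> 3  sub-00003 bankssts -0.2168872 41.164899
#> 4  sub-00004 bankssts  1.6831662 95.564653
```

The R^2 is the variance in log thickness explained by age, sex, and
site; the z-scores are deviations from the age/sex-specific healthy
distribution after removing the new site's offset, and the centiles
place each subject within it (subject 2 sits at the 5th centile —
thinner cortex than ~95% of healthy peers of the same age and sex).

Real data enter through `read_aparc_table()` (FreeSurfer
`aparcstats2table` exports), `read_folding_table()` +` add_kis()`
(folding-toolbox tables), and `read_metadata()`; `join_cohort()` and
`log_metrics()` prepare the cohort for fitting. `fit_modelset()` /
`save_modelset()` fit and serialise all regions at once;
`score_cohort()` scores a whole upload per site. `run_qc()` flags
subjects with residuals beyond 5 MADs and excludes them listwise.
`group_abnormality()` computes per-region Cohen's d (case-control or
normative mode), and `lateralize()` calls the more abnormal hemisphere
from left-right z differences.

A command-line wrapper with `simulate / qc / fit / score / report`
subcommands lives at `inst/cli/brainnorm`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","brainnorm",package="brainnorm"))')" \
    fit --config config.json
```

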