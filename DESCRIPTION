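Package: brainnorm
Title: Normative Modelling of Regional Brain Morphometry with Multi-Site Harmonisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits four-parameter distributional normative models (location,
    scale, skew, kurtosis) of log-transformed regional brain morphometry
    against age, sex, and scanning site, using a sinh-arcsinh response family
    with penalised B-spline age smooths and ridge-shrunk random site
    intercepts. Harmonises unseen sites via their healthy controls, scores
    individual subjects as z-scores and centiles, derives the independent
    cortical-folding components K, I, and S from hemisphere-level surface
    areas and thickness, flags residual outliers by median absolute
    deviation, and summarises group-level abnormality as regional Cohen's d
    and hemispheric lateralisation. Includes a seeded multi-site synthetic
    cohort generator with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
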