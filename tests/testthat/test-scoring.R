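# Unseen-site harmonisation, z-scores, centiles, and the 30-control
# SD rule.

# a fresh unseen-site cohort drawn from the same generator as the
# training data, with its own site offset/scale and relabelled site
make_unseen_cohort <- function(seed, n, shift = 0, ...) {
  cfg <- sim_config(n_subjects = n, n_sites = 1, seed = seed, ...)
  co <- simulate_cohort(cfg)
  co$meta$site <- "unseen01"
  co$morphometry$value <- co$morphometry$value + shift
  co
}

test_that("the SD source follows the 30-control rule", {
  fx <- std_model_fixture()
  hc29 <- make_unseen_cohort(301, 29)
  adj29 <- estimate_site_adjustment(fx$model, hc29)
  expect_identical(adj29$sd_source, "normative_average")
  expect_equal(adj29$sd,
               mean(unlist(fx$model$per_site_residual_sd)))

  hc30 <- make_unseen_cohort(302, 30)
  adj30 <- estimate_site_adjustment(fx$model, hc30)
  expect_identical(adj30$sd_source, "unseen_hc")
  expect_equal(adj30$n_hc, 30)
})

test_that("a known mean shift of the unseen site is recovered as the
          offset", {
  fx <- std_model_fixture()
  # controls drawn from the reference site's own distribution, then
  # shifted by +0.10 log units
  gt <- attr(fx$cohort, "ground_truth")
  ref_offset <- gt$site_offset[[fx$model$reference_site]]
  base <- make_unseen_cohort(303, 200, site_offset_sd = 0,
                             site_scale_sd = 0)
  base$morphometry$value <- base$morphometry$value + ref_offset
  adj0 <- estimate_site_adjustment(fx$model, base)
  shifted <- base
  shifted$morphometry$value <- shifted$morphometry$value + 0.10
  adj <- estimate_site_adjustment(fx$model, shifted)
  expect_equal(adj$offset - adj0$offset, 0.10, tolerance = 1e-10)
  expect_lt(abs(adj$offset - 0.10), 0.012)
})

test_that("harmonisation inputs are validated", {
  fx <- std_model_fixture()
  empty <- make_unseen_cohort(304, 50)
  empty$meta <- empty$meta[0, ]
  empty$morphometry <- empty$morphometry[0, ]
  expect_error(estimate_site_adjustment(fx$model, empty),
               "healthy controls required")

  mixed <- make_unseen_cohort(305, 50)
  mixed$meta$group[1:10] <- "patient"
  expect_error(estimate_site_adjustment(fx$model, mixed),
               "healthy controls only")
})

test_that("z-scores are exact at constructed anchor points", {
  fx <- std_model_fixture()
  hc <- make_unseen_cohort(306, 100)
  adj <- estimate_site_adjustment(fx$model, hc)
  probe <- hc
  probe$meta <- probe$meta[1:2, ]
  pp <- predict_params(fx$model, probe$meta$age, probe$meta$sex,
                       "reference")
  sel <- probe$morphometry$subject_id %in% probe$meta$subject_id &
    probe$morphometry$hemisphere == "left"
  probe$morphometry <- probe$morphometry[sel, ]
  probe$morphometry$value <- pp$mu + adj$offset + c(0, adj$sd)
  z <- compute_zscores(fx$model, adj, probe)
  expect_equal(z$z, c(0, 1), tolerance = 1e-10)
})

test_that("held-out controls from a new site score as standard normal", {
  fx <- std_model_fixture()
  big <- make_unseen_cohort(307, 2000, age_range = c(6, 94))
  adj_ids <- big$meta$subject_id[1:1000]
  adj <- estimate_site_adjustment(fx$model,
                                  brainnorm:::subset_cohort(big, adj_ids))
  held <- brainnorm:::subset_cohort(
    big, setdiff(big$meta$subject_id, adj_ids))
  z <- compute_zscores(fx$model, adj, held)
  z <- z$z[z$hemisphere == "left"]
  # the offset carries its own estimation noise of about 1/sqrt(1000)
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.10)
})

test_that("centiles sit at their anchors and agree with the normal CDF
          when the family is Gaussian", {
  cohort <- simulate_cohort(std_sim_config(seed = 308, n = 1200))
  gmod <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal", min_n = 100)))
  hc <- make_unseen_cohort(309, 100)
  adj <- estimate_site_adjustment(gmod, hc)
  probe <- hc
  probe$meta <- probe$meta[1:2, ]
  pp <- predict_params(gmod, probe$meta$age, probe$meta$sex, "reference")
  sel <- probe$morphometry$subject_id %in% probe$meta$subject_id &
    probe$morphometry$hemisphere == "left"
  probe$morphometry <- probe$morphometry[sel, ]
  probe$morphometry$value <- pp$mu + adj$offset + c(0, adj$sd)
  cent <- compute_centiles(gmod, adj, probe)
  expect_equal(cent$centile, c(50, 100 * pnorm(1)), tolerance = 1e-6)
})

test_that("low-centile coverage matches its nominal rate", {
  fx <- std_model_fixture()
  big <- make_unseen_cohort(310, 3000, age_range = c(6, 94))
  adj_ids <- big$meta$subject_id[1:1000]
  adj <- estimate_site_adjustment(fx$model,
                                  brainnorm:::subset_cohort(big, adj_ids))
  held <- brainnorm:::subset_cohort(
    big, setdiff(big$meta$subject_id, adj_ids))
  cent <- compute_centiles(fx$model, adj, held)
  frac <- mean(cent$centile[cent$hemisphere == "left"] < 10)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
})

test_that("offset is equivariant and z-scores are shift-invariant", {
  fx <- std_model_fixture()
  hc <- make_unseen_cohort(311, 120)
  adj <- estimate_site_adjustment(fx$model, hc)
  z <- compute_zscores(fx$model, adj, hc)

  shifted <- hc
  shifted$morphometry$value <- shifted$morphometry$value + 0.37
  adj2 <- estimate_site_adjustment(fx$model, shifted)
  expect_equal(adj2$offset - adj$offset, 0.37, tolerance = 1e-10)
  expect_equal(adj2$sd, adj$sd, tolerance = 1e-10)
  z2 <- compute_zscores(fx$model, adj2, shifted)
  expect_equal(z2$z, z$z, tolerance = 1e-9)
})

test_that("ranking by z equals ranking by centile for shared
          covariates", {
  fx <- std_model_fixture()
  hc <- make_unseen_cohort(312, 80)
  adj <- estimate_site_adjustment(fx$model, hc)
  # same age, sex, and site: only the raw value varies
  probe <- hc
  probe$meta$age <- 47.3
  probe$meta$sex <- "female"
  z <- compute_zscores(fx$model, adj, probe)
  cent <- compute_centiles(fx$model, adj, probe)
  sel <- z$hemisphere == "left"
  expect_identical(order(z$z[sel]), order(cent$centile[sel]))
})

test_that("self-scoring the reference site's controls centres at zero", {
  fx <- std_model_fixture()
  ref <- fx$model$reference_site
  ids <- fx$cohort$meta$subject_id[fx$cohort$meta$site == ref]
  own <- brainnorm:::subset_cohort(fx$cohort, ids)
  adj <- estimate_site_adjustment(fx$model, own)
  z <- compute_zscores(fx$model, adj, own)
  expect_lt(abs(mean(z$z)), 0.05)
})

test_that("score_cohort requires controls at every site", {
  fx <- std_model_fixture()
  ms <- structure(list(models = setNames(list(fx$model),
                                         "bankssts|left|thickness_mm"),
                       training_summary = list()), class = "modelset")
  co <- make_unseen_cohort(313, 60)
  co$meta$group <- "patient"
  expect_error(score_cohort(ms, co), "healthy controls required")
})

test_that("the SD rule probabilities match the chi-square closed form", {
  r10 <- sd_rule_probability(30, 0.10, reps = 2e4, seed = 5)
  expect_lt(abs(r10$p_mc - r10$p_exact), 3 * r10$mc_se)
  r25 <- sd_rule_probability(30, 0.25, reps = 2e4, seed = 6)
  expect_lt(abs(r25$p_mc - r25$p_exact), 3 * r25$mc_se)
  # certainty limit and input validation
  expect_equal(sd_rule_probability(30, 10, reps = 1e4, seed = 7)$p_mc, 1)
  expect_error(sd_rule_probability(30, -0.1), "positive")
})
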