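# The penalised four-parameter distributional regression engine.

test_that("a linear age decline, sex, and site effects are recovered
          under Gaussian noise", {
  cohort <- simulate_cohort(linear_sim_config(seed = 201))
  model <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal")))
  expect_true(model$fit$converged)

  # fitted slope from the mean curve (population site level)
  pp <- predict_params(model, c(25, 75), "female", "population")
  slope <- (pp$mu[2] - pp$mu[1]) / 50
  expect_lt(abs(slope - (-0.002)), 0.1 * 0.002)

  # site offsets within 2 posterior SEs of their generated values
  gt <- attr(cohort, "ground_truth")
  co <- model$submodels$mu$coef
  se <- model$submodels$mu$se
  keys <- paste0("site_", names(gt$site_offset))
  est <- co[keys] - mean(co[keys])
  truth <- gt$site_offset - mean(gt$site_offset)
  expect_true(all(abs(est - truth) < 2 * se[keys] + 1e-4))

  # sex effect
  expect_lt(abs(co[["sex_male"]] - 0.01), 2.5 * se[["sex_male"]])
})

test_that("a null sex effect is covered by its confidence interval", {
  cohort <- simulate_cohort(std_sim_config(seed = 202, sex_effect = 0))
  model <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal")))
  co <- model$submodels$mu$coef[["sex_male"]]
  se <- model$submodels$mu$se[["sex_male"]]
  expect_lt(abs(co), 2 * se)
})

test_that("an age-increasing scale is recovered within 15%", {
  cfg <- std_sim_config(seed = 203, sigma = c(0.015, 0.045),
                        site_scale_sd = 0)
  cohort <- simulate_cohort(cfg)
  model <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm")))
  pp <- predict_params(model, c(20, 80), "female", "population")
  sig <- function(a) 0.015 + 0.03 * (a - 5) / 90
  truth_ratio <- sig(80) / sig(20)
  expect_equal(pp$sigma[2] / pp$sigma[1], truth_ratio,
               tolerance = 0.15 * truth_ratio)
})

test_that("prediction is deterministic and site modes differ structurally", {
  fx <- std_model_fixture()
  p1 <- predict_params(fx$model, c(30, 60), "male")
  p2 <- predict_params(fx$model, c(30, 60), "male")
  expect_identical(p1, p2)

  pop <- predict_params(fx$model, 40, "female", "population")
  ref <- predict_params(fx$model, 40, "female", "reference")
  sub <- fx$model$submodels
  ref_site <- fx$model$reference_site
  expect_equal(ref$mu - pop$mu,
               unname(sub$mu$coef[[paste0("site_", ref_site)]]))
  expect_equal(log(ref$sigma) - log(pop$sigma),
               unname(sub$sigma$coef[[paste0("site_", ref_site)]]))
  expect_identical(pop$nu, ref$nu)
  expect_identical(pop$tau, ref$tau)

  expect_error(predict_params(fx$model, 40, "female", "not-a-site"),
               "unknown site")
  expect_warning(predict_params(fx$model, 100, "female"), "extrapolat")
})

test_that("centile curves are ordered and match normal quantiles when
          reduced to the Gaussian", {
  fx <- std_model_fixture()
  ages <- seq(10, 90, by = 5)
  cc <- centile_curves(fx$model, ages, "female", c(0.05, 0.5, 0.95))
  wide <- reshape(cc, idvar = "age", timevar = "centile",
                  direction = "wide")
  expect_true(all(wide$`value.0.05` < wide$`value.0.5`))
  expect_true(all(wide$`value.0.5` < wide$`value.0.95`))

  cohort <- simulate_cohort(std_sim_config(seed = 204, n = 1200))
  gmod <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal", min_n = 100)))
  pp <- predict_params(gmod, 50, "female")
  cc <- centile_curves(gmod, 50, "female", c(0.5, 0.975))
  expect_equal(cc$value[cc$centile == 0.5], pp$mu, tolerance = 1e-10)
  expect_equal(cc$value[cc$centile == 0.975] - pp$mu,
               1.959964 * pp$sigma, tolerance = 1e-5 * pp$sigma)
})

test_that("R-squared behaves at its three anchors", {
  fx <- std_model_fixture()
  # noise-free: responses set exactly to the fitted location
  cohort <- fx$cohort
  d <- brainnorm:::extract_target(cohort, fx$model)
  pp <- brainnorm:::predict_for_cohort(fx$model, d$meta, "own")
  noise_free <- cohort
  m <- cohort$morphometry
  sel <- m$region == "bankssts" & m$hemisphere == "left"
  m$value[sel] <- pp$mu[match(m$subject_id[sel], d$subject_id)]
  noise_free$morphometry <- m
  expect_equal(model_r2(fx$model, noise_free), 1, tolerance = 1e-12)

  # pure noise: no age, sex, or site structure
  flat <- simulate_cohort(sim_config(
    n_subjects = 5000, n_sites = 5, seed = 205, sex_effect = 0,
    site_offset_sd = 0, site_scale_sd = 0,
    age_values = rep(0.4, 4)))
  fmod <- suppressMessages(
    fit_normative(flat, c("bankssts", "left", "thickness_mm")))
  expect_lt(abs(model_r2(fmod, flat)), 0.02)

  # age effect built to explain 80% of the variance:
  # uniform age on [5,95] has variance 675, slope 0.002 gives
  # explained 2.7e-3; noise sd sqrt(2.7e-3/4) completes the budget
  strong <- simulate_cohort(linear_sim_config(
    seed = 206, n = 5000, b = 0.002, sex_effect = 0, site_offset_sd = 0,
    site_scale_sd = 0, sigma = rep(sqrt(0.002^2 * 675 / 4), 2)))
  smod <- suppressMessages(
    fit_normative(strong, c("bankssts", "left", "thickness_mm")))
  expect_equal(model_r2(smod, strong), 0.80, tolerance = 0.03 / 0.80)
})

test_that("quantile residuals of the training controls are calibrated", {
  cohort <- simulate_cohort(std_sim_config(seed = 207, n = 5000,
                                           nu = 0.3, tau = 1.15))
  model <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm")))
  qr <- quantile_residuals(model, cohort)
  expect_lt(abs(mean(qr)), 0.05)
  expect_lt(abs(sd(qr) - 1), 0.05)
})

test_that("the penalised log-likelihood is monotone after the
          hyperparameter phase", {
  fx <- std_model_fixture()
  tr <- fx$model$fit$pen_loglik_trace
  h <- fx$model$fit$hyper_iter
  expect_true(all(diff(tr[-seq_len(h)]) > -1e-6))
})

test_that("the Gaussian family reproduces a penalised WLS fit of mu", {
  cohort <- simulate_cohort(std_sim_config(seed = 208, n = 1500))
  model <- suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal", min_n = 100)))
  # independent route: direct penalised weighted least squares with the
  # model's own design, weights, and frozen hyperparameters
  d <- brainnorm:::extract_target(cohort, model)
  spec <- model$submodels$mu$spec
  sm <- brainnorm:::build_submodel(d$meta$age, d$meta$sex, d$meta$site,
                                   spec, TRUE, TRUE)
  pp <- brainnorm:::predict_for_cohort(model, d$meta, "own")
  w <- 1 / pp$sigma^2
  S <- brainnorm:::penalty_matrix(sm, model$submodels$mu$lambda,
                                  model$site_tau2$mu)
  beta <- solve(t(sm$X * w) %*% sm$X + S, t(sm$X * w) %*% d$y)
  expect_lt(max(abs(model$submodels$mu$coef - drop(beta))), 1e-6)
})

test_that("fits agree with an independent mgcv location-scale oracle", {
  skip_if_not_installed("mgcv")
  cohort <- simulate_cohort(sim_config(
    n_subjects = 1500, n_sites = 1, site_offset_sd = 0, site_scale_sd = 0,
    seed = 209, sigma = c(0.015, 0.035)))
  model <- suppressWarnings(suppressMessages(
    fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                  fit_config(family = "normal", min_n = 100))))
  d <- brainnorm:::extract_target(cohort, model)
  df <- data.frame(y = d$y, age = d$meta$age,
                   male = as.numeric(d$meta$sex == "male"))
  g <- mgcv::gam(list(y ~ s(age) + male, ~ s(age)), data = df,
                 family = mgcv::gaulss())
  grid <- data.frame(age = seq(15, 85, by = 10), male = 0)
  gp <- predict(g, grid, type = "response")
  ours <- predict_params(model, grid$age, "female", "population")
  expect_lt(max(abs(ours$mu - gp[, 1])), 0.012)
  # gaulss's second response column is the precision 1/sigma
  expect_lt(max(abs(ours$sigma * gp[, 2] - 1)), 0.15)
})

test_that("model sets serialise to JSON and reload without refitting", {
  fx <- std_model_fixture()
  ms <- structure(list(models = setNames(list(fx$model),
                                         "bankssts|left|thickness_mm"),
                       training_summary = list(n_subjects = 2000,
                                               n_sites = 5,
                                               age_range = c(5, 95))),
                  class = "modelset")
  p <- withr::local_tempfile(fileext = ".json")
  save_modelset(ms, p)
  back <- load_modelset(p)
  m2 <- back$models[[1]]
  ages <- c(12, 40, 77)
  expect_equal(predict_params(m2, ages, "male"),
               predict_params(fx$model, ages, "male"), tolerance = 1e-12)
  cc1 <- centile_curves(fx$model, ages, "female", c(0.1, 0.9))
  cc2 <- centile_curves(m2, ages, "female", c(0.1, 0.9))
  expect_equal(cc2$value, cc1$value, tolerance = 1e-12)
})

test_that("degenerate designs are handled with warnings, not crashes", {
  cohort <- simulate_cohort(sim_config(n_subjects = 400, n_sites = 1,
                                       seed = 210))
  w1 <- capture_warnings(
    model <- suppressMessages(
      fit_normative(cohort, c("bankssts", "left", "thickness_mm"),
                    fit_config(min_n = 100))))
  expect_match(w1, "fewer than 2 sites", all = FALSE)
  expect_true(model$fit$converged)

  one_sex <- cohort
  one_sex$meta$sex <- "female"
  w2 <- capture_warnings(
    m2 <- suppressMessages(
      fit_normative(one_sex, c("bankssts", "left", "thickness_mm"),
                    fit_config(min_n = 100, max_iter = 50))))
  expect_match(w2, "single sex", all = FALSE)
  # if this degenerate fit stops early it must say so, never silently
  if (!m2$fit$converged) expect_match(w2, "did not converge", all = FALSE)

  small <- simulate_cohort(sim_config(n_subjects = 150, n_sites = 2,
                                      seed = 211))
  w3 <- capture_warnings(
    suppressMessages(fit_normative(small,
                                   c("bankssts", "left", "thickness_mm"))))
  expect_match(w3, "below recommended minimum", all = FALSE)
})
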