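# Penalised four-parameter distributional regression engine.
#
# Each distribution parameter has its own additive predictor:
#   mu    ~ intercept + age spline + sex + site (ridge-shrunk intercepts)
#   sigma ~ intercept + age spline + sex + site        (log link)
#   nu    ~ intercept + age spline + sex
#   tau   ~ intercept + age spline                     (log link)
# Fitting is cyclic penalised Newton scoring in the style of Rigby &
# Stasinopoulos: each submodel is updated against working responses and
# weights from the current likelihood, with step halving so the penalised
# log-likelihood never decreases once hyperparameters are frozen.

#' Fitting configuration for normative models
#'
#' @param family Response family, \code{"shash"} (default) or
#'   \code{"normal"}; see \code{\link{bn_family}}.
#' @param n_knots Number of interior knots of the cubic B-spline age
#'   smooth, placed at age quantiles.
#' @param degree B-spline degree.
#' @param lambda_grid Candidate smoothing parameters searched by
#'   GAIC(k = 2) for each submodel's age smooth.
#' @param max_iter Maximum outer (cyclic) iterations.
#' @param tol Relative penalised-deviance convergence tolerance.
#' @param min_n Minimum training size per model; smaller cohorts fit with
#'   a warning.
#' @param reference_site Site id used as scoring reference; default the
#'   training site with the most healthy controls.
#' @param hyper_iter Outer iterations of the hyperparameter phase during
#'   which the site shrinkage variance is profiled (EM moment updates)
#'   and smooth lambdas chosen; both are frozen afterwards.
#' @return List of class \code{"fit_config"}.
#' @export
fit_config <- function(family = "shash", n_knots = 10, degree = 3,
                       lambda_grid = 10^seq(-2, 6, by = 0.5),
                       max_iter = 200, tol = 1e-6, min_n = 200,
                       reference_site = NULL, hyper_iter = 5) {
  structure(list(family = family, n_knots = n_knots, degree = degree,
                 lambda_grid = lambda_grid, max_iter = max_iter, tol = tol,
                 min_n = min_n, reference_site = reference_site,
                 hyper_iter = hyper_iter),
            class = "fit_config")
}

# ---- spline basis with sum-to-zero (centering) constraint --------------

make_spline_spec <- function(age, n_knots, degree) {
  lo <- min(age); hi <- max(age)
  interior <- unique(quantile(age, probs = seq_len(n_knots) / (n_knots + 1),
                              names = FALSE, type = 7))
  interior <- interior[interior > lo & interior < hi]
  ord <- degree + 1L
  knots <- c(rep(lo, ord), interior, rep(hi, ord))
  B <- splines::splineDesign(knots, x = age, ord = ord)
  cs <- colSums(B)
  qr_c <- qr(matrix(cs, ncol = 1))
  Q2 <- qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE]
  list(boundary = c(lo, hi), interior = interior, degree = degree, Q2 = Q2)
}

eval_spline <- function(spec, age) {
  ord <- spec$degree + 1L
  knots <- c(rep(spec$boundary[1], ord), spec$interior,
             rep(spec$boundary[2], ord))
  # constant extrapolation outside the training support
  age_c <- pmin(pmax(age, spec$boundary[1]), spec$boundary[2])
  B <- splines::splineDesign(knots, x = age_c, ord = ord)
  B %*% spec$Q2
}

spline_penalty <- function(spec) {
  p_full <- length(spec$interior) + spec$degree + 1L
  D <- diff(diag(p_full), differences = 2)
  t(spec$Q2) %*% crossprod(D) %*% spec$Q2
}

# ---- submodel design ----------------------------------------------------

# blocks: intercept (1 col), spline (p cols), optional sex, optional site
build_submodel <- function(age, sex, site, spec, with_sex, with_site) {
  Z <- eval_spline(spec, age)
  X <- cbind(`(Intercept)` = 1, Z)
  idx <- list(intercept = 1L, spline = 1L + seq_len(ncol(Z)))
  if (with_sex) {
    X <- cbind(X, sex_male = as.numeric(sex == "male"))
    idx$sex <- ncol(X)
  }
  site_levels <- NULL
  if (with_site) {
    site_levels <- sort(unique(site))
    Dm <- outer(site, site_levels, `==`) * 1
    colnames(Dm) <- paste0("site_", site_levels)
    idx$site <- ncol(X) + seq_len(ncol(Dm))
    X <- cbind(X, Dm)
  }
  list(X = X, idx = idx, spec = spec, with_sex = with_sex,
       with_site = with_site, site_levels = site_levels)
}

penalty_matrix <- function(sm, lambda, site_tau2) {
  p <- ncol(sm$X)
  S <- matrix(0, p, p)
  Ssp <- spline_penalty(sm$spec)
  S[sm$idx$spline, sm$idx$spline] <- lambda * Ssp
  if (sm$with_site)
    S[cbind(sm$idx$site, sm$idx$site)] <- 1 / site_tau2
  S
}

quad_penalty <- function(beta, S) 0.5 * drop(crossprod(beta, S %*% beta))

# ---- the fit ------------------------------------------------------------

#' Fit a normative model for one region x hemisphere x metric
#'
#' Fits the four-parameter distributional regression by cyclic penalised
#' Newton scoring. Only healthy controls (\code{group == "control"}) are
#' used; values are modelled on the scale present in the cohort, which
#' for raw morphometrics should be base-10 log (\code{\link{log_metrics}}).
#' Smoothing parameters are chosen by GAIC(k = 2) grid search and the
#' site shrinkage variance by an EM moment profile during an initial
#' hyperparameter phase; both are then frozen and the cyclic updates run
#' to convergence with step halving, so the penalised log-likelihood is
#' non-decreasing over the final phase.
#'
#' @param cohort A \code{"cohort"} object (see \code{\link{join_cohort}}).
#' @param target Character vector \code{c(region, hemisphere, metric)}.
#' @param config A \code{\link{fit_config}}.
#' @return Object of class \code{"normative_model"}.
#' @export
fit_normative <- function(cohort, target, config = fit_config()) {
  stopifnot(inherits(cohort, "cohort"), length(target) == 3)
  fam <- bn_family(config$family)

  m <- cohort$morphometry
  rows <- m[m$region == target[1] & m$hemisphere == target[2] &
              m$metric == target[3], ]
  if (!nrow(rows))
    stop("no data for target ", paste(target, collapse = " / "))
  meta <- cohort$meta[match(rows$subject_id, cohort$meta$subject_id), ]
  keep <- meta$group == "control"
  if (any(!keep))
    message("excluding ", sum(!keep), " non-control subject(s) from training")
  rows <- rows[keep, ]; meta <- meta[keep, ]
  y <- rows$value; age <- meta$age; sex <- meta$sex
  site <- as.character(meta$site)
  n <- length(y)
  if (n < config$min_n)
    warning("training n = ", n, " below recommended minimum ", config$min_n)

  sites <- sort(unique(site))
  with_site <- length(sites) >= 2
  if (!with_site)
    warning("fewer than 2 sites; site effect absorbed into the intercept")
  else if (length(sites) < 10)
    message(length(sites), " sites; random site intercepts are shrunk but ",
            "a fixed-effect treatment is often advised below 10 levels")
  with_sex <- length(unique(sex)) == 2
  if (!with_sex)
    warning("single sex in training data; dropping the sex coefficient")

  spec <- make_spline_spec(age, config$n_knots, config$degree)
  sm <- list(
    mu    = build_submodel(age, sex, site, spec, with_sex, with_site),
    sigma = build_submodel(age, sex, site, spec, with_sex, with_site),
    nu    = build_submodel(age, sex, site, spec, with_sex, FALSE),
    tau   = build_submodel(age, sex, site, spec, FALSE, FALSE))

  free <- fam$free
  beta <- lapply(sm, function(s) numeric(ncol(s$X)))
  lambda <- c(mu = 100, sigma = 100, nu = 1000, tau = 1000)
  tau2 <- c(mu = 0.01, sigma = 0.01)

  # Gaussian initialisation for mu (penalised least squares, GAIC lambda)
  init <- init_mu(sm$mu, y, config$lambda_grid, tau2["mu"])
  beta$mu <- init$beta; lambda["mu"] <- init$lambda
  r0 <- y - drop(sm$mu$X %*% beta$mu)
  beta$sigma[1] <- log(max(sd(r0), 1e-8))

  eta <- function() lapply(names(sm), function(p) drop(sm[[p]]$X %*% beta[[p]]))
  params <- function() {
    e <- eta(); names(e) <- names(sm)
    list(mu = e$mu, sigma = exp(e$sigma),
         nu = if ("nu" %in% free) e$nu else rep(fam$neutral["nu"], n),
         tau = if ("tau" %in% free) exp(e$tau) else rep(fam$neutral["tau"], n))
  }
  pen_ll <- function() {
    pp <- params()
    ll <- family_loglik(fam, y, pp$mu, pp$sigma, pp$nu, pp$tau)
    pen <- 0
    for (p in free) {
      S <- penalty_matrix(sm[[p]], lambda[[p]],
                          if (p %in% names(tau2)) tau2[[p]] else 1)
      pen <- pen + quad_penalty(beta[[p]], S)
    }
    ll - pen
  }

  select_lambda <- c(mu = FALSE, sigma = TRUE, nu = TRUE, tau = TRUE)
  trace <- numeric(0)
  converged <- FALSE
  it_total <- 0L
  last <- pen_ll()

  for (it in seq_len(config$max_iter)) {
    it_total <- it
    hyper_phase <- it <= config$hyper_iter
    for (p in free) {
      if (p %in% c("nu", "tau") && it <= 2) next   # stabilise mu/sigma first
      if (hyper_phase && select_lambda[[p]] &&
          !(p %in% c("nu", "tau") && it <= 2)) {
        lambda[[p]] <- gaic_lambda(fam, sm, beta, p, y, free, fam$neutral,
                                   config$lambda_grid,
                                   if (p %in% names(tau2)) tau2[[p]] else 1)
        select_lambda[[p]] <- FALSE
      }
      st <- if (p %in% names(tau2)) tau2[[p]] else 1
      S <- penalty_matrix(sm[[p]], lambda[[p]], st)
      upd <- newton_update(fam, sm, beta, p, y, S, free, fam$neutral,
                           function(b) { beta2 <- beta; beta2[[p]] <- b
                             pen_ll_at(fam, sm, beta2, y, free, fam$neutral,
                                       lambda, tau2) })
      beta[[p]] <- upd$beta
      if (hyper_phase && p %in% names(tau2) && sm[[p]]$with_site) {
        tau2[[p]] <- em_tau2(sm[[p]], beta[[p]], upd$A)
      }
    }
    cur <- pen_ll()
    trace <- c(trace, cur)
    if (!hyper_phase &&
        abs(cur - last) / (abs(cur) + 0.1) < config$tol) {
      converged <- TRUE
      break
    }
    last <- cur
  }
  if (!converged)
    warning("normative model did not converge in ", config$max_iter,
            " iterations (target ", paste(target, collapse = "/"), ")")

  pp <- params()
  # coefficient (posterior) covariance at the converged state
  vcovs <- ses <- list()
  for (p in free) {
    S <- penalty_matrix(sm[[p]], lambda[[p]],
                        if (p %in% names(tau2)) tau2[[p]] else 1)
    sw <- score_and_weight(fam, y, pp, p)
    A <- t(sm[[p]]$X * sw$w) %*% sm[[p]]$X + S
    V <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(V)) {
      dimnames(V) <- list(colnames(sm[[p]]$X), colnames(sm[[p]]$X))
      vcovs[[p]] <- V
      ses[[p]] <- sqrt(pmax(diag(V), 0))
    }
  }
  fitted_mu <- pp$mu
  resid <- y - fitted_mu
  per_site_sd <- tapply(resid, site, sd)
  site_n <- table(site)
  ref <- config$reference_site
  if (is.null(ref)) ref <- names(which.max(site_n))
  if (!(ref %in% sites) && with_site)
    stop("reference site '", ref, "' not among training sites")

  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero variance in the response")
  r2 <- 1 - sum(resid^2) / ss_tot

  model <- structure(list(
    family = fam$name,
    target = list(region = target[1], hemisphere = target[2],
                  metric = target[3]),
    submodels = lapply(names(sm), function(p) list(
      coef = setNames(beta[[p]], colnames(sm[[p]]$X)),
      spec = sm[[p]]$spec, with_sex = sm[[p]]$with_sex,
      with_site = sm[[p]]$with_site, site_levels = sm[[p]]$site_levels,
      lambda = unname(lambda[[p]]),
      se = if (p %in% names(ses)) setNames(ses[[p]], colnames(sm[[p]]$X)),
      free = p %in% free)),
    vcov = vcovs,
    neutral = as.list(fam$neutral),
    site_tau2 = as.list(tau2),
    reference_site = ref,
    per_site_residual_sd = as.list(per_site_sd),
    site_n = as.list(as.integer(site_n)),
    fit = list(converged = converged, iterations = it_total,
               pen_loglik = last, pen_loglik_trace = trace,
               hyper_iter = config$hyper_iter, r2 = r2, n = n,
               age_range = range(age), n_sites = length(sites))),
    class = "normative_model")
  names(model$submodels) <- names(sm)
  names(model$site_n) <- names(site_n)
  model
}

# penalised log-likelihood at an arbitrary coefficient state
pen_ll_at <- function(fam, sm, beta, y, free, neutral, lambda, tau2) {
  n <- length(y)
  e <- lapply(names(sm), function(p) drop(sm[[p]]$X %*% beta[[p]]))
  names(e) <- names(sm)
  mu <- e$mu; sigma <- exp(e$sigma)
  nu <- if ("nu" %in% free) e$nu else rep(neutral["nu"], n)
  tau <- if ("tau" %in% free) exp(e$tau) else rep(neutral["tau"], n)
  ll <- family_loglik(fam, y, mu, sigma, nu, tau)
  pen <- 0
  for (p in free) {
    S <- penalty_matrix(sm[[p]], lambda[[p]],
                        if (p %in% names(tau2)) tau2[[p]] else 1)
    pen <- pen + quad_penalty(beta[[p]], S)
  }
  ll - pen
}

current_params <- function(fam, sm, beta, free, neutral, n) {
  e <- lapply(names(sm), function(p) drop(sm[[p]]$X %*% beta[[p]]))
  names(e) <- names(sm)
  list(mu = e$mu, sigma = exp(e$sigma),
       nu = if ("nu" %in% free) e$nu else rep(neutral["nu"], n),
       tau = if ("tau" %in% free) exp(e$tau) else rep(neutral["tau"], n),
       eta = e)
}

# score and (finite-difference) observed information on the eta scale
score_and_weight <- function(fam, y, pp, par) {
  u <- fam$score(y, pp$mu, pp$sigma, pp$nu, pp$tau, par)
  h <- 1e-4
  perturb <- function(d) {
    q <- pp
    q[[par]] <- switch(par, mu = pp$mu + d, nu = pp$nu + d,
                       sigma = pp$sigma * exp(d), tau = pp$tau * exp(d))
    fam$score(y, q$mu, q$sigma, q$nu, q$tau, par)
  }
  w <- -(perturb(h) - perturb(-h)) / (2 * h)
  bad <- !is.finite(w) | w < 1e-8
  w[bad] <- pmax(u[bad]^2, 1e-4)       # BHHH fallback
  list(u = u, w = pmin(w, 1e8))
}

newton_update <- function(fam, sm, beta, par, y, S, free, neutral, obj) {
  n <- length(y)
  pp <- current_params(fam, sm, beta, free, neutral, n)
  sw <- score_and_weight(fam, y, pp, par)
  X <- sm[[par]]$X
  eta <- pp$eta[[par]]
  z <- eta + sw$u / sw$w
  XtW <- t(X * sw$w)
  A <- XtW %*% X + S
  b_new <- tryCatch(drop(solve(A, XtW %*% z)), error = function(e) {
    drop(solve(A + diag(1e-6, ncol(A)), XtW %*% z))
  })
  b_old <- beta[[par]]
  f_old <- obj(b_old)
  step <- 1
  for (k in 1:20) {
    b_try <- b_old + step * (b_new - b_old)
    f_try <- obj(b_try)
    if (is.finite(f_try) && f_try >= f_old - 1e-12)
      return(list(beta = b_try, A = A))
    step <- step / 2
  }
  list(beta = b_old, A = A)             # no improving step found
}

# EM moment update of the site shrinkage variance
em_tau2 <- function(sm, beta, A) {
  idx <- sm$idx$site
  b <- beta[idx]
  V <- tryCatch(diag(solve(A))[idx], error = function(e) rep(0, length(idx)))
  max(mean(b^2 + pmax(V, 0)), 1e-8)
}

# GAIC(k=2) selection of a submodel's smoothing parameter
gaic_lambda <- function(fam, sm, beta, par, y, free, neutral, grid, site_tau2) {
  n <- length(y)
  pp <- current_params(fam, sm, beta, free, neutral, n)
  sw <- score_and_weight(fam, y, pp, par)
  X <- sm[[par]]$X
  z <- pp$eta[[par]] + sw$u / sw$w
  XtW <- t(X * sw$w)
  XtWX <- XtW %*% X
  XtWz <- XtW %*% z
  best <- grid[1]; best_gaic <- Inf
  for (lam in grid) {
    S <- penalty_matrix(sm[[par]], lam, site_tau2)
    A <- XtWX + S
    b <- tryCatch(drop(solve(A, XtWz)), error = function(e) NULL)
    if (is.null(b)) next
    edf <- sum(diag(solve(A, XtWX)))
    beta2 <- beta; beta2[[par]] <- b
    pp2 <- current_params(fam, sm, beta2, free, neutral, n)
    ll <- family_loglik(fam, y, pp2$mu, pp2$sigma, pp2$nu, pp2$tau)
    gaic <- -2 * ll + 2 * edf
    if (is.finite(gaic) && gaic < best_gaic) { best_gaic <- gaic; best <- lam }
  }
  best
}

init_mu <- function(sm, y, grid, site_tau2) {
  X <- sm$X
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  best <- NULL; best_lambda <- grid[1]; best_gaic <- Inf
  for (lam in grid) {
    S <- penalty_matrix(sm, lam, site_tau2)
    A <- XtX + S
    b <- tryCatch(drop(solve(A, Xty)), error = function(e) NULL)
    if (is.null(b)) next
    r <- y - drop(X %*% b)
    edf <- sum(diag(solve(A, XtX)))
    n <- length(y)
    sig2 <- sum(r^2) / n
    gaic <- n * log(sig2) + 2 * edf
    if (is.finite(gaic) && gaic < best_gaic) {
      best_gaic <- gaic; best <- b; best_lambda <- lam
    }
  }
  if (is.null(best)) stop("singular design in initialisation")
  list(beta = best, lambda = best_lambda)
}

# ---- prediction ---------------------------------------------------------

eval_submodel <- function(sub, age, sex, site_effect) {
  Z <- eval_spline(sub$spec, age)
  eta <- sub$coef[1] + drop(Z %*% sub$coef[1 + seq_len(ncol(Z))])
  if (sub$with_sex)
    eta <- eta + sub$coef[["sex_male"]] * as.numeric(sex == "male")
  eta + site_effect
}

site_effect_of <- function(sub, site_mode, site) {
  if (!sub$with_site || identical(site_mode, "population")) return(0)
  lev <- sub$site_levels
  nm <- paste0("site_", site)
  if (!(site %in% lev)) stop("unknown site '", site, "'")
  unname(sub$coef[[nm]])
}

#' Predict distribution parameters at given covariates
#'
#' Evaluates the four fitted submodels at the supplied age and sex.
#' \code{site_mode} controls the site contribution to mu and sigma:
#' \code{"reference"} uses the model's designated reference site,
#' \code{"population"} sets the site effect to zero, and any training
#' site id uses that site's fitted effect.
#'
#' @param model A \code{"normative_model"}.
#' @param age Age(s) in years.
#' @param sex \code{"female"} or \code{"male"} (scalar or vector).
#' @param site_mode \code{"reference"}, \code{"population"}, or a
#'   training site id.
#' @param allow_unconverged Permit prediction from a model whose fit did
#'   not converge.
#' @return \code{data.frame} with columns \code{mu, sigma, nu, tau}.
#' @export
predict_params <- function(model, age, sex, site_mode = "reference",
                           allow_unconverged = FALSE) {
  stopifnot(inherits(model, "normative_model"))
  if (!model$fit$converged && !allow_unconverged)
    stop("model did not converge; pass allow_unconverged = TRUE to override")
  rng <- model$fit$age_range
  if (any(age < rng[1] | age > rng[2]))
    warning("age outside the training range [", rng[1], ", ", rng[2],
            "]; extrapolating with boundary values")
  site <- if (identical(site_mode, "reference")) model$reference_site
          else site_mode
  sub <- model$submodels
  mu <- eval_submodel(sub$mu, age, sex, site_effect_of(sub$mu, site_mode, site))
  sigma <- exp(eval_submodel(sub$sigma, age, sex,
                             site_effect_of(sub$sigma, site_mode, site)))
  nu <- if (sub$nu$free) eval_submodel(sub$nu, age, sex, 0)
        else rep(model$neutral$nu, length(age))
  tau <- if (sub$tau$free) exp(eval_submodel(sub$tau, age, sex, 0))
         else rep(model$neutral$tau, length(age))
  data.frame(mu = mu, sigma = sigma, nu = nu, tau = tau)
}

#' Centile curves over an age grid
#'
#' Inverse-CDF curves of the fitted family at the requested probabilities,
#' evaluated along an age grid for one sex.
#'
#' @inheritParams predict_params
#' @param ages Numeric age grid.
#' @param centiles Probabilities in (0, 1).
#' @return \code{data.frame} with columns \code{age}, \code{centile}
#'   (probability), \code{value}.
#' @export
centile_curves <- function(model, ages, sex, centiles = c(0.05, 0.25, 0.5,
                                                          0.75, 0.95),
                           site_mode = "reference") {
  stopifnot(all(centiles > 0 & centiles < 1))
  fam <- bn_family(model$family)
  pp <- predict_params(model, ages, sex, site_mode)
  out <- do.call(rbind, lapply(centiles, function(p)
    data.frame(age = ages, centile = p,
               value = fam$qfun(p, pp$mu, pp$sigma, pp$nu, pp$tau))))
  rownames(out) <- NULL
  out
}

# per-subject parameter prediction with each subject's own site effect
predict_for_cohort <- function(model, meta, site_mode = c("own", "reference",
                                                          "population")) {
  site_mode <- match.arg(site_mode)
  if (site_mode != "own") {
    return(predict_params(model, meta$age, meta$sex, site_mode,
                          allow_unconverged = TRUE))
  }
  out <- vector("list", nrow(meta))
  for (s in unique(meta$site)) {
    i <- which(meta$site == s)
    mode <- if (model$submodels$mu$with_site &&
                s %in% model$submodels$mu$site_levels) s else "population"
    out[i] <- split(
      predict_params(model, meta$age[i], meta$sex[i], mode,
                     allow_unconverged = TRUE),
      seq_along(i))
  }
  do.call(rbind, out)
}

#' Variance explained by a fitted normative model
#'
#' \eqn{R^2 = 1 - SS_{resid}/SS_{total}} on the modelled (log) scale,
#' residuals taken about the fitted location including each subject's own
#' site effect.
#'
#' @param model A \code{"normative_model"}.
#' @param cohort Cohort to evaluate on (training cohort for in-sample
#'   R-squared). Only controls are used.
#' @return Numeric scalar in \eqn{(-\infty, 1]}.
#' @export
model_r2 <- function(model, cohort) {
  d <- extract_target(cohort, model)
  pp <- predict_for_cohort(model, d$meta, "own")
  ss_tot <- sum((d$y - mean(d$y))^2)
  if (ss_tot == 0) stop("zero variance in the response")
  1 - sum((d$y - pp$mu)^2) / ss_tot
}

#' Normalised quantile residuals of a cohort under a fitted model
#'
#' Maps each observation through the fitted conditional CDF and the
#' standard-normal quantile function; for a well-calibrated model these
#' are standard normal.
#'
#' @inheritParams model_r2
#' @return Numeric vector, one value per control subject.
#' @export
quantile_residuals <- function(model, cohort) {
  fam <- bn_family(model$family)
  d <- extract_target(cohort, model)
  pp <- predict_for_cohort(model, d$meta, "own")
  u <- fam$pfun(d$y, pp$mu, pp$sigma, pp$nu, pp$tau)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

extract_target <- function(cohort, model) {
  t <- model$target
  m <- cohort$morphometry
  rows <- m[m$region == t$region & m$hemisphere == t$hemisphere &
              m$metric == t$metric, ]
  if (!nrow(rows)) stop("cohort has no data for the model's target")
  meta <- cohort$meta[match(rows$subject_id, cohort$meta$subject_id), ]
  keep <- meta$group == "control"
  list(y = rows$value[keep], meta = meta[keep, , drop = FALSE],
       subject_id = rows$subject_id[keep])
}

#' @export
print.normative_model <- function(x, ...) {
  cat("normative model (", x$family, "): ",
      x$target$hemisphere, " ", x$target$region, " ", x$target$metric, "\n",
      "  n = ", x$fit$n, ", sites = ", x$fit$n_sites,
      ", reference site = ", x$reference_site, "\n",
      "  converged = ", x$fit$converged, " in ", x$fit$iterations,
      " iterations; R^2 = ", round(x$fit$r2, 3), "\n", sep = "")
  invisible(x)
}

# ---- model sets ---------------------------------------------------------

target_key <- function(region, hemisphere, metric)
  paste(region, hemisphere, metric, sep = "|")

#' Fit normative models for many targets
#'
#' Fits one \code{\link{fit_normative}} model per requested
#' region x hemisphere x metric combination (default: all combinations
#' present in the cohort), on the identical post-QC subject list.
#'
#' @param cohort Training cohort of healthy controls.
#' @param targets Optional data.frame/matrix with columns region,
#'   hemisphere, metric; default all combinations in the cohort.
#' @param config A \code{\link{fit_config}}.
#' @return Object of class \code{"modelset"}: list of models keyed
#'   \code{"region|hemisphere|metric"} plus a training summary.
#' @export
fit_modelset <- function(cohort, targets = NULL, config = fit_config()) {
  m <- cohort$morphometry
  if (is.null(targets))
    targets <- unique(m[c("region", "hemisphere", "metric")])
  targets <- as.data.frame(targets)
  models <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- as.character(unlist(targets[i, c("region", "hemisphere", "metric")]))
    models[[target_key(tg[1], tg[2], tg[3])]] <-
      fit_normative(cohort, tg, config)
  }
  structure(list(
    models = models,
    training_summary = list(
      n_subjects = length(unique(cohort$meta$subject_id)),
      n_sites = length(unique(cohort$meta$site)),
      age_range = range(cohort$meta$age))),
    class = "modelset")
}

#' @export
print.modelset <- function(x, ...) {
  cat("brainnorm modelset:", length(x$models), "model(s);",
      x$training_summary$n_subjects, "training subjects across",
      x$training_summary$n_sites, "site(s)\n")
  invisible(x)
}

# ---- JSON serialisation -------------------------------------------------

model_to_list <- function(model) {
  out <- unclass(model)
  out$vcov <- NULL                     # kept in memory only
  out$submodels <- lapply(out$submodels, function(s) {
    s$spec$Q2 <- as.list(as.data.frame(s$spec$Q2))
    s$coef <- as.list(s$coef)
    s$se <- if (!is.null(s$se)) as.list(s$se)
    s
  })
  out
}

list_to_model <- function(lst) {
  lst$submodels <- lapply(lst$submodels, function(s) {
    s$spec$Q2 <- as.matrix(as.data.frame(s$spec$Q2))
    s$coef <- unlist(s$coef)
    s$se <- if (!is.null(s$se)) unlist(s$se)
    s$site_levels <- unlist(s$site_levels)
    s
  })
  lst$fit$age_range <- unlist(lst$fit$age_range)
  structure(lst, class = "normative_model")
}

#' Save / load a fitted model set as versioned JSON
#'
#' Serialises every fitted model (family id, spline bases, coefficients,
#' site tables, diagnostics) so pre-trained model sets can be shipped and
#' reloaded without refitting.
#'
#' @param modelset A \code{"modelset"}.
#' @param path Output JSON path.
#' @return \code{path} (save) or the restored \code{"modelset"} (load).
#' @export
save_modelset <- function(modelset, path) {
  stopifnot(inherits(modelset, "modelset"))
  payload <- list(
    format = "brainnorm-modelset",
    format_version = 1L,
    package_version = as.character(packageVersion("brainnorm")),
    training_summary = modelset$training_summary,
    models = lapply(modelset$models, model_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_modelset
#' @export
load_modelset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "brainnorm-modelset"))
    stop("not a brainnorm modelset file")
  models <- lapply(payload$models, list_to_model)
  ts <- payload$training_summary
  ts$age_range <- unlist(ts$age_range)
  structure(list(models = models, training_summary = ts),
            class = "modelset")
}
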