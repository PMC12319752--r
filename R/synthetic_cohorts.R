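# Seeded multi-site synthetic cohort generator with known ground truth.
#
# Emulates the statistical structure the normative models assume: a
# smooth age trajectory with steeper decline in early and late life, a
# fixed sex offset, random per-site mean and scale perturbations, and
# sinh-arcsinh noise whose scale may drift linearly with age. All
# generating parameters are recorded so the generator is its own oracle.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a multi-site healthy cohort spanning the normative age range
#' 5-95 years with modest scanner-site perturbations on the base-10 log
#' scale of a thickness-like metric.
#'
#' @param n_subjects Number of subjects.
#' @param n_sites Number of scanning sites (multinomial assignment,
#'   balanced expected sizes).
#' @param site_offset_sd SD of random per-site mean shifts, log10 units.
#' @param site_scale_sd SD of log multiplicative per-site scale factors.
#' @param age_range Age support in years.
#' @param sex_effect Additive male-minus-female offset, log10 units.
#' @param age_knots,age_values Control points of the median age
#'   trajectory (log10 scale); interpolated monotonically. The default
#'   declines steeply before age 20 and after 65 and gently in between.
#' @param sigma Noise SD at the ends of the age range,
#'   \code{c(at_min_age, at_max_age)}, log10 units; linear in age.
#' @param nu,tau Skew and tail-weight of the sinh-arcsinh noise
#'   (0 and 1 give Gaussian noise).
#' @param hemi_corr Gaussian-copula correlation of the left and right
#'   noise within a region; real hemispheric morphometry is strongly
#'   correlated, which narrows the control left-right difference
#'   distribution.
#' @param regions Region labels to simulate (both hemispheres each).
#' @param metric Metric name for the simulated values.
#' @param region_spread Half-range of fixed per-region baseline shifts.
#' @param seed Mandatory RNG seed.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 2000, n_sites = 5,
                       site_offset_sd = 0.02, site_scale_sd = 0.15,
                       age_range = c(5, 95), sex_effect = 0.01,
                       age_knots = c(5, 20, 65, 95),
                       age_values = log10(c(2.9, 2.65, 2.5, 2.2)),
                       sigma = c(0.02, 0.02), nu = 0, tau = 1,
                       hemi_corr = 0.8,
                       regions = "bankssts", metric = "thickness_mm",
                       region_spread = 0.04, seed) {
  if (missing(seed)) stop("sim_config: 'seed' is mandatory")
  stopifnot(n_subjects >= 1, n_sites >= 1, site_offset_sd >= 0,
            site_scale_sd >= 0, all(sigma >= 0), tau > 0,
            hemi_corr >= 0, hemi_corr <= 1,
            length(age_range) == 2, age_range[1] < age_range[2])
  bad <- setdiff(regions, c(DK_REGIONS, "hemisphere"))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  structure(list(n_subjects = n_subjects, n_sites = n_sites,
                 site_offset_sd = site_offset_sd,
                 site_scale_sd = site_scale_sd, age_range = age_range,
                 sex_effect = sex_effect, age_knots = age_knots,
                 age_values = age_values, sigma = sigma, nu = nu, tau = tau,
                 hemi_corr = hemi_corr, regions = regions, metric = metric,
                 region_spread = region_spread, seed = seed),
            class = "sim_config")
}

age_curve_fun <- function(config) {
  splinefun(config$age_knots, config$age_values, method = "hyman")
}

sigma_at <- function(config, age) {
  r <- config$age_range
  config$sigma[1] + (config$sigma[2] - config$sigma[1]) *
    (age - r[1]) / (r[2] - r[1])
}

#' Simulate a multi-site healthy cohort
#'
#' Draws subjects with uniform age, balanced sex, and multinomial site
#' assignment, then generates, for every region x hemisphere, values
#' \deqn{y = b_r + f(age) + \beta_{sex}\,[male] + \delta_{site} +
#'   \epsilon,\qquad \epsilon \sim SHASH(0,\; \sigma(age)\,s_{site},\;
#'   \nu,\; \tau),}
#' where \eqn{f} is the configured age trajectory, \eqn{b_r} a fixed
#' per-region baseline, \eqn{\delta_{site}} and \eqn{s_{site}} the random
#' site mean shift and scale factor. The full set of generating
#' parameters is attached as attribute \code{"ground_truth"}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{"cohort"} object; \code{attr(, "ground_truth")} holds
#'   every generating parameter, including realised site offsets/scales.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("sub-%05d", seq_len(n))
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(rep(c("female", "male"), length.out = n))
  site_levels <- sprintf("site%02d", seq_len(config$n_sites))
  site <- sample(site_levels, n, replace = TRUE)
  site_offset <- setNames(rnorm(config$n_sites, 0, config$site_offset_sd),
                          site_levels)
  site_scale <- setNames(exp(rnorm(config$n_sites, 0, config$site_scale_sd)),
                         site_levels)
  f_age <- age_curve_fun(config)
  regions <- config$regions
  baseline <- if (length(regions) > 1)
    setNames(seq(-config$region_spread, config$region_spread,
                 length.out = length(regions)), regions)
  else setNames(0, regions)

  fam <- bn_family("shash")
  sig_i <- sigma_at(config, age) * site_scale[site]
  det_i <- f_age(age) + config$sex_effect * (sex == "male") +
    site_offset[site]

  # hemispheric noise via a Gaussian copula: a shared and a
  # hemisphere-specific normal component, pushed through the
  # sinh-arcsinh quantile so the marginals stay exact
  shash_noise <- function(z)
    sig_i * sinh((asinh(z) + config$nu) / config$tau)
  blocks <- list()
  for (r in regions) {
    z_shared <- rnorm(n)
    for (h in c("left", "right")) {
      z_h <- sqrt(config$hemi_corr) * z_shared +
        sqrt(1 - config$hemi_corr) * rnorm(n)
      noise <- if (all(sig_i == 0)) numeric(n) else shash_noise(z_h)
      blocks[[paste(r, h)]] <- data.frame(
        subject_id = ids, hemisphere = h, region = r,
        metric = config$metric, value = baseline[r] + det_i + noise,
        stringsAsFactors = FALSE)
    }
  }
  morph <- do.call(rbind, blocks)
  rownames(morph) <- NULL
  meta <- data.frame(subject_id = ids, age = age, sex = sex,
                     group = "control", dataset = "synthetic",
                     site = site, session = "ses-01",
                     stringsAsFactors = FALSE)
  cohort <- structure(list(morphometry = morph, meta = meta,
                           join_report = list(morphometry_only = character(0),
                                              metadata_only = character(0))),
                      class = "cohort")
  attr(cohort, "ground_truth") <- list(
    config = unclass(config),
    site_offset = site_offset, site_scale = site_scale,
    baseline = baseline,
    age_curve = f_age,
    noise_sd = function(a) sigma_at(config, a))
  cohort
}

#' Inject a disease effect into a simulated cohort
#'
#' Relabels a subset of subjects as patients and shifts their values in
#' the targeted regions by \code{effect_size} control (noise) standard
#' deviations, optionally lateralised to one hemisphere. The control SD
#' is the generator's noise SD for each subject's site and age (taken
#' from the cohort's ground truth); for cohorts without ground truth the
#' empirical residual SD about an age trend is used.
#'
#' @param cohort A \code{"cohort"}, typically from
#'   \code{\link{simulate_cohort}}.
#' @param regions Region labels to perturb.
#' @param effect_size Shift in control-SD units (negative = reduction).
#' @param side \code{"both"}, \code{"left"}, or \code{"right"}.
#' @param n_patients Number of subjects to relabel.
#' @param metric Metric to perturb (default: all metrics present).
#' @param label Group label given to the relabelled subjects.
#' @param seed Seed for the patient draw.
#' @return The modified cohort; \code{attr(, "disease_truth")} records
#'   the injected specification and the chosen subject ids.
#' @export
inject_disease <- function(cohort, regions, effect_size, side = "both",
                           n_patients, metric = NULL, label = "patient",
                           seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  side <- match.arg(side, c("both", "left", "right"))
  bad <- setdiff(regions, unique(cohort$morphometry$region))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  ctrl <- cohort$meta$subject_id[cohort$meta$group == "control"]
  if (n_patients > length(ctrl))
    stop("n_patients exceeds the number of control subjects")
  set.seed(seed)
  chosen <- sample(ctrl, n_patients)
  cohort$meta$group[cohort$meta$subject_id %in% chosen] <- label

  gt <- attr(cohort, "ground_truth")
  m <- cohort$morphometry
  hemi_ok <- if (side == "both") c("left", "right") else side
  sel <- m$subject_id %in% chosen & m$region %in% regions &
    m$hemisphere %in% hemi_ok
  if (!is.null(metric)) sel <- sel & m$metric == metric
  if (any(sel)) {
    meta_idx <- match(m$subject_id[sel], cohort$meta$subject_id)
    sd_i <- if (!is.null(gt))
      gt$noise_sd(cohort$meta$age[meta_idx]) *
        gt$site_scale[cohort$meta$site[meta_idx]]
    else {
      r <- resid(lm(m$value[sel] ~ cohort$meta$age[meta_idx]))
      rep(sd(r), sum(sel))
    }
    m$value[sel] <- m$value[sel] + effect_size * sd_i
  }
  cohort$morphometry <- m
  attr(cohort, "disease_truth") <- list(
    regions = regions, effect_size = effect_size, side = side,
    subjects = chosen, metric = metric, label = label)
  cohort
}

#' Simulate a hemisphere-level folding table
#'
#' Generates plausible total pial area, exposed area, and average
#' thickness per subject and hemisphere (log-normal variation around
#' adult human magnitudes) for exercising the folding-component
#' pipeline.
#'
#' @param n_subjects Number of subjects.
#' @param seed RNG seed.
#' @return Tidy morphometry \code{data.frame} with the three folding
#'   metrics at region \code{"hemisphere"}.
#' @export
simulate_folding_table <- function(n_subjects = 50, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  ids <- sprintf("sub-%05d", seq_len(n_subjects))
  blocks <- lapply(c("left", "right"), function(h) {
    A_t <- 10^rnorm(n_subjects, log10(9e4), 0.05)
    A_e <- A_t * runif(n_subjects, 0.35, 0.45)
    T_avg <- 10^rnorm(n_subjects, log10(2.5), 0.03)
    do.call(rbind, list(
      data.frame(subject_id = ids, hemisphere = h, region = "hemisphere",
                 metric = "total_pial_area_mm2", value = A_t),
      data.frame(subject_id = ids, hemisphere = h, region = "hemisphere",
                 metric = "exposed_area_mm2", value = A_e),
      data.frame(subject_id = ids, hemisphere = h, region = "hemisphere",
                 metric = "avg_thickness_mm", value = T_avg)))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort in the three input dialects
#'
#' Emits an aparcstats2table-style wide file per hemisphere, a metadata
#' CSV, and (if folding metrics are present) a folding-toolbox table, so
#' the file readers can be exercised end to end.
#'
#' @param cohort A \code{"cohort"}.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$morphometry
  paths <- list()
  aparc_metric <- c(thickness_mm = "thickness", volume_mm3 = "volume",
                    area_mm2 = "area")
  std <- m[m$metric %in% names(aparc_metric) & m$region != "hemisphere", ]
  for (h in intersect(c("left", "right"), unique(std$hemisphere))) {
    hm <- std[std$hemisphere == h, ]
    pre <- if (h == "left") "lh" else "rh"
    wide <- reshape(
      transform(hm, col = paste0(pre, "_", region, "_",
                                 aparc_metric[metric]))[
        c("subject_id", "col", "value")],
      idvar = "subject_id", timevar = "col", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    names(wide)[1] <- paste0(pre, ".aparc.stats")
    p <- file.path(dir, paste0("aparc_", h, ".csv"))
    write.csv(wide, p, row.names = FALSE, quote = FALSE)
    paths[[paste0("aparc_", h)]] <- p
  }
  fold <- m[m$metric %in% c("total_pial_area_mm2", "exposed_area_mm2",
                            "avg_thickness_mm"), ]
  if (nrow(fold)) {
    wide <- reshape(fold[c("subject_id", "hemisphere", "metric", "value")],
                    idvar = c("subject_id", "hemisphere"), timevar = "metric",
                    direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    names(wide) <- sub("_mm2?$", "", names(wide))
    p <- file.path(dir, "folding.csv")
    write.csv(wide, p, row.names = FALSE, quote = FALSE)
    paths$folding <- p
  }
  p <- file.path(dir, "metadata.csv")
  write.csv(cohort$meta, p, row.names = FALSE, quote = FALSE)
  paths$metadata <- p
  paths
}
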