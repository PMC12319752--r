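# Harmonisation of unseen sites via their healthy controls, and
# per-subject z-scores and centiles against the normative distribution.

#' Estimate the harmonisation adjustment for an unseen site
#'
#' Predicts the normative location for each healthy control of the new
#' site relative to the model's reference site and takes the mean
#' residual as the site-specific offset. The scoring standard deviation
#' follows the 30-control rule: with 30 or more controls it is the SD of
#' their residuals; with fewer, the average residual SD across the
#' normative training sites is used instead, since small samples estimate
#' an SD poorly (see \code{\link{sd_rule_probability}}).
#'
#' @param model A \code{"normative_model"}.
#' @param new_hc Cohort containing only healthy controls from a single
#'   unseen site.
#' @param sd_weighting \code{"unweighted"} (default) or \code{"by_n"}:
#'   how training-site residual SDs are averaged when the control count
#'   is below 30.
#' @return Object of class \code{"site_adjustment"}: \code{site},
#'   \code{offset}, \code{sd}, \code{sd_source}, \code{n_hc}.
#' @export
estimate_site_adjustment <- function(model, new_hc,
                                     sd_weighting = c("unweighted", "by_n")) {
  sd_weighting <- match.arg(sd_weighting)
  stopifnot(inherits(model, "normative_model"), inherits(new_hc, "cohort"))
  if (!nrow(new_hc$meta)) stop("healthy controls required for unseen site")
  if (any(new_hc$meta$group != "control"))
    stop("non-control subjects present; the site adjustment must be ",
         "estimated from healthy controls only")
  sites <- unique(new_hc$meta$site)
  if (length(sites) != 1)
    stop("expected a single site, found: ", paste(sites, collapse = ", "))
  d <- extract_target(new_hc, model)
  if (!length(d$y)) stop("healthy controls required for unseen site")
  pp <- predict_params(model, d$meta$age, d$meta$sex, "reference",
                       allow_unconverged = TRUE)
  r <- d$y - pp$mu
  n_hc <- length(r)
  if (n_hc >= 30) {
    sd_val <- sd(r)
    sd_source <- "unseen_hc"
  } else {
    sds <- unlist(model$per_site_residual_sd)
    w <- if (sd_weighting == "by_n")
      unlist(model$site_n)[names(model$per_site_residual_sd)]
    else rep(1, length(sds))
    sd_val <- sum(sds * w) / sum(w)
    sd_source <- "normative_average"
  }
  structure(list(site = sites, offset = mean(r), sd = sd_val,
                 sd_source = sd_source, n_hc = n_hc),
            class = "site_adjustment")
}

#' @export
print.site_adjustment <- function(x, ...) {
  cat("site adjustment for '", x$site, "': offset = ",
      signif(x$offset, 4), ", sd = ", signif(x$sd, 4), " (",
      x$sd_source, ", n_hc = ", x$n_hc, ")\n", sep = "")
  invisible(x)
}

score_inputs <- function(model, adj, subjects) {
  stopifnot(inherits(model, "normative_model"),
            inherits(adj, "site_adjustment"),
            inherits(subjects, "cohort"))
  if (!all(subjects$meta$site == adj$site))
    stop("subjects' site does not match the adjustment's site '",
         adj$site, "'")
  t <- model$target
  m <- subjects$morphometry
  rows <- m[m$region == t$region & m$hemisphere == t$hemisphere &
              m$metric == t$metric, ]
  if (!nrow(rows)) stop("no data for the model's target in 'subjects'")
  meta <- subjects$meta[match(rows$subject_id, subjects$meta$subject_id), ]
  if (anyNA(meta$age) || anyNA(meta$sex))
    stop("missing covariates for subject(s): ",
         paste(rows$subject_id[is.na(meta$age) | is.na(meta$sex)],
               collapse = ", "))
  list(rows = rows, meta = meta)
}

#' Z-scores for subjects at a harmonised site
#'
#' \eqn{z_i = (y_i - \mu_{ref}(age_i, sex_i) - offset) / sd} with the
#' site offset and SD from \code{\link{estimate_site_adjustment}}.
#'
#' @param model A \code{"normative_model"}.
#' @param adj A \code{"site_adjustment"} for the subjects' site.
#' @param subjects Cohort of subjects (controls and/or patients) from
#'   that site.
#' @return \code{data.frame}: subject_id, region, hemisphere, metric, z.
#' @export
compute_zscores <- function(model, adj, subjects) {
  si <- score_inputs(model, adj, subjects)
  pp <- predict_params(model, si$meta$age, si$meta$sex, "reference",
                       allow_unconverged = TRUE)
  z <- (si$rows$value - pp$mu - adj$offset) / adj$sd
  data.frame(subject_id = si$rows$subject_id,
             region = si$rows$region, hemisphere = si$rows$hemisphere,
             metric = si$rows$metric, z = z, stringsAsFactors = FALSE)
}

#' Centiles for subjects at a harmonised site
#'
#' Each subject's value is mapped through the family CDF of the
#' distribution whose mean is the site-adjusted location
#' (\eqn{\mu_{ref} + offset}), whose SD is the site-specific scoring SD,
#' and whose skew and kurtosis are predicted at the subject's own age
#' (and sex, for skew). Because the harmonisation offset and the
#' 30-control rule estimate a mean and an SD, the family's location and
#' scale are solved from those two moments rather than used verbatim;
#' for the Gaussian the two parameterisations coincide. Centiles are
#' clipped to [0.01, 99.99]; the \code{clipped} column flags affected
#' subjects.
#'
#' @inheritParams compute_zscores
#' @return \code{data.frame}: subject_id, region, hemisphere, metric,
#'   centile, clipped.
#' @export
compute_centiles <- function(model, adj, subjects) {
  si <- score_inputs(model, adj, subjects)
  fam <- bn_family(model$family)
  pp <- predict_params(model, si$meta$age, si$meta$sex, "reference",
                       allow_unconverged = TRUE)
  scale <- adj$sd / fam$sdz(pp$nu, pp$tau)
  loc <- pp$mu + adj$offset - scale * fam$meanz(pp$nu, pp$tau)
  cent <- 100 * fam$pfun(si$rows$value, loc, scale, pp$nu, pp$tau)
  clipped <- cent < 0.01 | cent > 99.99
  cent <- pmin(pmax(cent, 0.01), 99.99)
  data.frame(subject_id = si$rows$subject_id,
             region = si$rows$region, hemisphere = si$rows$hemisphere,
             metric = si$rows$metric, centile = cent, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Score a full cohort against a model set
#'
#' Splits the cohort by site, estimates each site's adjustment from its
#' own healthy controls (sites are harmonised independently), and scores
#' every subject under every model. A site without controls is an error:
#' a healthy-control cohort from each unseen site is required.
#'
#' @param modelset A \code{"modelset"}.
#' @param cohort Cohort of subjects to score (may mix controls and
#'   patients across several sites).
#' @return \code{data.frame} with one row per subject x region x
#'   hemisphere x metric: z, centile, clipped, site.
#' @export
score_cohort <- function(modelset, cohort) {
  stopifnot(inherits(modelset, "modelset"), inherits(cohort, "cohort"))
  out <- list()
  for (s in unique(cohort$meta$site)) {
    ids <- cohort$meta$subject_id[cohort$meta$site == s]
    sub <- subset_cohort(cohort, ids)
    hc_ids <- sub$meta$subject_id[sub$meta$group == "control"]
    if (!length(hc_ids))
      stop("healthy controls required for unseen site '", s, "'")
    hc <- subset_cohort(sub, hc_ids)
    for (key in names(modelset$models)) {
      model <- modelset$models[[key]]
      adj <- estimate_site_adjustment(model, hc)
      z <- compute_zscores(model, adj, sub)
      cent <- compute_centiles(model, adj, sub)
      z$centile <- cent$centile
      z$clipped <- cent$clipped
      z$site <- s
      out[[paste(s, key)]] <- z
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# restrict a cohort to a set of subject ids
subset_cohort <- function(cohort, ids) {
  structure(list(
    morphometry = cohort$morphometry[
      cohort$morphometry$subject_id %in% ids, , drop = FALSE],
    meta = cohort$meta[cohort$meta$subject_id %in% ids, , drop = FALSE],
    join_report = cohort$join_report), class = "cohort")
}

#' Probability that a sample SD is within a given accuracy of the truth
#'
#' Monte-Carlo estimate of \eqn{P(|s/\sigma - 1| \le a)} for the sample
#' SD \eqn{s} of \eqn{n} independent standard-normal draws, with the
#' exact chi-square value for cross-checking. This is the calculation
#' behind the 30-control rule: n = 30 gives roughly a 55\% chance of
#' being within 10\% of the true SD and roughly 95\% within 25\%.
#'
#' @param n Sample size (>= 2).
#' @param accuracy Relative accuracy a > 0.
#' @param reps Monte-Carlo replicates (>= 10000).
#' @param seed RNG seed.
#' @return List: \code{p_mc} (Monte-Carlo), \code{p_exact} (chi-square
#'   closed form), \code{mc_se} (Monte-Carlo standard error).
#' @export
sd_rule_probability <- function(n, accuracy, reps = 1e5, seed = 1L) {
  stopifnot(n >= 2, reps >= 1e4)
  if (accuracy <= 0) stop("'accuracy' must be positive")
  set.seed(seed)
  x <- matrix(rnorm(n * reps), nrow = n)
  s <- sqrt((colSums(x^2) - colSums(x)^2 / n) / (n - 1))
  p_mc <- mean(abs(s - 1) <= accuracy)
  lo <- max(0, 1 - accuracy)
  p_exact <- pchisq((1 + accuracy)^2 * (n - 1), n - 1) -
    pchisq(lo^2 * (n - 1), n - 1)
  list(p_mc = p_mc, p_exact = p_exact,
       mc_se = sqrt(p_mc * (1 - p_mc) / reps))
}
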