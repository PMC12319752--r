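# Residual-based statistical quality control with listwise exclusion.

#' Flag outlying residuals by median absolute deviation
#'
#' Flags residuals lying more than \code{k} (default 5) median absolute
#' deviations from the median. The MAD is scaled by the normal
#' consistency constant 1.4826 by default so \code{k} is in SD-like
#' units; set \code{constant = 1} for the raw-MAD reading.
#'
#' @param residuals Numeric vector, length >= 3.
#' @param k Threshold in MAD units.
#' @param constant MAD scale constant (1.4826 = consistent for normal).
#' @return Logical vector of flags. If the MAD is zero no observation is
#'   flagged and a degenerate-scale warning is raised.
#' @export
flag_outliers <- function(residuals, k = 5, constant = 1.4826) {
  if (length(residuals) < 3)
    stop("at least 3 residuals are required")
  med <- median(residuals)
  scale <- mad(residuals, center = med, constant = constant)
  if (scale == 0) {
    warning("degenerate residual scale (MAD = 0); nothing flagged")
    return(rep(FALSE, length(residuals)))
  }
  abs(residuals - med) / scale > k
}

#' Listwise exclusion across outlier reports
#'
#' A subject flagged in any model is excluded from all models, so every
#' normative model is trained on the identical reference set and model
#' statistics stay comparable across models.
#'
#' @param reports List of outlier reports; each either a character
#'   vector of flagged subject ids or a list with element
#'   \code{flagged_subjects}.
#' @param universe Character vector of all candidate subject ids.
#' @return Character vector of retained subjects (flagged in no model).
#' @export
listwise_exclude <- function(reports, universe) {
  flagged <- unique(unlist(lapply(reports, function(r)
    if (is.list(r)) r$flagged_subjects else r)))
  retained <- setdiff(universe, flagged)
  if (!length(retained)) stop("empty training set: every subject was flagged")
  retained
}

#' Fit-flag-exclude quality control pass over a cohort
#'
#' Fits a normative model per target, flags subjects whose residuals
#' (about the fitted location, own-site effects included) exceed the MAD
#' threshold, and excludes flagged subjects listwise.
#'
#' @param cohort Training cohort (controls).
#' @param targets Optional targets data.frame as in
#'   \code{\link{fit_modelset}}.
#' @param config A \code{\link{fit_config}}.
#' @param k,constant Passed to \code{\link{flag_outliers}}.
#' @return List of class \code{"qc_report"}: per-target flag tables,
#'   \code{excluded_subjects}, \code{retained_subjects}, and the
#'   filtered \code{cohort}.
#' @export
run_qc <- function(cohort, targets = NULL, config = fit_config(),
                   k = 5, constant = 1.4826) {
  m <- cohort$morphometry
  if (is.null(targets))
    targets <- unique(m[c("region", "hemisphere", "metric")])
  targets <- as.data.frame(targets)
  per_target <- list()
  reports <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- as.character(unlist(targets[i, c("region", "hemisphere",
                                           "metric")]))
    model <- fit_normative(cohort, tg, config)
    d <- extract_target(cohort, model)
    pp <- predict_for_cohort(model, d$meta, "own")
    r <- d$y - pp$mu
    fl <- flag_outliers(r, k = k, constant = constant)
    key <- target_key(tg[1], tg[2], tg[3])
    per_target[[key]] <- data.frame(subject_id = d$subject_id,
                                    residual = r, flagged = fl,
                                    stringsAsFactors = FALSE)
    reports[[key]] <- d$subject_id[fl]
  }
  universe <- unique(cohort$meta$subject_id)
  retained <- listwise_exclude(reports, universe)
  excluded <- setdiff(universe, retained)
  structure(list(per_target = per_target,
                 excluded_subjects = excluded,
                 retained_subjects = retained,
                 threshold_mads = k, mad_constant = constant,
                 cohort = subset_cohort(cohort, retained)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("brainnorm QC:", length(x$per_target), "model(s);",
      length(x$excluded_subjects), "subject(s) excluded listwise at",
      x$threshold_mads, "MADs\n")
  invisible(x)
}
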