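# Group-level abnormality summaries and hemispheric lateralisation.

#' Cohen's d standardised mean difference
#'
#' \eqn{d = (\bar{a} - \bar{b}) / s_p} with the pooled SD
#' \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}.
#'
#' @param z_a,z_b Numeric vectors (each length >= 2).
#' @return Numeric scalar.
#' @export
cohens_d <- function(z_a, z_b) {
  z_a <- z_a[!is.na(z_a)]; z_b <- z_b[!is.na(z_b)]
  n_a <- length(z_a); n_b <- length(z_b)
  if (n_a < 2 || n_b < 2) stop("both groups need at least 2 observations")
  sp <- sqrt(((n_a - 1) * var(z_a) + (n_b - 1) * var(z_b)) /
               (n_a + n_b - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(z_a) - mean(z_b)) / sp
}

#' Group-level abnormality summary per region
#'
#' Summarises patient z-scores per region x hemisphere x metric as an
#' effect size. In \code{case_control} mode the patients' z-scores are
#' compared with the uploaded control group's by Cohen's d. In
#' \code{normative} mode patients are compared against the normative
#' reference population, whose z-scores are 0 with unit SD by
#' construction, via the one-sample standardised mean
#' \eqn{d = \bar{z}_p / s_{z_p}}.
#'
#' @param scores Score table from \code{\link{score_cohort}} (or any
#'   data.frame with subject_id, region, hemisphere, metric, z).
#' @param meta Metadata with subject_id and group.
#' @param mode \code{"case_control"} or \code{"normative"}.
#' @param patient_label Group label identifying patients; default: every
#'   non-control group.
#' @return \code{data.frame} per region x hemisphere x metric: d,
#'   mean_z_patients, mean_z_controls, n_patients, n_controls, mode.
#' @export
group_abnormality <- function(scores, meta,
                              mode = c("case_control", "normative"),
                              patient_label = NULL) {
  mode <- match.arg(mode)
  grp <- meta$group[match(scores$subject_id, meta$subject_id)]
  if (anyNA(grp)) stop("scores contain subjects absent from the metadata")
  is_pat <- if (is.null(patient_label)) grp != "control"
            else grp == patient_label
  if (!any(is_pat)) stop("no patients found")
  if (mode == "case_control" && !any(grp == "control"))
    stop("case_control mode requires a control group")
  keys <- unique(scores[c("region", "hemisphere", "metric")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- scores$region == keys$region[i] &
      scores$hemisphere == keys$hemisphere[i] &
      scores$metric == keys$metric[i]
    zp <- scores$z[sel & is_pat]
    zc <- scores$z[sel & grp == "control"]
    zp <- zp[!is.na(zp)]; zc <- zc[!is.na(zc)]
    d <- if (mode == "case_control") cohens_d(zp, zc)
         else if (sd(zp) > 0) mean(zp) / sd(zp)
         else if (mean(zp) == 0) 0
         else stop("zero patient z-score SD with a nonzero mean")
    data.frame(region = keys$region[i], hemisphere = keys$hemisphere[i],
               metric = keys$metric[i], d = d,
               mean_z_patients = mean(zp),
               mean_z_controls = if (length(zc)) mean(zc) else NA_real_,
               n_patients = length(zp), n_controls = length(zc),
               mode = mode, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lateralisation from hemispheric z-score differences
#'
#' Computes \eqn{\Delta z = z_{left} - z_{right}} per subject and calls
#' the more abnormal hemisphere. With \code{direction =
#' "lower_abnormal"} (atrophy-like metrics) a negative \eqn{\Delta z}
#' implicates the left hemisphere. A subject exceeds the control range
#' when \eqn{|\Delta z - \bar{\Delta z}_{ctrl}| > 2\,SD(\Delta
#' z_{ctrl})}. If true side labels are supplied a confusion matrix and
#' accuracy are returned (subjects with \eqn{\Delta z = 0} are
#' indeterminate and count as errors).
#'
#' @param scores_left,scores_right Data frames with subject_id and z for
#'   each hemisphere (same subjects).
#' @param control_delta Numeric vector of control \eqn{\Delta z} values
#'   (length >= 10).
#' @param direction \code{"lower_abnormal"} or \code{"higher_abnormal"}.
#' @param true_side Optional named character vector (or vector aligned
#'   with subjects) of true sides \code{"left"}/\code{"right"}.
#' @return List of class \code{"laterality_result"}: per-subject table
#'   (delta_z, predicted_side, exceeds_2sd), and, when \code{true_side}
#'   is given, \code{confusion} and \code{accuracy}.
#' @export
lateralize <- function(scores_left, scores_right, control_delta,
                       direction = c("lower_abnormal", "higher_abnormal"),
                       true_side = NULL) {
  direction <- match.arg(direction)
  if (length(control_delta) < 10)
    stop("at least 10 control delta-z values are required")
  if (!setequal(scores_left$subject_id, scores_right$subject_id))
    stop("left and right score tables cover different subjects")
  ord <- match(scores_left$subject_id, scores_right$subject_id)
  delta <- scores_left$z - scores_right$z[ord]
  sgn <- if (direction == "lower_abnormal") -1 else 1
  side <- ifelse(delta == 0, "indeterminate",
                 ifelse(sgn * delta > 0, "left", "right"))
  mu_c <- mean(control_delta); sd_c <- sd(control_delta)
  exceeds <- abs(delta - mu_c) > 2 * sd_c
  tab <- data.frame(subject_id = scores_left$subject_id, delta_z = delta,
                    predicted_side = side, exceeds_2sd = exceeds,
                    stringsAsFactors = FALSE)
  res <- list(per_subject = tab, control_mean = mu_c, control_sd = sd_c,
              direction = direction)
  if (!is.null(true_side)) {
    truth <- if (!is.null(names(true_side)))
      true_side[tab$subject_id] else true_side
    res$confusion <- table(predicted = factor(side, c("left", "right",
                                                      "indeterminate")),
                           truth = factor(truth, c("left", "right")))
    res$accuracy <- mean(side == truth)
  }
  structure(res, class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat("lateralisation of", nrow(x$per_subject), "subject(s);",
      sum(x$per_subject$exceeds_2sd), "outside 2 control SDs\n")
  if (!is.null(x$accuracy)) {
    cat("accuracy:", round(x$accuracy, 3), "\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Correlation of two regional effect-size maps
#'
#' Pearson correlation of per-region effect sizes across aligned region
#' vocabularies, e.g. to compare an abnormality map against a published
#' reference map.
#'
#' @param d_1,d_2 Numeric vectors; if named, aligned by name.
#' @return Pearson correlation coefficient.
#' @export
effectsize_correlation <- function(d_1, d_2) {
  if (!is.null(names(d_1)) && !is.null(names(d_2))) {
    if (!setequal(names(d_1), names(d_2)))
      stop("region vocabularies differ")
    d_2 <- d_2[names(d_1)]
  }
  if (length(d_1) != length(d_2)) stop("effect-size maps differ in length")
  if (length(d_1) < 3) stop("at least 3 regions are required")
  if (sd(d_1) == 0 || sd(d_2) == 0) stop("zero variance in effect sizes")
  cor(d_1, d_2)
}
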