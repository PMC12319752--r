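# Regional effect sizes, group abnormality modes, and lateralisation.

test_that("Cohen's d matches the hand-computed example exactly", {
  # means 2.5 and 1.5, each variance 0.25, pooled SD 0.5, d = 2.0
  expect_equal(cohens_d(c(2.0, 2.5, 3.0), c(1.0, 1.5, 2.0)), 2.0)
})

test_that("Cohen's d has its structural properties", {
  set.seed(51)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(2.5 * a + 3, 2.5 * b + 3), cohens_d(a, b),
               tolerance = 1e-12)
  big_a <- rnorm(20000, 1); big_b <- rnorm(20000, 0)
  expect_equal(cohens_d(big_a, big_b), 1, tolerance = 0.05)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1, 1), c(1, 1, 1)), "pooled")
})

make_score_table <- function(z_pat, z_ctrl, region = "bankssts") {
  n_p <- length(z_pat); n_c <- length(z_ctrl)
  data.frame(
    subject_id = c(sprintf("p%03d", seq_len(n_p)),
                   sprintf("c%03d", seq_len(n_c))),
    region = region, hemisphere = "left", metric = "thickness",
    z = c(z_pat, z_ctrl), stringsAsFactors = FALSE)
}

make_meta <- function(scores) {
  data.frame(subject_id = unique(scores$subject_id),
             group = ifelse(grepl("^p", unique(scores$subject_id)),
                            "patient", "control"),
             stringsAsFactors = FALSE)
}

test_that("both abnormality modes recover a planted group shift", {
  set.seed(52)
  z_pat <- rnorm(56, -0.8, 1)
  z_ctrl <- rnorm(26, 0, 1)
  scores <- make_score_table(z_pat, z_ctrl)
  meta <- make_meta(scores)

  gn <- group_abnormality(scores, meta, "normative")
  expect_equal(gn$d, mean(z_pat) / sd(z_pat))
  expect_lt(abs(gn$d - (-0.8)), 0.2)
  expect_equal(gn$n_patients, 56)

  gc <- group_abnormality(scores, meta, "case_control")
  expect_equal(gc$d, cohens_d(z_pat, z_ctrl))
  expect_lt(abs(gc$d - (-0.8)), 0.35)

  # patients all exactly at the reference mean give d = 0 in both modes
  zero <- make_score_table(rep(0, 20), rep(c(-1, 1), 13))
  g0n <- group_abnormality(zero, make_meta(zero), "normative")
  g0c <- group_abnormality(zero, make_meta(zero), "case_control")
  expect_identical(g0n$d, 0)
  expect_identical(g0c$d, 0)

  expect_error(group_abnormality(scores[grepl("^p", scores$subject_id), ],
                                 meta, "case_control"),
               "control")
})

test_that("lateralisation calls the planted side and flags 2-SD
          exceedance at the normal rate", {
  set.seed(53)
  n <- 100
  # left-onset subjects: left hemisphere more abnormal by 1.5 control SDs
  # of the delta distribution (delta SD = sqrt(2) for unit z noise)
  zl <- rnorm(n, -1.5 * sqrt(2), 1)
  zr <- rnorm(n, 0, 1)
  left <- data.frame(subject_id = sprintf("p%03d", 1:n), z = zl)
  right <- data.frame(subject_id = sprintf("p%03d", 1:n), z = zr)
  control_delta <- rnorm(2000, 0, sqrt(2))
  lat <- lateralize(left, right, control_delta, "lower_abnormal",
                    true_side = setNames(rep("left", n), left$subject_id))
  expect_gt(lat$accuracy, 0.9)
  expect_equal(lat$per_subject$delta_z, zl - zr)

  # controls against their own delta distribution: ~4.6% outside 2 SD
  ctrl_left <- data.frame(subject_id = sprintf("c%04d", 1:2000),
                          z = rnorm(2000))
  ctrl_right <- data.frame(subject_id = sprintf("c%04d", 1:2000),
                           z = rnorm(2000))
  lat_c <- lateralize(ctrl_left, ctrl_right,
                      ctrl_left$z - ctrl_right$z, "lower_abnormal")
  rate <- mean(lat_c$per_subject$exceeds_2sd)
  expect_gt(rate, 0.026)
  expect_lt(rate, 0.066)
})

test_that("a zero hemispheric difference is indeterminate and symmetric
          cohorts carry no lateralising information", {
  left <- data.frame(subject_id = c("a", "b"), z = c(0.5, -1))
  right <- data.frame(subject_id = c("a", "b"), z = c(0.5, 2))
  lat <- lateralize(left, right, rnorm(20), "lower_abnormal")
  expect_identical(lat$per_subject$predicted_side, c("indeterminate",
                                                     "left"))

  set.seed(54)
  n <- 400
  sym_l <- data.frame(subject_id = sprintf("s%04d", 1:n), z = rnorm(n))
  sym_r <- data.frame(subject_id = sprintf("s%04d", 1:n), z = rnorm(n))
  truth <- setNames(sample(c("left", "right"), n, replace = TRUE),
                    sym_l$subject_id)
  lat_s <- lateralize(sym_l, sym_r, rnorm(100, 0, sqrt(2)),
                      "lower_abnormal", true_side = truth)
  expect_lt(abs(lat_s$accuracy - 0.5), 0.08)
})

test_that("misaligned or short inputs are rejected", {
  left <- data.frame(subject_id = c("a", "b"), z = c(1, 2))
  right <- data.frame(subject_id = c("a", "c"), z = c(1, 2))
  expect_error(lateralize(left, right, rnorm(20)), "different subjects")
  expect_error(lateralize(left, left, rnorm(5)), "at least 10")
})

test_that("effect-size maps correlate as constructed", {
  set.seed(55)
  d1 <- rnorm(68, 0, 0.4)
  names(d1) <- paste0("r", 1:68)
  expect_equal(effectsize_correlation(d1, d1), 1)
  expect_equal(effectsize_correlation(d1, -d1), -1)
  d2 <- 0.5 * d1 + rnorm(68, 0, 0.01)
  names(d2) <- names(d1)
  expect_gt(effectsize_correlation(d1, d2[sample(names(d2))]), 0.99)
  expect_error(effectsize_correlation(d1[1:2], d1[1:2]), "at least 3")
  expect_error(effectsize_correlation(d1, setNames(d1, paste0("q", 1:68))),
               "vocabularies")
})
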