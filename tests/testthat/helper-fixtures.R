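# Shared fixtures: small text files built in code, and a lazily fitted
# reference model reused across test files.

write_aparc_fixture <- function(path, n = 3, hemi = "lh",
                                metric = "thickness", sep = ",",
                                extra_cols = character(0),
                                dup_subject = FALSE, seed = 11) {
  set.seed(seed)
  regions <- dk_regions()
  ids <- sprintf("sub-%03d", seq_len(n))
  if (dup_subject) ids[n] <- ids[1]
  header <- c(paste0(hemi, ".aparc.", metric),
              paste0(hemi, "_", regions, "_", metric), extra_cols)
  rows <- vapply(seq_len(n), function(i) {
    vals <- round(runif(length(regions) + length(extra_cols), 1.5, 3.5), 3)
    paste(c(ids[i], vals), collapse = sep)
  }, character(1))
  writeLines(c(paste(header, collapse = sep), rows), path)
  path
}

write_meta_fixture <- function(path, n = 3, sex_codes = c("F", "M"),
                               drop_col = NULL, seed = 12) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = round(runif(n, 20, 80), 1),
    sex = rep_len(sex_codes, n),
    group = "control", dataset = "fix", site = "siteA",
    session = "ses-01", stringsAsFactors = FALSE)
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# standard multi-site training cohort used by several files
std_sim_config <- function(seed = 101, n = 2000, ...) {
  sim_config(n_subjects = n, n_sites = 5, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# lazily fitted reference model on the standard cohort (shash family)
std_model_fixture <- function() {
  if (is.null(.fixture_env$model)) {
    cohort <- simulate_cohort(std_sim_config())
    model <- suppressMessages(
      fit_normative(cohort, c("bankssts", "left", "thickness_mm")))
    .fixture_env$cohort <- cohort
    .fixture_env$model <- model
  }
  list(cohort = .fixture_env$cohort, model = .fixture_env$model)
}

# linear-in-age generator used for slope-recovery checks:
# mu = a + b*age with b = -0.002 on the log10 scale
linear_sim_config <- function(seed, n = 2000, b = -0.002, ...) {
  sim_config(n_subjects = n, n_sites = 5, seed = seed,
             age_knots = c(5, 35, 65, 95),
             age_values = 0.5 + b * c(5, 35, 65, 95), ...)
}
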