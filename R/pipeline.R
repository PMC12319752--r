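# Headless pipeline orchestration behind the command-line interface:
# simulate / qc / fit / score / report, driven by a single JSON config.

#' Run configuration for the pipeline
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed used for every stochastic stage.
#' @param inputs Named list of input paths: \code{aparc_left},
#'   \code{aparc_right}, \code{folding}, \code{metadata} (any subset;
#'   at least one data table plus metadata for fit/score).
#' @param model_path Path of the model-set JSON (written by \code{fit},
#'   read by \code{score}/\code{report}).
#' @param family Distribution family for fitting.
#' @param qc Logical: run the MAD QC pass before fitting.
#' @param qc_k QC threshold in MADs.
#' @param min_n Minimum training size per model (see
#'   \code{\link{fit_config}}).
#' @param sim Named list of \code{\link{sim_config}} overrides for the
#'   \code{simulate} command.
#' @param disease Named list for \code{\link{inject_disease}} (regions,
#'   effect_size, side, n_patients) applied after simulation.
#' @param laterality List with \code{region} (default
#'   \code{"hemisphere"} when present, else the first region) and
#'   \code{direction} (\code{"lower_abnormal"} default) for the report.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(out_dir = "brainnorm_out", seed = 1L,
                       inputs = list(), model_path = NULL,
                       family = "shash", qc = FALSE, qc_k = 5,
                       min_n = 200, sim = list(), disease = NULL,
                       laterality = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 inputs = inputs, model_path = model_path, family = family,
                 qc = isTRUE(qc), qc_k = qc_k, min_n = min_n, sim = sim,
                 disease = disease, laterality = laterality),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with \code{\link{run_config}} fields.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  do.call(run_config, raw[intersect(names(raw),
                                    names(formals(run_config)))])
}

output_header <- function(config) {
  hash <- if (!is.null(config$model_path) && file.exists(config$model_path))
    unname(tools::md5sum(config$model_path)) else "none"
  paste0("# brainnorm ", packageVersion("brainnorm"), " model ", hash)
}

write_artifact <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(output_header(config), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

read_artifact <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

load_input_cohort <- function(config) {
  inp <- config$inputs
  if (is.null(inp$metadata)) stop("inputs$metadata is required")
  tabs <- list()
  if (!is.null(inp$aparc_left))
    tabs$left <- read_aparc_table(inp$aparc_left)
  if (!is.null(inp$aparc_right))
    tabs$right <- read_aparc_table(inp$aparc_right)
  if (!is.null(inp$folding))
    tabs$folding <- read_folding_table(inp$folding)
  if (!is.null(inp$tidy))
    tabs$tidy <- read_morphometry(inp$tidy)
  if (!length(tabs)) stop("no morphometry inputs configured")
  morph <- do.call(rbind, unname(tabs))
  meta <- read_metadata(inp$metadata)
  cohort <- join_cohort(morph, meta)
  if (!is.null(inp$folding))
    cohort$morphometry <- add_kis(cohort$morphometry)
  cohort$morphometry <- log_metrics(cohort$morphometry)
  cohort
}

#' Run one pipeline stage
#'
#' Headless equivalent of the interactive upload-and-run workflow:
#' \describe{
#'   \item{simulate}{Generate a synthetic multi-site cohort (plus
#'     optional injected disease effect) and write the standard input
#'     files and a ground-truth JSON.}
#'   \item{qc}{Fit models, flag MAD outliers, write the outlier report
#'     and exclusion summary.}
#'   \item{fit}{Read the input tables, optionally QC, fit the model set,
#'     and serialise it to JSON.}
#'   \item{score}{Load the model set, harmonise each site through its
#'     healthy controls, and write per-subject z-score and centile
#'     tables (wide, one column per region x hemisphere x metric).}
#'   \item{report}{Score, then write the group abnormality summary
#'     (case-control and normative modes) and the hemispheric
#'     lateralisation table.}
#' }
#' Every artifact carries a header comment with the package version and
#' model hash; the configuration is echoed into the output directory.
#'
#' @param config A \code{"run_config"} or path to its JSON file.
#' @param command One of \code{"simulate"}, \code{"qc"}, \code{"fit"},
#'   \code{"score"}, \code{"report"}.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, command = c("simulate", "fit", "score",
                                             "qc", "report")) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config_used.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  paths <- switch(command,
                  simulate = stage_simulate(config),
                  qc = stage_qc(config),
                  fit = stage_fit(config),
                  score = stage_score(config)$paths,
                  report = stage_report(config))
  paths$config <- file.path(config$out_dir, "config_used.json")
  invisible(paths)
}

stage_simulate <- function(config) {
  args <- config$sim
  args$seed <- config$seed
  sc <- do.call(sim_config, args)
  cohort <- simulate_cohort(sc)
  if (!is.null(config$disease)) {
    d <- config$disease
    cohort <- inject_disease(cohort, regions = unlist(d$regions),
                             effect_size = d$effect_size,
                             side = if (is.null(d$side)) "both" else d$side,
                             n_patients = d$n_patients,
                             seed = config$seed)
  }
  paths <- write_cohort_files(cohort, config$out_dir)
  # tidy table covers metrics the wide dialects cannot carry
  tidy_path <- file.path(config$out_dir, "morphometry_tidy.csv")
  write_morphometry(cohort$morphometry, tidy_path)
  paths$tidy <- tidy_path
  gt <- attr(cohort, "ground_truth")
  gt$age_curve <- NULL; gt$noise_sd <- NULL
  gt$disease <- attr(cohort, "disease_truth")
  gt$disease$subjects <- NULL
  gt_path <- file.path(config$out_dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths$ground_truth <- gt_path
  paths
}

stage_qc <- function(config) {
  cohort <- load_input_cohort(config)
  hc <- subset_cohort(cohort,
                      cohort$meta$subject_id[cohort$meta$group == "control"])
  qc <- run_qc(hc, config = fit_config(family = config$family,
                                       min_n = config$min_n),
               k = config$qc_k)
  flags <- do.call(rbind, lapply(names(qc$per_target), function(k) {
    d <- qc$per_target[[k]]
    d$target <- k
    d
  }))
  paths <- list(
    outliers = write_artifact(flags,
                              file.path(config$out_dir, "qc_outliers.csv"),
                              config))
  summary_path <- file.path(config$out_dir, "qc_summary.txt")
  writeLines(c(output_header(config),
               paste("models:", length(qc$per_target)),
               paste("threshold (MADs):", qc$threshold_mads),
               paste("excluded subjects:",
                     length(qc$excluded_subjects)),
               qc$excluded_subjects), summary_path)
  paths$summary <- summary_path
  paths
}

stage_fit <- function(config) {
  cohort <- load_input_cohort(config)
  hc <- subset_cohort(cohort,
                      cohort$meta$subject_id[cohort$meta$group == "control"])
  fc <- fit_config(family = config$family, min_n = config$min_n)
  if (config$qc) {
    qc <- run_qc(hc, config = fc, k = config$qc_k)
    hc <- qc$cohort
  }
  ms <- fit_modelset(hc, config = fc)
  model_path <- if (is.null(config$model_path))
    file.path(config$out_dir, "modelset.json") else config$model_path
  save_modelset(ms, model_path)
  list(model = model_path)
}

widen_scores <- function(scores, value_col) {
  scores$key <- paste(scores$hemisphere, scores$region, scores$metric,
                      sep = "_")
  wide <- reshape(scores[c("subject_id", "key", value_col)],
                  idvar = "subject_id", timevar = "key",
                  direction = "wide")
  names(wide) <- sub(paste0("^", value_col, "\\."), "", names(wide))
  wide
}

stage_score <- function(config) {
  if (is.null(config$model_path) || !file.exists(config$model_path))
    stop("score requires model_path pointing at a fitted model set")
  ms <- load_modelset(config$model_path)
  cohort <- load_input_cohort(config)
  scores <- score_cohort(ms, cohort)
  paths <- list(
    zscores = write_artifact(widen_scores(scores, "z"),
                             file.path(config$out_dir, "zscores.csv"),
                             config),
    centiles = write_artifact(widen_scores(scores, "centile"),
                              file.path(config$out_dir, "centiles.csv"),
                              config),
    scores_long = write_artifact(scores,
                                 file.path(config$out_dir,
                                           "scores_long.csv"), config))
  list(paths = paths, scores = scores, cohort = cohort)
}

stage_report <- function(config) {
  sc <- stage_score(config)
  scores <- sc$scores
  meta <- sc$cohort$meta
  paths <- sc$paths
  has_patients <- any(meta$group != "control")
  if (has_patients) {
    gs <- rbind(group_abnormality(scores, meta, "normative"),
                group_abnormality(scores, meta, "case_control"))
    paths$group_summary <- write_artifact(
      gs, file.path(config$out_dir, "group_summary.csv"), config)
  }
  lat_cfg <- config$laterality
  region <- lat_cfg$region
  if (is.null(region))
    region <- if ("hemisphere" %in% scores$region) "hemisphere"
              else scores$region[1]
  direction <- if (is.null(lat_cfg$direction)) "lower_abnormal"
               else lat_cfg$direction
  metric <- if (is.null(lat_cfg$metric)) scores$metric[1] else lat_cfg$metric
  sel <- scores$region == region & scores$metric == metric
  left <- scores[sel & scores$hemisphere == "left", ]
  right <- scores[sel & scores$hemisphere == "right", ]
  if (nrow(left) && nrow(right) && has_patients) {
    grp <- meta$group[match(left$subject_id, meta$subject_id)]
    ctrl_ids <- left$subject_id[grp == "control"]
    cd <- left$z[grp == "control"] -
      right$z[match(ctrl_ids, right$subject_id)]
    pat_left <- left[grp != "control", ]
    pat_right <- right[right$subject_id %in% pat_left$subject_id, ]
    lat <- lateralize(pat_left, pat_right, cd, direction)
    paths$laterality <- write_artifact(
      lat$per_subject, file.path(config$out_dir, "laterality.csv"),
      config)
  }
  paths
}
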