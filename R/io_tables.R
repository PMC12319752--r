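# Readers/writers for the three tabular input dialects and the cohort join.

# Metric-name aliases in aparcstats2table column headers.
APARC_METRIC_MAP <- c(thickness = "thickness_mm",
                      volume    = "volume_mm3",
                      area      = "area_mm2")

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

validate_morphometry <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("subject_id", "hemisphere", "region", "metric", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("morphometry table missing column(s): ", paste(miss, collapse = ", "))
  bad_hemi <- setdiff(unique(tab$hemisphere), c("left", "right"))
  if (length(bad_hemi))
    stop("invalid hemisphere label(s): ", paste(bad_hemi, collapse = ", "))
  bad_reg <- setdiff(unique(tab$region), c(DK_REGIONS, "hemisphere"))
  if (length(bad_reg))
    stop("unknown region label(s): ", paste(bad_reg, collapse = ", "))
  key <- paste(tab$subject_id, tab$hemisphere, tab$region, tab$metric)
  if (anyDuplicated(key))
    stop("duplicate (subject, hemisphere, region, metric) records: ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  invisible(tab)
}

#' Read a FreeSurfer aparcstats2table morphometry file
#'
#' Parses the wide table written by FreeSurfer's \code{aparcstats2table}
#' (tab- or comma-delimited, auto-detected): first column is the subject
#' identifier, remaining columns follow the \code{<lh|rh>_<region>_<metric>}
#' grammar over the 34 Desikan-Killiany regions. The per-hemisphere mean
#' column (\code{MeanThickness} or \code{WhiteSurfArea}) is mapped to the
#' pseudo-region \code{"hemisphere"}. Columns that match neither the grammar
#' nor the region vocabulary (e.g. \code{BrainSegVolNotVent}, \code{eTIV})
#' are skipped with a message.
#'
#' @param path Path to the delimiter-separated file.
#' @param hemisphere Optional check: \code{"left"} or \code{"right"}; errors
#'   if the file's columns belong to the other hemisphere.
#' @param metric Optional check: expected metric (\code{"thickness"},
#'   \code{"volume"} or \code{"area"}, or their canonical unit-suffixed
#'   names).
#' @return A tidy morphometry \code{data.frame} with columns
#'   \code{subject_id, hemisphere, region, metric, value} (one row per
#'   subject x region).
#' @export
read_aparc_table <- function(path, hemisphere = NULL, metric = NULL) {
  raw <- read.csv(path, sep = detect_delim(path), check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("format error: expected a subject column plus region columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  cols <- names(raw)[-1L]
  parsed <- lapply(cols, parse_aparc_column)
  keep <- !vapply(parsed, is.null, logical(1))
  if (any(!keep))
    message("skipping unrecognised column(s): ",
            paste(cols[!keep], collapse = ", "))
  if (!any(keep)) stop("no parseable region columns found")

  recs <- do.call(rbind, lapply(which(keep), function(j) {
    info <- parsed[[j]]
    vals <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(vals) & !(raw[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1L], ", column '", cols[j], "'")
    data.frame(subject_id = ids, hemisphere = info$hemisphere,
               region = info$region, metric = info$metric, value = vals,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(hemisphere)) {
    hemisphere <- match.arg(hemisphere, c("left", "right"))
    if (!all(recs$hemisphere == hemisphere))
      stop("file contains ", setdiff(unique(recs$hemisphere), hemisphere),
           "-hemisphere columns but hemisphere='", hemisphere, "' was requested")
  }
  if (!is.null(metric)) {
    canon <- if (metric %in% names(APARC_METRIC_MAP)) APARC_METRIC_MAP[[metric]] else metric
    if (!all(recs$metric == canon))
      stop("file metric differs from requested '", metric, "'")
  }
  rownames(recs) <- NULL
  validate_morphometry(recs)
}

# Parse one aparcstats2table column name; NULL if unrecognised.
parse_aparc_column <- function(nm) {
  m <- regmatches(nm, regexec("^(lh|rh)[._](.+)[._](thickness|volume|area)$", nm))[[1]]
  if (length(m) != 4L) return(NULL)
  hemi <- if (m[2] == "lh") "left" else "right"
  metric <- APARC_METRIC_MAP[[m[4]]]
  region <- m[3]
  if (region %in% c("MeanThickness", "WhiteSurfArea", "TotalGrayVol"))
    return(list(hemisphere = hemi, region = "hemisphere", metric = metric))
  if (!(region %in% DK_REGIONS)) return(NULL)
  list(hemisphere = hemi, region = region, metric = metric)
}

#' Read a cortical-folding toolbox hemisphere table
#'
#' Parses the hemisphere-level table of the cortical-folding toolbox
#' dialect: columns \code{subject_id}, \code{hemisphere}, and the raw
#' scaling-law inputs \code{total_pial_area}, \code{exposed_area},
#' \code{avg_thickness} (mm^2, mm^2, mm). Hemisphere labels \code{lh/rh}
#' or \code{left/right} are accepted.
#'
#' @param path Path to the CSV/TSV file.
#' @return A tidy morphometry \code{data.frame} with region
#'   \code{"hemisphere"} and metrics \code{total_pial_area_mm2},
#'   \code{exposed_area_mm2}, \code{avg_thickness_mm}.
#' @export
read_folding_table <- function(path) {
  raw <- read.csv(path, sep = detect_delim(path), check.names = FALSE,
                  strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  need <- c("subject_id", "hemisphere", "total_pial_area", "exposed_area",
            "avg_thickness")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  hemi <- c(lh = "left", rh = "right", left = "left", right = "right")[
    tolower(as.character(raw$hemisphere))]
  if (anyNA(hemi)) stop("invalid hemisphere label(s) in folding table")
  metric_cols <- c(total_pial_area = "total_pial_area_mm2",
                   exposed_area = "exposed_area_mm2",
                   avg_thickness = "avg_thickness_mm")
  recs <- do.call(rbind, lapply(names(metric_cols), function(col) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(vals)) stop("non-numeric cell in column '", col, "'")
    data.frame(subject_id = as.character(raw$subject_id), hemisphere = hemi,
               region = "hemisphere", metric = metric_cols[[col]],
               value = vals, stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  validate_morphometry(recs)
}

#' Read a subject metadata file
#'
#' Parses the metadata CSV with the seven required fields (header matched
#' case-insensitively, any column order): subject id, age, sex, group,
#' dataset, site, and session. Sex is normalised to \code{female/male}
#' from \code{F/M}, \code{0/1}, or spelled-out values; common healthy
#' control spellings (\code{HC}, \code{healthy}, \code{control}) are
#' normalised to \code{"control"}. Subjects with multiple sessions keep
#' the first session by sort order, with a warning. Ages outside the
#' normative support [5, 95] years trigger a warning.
#'
#' @param path Path to the metadata CSV/TSV file.
#' @return \code{data.frame} with columns \code{subject_id, age, sex,
#'   group, dataset, site, session}.
#' @export
read_metadata <- function(path) {
  raw <- read.csv(path, sep = detect_delim(path), check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  names(raw) <- tolower(gsub("[ .]", "_", names(raw)))
  alias <- c(subject = "subject_id", id = "subject_id",
             participant_id = "subject_id", subjectid = "subject_id")
  for (a in names(alias))
    if (a %in% names(raw) && !(alias[[a]] %in% names(raw)))
      names(raw)[names(raw) == a] <- alias[[a]]
  need <- c("subject_id", "age", "sex", "group", "dataset", "site", "session")
  for (col in need)
    if (!(col %in% names(raw))) stop("missing column: ", col)

  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age))
    stop("unparseable age at row ", which(is.na(age))[1L])
  if (any(age < 5 | age > 95))
    warning("age outside the normative support [5, 95] years for ",
            sum(age < 5 | age > 95), " subject(s)")

  sex_map <- c(f = "female", m = "male", female = "female", male = "male",
               "0" = "female", "1" = "male")
  sex <- sex_map[tolower(raw$sex)]
  if (anyNA(sex))
    stop("unrecognised sex code(s): ",
         paste(unique(raw$sex[is.na(sex)]), collapse = ", "))

  grp <- raw$group
  grp[tolower(grp) %in% c("control", "controls", "hc", "healthy",
                          "healthy_control")] <- "control"

  meta <- data.frame(subject_id = raw$subject_id, age = age,
                     sex = unname(sex), group = grp, dataset = raw$dataset,
                     site = raw$site, session = raw$session,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(meta[c("subject_id", "session")]))
    stop("duplicate subject_id/session pairs in metadata")
  if (anyDuplicated(meta$subject_id)) {
    warning("multiple sessions per subject; keeping the first by sort order")
    meta <- meta[order(meta$subject_id, meta$session), ]
    meta <- meta[!duplicated(meta$subject_id), ]
  }
  rownames(meta) <- NULL
  meta
}

#' Join morphometry and metadata into a cohort
#'
#' Inner-joins a tidy morphometry table and a metadata table on
#' \code{subject_id}. Subjects present in only one input are dropped and
#' listed in the join report; an empty intersection is an error.
#'
#' @param morph Tidy morphometry \code{data.frame}
#'   (\code{\link{read_aparc_table}} / \code{\link{read_folding_table}}).
#' @param meta Metadata \code{data.frame} (\code{\link{read_metadata}}).
#' @return An object of class \code{"cohort"}: list with elements
#'   \code{morphometry}, \code{meta} (restricted to shared subjects), and
#'   \code{join_report} (subjects dropped from either side).
#' @export
join_cohort <- function(morph, meta) {
  validate_morphometry(morph)
  shared <- intersect(unique(morph$subject_id), meta$subject_id)
  if (!length(shared))
    stop("no subjects shared between morphometry and metadata")
  report <- list(
    morphometry_only = setdiff(unique(morph$subject_id), shared),
    metadata_only = setdiff(meta$subject_id, shared))
  morph <- morph[morph$subject_id %in% shared, , drop = FALSE]
  meta <- meta[meta$subject_id %in% shared, , drop = FALSE]
  if (anyNA(morph$value)) {
    bad <- unique(morph$subject_id[is.na(morph$value)])
    message("dropping ", length(bad),
            " subject(s) with missing morphometry values: ",
            paste(head(bad, 5), collapse = ", "))
    report$missing_value <- bad
    morph <- morph[!(morph$subject_id %in% bad), , drop = FALSE]
    meta <- meta[!(meta$subject_id %in% bad), , drop = FALSE]
    if (!nrow(meta)) stop("all shared subjects had missing values")
  }
  rownames(morph) <- rownames(meta) <- NULL
  structure(list(morphometry = morph, meta = meta, join_report = report),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("brainnorm cohort:", length(unique(x$meta$subject_id)), "subjects,",
      length(unique(x$morphometry$region)), "region label(s),",
      length(unique(x$morphometry$metric)), "metric(s),",
      length(unique(x$meta$site)), "site(s)\n")
  dropped <- length(x$join_report$morphometry_only) +
    length(x$join_report$metadata_only)
  if (dropped) cat("  join dropped", dropped, "unmatched subject(s)\n")
  invisible(x)
}

#' Write a tidy morphometry table to CSV
#'
#' Values are written with 17 significant digits so a write/read round
#' trip reproduces them exactly.
#'
#' @param tab Tidy morphometry \code{data.frame}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_morphometry <- function(tab, path) {
  validate_morphometry(tab)
  out <- tab
  out$value <- sprintf("%.17g", out$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy morphometry table written by \code{\link{write_morphometry}}
#' @param path CSV path.
#' @return Tidy morphometry \code{data.frame}.
#' @export
read_morphometry <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
  validate_morphometry(tab)
}
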