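# CSV ingestion and validation.
#
# All three inputs are tidy UTF-8 comma-separated files with a header:
#   grades.csv:        patient_id,laterality,grader_id,grade,n_images
#   ai.csv:            patient_id,ai_grade
#   adjudications.csv: patient_id,laterality,final_grade
# Grade fields hold the integers 0-4 (0-3 for the AI) or the literal token
# "NA" for an ungradable decision.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[, cols, drop = FALSE]
}

parse_grade_column <- function(x, K, col, allow_na = TRUE) {
  x <- as.character(x)
  na <- is.na(x) | x == "NA"
  ok <- na | grepl(sprintf("^[0-%d]$", K - 1L), x)
  if (!all(ok))
    stop(sprintf("column '%s', row %d: invalid grade token '%s' (expected 0-%d or NA)",
                 col, which(!ok)[1], x[which(!ok)[1]], K - 1L), call. = FALSE)
  if (!allow_na && any(na))
    stop(sprintf("column '%s' must not contain NA", col), call. = FALSE)
  out <- rep(NA_integer_, length(x))
  out[!na] <- as.integer(x[!na])
  out
}

check_laterality <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% c("OD", "OS"))
  if (any(bad))
    stop(sprintf("column 'laterality', row %d: '%s' (expected OD or OS)",
                 which(bad)[1], x[which(bad)[1]]), call. = FALSE)
  x
}

check_no_duplicates <- function(keys, what) {
  d <- duplicated(keys)
  if (any(d))
    stop(sprintf("duplicate %s: %s", what, keys[which(d)[1]]), call. = FALSE)
}

validate_grades <- function(grades) {
  grades <- require_columns(as.data.frame(grades),
                            c("patient_id", "laterality", "grader_id",
                              "grade", "n_images"), "grades")
  grades$patient_id <- as.character(grades$patient_id)
  grades$laterality <- check_laterality(grades$laterality)
  grades$grader_id <- as.character(grades$grader_id)
  grades$grade <- assert_grade(grades$grade, 5L, what = "grade")
  if (any(is.na(grades$n_images)) || any(grades$n_images < 1) ||
      any(grades$n_images != trunc(grades$n_images)))
    stop("n_images must be integers >= 1", call. = FALSE)
  grades$n_images <- as.integer(grades$n_images)
  check_no_duplicates(
    paste(grades$patient_id, grades$laterality, grades$grader_id, sep = "/"),
    "(patient_id, laterality, grader_id) key")
  grades
}

validate_ai <- function(ai) {
  ai <- require_columns(as.data.frame(ai), c("patient_id", "ai_grade"), "ai")
  ai$patient_id <- as.character(ai$patient_id)
  ai$ai_grade <- assert_grade(ai$ai_grade, 4L, what = "ai_grade")
  check_no_duplicates(ai$patient_id, "patient_id in ai table")
  ai
}

validate_adjudications <- function(adj) {
  adj <- require_columns(as.data.frame(adj),
                         c("patient_id", "laterality", "final_grade"),
                         "adjudications")
  adj$patient_id <- as.character(adj$patient_id)
  adj$laterality <- check_laterality(adj$laterality)
  adj$final_grade <- assert_grade(adj$final_grade, 5L,
                                  allow_ungradable = FALSE,
                                  what = "final_grade")
  check_no_duplicates(paste(adj$patient_id, adj$laterality, sep = "/"),
                      "(patient_id, laterality) key in adjudications")
  adj
}

read_input_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, colClasses = "character", na.strings = "NA",
                  check.names = FALSE)
}

#' Load and validate per-eye grades
#'
#' Reads `grades.csv` (columns `patient_id,laterality,grader_id,grade,
#' n_images`; grade 0-4 or `NA` for ungradable). Duplicate
#' (patient, eye, grader) rows and out-of-range grade tokens are errors that
#' name the offending row.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
load_grades <- function(path) {
  df <- read_input_csv(path)
  df <- require_columns(df, c("patient_id", "laterality", "grader_id",
                              "grade", "n_images"), basename(path))
  df$grade <- parse_grade_column(df$grade, 5L, "grade")
  n <- suppressWarnings(as.integer(df$n_images))
  if (any(is.na(n)))
    stop(sprintf("column 'n_images', row %d: '%s' is not an integer",
                 which(is.na(n))[1], df$n_images[which(is.na(n))[1]]),
         call. = FALSE)
  df$n_images <- n
  validate_grades(df)
}

#' Load and validate patient-level AI grades
#'
#' Reads `ai.csv` (columns `patient_id,ai_grade`; grade 0-3 or `NA`).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
load_ai <- function(path) {
  df <- read_input_csv(path)
  df <- require_columns(df, c("patient_id", "ai_grade"), basename(path))
  df$ai_grade <- parse_grade_column(df$ai_grade, 4L, "ai_grade")
  validate_ai(df)
}

#' Load and validate adjudicated final eye grades
#'
#' Reads `adjudications.csv` (columns `patient_id,laterality,final_grade`;
#' grade 0-4, never NA -- an adjudication is a decision).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
load_adjudications <- function(path) {
  df <- read_input_csv(path)
  df <- require_columns(df, c("patient_id", "laterality", "final_grade"),
                        basename(path))
  df$final_grade <- parse_grade_column(df$final_grade, 5L, "final_grade",
                                       allow_na = FALSE)
  validate_adjudications(df)
}

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a simulated dataset to CSV files
#'
#' Writes `grades.csv`, `ai.csv`, `adjudications.csv`, `truth_eyes.csv` and
#' `truth_patients.csv` into a directory, in the same dialects the analysis
#' loaders read. Output is deterministic: re-running on the same simulation
#' produces byte-identical files.
#'
#' @param sim A `dr_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "dr_simulation"))
    stop("sim must come from simulate_dataset()", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(grades = file.path(dir, "grades.csv"),
             ai = file.path(dir, "ai.csv"),
             adjudications = file.path(dir, "adjudications.csv"),
             truth_eyes = file.path(dir, "truth_eyes.csv"),
             truth_patients = file.path(dir, "truth_patients.csv"))
  write_plain_csv(sim$grades, paths["grades"])
  write_plain_csv(sim$ai, paths["ai"])
  write_plain_csv(sim$adjudications, paths["adjudications"])
  write_plain_csv(sim$truth_eyes, paths["truth_eyes"])
  write_plain_csv(sim$truth_patients, paths["truth_patients"])
  invisible(paths)
}

as_confusion <- function(x, K, what) {
  if (is.list(x) && !is.null(x$accuracy))
    return(confusion_from_accuracy(x$accuracy, K = K,
                                   decay = x$decay %||% 0.5))
  if (is.list(x)) x <- do.call(rbind, x)
  check_stochastic(matrix(as.numeric(x), K, K, byrow = FALSE), K, what)
}

#' Read a simulation configuration from YAML
#'
#' Confusion matrices may be given either in full (a list of K rows) or in
#' shorthand as `{accuracy: 0.8}` (optionally with `decay`), which expands
#' via [confusion_from_accuracy()].
#'
#' @param path Path to a YAML file with the [sim_config()] fields.
#' @return A validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  confs <- lapply(y$grader_confusions, as_confusion, K = 5L,
                  what = "grader confusion")
  qf <- unlist(y$quality_fail)
  args <- list(
    grader_confusions = confs,
    quality_fail = qf[names(confs)])
  for (f in c("n_patients", "prevalence", "inter_eye_concordance",
              "ai_ungradable", "images_per_eye", "adjudication_policy",
              "seed"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  if (!is.null(y$ai_confusion))
    args$ai_confusion <- as_confusion(y$ai_confusion, 4L, "ai_confusion")
  do.call(sim_config, args)
}
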