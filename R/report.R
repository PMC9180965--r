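# Pipeline orchestration and report generation.

# Eyes/images counts per agreement pattern within a row mask.
agreement3_counts_for <- function(cls, n_images, mask, scope) {
  c_eyes <- table(cls[mask])[AGREEMENT3_LEVELS]
  c_img <- tapply(n_images[mask], cls[mask], sum)[AGREEMENT3_LEVELS]
  c_img[is.na(c_img)] <- 0
  data.frame(scope = scope, pattern = AGREEMENT3_LEVELS,
             n_eyes = as.integer(c_eyes), n_images = as.integer(c_img),
             stringsAsFactors = FALSE)
}

# Eyes/images per final severity grade within a row mask.
severity_breakdown_for <- function(final, n_images, mask, K = 5L) {
  eyes <- tabulate(final[mask] + 1L, nbins = K)
  img <- tapply(n_images[mask], factor(final[mask], levels = 0:(K - 1)), sum)
  img[is.na(img)] <- 0
  data.frame(grade = 0:(K - 1), label = icdr_labels(K),
             n_eyes = eyes, n_images = as.integer(img),
             stringsAsFactors = FALSE)
}

#' Run the full concordance analysis
#'
#' Executes, in order: quality-based patient exclusion, eye-level consensus
#' (majority with adjudication override), per-patient aggregation (worse-eye
#' maximum) and compression to the 4-point scale, the 3-rater and 4-rater
#' agreement taxonomies, Cohen's kappa analyses, and the post hoc
#' referable-DR analysis on the original (non-adjudicated) grades.
#'
#' If any fully discordant eye lacks an adjudication entry the pipeline
#' refuses to guess: it raises an error of class
#' `"drc_adjudication_required"` whose `worklist` field holds the eyes to be
#' adjudicated (see [adjudication_worklist()]).
#'
#' The pipeline accepts any number of graders `G >= 2`; the 3-rater
#' agreement-class table, the 4-rater taxonomy and the referable-DR analysis
#' are produced only when `G == 3` (the design the taxonomies are defined
#' for), the kappa and distribution tables always.
#'
#' @param grades Per-eye grades data frame (see [load_grades()]).
#' @param ai Patient-level AI grades (see [load_ai()]).
#' @param adjudications Optional adjudicated final eye grades (see
#'   [load_adjudications()]). Entries always override the modal grade.
#' @param rdr_cutoff Referable-DR cutoff grade (default 2).
#' @param kappa_weighting Weighting for all kappa computations
#'   (default `"none"`).
#' @param verbose If `TRUE`, log exclusions and adjudication overrides.
#' @return Object of class `study_report`; print it for a summary, or pass
#'   it to [render_report()].
#' @export
run_analysis <- function(grades, ai, adjudications = NULL, rdr_cutoff = 2L,
                         kappa_weighting = "none", verbose = FALSE) {
  grades <- validate_grades(grades)
  ai <- validate_ai(ai)
  if (!is.null(adjudications) && nrow(adjudications) > 0L)
    adjudications <- validate_adjudications(adjudications)
  else adjudications <- NULL

  excl <- apply_quality_exclusion(grades, ai, verbose = verbose)
  g <- excl$grades
  a <- excl$ai
  graders <- sort(unique(grades$grader_id))
  G <- length(graders)
  if (G < 2L) stop("at least two graders are required", call. = FALSE)

  wide <- eye_table(g)
  if (nrow(g) == 0L) {
    # no analyzable patients: empty wide table over the full grader set
    wide <- data.frame(patient_id = character(0), laterality = character(0),
                       stringsAsFactors = FALSE)
    for (gr in graders) wide[[paste0("grade_", gr)]] <- integer(0)
    wide$n_images <- integer(0)
  }
  attr(wide, "graders") <- graders      # keep full grader set even if empty
  consensus <- consensus_table(wide, adjudications)
  if (verbose) {
    for (i in which(consensus$source == "ADJUDICATED"))
      message(sprintf("adjudicated final for %s %s: grade %d",
                      consensus$patient_id[i], consensus$laterality[i],
                      consensus$final_grade[i]))
  }
  cls <- consensus$agreement_class
  n_img <- consensus$n_images
  is3 <- G == 3L

  agreement3 <- if (is3) rbind(
    agreement3_counts_for(cls, n_img, rep(TRUE, nrow(consensus)), "all"),
    agreement3_counts_for(cls, n_img, consensus$laterality == "OD", "OD"),
    agreement3_counts_for(cls, n_img, consensus$laterality == "OS", "OS"))
  else NULL

  unan_mask <- if (is3) !is.na(cls) & cls == "3:0"
               else consensus$source == "UNANIMOUS"
  major_mask <- if (is3) !is.na(cls) & cls == "2:1"
                else consensus$source == "MAJORITY"
  unanimous_eyes_by_grade <-
    severity_breakdown_for(consensus$final_grade, n_img, unan_mask)
  majority_eyes_by_grade <-
    severity_breakdown_for(consensus$final_grade, n_img, major_mask)

  # patient-level grades: each grader's own worse-eye maximum, compressed
  pats <- sort(unique(wide$patient_id))
  fpat <- factor(wide$patient_id, levels = pats)
  gm <- as.matrix(wide[paste0("grade_", graders)])
  pg4 <- matrix(NA_integer_, nrow = length(pats), ncol = G,
                dimnames = list(pats, graders))
  if (length(pats) > 0L) {
    for (j in seq_len(G))
      pg4[, j] <- compress_5_to_4(as.integer(tapply(gm[, j], fpat, max)))
  }
  final_pat4 <- if (length(pats) > 0L)
    compress_5_to_4(as.integer(tapply(consensus$final_grade, fpat, max)))
  else integer(0)
  ai4 <- a$ai_grade[match(pats, a$patient_id)]

  unan_pat <- if (length(pats) > 0L)
    rowSums(pg4 == pg4[, 1]) == G
  else logical(0)
  unanimous_patients_by_grade <- {
    d <- distribution_table(pg4[unan_pat, 1], 4L)
    data.frame(grade = d$grade, label = d$label, n_patients = d$n,
               percentage = d$percentage, stringsAsFactors = FALSE)
  }

  agreement4 <- if (is3) {
    cls4 <- classify_agreement_4(pg4[, 1], pg4[, 2], pg4[, 3], ai4)
    data.frame(pattern = AGREEMENT4_LEVELS,
               n_patients = as.integer(table(cls4)[AGREEMENT4_LEVELS]),
               stringsAsFactors = FALSE)
  } else NULL

  kappa <- if (nrow(g) > 0L)
    kappa_report(g, consensus, K = 5L, weighting = kappa_weighting)
  else structure(list(vs_final = stats::setNames(rep(NA_real_, G), graders),
                      pairwise = NULL,
                      mean_pairwise = stats::setNames(rep(NA_real_, G),
                                                      graders),
                      weighting = kappa_weighting),
                 class = "kappa_report")

  rdr <- if (!is3) NULL
         else if (nrow(g) > 0L) rdr_analysis(g, a, cutoff = rdr_cutoff)
         else empty_rdr_summary(as.integer(rdr_cutoff))

  structure(list(
    graders = graders,
    n_graders = G,
    exclusion_flow = excl$flow,
    excluded = excl$excluded,
    consensus = consensus,
    distribution_eye_5pt = distribution_table(consensus$final_grade, 5L),
    distribution_patient_4pt = distribution_table(final_pat4, 4L),
    agreement3 = agreement3,
    unanimous_eyes_by_grade = unanimous_eyes_by_grade,
    majority_eyes_by_grade = majority_eyes_by_grade,
    unanimous_patients_by_grade = unanimous_patients_by_grade,
    agreement4 = agreement4,
    kappa = kappa,
    rdr = rdr,
    params = list(rdr_cutoff = as.integer(rdr_cutoff),
                  kappa_weighting = kappa_weighting)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Multi-grader DR concordance report\n")
  cat("==================================\n")
  print(x$exclusion_flow)
  n_eyes <- nrow(x$consensus)
  cat(sprintf("Eyes analyzed: %d (%d images)\n", n_eyes,
              sum(x$consensus$n_images)))
  if (!is.null(x$agreement3)) {
    all3 <- x$agreement3[x$agreement3$scope == "all", ]
    cat("Eye-level agreement:",
        paste(sprintf("%s %d (%.0f%%)", all3$pattern, all3$n_eyes,
                      if (n_eyes > 0) 100 * all3$n_eyes / n_eyes else 0),
              collapse = ", "), "\n")
  }
  d <- x$distribution_patient_4pt
  cat("Final patient grades (4-point):",
      paste(sprintf("%d: %d (%.2f%%)", d$grade, d$n, d$percentage),
            collapse = ", "), "\n")
  if (!is.null(x$agreement4)) {
    cat("Four-rater patient patterns:",
        paste(sprintf("%s %d", x$agreement4$pattern,
                      x$agreement4$n_patients), collapse = ", "), "\n")
  }
  print(x$kappa)
  if (!is.null(x$rdr)) print(x$rdr)
  invisible(x)
}

# Recursively turn factors into characters for serialization.
unfactor <- function(x) {
  if (is.factor(x)) return(as.character(x))
  if (is.data.frame(x)) {
    x[] <- lapply(x, unfactor)
    return(x)
  }
  if (inherits(x, "kappa_report")) {
    x <- unclass(x)
    # named vectors serialize as JSON objects, not bare arrays
    x$vs_final <- as.list(x$vs_final)
    x$mean_pairwise <- as.list(x$mean_pairwise)
    return(unfactor(x))
  }
  if (inherits(x, "exclusion_flow") || inherits(x, "rdr_summary"))
    return(unfactor(unclass(x)))
  if (is.list(x)) return(lapply(x, unfactor))
  x
}

#' Render a study report to files
#'
#' Writes one CSV per report table, a single JSON bundle of the whole report
#' and a human-readable text summary into a directory. Output is
#' deterministic: rendering the same report twice produces byte-identical
#' files.
#'
#' @param report A `study_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(report, out_dir) {
  if (!inherits(report, "study_report"))
    stop("report must come from run_analysis()", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    write_plain_csv(unfactor(df), p)
    paths <<- c(paths, p)
  }
  put(data.frame(metric = names(unclass(report$exclusion_flow)),
                 value = unlist(unclass(report$exclusion_flow)),
                 stringsAsFactors = FALSE), "exclusion_flow.csv")
  put(report$consensus, "consensus_eyes.csv")
  put(report$distribution_eye_5pt, "distribution_eye_5pt.csv")
  put(report$distribution_patient_4pt, "distribution_patient_4pt.csv")
  put(report$agreement3, "agreement3_counts.csv")
  put(report$unanimous_eyes_by_grade, "unanimous_eyes_by_grade.csv")
  put(report$majority_eyes_by_grade, "majority_eyes_by_grade.csv")
  put(report$unanimous_patients_by_grade, "unanimous_patients_by_grade.csv")
  put(report$agreement4, "agreement4_counts.csv")

  k <- report$kappa
  kdf <- rbind(
    data.frame(statistic = "vs_final", grader_a = names(k$vs_final),
               grader_b = "", kappa = unname(k$vs_final),
               stringsAsFactors = FALSE),
    if (!is.null(k$pairwise))
      data.frame(statistic = "pairwise", grader_a = k$pairwise$grader_a,
                 grader_b = k$pairwise$grader_b,
                 kappa = k$pairwise$kappa, stringsAsFactors = FALSE),
    data.frame(statistic = "mean_pairwise",
               grader_a = names(k$mean_pairwise), grader_b = "",
               kappa = unname(k$mean_pairwise), stringsAsFactors = FALSE))
  put(kdf, "kappa.csv")

  if (!is.null(report$rdr)) {
    r <- unlist(unclass(report$rdr))
    put(data.frame(metric = names(r), value = unname(r),
                   stringsAsFactors = FALSE), "rdr_summary.csv")
  }

  bundle <- file.path(out_dir, "bundle.json")
  jsonlite::write_json(unfactor(unclass(report)), bundle,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- c(paths, bundle)

  summary_txt <- file.path(out_dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), summary_txt)
  invisible(c(paths, summary_txt))
}

#' Reload a rendered report bundle
#'
#' Reads the JSON bundle written by [render_report()] back into a
#' `study_report`-shaped list (data frames restored by simplification), so a
#' stored report can be re-rendered or inspected without re-running the
#' analysis.
#'
#' @param path Path to `bundle.json`.
#' @return A `study_report` object.
#' @export
load_report_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x$exclusion_flow) <- "exclusion_flow"
  if (!is.null(x$kappa)) {
    x$kappa$vs_final <- unlist(x$kappa$vs_final)
    x$kappa$mean_pairwise <- unlist(x$kappa$mean_pairwise)
    class(x$kappa) <- "kappa_report"
  }
  if (!is.null(x$rdr)) class(x$rdr) <- "rdr_summary"
  structure(x, class = "study_report")
}

#' Write an adjudication worklist CSV
#'
#' @param worklist Data frame from [adjudication_worklist()] or carried by a
#'   `"drc_adjudication_required"` error.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_worklist <- function(worklist, path) {
  write_plain_csv(worklist, path)
}
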