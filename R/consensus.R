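# Quality exclusion, agreement taxonomies and eye-level consensus.

AGREEMENT3_LEVELS <- c("3:0", "2:1", "1:1:1")
AGREEMENT4_LEVELS <- c("4:0", "3:1_ai_majority", "3:1_ai_odd", "2:2",
                       "2:1:1_ai_pair", "2:1:1_ai_odd", "1:1:1:1")

#' Classify the agreement pattern of three human graders
#'
#' The pattern is determined solely by the multiset of the three grades:
#' `"3:0"` complete agreement, `"2:1"` two of three agree, `"1:1:1"` all
#' three differ (fully discordant, requires adjudication). Ungradable inputs
#' are an error -- quality exclusion happens upstream.
#'
#' @param g1,g2,g3 Equal-length integer grade vectors, one per grader.
#' @param K Scale size (5 by default; 2 for binarized grades).
#' @return Factor with levels `"3:0"`, `"2:1"`, `"1:1:1"`.
#' @examples
#' classify_agreement_3(c(0, 2, 2), c(0, 0, 0), c(0, 1, 0))
#' @export
classify_agreement_3 <- function(g1, g2, g3, K = 5L) {
  g1 <- assert_grade(g1, K, FALSE, "g1")
  g2 <- assert_grade(g2, K, FALSE, "g2")
  g3 <- assert_grade(g3, K, FALSE, "g3")
  if (length(g1) != length(g2) || length(g1) != length(g3))
    stop("g1, g2, g3 must have equal length", call. = FALSE)
  # number of equal pairs: 3 -> unanimous, 1 -> majority, 0 -> discordant
  e <- (g1 == g2) + (g1 == g3) + (g2 == g3)
  factor(c("1:1:1", "2:1", NA, "3:0")[e + 1L], levels = AGREEMENT3_LEVELS)
}

#' Classify the four-rater (three humans + AI) agreement pattern
#'
#' The pattern is the partition of the multiset of the four grades, refined
#' by whether the automated grader sits inside the agreeing block:
#'
#' * `"4:0"` -- all four agree;
#' * `"3:1_ai_majority"` -- two humans and the AI agree, one human differs;
#' * `"3:1_ai_odd"` -- all three humans agree, the AI differs;
#' * `"2:2"` -- two pairs;
#' * `"2:1:1_ai_pair"` -- the AI agrees with exactly one human and that pair
#'   is the (relative) majority;
#' * `"2:1:1_ai_odd"` -- two humans agree, the AI differs from everyone;
#' * `"1:1:1:1"` -- complete discordance, every rater assigned a different
#'   grade.
#'
#' The classification is invariant under permutation of the three human
#' positions but not under swapping the AI with a human.
#'
#' @param h1,h2,h3 Equal-length integer vectors of human patient-level grades
#'   (4-point scale).
#' @param ai Integer vector of automated patient-level grades.
#' @param K Scale size (4 by default).
#' @return Factor with the seven pattern levels above.
#' @examples
#' classify_agreement_4(0, 1, 2, ai = 3)  # every grade different
#' @export
classify_agreement_4 <- function(h1, h2, h3, ai, K = 4L) {
  h1 <- assert_grade(h1, K, FALSE, "h1")
  h2 <- assert_grade(h2, K, FALSE, "h2")
  h3 <- assert_grade(h3, K, FALSE, "h3")
  ai <- assert_grade(ai, K, FALSE, "ai")
  n <- length(h1)
  if (length(h2) != n || length(h3) != n || length(ai) != n)
    stop("h1, h2, h3, ai must have equal length", call. = FALSE)
  out <- character(n)
  for (i in seq_len(n)) {
    counts <- tabulate(c(h1[i], h2[i], h3[i], ai[i]) + 1L, nbins = K)
    top <- max(counts)
    ai_n <- counts[ai[i] + 1L]
    out[i] <-
      if (top == 4L) "4:0"
      else if (top == 3L) {
        if (ai_n == 3L) "3:1_ai_majority" else "3:1_ai_odd"
      } else if (top == 2L && sum(counts == 2L) == 2L) "2:2"
      else if (top == 2L) {
        if (ai_n == 2L) "2:1:1_ai_pair" else "2:1:1_ai_odd"
      } else "1:1:1:1"
  }
  factor(out, levels = AGREEMENT4_LEVELS)
}

#' Eye-level consensus grade for one eye
#'
#' Resolves one eye's final grade from the three graders' assessments:
#' unanimity and 2-of-3 majority yield the modal grade (source `"UNANIMOUS"`
#' or `"MAJORITY"`); a fully discordant eye must be resolved externally, so
#' without an adjudication entry an error of class
#' `"drc_adjudication_required"` is raised. An explicit `adjudication` entry,
#' when supplied, always takes precedence over the modal grade -- adjudication
#' panels may overturn a majority.
#'
#' @param grades Integer vector of the three graders' grades for one eye
#'   (no NA).
#' @param adjudication Optional single adjudicated final grade.
#' @param K Scale size (default 5).
#' @return List with `final_grade`, `agreement_class` (`"3:0"`, `"2:1"`,
#'   `"1:1:1"`) and `source` (`"UNANIMOUS"`, `"MAJORITY"`, `"ADJUDICATED"`).
#' @examples
#' consensus_eye(c(1, 1, 2))
#' consensus_eye(c(2, 0, 0), adjudication = 1)  # override
#' @export
consensus_eye <- function(grades, adjudication = NULL, K = 5L) {
  g <- assert_grade(grades, K, FALSE, "grades")
  if (length(g) != 3L)
    stop("consensus_eye expects exactly three grades", call. = FALSE)
  cls <- as.character(classify_agreement_3(g[1], g[2], g[3], K = K))
  if (!is.null(adjudication)) {
    final <- assert_grade(adjudication, K, FALSE, "adjudication")
    return(list(final_grade = final, agreement_class = cls,
                source = "ADJUDICATED"))
  }
  if (cls == "1:1:1")
    stop(errorCondition(
      "fully discordant eye requires an adjudication entry",
      class = c("drc_adjudication_required", "error", "condition")))
  counts <- tabulate(g + 1L, nbins = K)
  list(final_grade = which.max(counts) - 1L,
       agreement_class = cls,
       source = if (cls == "3:0") "UNANIMOUS" else "MAJORITY")
}

#' Quality-based patient exclusion
#'
#' A patient enters the analysis only if every human grader graded every
#' assessed eye (no ungradable flag anywhere) *and* the automated grader
#' produced a grade. Each excluded patient is counted exactly once, with
#' precedence: structurally incomplete records first (a grader's row missing
#' for an assessed eye, or no AI row at all), then patients nobody could
#' grade, then any human quality flag, then AI-only failures.
#'
#' @param grades Long data frame of per-eye assessments with columns
#'   `patient_id`, `laterality` (`"OD"`/`"OS"`), `grader_id`, `grade`
#'   (0..4 or NA), `n_images`.
#' @param ai Data frame with columns `patient_id`, `ai_grade` (0..3 or NA).
#' @param verbose If `TRUE`, emit one message per excluded patient so the
#'   selection flow can be audited from the log.
#' @return List with elements `grades` and `ai` (restricted to analyzable
#'   patients), `flow` (an `exclusion_flow` count list) and `excluded`
#'   (data frame of `patient_id`, `reason`).
#' @export
apply_quality_exclusion <- function(grades, ai, verbose = FALSE) {
  grades <- validate_grades(grades)
  ai <- validate_ai(ai)
  graders <- sort(unique(grades$grader_id))
  G <- length(graders)
  pats <- sort(unique(c(grades$patient_id, ai$patient_id)))
  fpat <- factor(grades$patient_id, levels = pats)

  rows_n <- tabulate(fpat, nbins = length(pats))
  eyes <- unique(grades[, c("patient_id", "laterality")])
  eyes_n <- tabulate(factor(eyes$patient_id, levels = pats),
                     nbins = length(pats))
  any_na <- tapply(is.na(grades$grade), fpat, any)
  any_na[is.na(any_na)] <- FALSE
  all_na <- tapply(is.na(grades$grade), fpat, all)
  all_na[is.na(all_na)] <- FALSE
  pos_ai <- match(pats, ai$patient_id)
  has_ai <- !is.na(pos_ai)
  ai_val <- ai$ai_grade[pos_ai]

  reason <- rep("analyzable", length(pats))
  reason[has_ai & is.na(ai_val)] <- "ai_ungradable"
  reason[any_na] <- "human_quality"
  reason[all_na & rows_n > 0L & has_ai & is.na(ai_val)] <- "all_ungradable"
  reason[!has_ai | rows_n == 0L | rows_n != G * eyes_n] <- "incomplete"

  if (verbose) {
    for (i in which(reason != "analyzable"))
      message(sprintf("excluding patient %s: %s", pats[i], reason[i]))
  }

  flow <- structure(list(
    n_total = length(pats),
    n_all_ungradable = sum(reason == "all_ungradable"),
    n_human_quality = sum(reason == "human_quality"),
    n_ai_ungradable = sum(reason == "ai_ungradable"),
    n_incomplete = sum(reason == "incomplete"),
    n_analyzed = sum(reason == "analyzable")
  ), class = "exclusion_flow")

  keep <- pats[reason == "analyzable"]
  list(grades = grades[grades$patient_id %in% keep, , drop = FALSE],
       ai = ai[ai$patient_id %in% keep, , drop = FALSE],
       flow = flow,
       excluded = data.frame(patient_id = pats[reason != "analyzable"],
                             reason = reason[reason != "analyzable"],
                             stringsAsFactors = FALSE))
}

#' @export
print.exclusion_flow <- function(x, ...) {
  cat("Patient selection flow\n")
  cat(sprintf("  total:                 %d\n", x$n_total))
  cat(sprintf("  ungradable by all:     %d\n", x$n_all_ungradable))
  cat(sprintf("  human quality flag:    %d\n", x$n_human_quality))
  cat(sprintf("  AI-only ungradable:    %d\n", x$n_ai_ungradable))
  cat(sprintf("  incomplete records:    %d\n", x$n_incomplete))
  cat(sprintf("  analyzed:              %d\n", x$n_analyzed))
  invisible(x)
}

#' Worklist of fully discordant eyes lacking an adjudication entry
#'
#' Lists every eye whose three grades are pairwise different and for which no
#' adjudicated final grade has been supplied, in stable
#' (`patient_id`, `laterality`) order. The analysis pipeline refuses to guess
#' a final grade for these eyes; this worklist is what an adjudication panel
#' needs to resolve.
#'
#' @param grades Long per-eye grades data frame (analyzable patients,
#'   three graders).
#' @param adjudications Optional data frame with `patient_id`, `laterality`,
#'   `final_grade`.
#' @return Data frame with `patient_id`, `laterality` and one `grade_<i>`
#'   column per grader (sorted grader order).
#' @export
adjudication_worklist <- function(grades, adjudications = NULL) {
  grades <- validate_grades(grades)
  wide <- eye_table(grades)
  graders <- attr(wide, "graders")
  if (length(graders) != 3L)
    stop("the 3-rater worklist requires exactly three graders", call. = FALSE)
  gm <- as.matrix(wide[paste0("grade_", graders)])
  if (anyNA(gm))
    stop("worklist requires fully graded eyes; run quality exclusion first",
         call. = FALSE)
  cls <- classify_agreement_3(gm[, 1], gm[, 2], gm[, 3])
  need <- cls == "1:1:1"
  if (!is.null(adjudications) && nrow(adjudications) > 0L) {
    adjudications <- validate_adjudications(adjudications)
    have <- paste(wide$patient_id, wide$laterality) %in%
      paste(adjudications$patient_id, adjudications$laterality)
    need <- need & !have
  }
  out <- data.frame(patient_id = wide$patient_id[need],
                    laterality = wide$laterality[need],
                    stringsAsFactors = FALSE)
  for (i in seq_along(graders)) out[[paste0("grade_", i)]] <- gm[need, i]
  out[order(out$patient_id, out$laterality), , drop = FALSE]
}

# Internal: wide per-eye table with one grade column per grader.
eye_table <- function(grades) {
  graders <- sort(unique(grades$grader_id))
  if (nrow(grades) == 0L) {
    wide <- data.frame(patient_id = character(0), laterality = character(0),
                       stringsAsFactors = FALSE)
    for (g in graders) wide[[paste0("grade_", g)]] <- integer(0)
    wide$n_images <- integer(0)
    attr(wide, "graders") <- graders
    return(wide)
  }
  sub <- grades[, c("patient_id", "laterality", "grader_id", "grade")]
  wide <- stats::reshape(sub, idvar = c("patient_id", "laterality"),
                         timevar = "grader_id", direction = "wide",
                         sep = "_")
  attr(wide, "reshapeWide") <- NULL
  img <- stats::aggregate(n_images ~ patient_id + laterality, grades, max)
  wide <- merge(wide, img, by = c("patient_id", "laterality"))
  wide <- wide[order(wide$patient_id, wide$laterality), , drop = FALSE]
  rownames(wide) <- NULL
  attr(wide, "graders") <- graders
  wide
}

# Internal: consensus over all eyes of a wide table. Returns the consensus
# data frame, or raises drc_adjudication_required carrying the worklist.
consensus_table <- function(wide, adjudications) {
  graders <- attr(wide, "graders")
  G <- length(graders)
  gm <- as.matrix(wide[paste0("grade_", graders)])
  n <- nrow(wide)
  adj_key <- character(0)
  adj_val <- integer(0)
  if (!is.null(adjudications) && nrow(adjudications) > 0L) {
    adj_key <- paste(adjudications$patient_id, adjudications$laterality)
    adj_val <- adjudications$final_grade
  }
  pos <- match(paste(wide$patient_id, wide$laterality), adj_key)

  final <- integer(n)
  source <- character(n)
  unresolved <- logical(n)
  for (i in seq_len(n)) {
    counts <- tabulate(gm[i, ] + 1L, nbins = 5L)
    top <- max(counts)
    if (!is.na(pos[i])) {
      final[i] <- adj_val[pos[i]]
      source[i] <- "ADJUDICATED"
    } else if (top * 2L > G) {        # strict majority (incl. unanimity)
      final[i] <- which.max(counts) - 1L
      source[i] <- if (top == G) "UNANIMOUS" else "MAJORITY"
    } else {
      unresolved[i] <- TRUE
    }
  }
  if (any(unresolved)) {
    wl <- data.frame(patient_id = wide$patient_id[unresolved],
                     laterality = wide$laterality[unresolved],
                     stringsAsFactors = FALSE)
    for (j in seq_len(G)) wl[[paste0("grade_", j)]] <- gm[unresolved, j]
    wl <- wl[order(wl$patient_id, wl$laterality), , drop = FALSE]
    stop(errorCondition(
      sprintf("%d fully discordant eye(s) lack an adjudication entry",
              nrow(wl)),
      worklist = wl,
      class = c("drc_adjudication_required", "error", "condition")))
  }
  cls <- if (G == 3L) classify_agreement_3(gm[, 1], gm[, 2], gm[, 3])
         else factor(rep(NA_character_, n), levels = AGREEMENT3_LEVELS)
  data.frame(patient_id = wide$patient_id,
             laterality = wide$laterality,
             agreement_class = cls,
             final_grade = final,
             source = source,
             n_images = wide$n_images,
             stringsAsFactors = FALSE)
}
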