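# Ordinal severity scales.
#
# Grades are plain integers: 0..4 on the 5-point ICDR per-eye scale
# (0 = no DR, 1 = mild, 2 = moderate, 3 = severe non-proliferative,
# 4 = proliferative) and 0..3 on the compressed 4-point patient-level scale
# (3 = sight-threatening DR, merging severe non-proliferative and
# proliferative). An ungradable eye -- an explicit image-quality failure
# recorded by a rater -- is encoded NA ("NA" in CSV). A row that is absent
# altogether means the rater never assessed that eye; that is a different
# situation and is handled by the ingestion/exclusion layer, not by the
# grade encoding.

ICDR5_LABELS <- c("no DR", "mild NPDR", "moderate NPDR", "severe NPDR",
                  "proliferative DR")
ICDR4_LABELS <- c("no DR", "mild NPDR", "moderate NPDR",
                  "sight-threatening DR")

#' Severity-scale level labels
#'
#' Human-readable names for the integer severity codes used throughout the
#' package. The 5-point scale is the ICDR per-eye scale; the 4-point scale is
#' its compression used for patient-level comparison against the automated
#' grader (see [compress_5_to_4()]).
#'
#' @param K Number of scale levels, 5 or 4.
#' @return Character vector of level names in grade order, starting at
#'   grade 0.
#' @examples
#' icdr_labels(5)
#' icdr_labels(4)[4]  # the merged top level
#' @export
icdr_labels <- function(K = 5L) {
  switch(as.character(K),
         "5" = ICDR5_LABELS,
         "4" = ICDR4_LABELS,
         stop("K must be 4 or 5", call. = FALSE))
}

# Validate a vector of grades on a K-level scale; returns integer vector.
# NA encodes an ungradable (quality-failure) assessment.
assert_grade <- function(x, K, allow_ungradable = TRUE, what = "grade") {
  if (length(x) == 0L) return(integer(0))
  if (!is.numeric(x) && !all(is.na(x)))
    stop(sprintf("%s must be numeric (integer codes 0..%d)", what, K - 1L),
         call. = FALSE)
  xi <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & (is.na(xi) | x != xi | xi < 0L | xi > K - 1L)
  if (any(bad))
    stop(sprintf("%s outside 0..%d: %s", what, K - 1L,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  if (!allow_ungradable && anyNA(x))
    stop(sprintf("%s contains ungradable (NA) values", what), call. = FALSE)
  xi
}

#' Compress the 5-point ICDR scale to the 4-point patient-level scale
#'
#' Merges the two highest severities -- severe non-proliferative (3) and
#' proliferative (4) DR -- into a single "sight-threatening DR" level so that
#' human grades become comparable with a 4-point automated grader output.
#' The mapping is `0 -> 0, 1 -> 1, 2 -> 2, 3 -> 3, 4 -> 3`; ungradable (NA)
#' stays ungradable. The map is total, monotone and surjective onto 0..3.
#'
#' @param grade Integer vector of 5-point grades (0..4), NA = ungradable.
#' @return Integer vector of 4-point grades (0..3), NA preserved.
#' @examples
#' compress_5_to_4(c(0, 1, 2, 3, 4, NA))
#' @export
compress_5_to_4 <- function(grade) {
  g <- assert_grade(grade, 5L)
  pmin(g, 3L)
}

#' Patient-level grade from per-eye grades
#'
#' A patient's overall grade for one grader is the *maximum* of that grader's
#' gradable eye grades: the worse eye drives the referral decision. If one eye
#' is ungradable the gradable eye is used; if every eye is ungradable there is
#' no patient grade and an error of class `"drc_no_patient_grade"` is raised
#' (such patients are normally removed upstream by
#' [apply_quality_exclusion()]).
#'
#' @param eye_grades Integer vector of one grader's eye grades for one patient
#'   (usually length 2: right then left eye), NA = ungradable.
#' @param K Scale size the grades live on (5, 4 or 2 for binarized grades).
#' @return Single integer grade on the same scale.
#' @examples
#' patient_grade(c(4, 2))    # worse eye wins
#' patient_grade(c(NA, 1))   # single informative eye
#' @export
patient_grade <- function(eye_grades, K = 5L) {
  g <- assert_grade(eye_grades, K, what = "eye grade")
  if (length(g) == 0L)
    stop("at least one eye grade is required", call. = FALSE)
  if (all(is.na(g)))
    stop(errorCondition(
      "no patient grade: every eye grade is ungradable",
      class = c("drc_no_patient_grade", "error", "condition")))
  max(g, na.rm = TRUE)
}

#' Binarize a grade at the referable-DR cutoff
#'
#' Referable DR (rDR) is more-than-mild DR: moderate and above, i.e. grade
#' `>= cutoff` with the default cutoff 2. The same cutoff applies on the
#' 5-point and the compressed 4-point scale because compression only merges
#' levels above it. Ungradable input is an error: a referability decision
#' requires a grade.
#'
#' @param grade Integer vector of grades, no NA allowed.
#' @param cutoff Lowest grade counted as referable (default 2, moderate DR).
#' @param K Scale size of the input grades (5 or 4).
#' @return Integer vector: 1 = rDR, 0 = no rDR.
#' @examples
#' binarize_rdr(c(0, 1, 2, 4))
#' @export
binarize_rdr <- function(grade, cutoff = 2L, K = 5L) {
  g <- assert_grade(grade, K, allow_ungradable = FALSE)
  as.integer(g >= cutoff)
}
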