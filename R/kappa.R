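# Cohen's kappa and related agreement statistics.

#' Build a K x K contingency table from two aligned rating vectors
#'
#' Cell (i, j) counts the units rater A graded `i` and rater B graded `j`.
#' The table dimension is fixed by the scale, not by the data: categories
#' never observed are kept as zero rows/columns so kappa values stay
#' comparable across rater pairs.
#'
#' @param a,b Equal-length integer rating vectors in `0..K-1`, no NA.
#' @param K Number of scale categories.
#' @return Integer `K x K` matrix (rows rater A, columns rater B).
#' @examples
#' build_contingency(c(0, 0, 1, 1), c(0, 1, 0, 1), K = 2)
#' @export
build_contingency <- function(a, b, K) {
  if (length(a) != length(b))
    stop("rating vectors must have equal length", call. = FALSE)
  a <- assert_grade(a, K, FALSE, "rating a")
  b <- assert_grade(b, K, FALSE, "rating b")
  tab <- table(factor(a, levels = 0:(K - 1)), factor(b, levels = 0:(K - 1)))
  matrix(as.integer(tab), K, K,
         dimnames = list(rater_a = 0:(K - 1), rater_b = 0:(K - 1)))
}

# Agreement weight matrix: 1 on the diagonal, decaying off it.
kappa_weights <- function(K, weighting) {
  if (K == 1L) return(matrix(1, 1, 1))
  d <- abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  switch(weighting,
         none = (d == 0) * 1,
         linear = 1 - d,
         quadratic = 1 - d^2)
}

#' Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o`
#' is the (weighted) observed proportion of agreement and `p_e` the
#' proportion expected from the row and column marginals under independence.
#' `weighting = "none"` is the classical unweighted kappa; `"linear"` and
#' `"quadratic"` use agreement weights `1 - |i-j|/(K-1)` and
#' `1 - ((i-j)/(K-1))^2` that give partial credit to near-misses on an
#' ordinal scale. If both raters are constant and identical (`p_e == 1`)
#' kappa is 1 by convention.
#'
#' @param tab Square non-negative matrix of joint counts (or proportions)
#'   with a positive total, e.g. from [build_contingency()].
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @return Kappa value in `[-1, 1]`.
#' @examples
#' cohen_kappa(matrix(c(4, 2, 0, 1, 3, 1, 0, 1, 4), 3))
#' @export
cohen_kappa <- function(tab, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (!is.matrix(tab) || nrow(tab) != ncol(tab))
    stop("tab must be a square matrix", call. = FALSE)
  if (any(tab < 0) || sum(tab) <= 0)
    stop("tab must be non-negative with a positive total", call. = FALSE)
  p <- tab / sum(tab)
  w <- kappa_weights(nrow(tab), weighting)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (1 - pe < sqrt(.Machine$double.eps)) return(1)
  (po - pe) / (1 - pe)
}

#' Per-grader kappa against the final (adjudicated) eye grades
#'
#' For each grader, Cohen's kappa between that grader's per-eye grades and
#' the final consensus grades, pooling both eyes of all analyzable patients
#' on the 5-point scale.
#'
#' @param grades Long per-eye grades (analyzable patients, no NA grades).
#' @param consensus Data frame with `patient_id`, `laterality`,
#'   `final_grade`, e.g. the `consensus` component of [run_analysis()].
#' @param K Scale size (default 5).
#' @param weighting Kappa weighting, see [cohen_kappa()].
#' @return Named numeric vector, one kappa per grader (NA if a grader has no
#'   eyes in common with the consensus).
#' @export
kappa_vs_final <- function(grades, consensus, K = 5L, weighting = "none") {
  grades <- validate_grades(grades)
  m <- merge(grades, consensus[, c("patient_id", "laterality", "final_grade")],
             by = c("patient_id", "laterality"))
  graders <- sort(unique(grades$grader_id))
  vapply(stats::setNames(graders, graders), function(g) {
    s <- m[m$grader_id == g & !is.na(m$grade), , drop = FALSE]
    if (nrow(s) == 0L) return(NA_real_)
    cohen_kappa(build_contingency(s$grade, s$final_grade, K), weighting)
  }, numeric(1))
}

#' Pairwise kappas between graders and per-grader averages
#'
#' Unweighted (by default) Cohen's kappa for every unordered pair of graders
#' on the per-eye grades, plus each grader's arithmetic mean over the
#' pairwise kappas that involve it -- a per-grader summary of how well a
#' grader agrees with the panel.
#'
#' @inheritParams kappa_vs_final
#' @return List with `pairwise` (data frame `grader_a`, `grader_b`, `kappa`)
#'   and `mean_pairwise` (named numeric vector).
#' @export
pairwise_kappa_summary <- function(grades, K = 5L, weighting = "none") {
  grades <- validate_grades(grades)
  wide <- eye_table(grades)
  graders <- attr(wide, "graders")
  if (length(graders) < 2L)
    stop("pairwise kappas require at least two graders", call. = FALSE)
  prs <- utils::combn(graders, 2L)
  kap <- apply(prs, 2, function(pr) {
    a <- wide[[paste0("grade_", pr[1])]]
    b <- wide[[paste0("grade_", pr[2])]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    cohen_kappa(build_contingency(a[ok], b[ok], K), weighting)
  })
  pairwise <- data.frame(grader_a = prs[1, ], grader_b = prs[2, ],
                         kappa = kap, stringsAsFactors = FALSE)
  mean_pairwise <- vapply(stats::setNames(graders, graders), function(g) {
    mean(kap[prs[1, ] == g | prs[2, ] == g])
  }, numeric(1))
  list(pairwise = pairwise, mean_pairwise = mean_pairwise)
}

#' Full kappa report for a graded dataset
#'
#' Bundles [kappa_vs_final()] and [pairwise_kappa_summary()] into one
#' object.
#'
#' @inheritParams kappa_vs_final
#' @return Object of class `kappa_report`: list with `vs_final`, `pairwise`,
#'   `mean_pairwise` and the `weighting` used.
#' @export
kappa_report <- function(grades, consensus, K = 5L, weighting = "none") {
  pw <- pairwise_kappa_summary(grades, K, weighting)
  structure(list(vs_final = kappa_vs_final(grades, consensus, K, weighting),
                 pairwise = pw$pairwise,
                 mean_pairwise = pw$mean_pairwise,
                 weighting = weighting),
            class = "kappa_report")
}

#' @export
print.kappa_report <- function(x, digits = 2, ...) {
  cat(sprintf("Cohen's kappa (%s weighting)\n", x$weighting))
  cat("  vs final grades: ",
      paste(sprintf("%s %.*f", names(x$vs_final), digits, x$vs_final),
            collapse = ", "), "\n", sep = "")
  cat("  pairwise:        ",
      paste(sprintf("%s-%s %.*f", x$pairwise$grader_a, x$pairwise$grader_b,
                    digits, x$pairwise$kappa), collapse = ", "),
      "\n", sep = "")
  cat("  mean pairwise:   ",
      paste(sprintf("%s %.*f", names(x$mean_pairwise), digits,
                    x$mean_pairwise), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Round half away from zero (printed-table convention); base round() would
# round half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Grade distribution table
#'
#' Counts and percentages per severity level, including zero-count levels.
#' Percentages are rounded half-up to 2 decimals, the convention used in
#' printed screening-study tables.
#'
#' @param grades Integer vector of final grades, no NA.
#' @param K Scale size of the grades.
#' @return Data frame with `grade`, `label`, `n`, `percentage`; the total is
#'   attached as attribute `"total"`.
#' @examples
#' distribution_table(rep(0:3, c(245, 54, 29, 7)), K = 4)
#' @export
distribution_table <- function(grades, K) {
  g <- assert_grade(grades, K, FALSE, "final grade")
  n <- tabulate(g + 1L, nbins = K)
  total <- sum(n)
  pct <- if (total > 0) round_half_up(100 * n / total, 2) else rep(0, K)
  out <- data.frame(grade = 0:(K - 1),
                    label = icdr_labels(K),
                    n = n,
                    percentage = pct,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Post hoc referable-DR binary analysis
#'
#' Collapses the ordinal severity scale to referable (rDR, grade `>= cutoff`)
#' versus non-referable DR and re-analyzes agreement on the *original* human
#' grades -- adjudication is deliberately not used, because on a binary scale
#' three graders always produce a majority and full discordance is
#' impossible. Reported are eye-level and patient-level full-agreement and
#' 2:1 counts, how often the automated grader sides with or against a 2:1
#' human majority, and, among patients with full human agreement, how many
#' AI disagreements there are and in which direction (AI referable while the
#' humans are not, or the reverse).
#'
#' Patient-level human calls aggregate each grader's own eye grades by
#' worse-eye maximum and then binarize; since binarization is monotone this
#' equals binarizing per eye and taking the maximum.
#'
#' @param grades Long per-eye grades of analyzable patients (three graders,
#'   no NA grades).
#' @param ai Data frame `patient_id`, `ai_grade` for the same patients
#'   (no NA).
#' @param cutoff Referable-DR cutoff grade (default 2 = moderate DR).
#' @return Object of class `rdr_summary` (a nested count list).
#' @export
rdr_analysis <- function(grades, ai, cutoff = 2L) {
  grades <- validate_grades(grades)
  ai <- validate_ai(ai)
  wide <- eye_table(grades)
  graders <- attr(wide, "graders")
  G <- length(graders)
  if (G != 3L)
    stop("the referable-DR analysis is defined for exactly three graders",
         call. = FALSE)
  gm <- as.matrix(wide[paste0("grade_", graders)])
  if (anyNA(gm))
    stop("rdr_analysis requires fully graded eyes", call. = FALSE)

  if (nrow(wide) == 0L) return(empty_rdr_summary(cutoff))

  bm <- gm >= cutoff                        # eye-level binary calls
  e <- (bm[, 1] == bm[, 2]) + (bm[, 1] == bm[, 3]) + (bm[, 2] == bm[, 3])
  eyes <- list(n = nrow(bm),
               full_agreement = sum(e == 3L),
               majority = sum(e == 1L))

  pats <- sort(unique(wide$patient_id))
  fpat <- factor(wide$patient_id, levels = pats)
  pb <- vapply(seq_len(G), function(j) {
    as.integer(tapply(gm[, j], fpat, max) >= cutoff)
  }, integer(length(pats)))
  pb <- matrix(pb, ncol = G)
  ep <- (pb[, 1] == pb[, 2]) + (pb[, 1] == pb[, 3]) + (pb[, 2] == pb[, 3])
  patients <- list(n = length(pats),
                   full_agreement = sum(ep == 3L),
                   majority = sum(ep == 1L))

  ai_bin <- as.integer(ai$ai_grade[match(pats, ai$patient_id)] >= cutoff)
  if (anyNA(ai_bin))
    stop("rdr_analysis requires an AI grade for every patient", call. = FALSE)
  maj_val <- as.integer(rowSums(pb) >= 2L)  # binary majority always exists
  is_maj <- ep == 1L
  is_full <- ep == 3L
  disagree_full <- is_full & ai_bin != maj_val

  structure(list(
    cutoff = cutoff,
    eyes = eyes,
    patients = patients,
    majority_patients_ai = list(
      with_majority = sum(is_maj & ai_bin == maj_val),
      against_majority = sum(is_maj & ai_bin != maj_val)),
    full_agreement_patients_ai = list(
      disagreements = sum(disagree_full),
      ai_referable = sum(disagree_full & ai_bin == 1L),
      ai_not_referable = sum(disagree_full & ai_bin == 0L))),
    class = "rdr_summary")
}

empty_rdr_summary <- function(cutoff) {
  zero <- list(n = 0L, full_agreement = 0L, majority = 0L)
  structure(list(
    cutoff = cutoff, eyes = zero, patients = zero,
    majority_patients_ai = list(with_majority = 0L, against_majority = 0L),
    full_agreement_patients_ai = list(disagreements = 0L,
                                      ai_referable = 0L,
                                      ai_not_referable = 0L)),
    class = "rdr_summary")
}

#' @export
print.rdr_summary <- function(x, ...) {
  cat(sprintf("Referable-DR analysis (cutoff: grade >= %d)\n", x$cutoff))
  cat(sprintf("  eyes:     %d analyzed, %d full agreement, %d majority (2:1)\n",
              x$eyes$n, x$eyes$full_agreement, x$eyes$majority))
  cat(sprintf("  patients: %d analyzed, %d full agreement, %d majority (2:1)\n",
              x$patients$n, x$patients$full_agreement, x$patients$majority))
  cat(sprintf("  AI on 2:1 patients: with majority %d, against %d\n",
              x$majority_patients_ai$with_majority,
              x$majority_patients_ai$against_majority))
  cat(sprintf(
    "  AI vs unanimous patients: %d disagreements (%d AI-referable, %d AI-non-referable)\n",
    x$full_agreement_patients_ai$disagreements,
    x$full_agreement_patients_ai$ai_referable,
    x$full_agreement_patients_ai$ai_not_referable))
  invisible(x)
}
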