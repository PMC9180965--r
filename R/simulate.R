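# Synthetic multi-grader screening data.
#
# The generator draws a latent true 5-point severity per eye, then passes it
# through per-grader row-stochastic confusion matrices (graders are
# conditionally independent given the truth -- the simplification that makes
# exact analytic oracles possible), adds independent per-grader-per-eye
# quality failures, and grades each patient with a 4x4-confusion AI applied
# to the compressed true patient grade. Left/right eye correlation is a copy
# mixture: with probability `inter_eye_concordance` the second eye copies the
# first, otherwise it is drawn fresh from the prevalence vector (which keeps
# each eye's marginal severity distribution equal to the prevalence).

#' Rater confusion matrix from a single accuracy parameter
#'
#' Convenience constructor for a plausible row-stochastic confusion matrix:
#' each row puts `accuracy` on the true grade and spreads the rest over the
#' other grades with geometrically decaying weight in ordinal distance, so
#' near-misses dominate errors -- the empirically typical shape for ordinal
#' grading.
#'
#' @param accuracy Probability the rater assigns the true grade (per row).
#' @param K Scale size (default 5).
#' @param decay Geometric decay of error mass per step of ordinal distance.
#' @return `K x K` row-stochastic matrix (rows: true grade, columns:
#'   assigned grade).
#' @examples
#' confusion_from_accuracy(0.8)
#' @export
confusion_from_accuracy <- function(accuracy, K = 5L, decay = 0.5) {
  if (!is.numeric(accuracy) || accuracy <= 0 || accuracy > 1)
    stop("accuracy must be in (0, 1]", call. = FALSE)
  m <- matrix(0, K, K)
  for (t in seq_len(K)) {
    row <- numeric(K)
    row[t] <- accuracy
    if (accuracy < 1) {
      w <- decay^abs(seq_len(K) - t)
      w[t] <- 0
      row <- row + (1 - accuracy) * w / sum(w)
    }
    m[t, ] <- row
  }
  dimnames(m) <- list(true = 0:(K - 1), assigned = 0:(K - 1))
  m
}

check_stochastic <- function(m, K, what) {
  if (!is.matrix(m) || nrow(m) != K || ncol(m) != K)
    stop(sprintf("%s must be a %dx%d matrix", what, K, K), call. = FALSE)
  if (any(m < 0) || any(m > 1))
    stop(sprintf("%s entries must be probabilities", what), call. = FALSE)
  if (any(abs(rowSums(m) - 1) > 1e-8))
    stop(sprintf("%s rows must each sum to 1", what), call. = FALSE)
  invisible(m)
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
  invisible(p)
}

#' Simulation configuration
#'
#' Full parameterization of the synthetic grader world. The defaults are a
#' plausibility preset for a screening population (mostly no DR, errors
#' concentrated on adjacent grades, occasional quality failures); they are
#' *not* fitted to any particular study -- real grader error structure is an
#' output of this kind of analysis, not an input.
#'
#' @param n_patients Number of patients.
#' @param prevalence Probability vector over the 5 true eye-severity levels.
#' @param inter_eye_concordance Probability the left eye's true severity
#'   copies the right eye's (otherwise drawn fresh from `prevalence`).
#' @param grader_confusions Named list of 5x5 row-stochastic matrices, one
#'   per human grader (row = true grade, column = assigned grade).
#' @param quality_fail Named numeric vector, per-grader probability of an
#'   ungradable flag per eye (independent across graders and eyes); names
#'   must match `grader_confusions`.
#' @param ai_confusion 4x4 row-stochastic matrix applied to the compressed
#'   true patient grade.
#' @param ai_ungradable Probability the AI fails to grade a patient.
#' @param images_per_eye Integer range (length 2) of fundus images per eye.
#' @param adjudication_policy `"truth"` (adjudication entries equal the true
#'   grade) or `"grader_median"` (median of the three assigned grades).
#' @param seed Master seed; independent substreams are derived from it for
#'   truth, each grader, quality flags, the AI and image counts, so adding a
#'   grader does not perturb the other streams.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 335L,
                       prevalence = c(0.78, 0.12, 0.07, 0.02, 0.01),
                       inter_eye_concordance = 0.8,
                       grader_confusions = list(
                         grader1 = confusion_from_accuracy(0.75),
                         grader2 = confusion_from_accuracy(0.92),
                         grader3 = confusion_from_accuracy(0.82)),
                       quality_fail = c(grader1 = 0.03, grader2 = 0.02,
                                        grader3 = 0.03),
                       ai_confusion = confusion_from_accuracy(0.80, K = 4L),
                       ai_ungradable = 0.10,
                       images_per_eye = c(2L, 3L),
                       adjudication_policy = c("truth", "grader_median"),
                       seed = 1L) {
  adjudication_policy <- match.arg(adjudication_policy)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  if (length(prevalence) != 5L)
    stop("prevalence must have 5 entries", call. = FALSE)
  check_prob(prevalence, "prevalence")
  if (abs(sum(prevalence) - 1) > 1e-8)
    stop("prevalence must sum to 1", call. = FALSE)
  check_prob(inter_eye_concordance, "inter_eye_concordance")
  if (is.null(names(grader_confusions)) ||
      anyDuplicated(names(grader_confusions)) ||
      any(names(grader_confusions) == ""))
    stop("grader_confusions must be a uniquely named list", call. = FALSE)
  for (g in names(grader_confusions))
    check_stochastic(grader_confusions[[g]], 5L,
                     sprintf("grader_confusions$%s", g))
  if (!setequal(names(quality_fail), names(grader_confusions)))
    stop("quality_fail names must match grader_confusions", call. = FALSE)
  check_prob(quality_fail, "quality_fail")
  check_stochastic(ai_confusion, 4L, "ai_confusion")
  check_prob(ai_ungradable, "ai_ungradable")
  if (length(images_per_eye) != 2L || any(images_per_eye < 1) ||
      images_per_eye[1] > images_per_eye[2])
    stop("images_per_eye must be an increasing positive integer range",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = as.numeric(prevalence),
                 inter_eye_concordance = inter_eye_concordance,
                 grader_confusions = grader_confusions,
                 quality_fail = quality_fail[names(grader_confusions)],
                 ai_confusion = ai_confusion,
                 ai_ungradable = ai_ungradable,
                 images_per_eye = as.integer(images_per_eye),
                 adjudication_policy = adjudication_policy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Independent substream seed derived from the master seed.
substream <- function(seed, k) {
  (abs(as.integer(seed)) + 97003L * as.integer(k)) %% 2147483647L
}

# Draw one assigned grade per unit from the confusion row of its true grade.
sample_from_confusion <- function(truth, conf) {
  K <- ncol(conf)
  out <- integer(length(truth))
  for (t in sort(unique(truth))) {
    idx <- which(truth == t)
    out[idx] <- sample.int(K, length(idx), replace = TRUE,
                           prob = conf[t + 1L, ]) - 1L
  }
  out
}

#' Simulate a multi-grader screening dataset
#'
#' Draws a dataset under a [sim_config()]: true per-eye severities, each
#' grader's assigned grades and quality failures, the AI's patient-level
#' grade, image counts, and adjudication entries for every eye (equal to the
#' true grade or the grader median, per the configured policy -- subset them
#' with [adjudication_worklist()] if you only want entries where adjudication
#' is actually needed). Fully reproducible given the config seed.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `dr_simulation`: list with data frames `grades`,
#'   `ai`, `adjudications`, `truth_eyes` (`patient_id`, `laterality`,
#'   `true_grade`) and `truth_patients` (`patient_id`, `true_grade4`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_patients = 20, seed = 7))
#' head(sim$grades)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  n <- config$n_patients
  graders <- names(config$grader_confusions)
  G <- length(graders)
  pid <- sprintf("P%0*d", max(4L, nchar(as.character(n))), seq_len(n))

  # truth stream: right eye, fresh left-eye draw, copy indicator
  set.seed(substream(config$seed, 1L))
  od <- sample.int(5L, n, replace = TRUE, prob = config$prevalence) - 1L
  fresh <- sample.int(5L, n, replace = TRUE, prob = config$prevalence) - 1L
  copy <- stats::runif(n) < config$inter_eye_concordance
  os <- ifelse(copy, od, fresh)
  true_eye <- c(od, os)                       # OD block then OS block
  lat <- rep(c("OD", "OS"), each = n)
  true_pat4 <- pmax(compress_5_to_4(od), compress_5_to_4(os))

  # one stream per grader
  assigned <- matrix(0L, nrow = 2L * n, ncol = G,
                     dimnames = list(NULL, graders))
  for (j in seq_len(G)) {
    set.seed(substream(config$seed, 10L + j))
    assigned[, j] <- sample_from_confusion(true_eye,
                                           config$grader_confusions[[j]])
  }

  # quality stream
  set.seed(substream(config$seed, 2L))
  u <- matrix(stats::runif(2L * n * G), ncol = G)
  failed <- sweep(u, 2L, config$quality_fail, "<")

  # AI stream
  set.seed(substream(config$seed, 3L))
  ai_grade <- sample_from_confusion(true_pat4, config$ai_confusion)
  ai_grade[stats::runif(n) < config$ai_ungradable] <- NA_integer_

  # image-count stream
  set.seed(substream(config$seed, 4L))
  lo <- config$images_per_eye[1]
  hi <- config$images_per_eye[2]
  n_images <- lo + sample.int(hi - lo + 1L, 2L * n, replace = TRUE) - 1L

  graded <- assigned
  graded[failed] <- NA_integer_
  grades <- data.frame(
    patient_id = rep(rep(pid, 2L), G),
    laterality = rep(lat, G),
    grader_id = rep(graders, each = 2L * n),
    grade = as.integer(graded),
    n_images = rep(n_images, G),
    stringsAsFactors = FALSE)
  grades <- grades[order(grades$patient_id, grades$laterality,
                         grades$grader_id), , drop = FALSE]
  rownames(grades) <- NULL

  adj_grade <- if (config$adjudication_policy == "truth") {
    true_eye
  } else {
    med <- apply(assigned, 1L, stats::median)
    as.integer(floor(med + 0.5))            # half-up to an integer grade
  }
  adjudications <- data.frame(patient_id = rep(pid, 2L),
                              laterality = lat,
                              final_grade = adj_grade,
                              stringsAsFactors = FALSE)
  adjudications <- adjudications[order(adjudications$patient_id,
                                       adjudications$laterality), ,
                                 drop = FALSE]
  rownames(adjudications) <- NULL

  truth_eyes <- data.frame(patient_id = rep(pid, 2L), laterality = lat,
                           true_grade = true_eye, stringsAsFactors = FALSE)
  truth_eyes <- truth_eyes[order(truth_eyes$patient_id,
                                 truth_eyes$laterality), , drop = FALSE]
  rownames(truth_eyes) <- NULL

  structure(list(
    grades = grades,
    ai = data.frame(patient_id = pid, ai_grade = ai_grade,
                    stringsAsFactors = FALSE),
    adjudications = adjudications,
    truth_eyes = truth_eyes,
    truth_patients = data.frame(patient_id = pid, true_grade4 = true_pat4,
                                stringsAsFactors = FALSE),
    config = config), class = "dr_simulation")
}

#' Exact kappa implied by a truth distribution and two confusion matrices
#'
#' Under conditional independence of the raters given the true grade, the
#' joint category distribution is
#' `P(a = i, b = j) = sum_t pi_t A[t, i] B[t, j]`; this function builds that
#' joint exactly and returns its unweighted Cohen's kappa. With `confusion_b`
#' omitted, rater B is the truth itself (identity matrix), giving the exact
#' kappa of a rater against the true grades. This is the analytic oracle for
#' Monte-Carlo parameter-recovery checks of [simulate_dataset()].
#'
#' @param true_dist Probability vector over the K true categories.
#' @param confusion_a,confusion_b `K x K` row-stochastic matrices;
#'   `confusion_b` defaults to the identity (truth).
#' @param weighting Kappa weighting, see [cohen_kappa()].
#' @return Exact kappa value.
#' @examples
#' analytic_kappa(c(0.8, 0.1, 0.05, 0.03, 0.02), confusion_from_accuracy(0.8))
#' @export
analytic_kappa <- function(true_dist, confusion_a, confusion_b = NULL,
                           weighting = "none") {
  K <- length(true_dist)
  check_prob(true_dist, "true_dist")
  if (abs(sum(true_dist) - 1) > 1e-8)
    stop("true_dist must sum to 1", call. = FALSE)
  check_stochastic(confusion_a, K, "confusion_a")
  if (is.null(confusion_b)) confusion_b <- diag(K)
  check_stochastic(confusion_b, K, "confusion_b")
  joint <- t(confusion_a) %*% (true_dist * confusion_b)
  cohen_kappa(joint, weighting)
}

#' Exact probabilities of the three-grader agreement classes
#'
#' Enumerates truth x three grader outcomes exactly (`K^4` terms) and returns
#' the probability that a random eye is unanimous (3:0), majority (2:1) or
#' fully discordant (1:1:1) under conditional independence given the truth.
#'
#' @param prevalence Probability vector over the K true categories.
#' @param confusions List of exactly three `K x K` row-stochastic matrices.
#' @return Named numeric vector over `"3:0"`, `"2:1"`, `"1:1:1"`; sums to 1.
#' @export
agreement3_probabilities <- function(prevalence, confusions) {
  K <- length(prevalence)
  check_prob(prevalence, "prevalence")
  if (abs(sum(prevalence) - 1) > 1e-8)
    stop("prevalence must sum to 1", call. = FALSE)
  if (length(confusions) != 3L)
    stop("exactly three confusion matrices are required", call. = FALSE)
  for (m in confusions) check_stochastic(m, K, "confusion matrix")
  joint <- array(0, dim = c(K, K, K))
  for (t in seq_len(K)) {
    joint <- joint + prevalence[t] *
      outer(outer(confusions[[1]][t, ], confusions[[2]][t, ]),
            confusions[[3]][t, ])
  }
  grid <- expand.grid(g1 = 0:(K - 1), g2 = 0:(K - 1), g3 = 0:(K - 1))
  cls <- classify_agreement_3(grid$g1, grid$g2, grid$g3, K = K)
  p <- vapply(split(as.vector(joint), cls), sum, numeric(1))
  p[AGREEMENT3_LEVELS]
}

#' Expected agreement-class frequencies under a simulation configuration
#'
#' @param config A [sim_config()] object with exactly three graders.
#' @return Named probability vector over `"3:0"`, `"2:1"`, `"1:1:1"`.
#' @seealso [agreement3_probabilities()]
#' @export
expected_agreement_frequencies <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  agreement3_probabilities(config$prevalence, config$grader_confusions)
}
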