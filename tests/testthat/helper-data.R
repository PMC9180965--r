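# Shared fixtures and small configurations.

fixture_path <- function(...) {
  system.file("extdata", ..., package = "drconcord")
}

load_discordant_fixture <- function() {
  d <- fixture_path("discordant_patients")
  list(grades = load_grades(file.path(d, "grades.csv")),
       ai = load_ai(file.path(d, "ai.csv")),
       adjudications = load_adjudications(file.path(d, "adjudications.csv")))
}

# Perfect graders: identity confusions, no quality failures, perfect AI.
identity_config <- function(n = 50, seed = 1, ...) {
  id5 <- diag(5)
  sim_config(n_patients = n,
             grader_confusions = list(g1 = id5, g2 = id5, g3 = id5),
             quality_fail = c(g1 = 0, g2 = 0, g3 = 0),
             ai_confusion = diag(4),
             ai_ungradable = 0,
             adjudication_policy = "truth",
             seed = seed, ...)
}

# Noisy three-grader world with all failure modes switched on.
noisy_config <- function(n = 150, seed = 3, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# A tiny hand-written dataset: 3 graders, 2 patients, fully graded.
tiny_grades <- function() {
  data.frame(
    patient_id = rep(c("p1", "p2"), each = 6),
    laterality = rep(rep(c("OD", "OS"), each = 3), 2),
    grader_id = rep(c("g1", "g2", "g3"), 4),
    grade = c(0, 0, 0, 1, 1, 2, 2, 2, 2, 0, 1, 0),
    n_images = 2L,
    stringsAsFactors = FALSE)
}

tiny_ai <- function() {
  data.frame(patient_id = c("p1", "p2"), ai_grade = c(1L, 2L),
             stringsAsFactors = FALSE)
}
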