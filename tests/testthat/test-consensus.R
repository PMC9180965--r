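# Agreement taxonomies, consensus resolution and quality exclusion.

test_that("three-rater agreement classes follow the multiset pattern", {
  expect_identical(as.character(classify_agreement_3(2, 0, 1)), "1:1:1")
  expect_identical(as.character(classify_agreement_3(0, 0, 0)), "3:0")
  expect_identical(as.character(classify_agreement_3(2, 0, 0)), "2:1")
  expect_error(classify_agreement_3(NA_integer_, 0, 0), "ungradable")
})

test_that("three-rater classification is permutation invariant (exhaustive)", {
  grid <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
  base <- classify_agreement_3(grid$a, grid$b, grid$c)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    g <- grid[, p]
    expect_identical(classify_agreement_3(g[[1]], g[[2]], g[[3]]), base)
  }
})

test_that("binary grades never produce full three-way discordance", {
  grid <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  cls <- classify_agreement_3(grid$a, grid$b, grid$c, K = 2)
  expect_false(any(cls == "1:1:1"))
})

test_that("four-rater classification distinguishes the AI position", {
  expect_identical(as.character(classify_agreement_4(0, 1, 2, ai = 3)),
                   "1:1:1:1")
  expect_identical(as.character(classify_agreement_4(1, 1, 1, ai = 1)),
                   "4:0")
  expect_identical(as.character(classify_agreement_4(2, 2, 0, ai = 2)),
                   "3:1_ai_majority")
  expect_identical(as.character(classify_agreement_4(2, 2, 2, ai = 0)),
                   "3:1_ai_odd")
  # same multiset {1,1,2,3}, class depends on whether the AI is in the pair
  expect_identical(as.character(classify_agreement_4(1, 2, 3, ai = 1)),
                   "2:1:1_ai_pair")
  expect_identical(as.character(classify_agreement_4(1, 1, 3, ai = 2)),
                   "2:1:1_ai_odd")
  expect_identical(as.character(classify_agreement_4(1, 1, 3, ai = 3)),
                   "2:2")
  expect_error(classify_agreement_4(NA_integer_, 0, 0, 0), "ungradable")
})

test_that("four-rater classification is invariant to human permutation only", {
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3, ai = 0:3)
  base <- classify_agreement_4(grid$a, grid$b, grid$c, grid$ai)
  expect_identical(classify_agreement_4(grid$c, grid$a, grid$b, grid$ai),
                   base)
  # swapping the AI with a human changes the refinement for some inputs
  swapped <- classify_agreement_4(grid$ai, grid$b, grid$c, grid$a)
  expect_true(any(swapped != base))
})

test_that("consensus resolves unanimity and majority, defers discordance", {
  u <- consensus_eye(c(1, 1, 1))
  expect_identical(u[c("final_grade", "source")],
                   list(final_grade = 1L, source = "UNANIMOUS"))
  m <- consensus_eye(c(1, 1, 2))
  expect_identical(m[c("final_grade", "source")],
                   list(final_grade = 1L, source = "MAJORITY"))
  expect_identical(m$agreement_class, "2:1")
  expect_error(consensus_eye(c(0, 1, 2)),
               class = "drc_adjudication_required")
})

test_that("an explicit adjudication entry overrides the majority", {
  a <- consensus_eye(c(2, 0, 0), adjudication = 1)
  expect_identical(a$final_grade, 1L)
  expect_identical(a$source, "ADJUDICATED")
})

test_that("non-adjudicated consensus grades come from the input multiset", {
  set.seed(42)
  for (i in 1:200) {
    g <- sample(0:4, 3, replace = TRUE)
    res <- tryCatch(consensus_eye(g), drc_adjudication_required = function(e) NULL)
    if (!is.null(res)) expect_true(res$final_grade %in% g)
    resa <- consensus_eye(g, adjudication = sample(0:4, 1))
    expect_identical(resa$source, "ADJUDICATED")
  }
})

test_that("quality exclusion categorizes every excluded patient once", {
  g <- rbind(
    tiny_grades(),                                  # p1, p2 clean
    within(tiny_grades(), patient_id <- sub("p", "q", patient_id)))
  # q1: one human quality flag; q2: everything ungradable
  g$grade[g$patient_id == "q1" & g$grader_id == "g2" &
            g$laterality == "OS"] <- NA
  g$grade[g$patient_id == "q2"] <- NA
  # r1: AI-only failure; r2: incomplete (one grader row missing)
  r <- tiny_grades()
  r$patient_id <- sub("p", "r", r$patient_id)
  r <- r[!(r$patient_id == "r2" & r$grader_id == "g3" &
             r$laterality == "OS"), ]
  g <- rbind(g, r)
  ai <- data.frame(
    patient_id = c("p1", "p2", "q1", "q2", "r1", "r2"),
    ai_grade = c(1L, 2L, 1L, NA, NA, 0L))
  res <- apply_quality_exclusion(g, ai)
  fl <- res$flow
  expect_identical(fl$n_total, 6L)
  expect_identical(fl$n_all_ungradable, 1L)   # q2
  expect_identical(fl$n_human_quality, 1L)    # q1
  expect_identical(fl$n_ai_ungradable, 1L)    # r1
  expect_identical(fl$n_incomplete, 1L)       # r2
  expect_identical(fl$n_analyzed, 2L)         # p1, p2
  expect_identical(
    fl$n_analyzed + fl$n_all_ungradable + fl$n_human_quality +
      fl$n_ai_ungradable + fl$n_incomplete, fl$n_total)
  expect_setequal(unique(res$grades$patient_id), c("p1", "p2"))
  expect_identical(sort(res$excluded$patient_id), c("q1", "q2", "r1", "r2"))
})

test_that("a patient ungradable by all humans but graded by the AI counts as a human quality exclusion", {
  g <- tiny_grades()
  g$grade[g$patient_id == "p2"] <- NA
  res <- apply_quality_exclusion(g, tiny_ai())
  expect_identical(res$flow$n_human_quality, 1L)
  expect_identical(res$flow$n_all_ungradable, 0L)
})

test_that("the worklist lists exactly the unresolved discordant eyes in stable order", {
  fx <- load_discordant_fixture()
  wl <- adjudication_worklist(fx$grades)
  expect_identical(nrow(wl), 7L)   # C-OS has a 2:1 majority, all others 1:1:1
  expect_identical(paste(wl$patient_id, wl$laterality),
                   c("A OD", "A OS", "B OD", "B OS", "C OD", "D OD", "D OS"))
  # supplying the adjudication entries empties the worklist
  expect_identical(nrow(adjudication_worklist(fx$grades, fx$adjudications)),
                   0L)
  # identity graders: no discordance at all
  sim <- simulate_dataset(identity_config(n = 40))
  expect_identical(nrow(adjudication_worklist(sim$grades)), 0L)
})

test_that("agreement-class counts partition the eyes and patients", {
  sim <- simulate_dataset(noisy_config(n = 120, seed = 9))
  rep <- run_analysis(sim$grades, sim$ai, sim$adjudications)
  all3 <- rep$agreement3[rep$agreement3$scope == "all", ]
  expect_identical(sum(all3$n_eyes), nrow(rep$consensus))
  expect_identical(sum(all3$n_images), sum(rep$consensus$n_images))
  per_lat <- rep$agreement3[rep$agreement3$scope != "all", ]
  expect_identical(sum(per_lat$n_eyes), sum(all3$n_eyes))
  expect_identical(sum(rep$agreement4$n_patients),
                   rep$exclusion_flow$n_analyzed)
})
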