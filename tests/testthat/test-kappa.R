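# Cohen's kappa, distribution tables and the referable-DR analysis.

test_that("contingency tables keep the full scale and validate input", {
  tab <- build_contingency(c(0, 1), c(0, 1), K = 5)
  expect_identical(dim(tab), c(5L, 5L))
  expect_identical(sum(tab), 2L)
  expect_identical(tab[1, 1] + tab[2, 2], 2L)
  expect_identical(as.vector(build_contingency(c(0, 0, 1, 1),
                                               c(0, 1, 0, 1), K = 2)),
                   rep(1L, 4))
  deg <- build_contingency(rep(0L, 4), rep(0L, 4), K = 5)
  expect_identical(deg[1, 1], 4L)
  expect_identical(sum(deg), 4L)
  expect_error(build_contingency(0:1, 0:2, K = 5), "equal length")
  expect_error(build_contingency(5, 0, K = 5), "outside")
})

test_that("kappa matches hand-computed and degenerate cases", {
  # identical ratings -> perfect agreement
  v <- c(0, 1, 2, 1, 0, 3)
  expect_equal(cohen_kappa(build_contingency(v, v, K = 5)), 1)
  # observed equals chance agreement -> 0
  expect_equal(cohen_kappa(matrix(c(1, 1, 1, 1), 2)), 0)
  # hand-derived from the marginals: p_o = 11/16, p_e = 85/256
  tab <- matrix(c(4, 2, 0, 1, 3, 1, 0, 1, 4), 3)
  expect_equal(cohen_kappa(tab), 91 / 171, tolerance = 1e-12)
  # both raters constant and identical: kappa 1 by convention
  expect_equal(cohen_kappa(build_contingency(rep(0L, 5), rep(0L, 5), 5)), 1)
  expect_error(cohen_kappa(matrix(0, 3, 3)), "positive total")
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa is symmetric, bounded and relabeling invariant", {
  set.seed(7)
  for (i in 1:60) {
    K <- sample(2:5, 1)
    tab <- matrix(rpois(K * K, 3), K)
    if (sum(tab) == 0) tab[1, 1] <- 1
    for (w in c("none", "linear", "quadratic")) {
      k <- cohen_kappa(tab, w)
      expect_gte(k, -1)
      expect_lte(k, 1)
      expect_equal(cohen_kappa(t(tab), w), k)
    }
    # joint relabeling of categories leaves unweighted kappa unchanged
    perm <- sample(K)
    expect_equal(cohen_kappa(tab[perm, perm]), cohen_kappa(tab))
    # all weightings agree on diagonal-only tables
    d <- diag(rpois(K, 4) + 1)
    expect_equal(cohen_kappa(d, "linear"), cohen_kappa(d))
    expect_equal(cohen_kappa(d, "quadratic"), cohen_kappa(d))
  }
})

test_that("unweighted kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    tab <- matrix(rpois(K * K, 2), K)
    if (sum(tab) == 0) tab[K, 1] <- 2
    expect_equal(cohen_kappa(tab), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("weighted kappa agrees with the textbook double-sum formula", {
  wk <- function(tab, power) {
    K <- nrow(tab); n <- sum(tab)
    r <- rowSums(tab) / n; cl <- colSums(tab) / n
    po <- 0; pe <- 0
    for (i in 1:K) for (j in 1:K) {
      w <- 1 - (abs(i - j) / (K - 1))^power
      po <- po + w * tab[i, j] / n
      pe <- pe + w * r[i] * cl[j]
    }
    (po - pe) / (1 - pe)
  }
  set.seed(13)
  for (i in 1:40) {
    K <- sample(3:5, 1)
    tab <- matrix(rpois(K * K, 3) + 1, K)
    expect_equal(cohen_kappa(tab, "linear"), wk(tab, 1), tolerance = 1e-12)
    expect_equal(cohen_kappa(tab, "quadratic"), wk(tab, 2), tolerance = 1e-12)
  }
})

test_that("per-grader kappa against the final grades is 1 for perfect graders", {
  sim <- simulate_dataset(identity_config(n = 60))
  rep <- run_analysis(sim$grades, sim$ai, sim$adjudications)
  expect_true(all(rep$kappa$vs_final == 1))
  expect_true(all(rep$kappa$pairwise$kappa == 1))
  expect_true(all(rep$kappa$mean_pairwise == 1))
})

test_that("with two graders the pairwise mean equals the single pairwise kappa", {
  g <- tiny_grades()
  g <- g[g$grader_id != "g3", ]
  pw <- pairwise_kappa_summary(g)
  expect_identical(nrow(pw$pairwise), 1L)
  expect_equal(unname(pw$mean_pairwise),
               rep(pw$pairwise$kappa, 2))
})

test_that("distribution tables report counts and half-up percentages", {
  d <- distribution_table(rep(0:3, c(245, 54, 29, 7)), K = 4)
  expect_identical(d$n, c(245L, 54L, 29L, 7L))
  expect_identical(d$percentage, c(73.13, 16.12, 8.66, 2.09))
  expect_identical(attr(d, "total"), 335L)
  one <- distribution_table(0L, K = 5)
  expect_identical(one$percentage[1], 100)
  unif <- distribution_table(0:3, K = 4)
  expect_identical(unif$percentage, rep(25, 4))
  # zero-count levels are retained
  expect_identical(nrow(distribution_table(c(0L, 0L), K = 5)), 5L)
})

test_that("referable-DR analysis follows the binary majority rule", {
  # one patient, human patient-level grades (0, 0, 2), AI moderate:
  # binary majority is non-referable, the AI sides against it
  g <- data.frame(
    patient_id = "p1",
    laterality = rep(c("OD", "OS"), each = 3),
    grader_id = rep(c("g1", "g2", "g3"), 2),
    grade = c(0, 0, 2, 0, 0, 0),
    n_images = 2L)
  ai <- data.frame(patient_id = "p1", ai_grade = 2L)
  r <- rdr_analysis(g, ai)
  expect_identical(r$patients$majority, 1L)
  expect_identical(r$majority_patients_ai$against_majority, 1L)
  expect_identical(r$majority_patients_ai$with_majority, 0L)
  expect_identical(r$full_agreement_patients_ai$disagreements, 0L)
})

test_that("referable-DR analysis matches a brute-force rule over all binary patterns", {
  # every combination of three human binary calls and one AI binary call
  grid <- expand.grid(h1 = 0:1, h2 = 0:1, h3 = 0:1, ai = 0:1)
  for (i in seq_len(nrow(grid))) {
    h <- unlist(grid[i, 1:3])
    ai_bin <- grid$ai[i]
    g <- data.frame(
      patient_id = "p1",
      laterality = rep(c("OD", "OS"), each = 3),
      grader_id = rep(c("g1", "g2", "g3"), 2),
      grade = c(h * 2L, h * 2L),      # grade 2 is referable, 0 is not
      n_images = 1L)
    ai <- data.frame(patient_id = "p1", ai_grade = ai_bin * 2L)
    r <- rdr_analysis(g, ai)
    full <- length(unique(h)) == 1L
    maj <- as.integer(sum(h) >= 2)
    expect_identical(r$patients$full_agreement, as.integer(full))
    expect_identical(r$patients$majority, as.integer(!full))
    expect_identical(r$eyes$full_agreement + r$eyes$majority, 2L)
    if (full) {
      expect_identical(r$full_agreement_patients_ai$disagreements,
                       as.integer(ai_bin != maj))
      expect_identical(r$full_agreement_patients_ai$ai_referable,
                       as.integer(ai_bin == 1L && maj == 0L))
    } else {
      expect_identical(r$majority_patients_ai$with_majority,
                       as.integer(ai_bin == maj))
      expect_identical(r$majority_patients_ai$against_majority,
                       as.integer(ai_bin != maj))
    }
  }
})

test_that("referable-DR patient counts partition the analyzable patients", {
  sim <- simulate_dataset(noisy_config(n = 200, seed = 21))
  excl <- apply_quality_exclusion(sim$grades, sim$ai)
  r <- rdr_analysis(excl$grades, excl$ai)
  expect_identical(r$patients$full_agreement + r$patients$majority,
                   r$patients$n)
  expect_identical(r$eyes$full_agreement + r$eyes$majority, r$eyes$n)
  expect_identical(r$patients$n, excl$flow$n_analyzed)
})
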