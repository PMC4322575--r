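test_that("contingency tables follow the A,B,C,D identities", {
  expect_identical(unname(tableCells(contingencyTable(0, 0, 0, 10))),
                   c(0, 0, 0, 10, 10))
  expect_identical(unname(tableCells(contingencyTable(5, 5, 5, 5))),
                   c(5, 0, 0, 0, 5))
  # direct evaluation: A=10, B=30-10, C=40-10, D=100-(30+40)+10
  expect_identical(unname(tableCells(contingencyTable(30, 40, 10, 100))),
                   c(10, 20, 30, 40, 100))
  expect_error(contingencyTable(5, 5, 6, 100), "inconsistent")
  expect_error(contingencyTable(60, 60, 0, 100), "inconsistent")
})

test_that("association statistics match closed forms and standard routines", {
  st <- associationStats(contingencyTable(30, 40, 10, 100))
  expect_equal(st$odds_ratio, (10 * 40) / (20 * 30))
  expect_equal(st$relative_risk, (10 / 30) / (30 / 70))
  # cross-check chi-squared against the standard uncorrected test
  tab <- matrix(c(10, 20, 30, 40), nrow = 2, byrow = TRUE)
  expect_equal(st$chi_squared,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic))
  expect_equal(st$p_marginal_x, 0.3)
  expect_equal(st$p_joint, 0.1)
  expect_equal(st$p_y_given_x, 0.1 / 0.3)
  expect_equal(st$lift, (0.1 / 0.3) / 0.4)
})

test_that("exact independence gives lift 1 and vanishing chi-squared and G", {
  st <- associationStats(contingencyTable(10, 10, 1, 100))  # A=1 B=9 C=9 D=81
  expect_equal(st$lift, 1)
  expect_equal(st$chi_squared, 0)
  expect_equal(st$g_statistic, 0)
})

test_that("zero denominators give explicit NA unless Haldane correction is on", {
  st <- associationStats(contingencyTable(5, 0, 0, 10))
  expect_true(is.na(st$odds_ratio))
  expect_match(paste(st$undefined, collapse = "; "), "odds_ratio")
  stc <- associationStats(contingencyTable(5, 0, 0, 10), continuityCorrection = TRUE)
  expect_true(is.finite(stc$odds_ratio))
})

test_that("the chain rule and lift symmetry hold on random tables", {
  withr::with_seed(31, {
    for (i in 1:50) {
      N <- sample(50:500, 1)
      fx <- sample.int(N, 1); fy <- sample.int(N, 1)
      lo <- max(0L, fx + fy - N)
      hi <- min(fx, fy)
      fxy <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      st <- associationStats(contingencyTable(fx, fy, fxy, N))
      # P(Y|X) P(X) = P(X,Y) to machine precision
      if (!is.na(st$p_y_given_x))
        expect_equal(st$p_y_given_x * st$p_marginal_x, st$p_joint)
      # Lift(X->Y) = Lift(Y->X) = P(X,Y) / (P(X) P(Y))
      sw <- associationStats(contingencyTable(fy, fx, fxy, N))
      if (!is.na(st$lift)) {
        expect_equal(st$lift, sw$lift)
        expect_equal(st$lift, st$p_joint / (st$p_marginal_x * st$p_marginal_y))
      }
    }
  })
})

test_that("chi-squared and G agree asymptotically on large balanced tables", {
  # a mild departure from independence on a large table
  st <- associationStats(contingencyTable(60000, 52000, 15800, 200000))
  expect_gt(st$chi_squared, 0)
  expect_lt(abs(st$chi_squared - st$g_statistic) / st$chi_squared, 0.02)
})

test_that("feature groups are lift-thresholded connected components", {
  sing <- new("SingletonCounts",
              counts = data.frame(id = 1:5, count = c(10L, 10L, 10L, 10L, 10L)),
              mode = "per-bin", width = 7, level = "term", N = 100L)
  # lift = N * fxy / (fx * fy) = fxy with these margins
  mat <- new("CoFrequencyMatrix",
             pairs = data.frame(id_x = c(1L, 2L, 4L), id_y = c(2L, 3L, 5L),
                                count = c(5L, 4L, 1L)),
             mode = "per-bin", width = 7, level = "term", N = 100L)
  # chain 1-2, 2-3 above threshold; 4-5 below: transitive closure
  g <- featureGroups(mat, sing, liftThreshold = 2, minCount = 1L)
  expect_identical(g, list(c(1L, 2L, 3L), 4L, 5L))
  # nothing passes: every ID its own group
  g2 <- featureGroups(mat, sing, liftThreshold = 100, minCount = 1L)
  expect_identical(lengths(g2), rep(1L, 5L))
  # mismatched N is an error
  bad <- new("SingletonCounts", counts = singletonCounts(sing),
             mode = "per-bin", width = 7, level = "term", N = 200L)
  expect_error(featureGroups(mat, bad), "mismatch")
})

test_that("lift of a planted association matches the generator analytics", {
  # single-note patients at infinite width: bins are notes; with k background
  # draws from V terms plus co-injection at rate p, the analytic per-bin lift
  # is [p + (1-p) k(k-1)/(V(V-1))] / [p + (1-p) k/V]^2
  k <- 3; V <- 40L; p <- 0.2; n <- 4000L
  cfg <- simulationConfig(nPatients = n, notesPerPatient = c(1L, 1L),
                          termsPerNote = c(k, k), vocabularySize = V,
                          plantedPairs = list(c(5, 9, p)), seed = 101L)
  corp <- generateCorpus(cfg)
  off <- drawOffsets(unique(corpusNotes(corp)$patient_id), Inf, 1L)
  g <- groundTruthCounts(corp, Inf, "per-bin", off)
  lifted <- pairLift(g$cofreq, g$singletons)
  est <- lifted$lift[lifted$id_x == 5L & lifted$id_y == 9L]
  pJoint <- p + (1 - p) * k * (k - 1) / (V * (V - 1))
  pMarg <- p + (1 - p) * k / V
  liftA <- pJoint / pMarg^2
  a <- lifted$count[lifted$id_x == 5L & lifted$id_y == 9L]
  s <- singletonCounts(g$singletons)
  seLog <- sqrt(1 / a + 1 / s$count[s$id == 5L] + 1 / s$count[s$id == 9L])
  expect_lt(abs(log(est / liftA)), 3 * seLog)
})

test_that("enrichment p-values match exhaustive hypergeometric enumeration", {
  # N=20 patients, 5 carry the annotation, cohort of 4 observes 3: enumerate
  # all C(20,4) cohorts to get the exact upper-tail probability
  N <- 20L; fy <- 5L; n <- 4L; obs <- 3L
  universe <- c(rep(TRUE, fy), rep(FALSE, N - fy))
  draws <- combn(N, n)
  tail <- mean(apply(draws, 2, function(ix) sum(universe[ix]) >= obs))
  bg <- new("SingletonCounts", counts = data.frame(id = 1L, count = fy),
            mode = "per-patient", width = Inf, level = "term", N = N)
  res <- enrichment(c("1" = obs), n, bg)
  expect_equal(res$p_value, tail)
  expect_equal(res$expected, n * fy / N)
  expect_equal(res$fold, obs / (n * fy / N))
})

test_that("conditioning on a co-occurring annotation raises expectation and p", {
  N <- 1000L
  bg <- new("SingletonCounts",
            counts = data.frame(id = c(1L, 2L), count = c(200L, 100L)),
            mode = "per-patient", width = Inf, level = "term", N = N)
  # f(x,y)/f(x) = 120/200 = 0.6 > f(y)/N = 0.1
  mat <- new("CoFrequencyMatrix",
             pairs = data.frame(id_x = 1L, id_y = 2L, count = 120L),
             mode = "per-patient", width = Inf, level = "term", N = N)
  res <- enrichment(c("2" = 30L), 50L, bg, adjustWith = mat, conditioningId = 1L)
  expect_gt(res$adjusted_expected, res$expected)
  expect_gt(res$adjusted_p, res$p_value)
  expect_error(enrichment(c("2" = 30L), 50L, bg, adjustWith = mat,
                          conditioningId = 9L), "absent")
})

test_that("null cohorts give near-unit fold and non-anticonservative p-values", {
  withr::with_seed(55, {
    N <- 400L; fy <- 120L; n <- 40L
    carriers <- sample.int(N, fy)
    bg <- new("SingletonCounts", counts = data.frame(id = 1L, count = fy),
              mode = "per-patient", width = Inf, level = "term", N = N)
    ps <- replicate(400, {
      cohort <- sample.int(N, n)
      enrichment(c("1" = sum(cohort %in% carriers)), n, bg)$p_value
    })
    folds <- replicate(200, {
      cohort <- sample.int(N, n)
      enrichment(c("1" = sum(cohort %in% carriers)), n, bg)$fold
    })
    expect_lt(abs(mean(folds) - 1), 0.1)
    expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  })
})
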