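test_that("BH adjustment matches the hand-worked example and the oracle", {
  expect_equal(fdrBH(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(fdrBH(0.2), 0.2)
  expect_equal(fdrBH(rep(0.03, 7)), rep(0.03, 7))
  expect_error(fdrBH(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (k in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdrBH(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("cognition regression reports exact and null R squared", {
  set.seed(23)
  n <- 2000
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  exact <- suppressWarnings(
    regressCognition(X, "f1", scores = list(s = X[, 1])))
  expect_equal(exact$r2, 1)
  expect_identical(exact$n, 2000L)

  null <- regressCognition(X, paste0("f", 1:5),
                           scores = list(s = rnorm(n)))
  expect_lt(null$r2, 0.01)

  # R squared identity and monotonicity under added regressors
  yv <- X[, 1] + rnorm(n)
  r2a <- regressCognition(X, "f1", scores = list(s = yv))$r2
  fit <- lm(yv ~ X[, 1])
  expect_equal(r2a, 1 - sum(resid(fit)^2) / sum((yv - mean(yv))^2),
               tolerance = 1e-10)
  r2b <- regressCognition(X, c("f1", "f2"), scores = list(s = yv))$r2
  expect_gte(r2b, r2a)

  expect_error(regressCognition(X[1:6, ], paste0("f", 1:5),
                                scores = list(s = yv[1:6])),
               "dimensionality")
})

test_that("synthetic cognition recovers the generating R squared", {
  set.seed(29)
  r2 <- replicate(10, {
    fe <- generateCohort(synthConfig(nRegions = 10, nInformative = 10,
                                     cognitionR2 = 0.6,
                                     seed = sample.int(1e6, 1)))
    regressCognition(fe, plantedTruth(fe)$feature,
                     scores = "wlt_retention")$r2
  })
  expect_equal(mean(r2), 0.6, tolerance = 0.1 / 0.6)
})

test_that("confound screen flags planted associations and only those", {
  fe <- generateCohort(synthConfig(nRegions = 8, seed = 37))
  ph <- as.data.frame(phenotypes(fe))
  X <- featureMatrix(fe)
  set.seed(41)
  X[, "edge_1_2"] <- 0.9 * scale(ph$madrs) + 0.1 * rnorm(ncol(fe))
  fe2 <- FeatureExperiment(X, as.data.frame(featureInfo(fe)), ph)
  scr <- confoundScreen(fe2, c("edge_1_2", "edge_1_3", "edge_2_3"))
  hit <- scr[scr$variable == "madrs" & scr$feature == "edge_1_2", ]
  expect_lt(hit$q, 0.05)
  expect_identical(hit$method, "pearson_r")
  expect_true(all(c("t", "F") %in% scr$method))

  # degenerate medication flag is skipped with a warning
  ph$med_antidep <- TRUE
  fe3 <- FeatureExperiment(featureMatrix(fe),
                           as.data.frame(featureInfo(fe)), ph)
  expect_warning(rep3 <- confoundScreen(fe3, "edge_1_2"), "degenerate")
  expect_false("med_antidep" %in% rep3$variable)
})

test_that("null features are flagged at no more than the nominal rate", {
  set.seed(43)
  hits <- replicate(150, {
    fe <- generateCohort(synthConfig(nLow = 30, nHigh = 30, nRegions = 4,
                                     nInformative = 3,
                                     seed = sample.int(1e6, 1)))
    scr <- confoundScreen(fe, c("edge_1_2", "edge_1_3", "edge_1_4"),
                          continuous = c("ymrs", "madrs"),
                          binary = character(0),
                          categorical = character(0))
    vapply(c("ymrs", "madrs"), function(v)
      any(scr$q[scr$variable == v] < 0.05, na.rm = TRUE), NA)
  })
  # within each variable family the FWER under the global null is at
  # most the FDR level
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / 150)
  expect_lte(mean(hits["ymrs", ]), bound)
  expect_lte(mean(hits["madrs", ]), bound)
})

test_that("demographic tests reproduce printed-summary statistics", {
  # age summaries of the low/high episode groups
  age <- pooledTTest(34.05, 14.386, 43, 41.45, 12.176, 55)
  expect_equal(age$p.value, 0.0069, tolerance = 2e-4 / 0.0069)
  expect_identical(age$parameter, 96)

  sex <- chisqNoCorrection(matrix(c(8, 35, 22, 33), 2, byrow = TRUE))
  expect_equal(sex$p.value, 0.0226, tolerance = 1e-4 / 0.0226)

  # raw-data path equals the summary path
  set.seed(47)
  ph <- data.frame(
    subject_id = as.character(1:40),
    grp = rep(c("a", "b"), each = 20),
    age = c(rnorm(20, 30, 5), rnorm(20, 40, 6)),
    sex = sample(c("female", "male"), 40, replace = TRUE))
  out <- groupCompareDemographics(ph, "grp", continuous = "age")
  byHand <- pooledTTest(mean(ph$age[1:20]), sd(ph$age[1:20]), 20,
                        mean(ph$age[21:40]), sd(ph$age[21:40]), 20)
  expect_equal(out$p[out$variable == "age"], byHand$p.value,
               tolerance = 1e-12)

  # identical groups cannot differ
  ph2 <- ph
  ph2$age <- rep(ph$age[1:20], 2)
  ph2$sex <- rep(ph$sex[1:20], 2)
  out2 <- groupCompareDemographics(ph2, "grp", continuous = "age")
  expect_equal(out2$p, rep(1, 2))

  expect_warning(groupCompareDemographics(ph, "grp",
                                          continuous = c("age", "height")),
                 "height")
})
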