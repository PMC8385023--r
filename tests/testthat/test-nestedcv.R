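test_that("metrics follow their definitions at the study's class sizes", {
  # 55 positives (40 hits), 43 negatives (30 correct rejections)
  yTrue <- rep(c("high", "low"), c(55, 43))
  yPred <- c(rep("high", 40), rep("low", 15), rep("low", 30),
             rep("high", 13))
  scores <- ifelse(yPred == "high", 1, -1) + rnorm(98, sd = 0.01)
  m <- computeMetrics(yTrue, yPred, scores, "high")
  expect_equal(unname(m["sensitivity"]), 40 / 55, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 30 / 43, tolerance = 1e-12)
  expect_equal(unname(m["accuracy"]),
               (m[["sensitivity"]] * 55 + m[["specificity"]] * 43) / 98,
               tolerance = 1e-12)

  # perfect ranking and all-tied ranking
  sPerfect <- ifelse(yTrue == "high", 2, -2)
  expect_equal(unname(computeMetrics(yTrue, yTrue, sPerfect,
                                     "high")["auc"]), 1)
  expect_equal(unname(computeMetrics(yTrue, yPred, rep(0, 98),
                                     "high")["auc"]), 0.5)
  expect_error(computeMetrics(rep("high", 10), yPred[1:10], scores[1:10],
                              "low"), "absent")
})

test_that("auc equals the probability a positive outranks a negative", {
  set.seed(17)
  for (k in 1:20) {
    y <- sample(c("p", "n"), 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # force some ties
    m <- computeMetrics(y, y, s, "p")
    brute <- mean(outer(s[y == "p"], s[y == "n"],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(unname(m["auc"]), brute, tolerance = 1e-12)
  }
})

test_that("nested CV separates a strong planted effect and is deterministic", {
  fe <- generateCohort(synthConfig(nRegions = 10, nInformative = 10,
                                   effectSize = 3, seed = 41))
  X <- featureMatrix(fe)[, plantedTruth(fe)$feature]
  y <- phenotypes(fe)$episodes
  cv <- nestedCV(X, y, repeats = 2, seed = 13)
  expect_gt(mean(performanceByRepeat(cv)$accuracy), 0.95)
  cv2 <- nestedCV(X, y, repeats = 2, seed = 13)
  expect_identical(performanceByRepeat(cv), performanceByRepeat(cv2))
  expect_identical(cv@selectionLog, cv2@selectionLog)
})

test_that("permuted labels on a balanced cohort stay at chance level", {
  # a single fixed permutation retains chance in-cohort structure, so
  # calibration is judged on the average over independent permutations
  fe <- generateCohort(synthConfig(nLow = 49, nHigh = 49, nRegions = 10,
                                   effectSize = 1.5, seed = 8))
  X <- featureMatrix(fe)
  set.seed(91)
  perf <- vapply(1:5, function(k) {
    yPerm <- sample(phenotypes(fe)$episodes)
    cv <- nestedCV(X, yPerm, repeats = 4, seed = 300 + k)
    c(mean(performanceByRepeat(cv)$accuracy),
      mean(performanceByRepeat(cv)$auc))
  }, numeric(2))
  expect_gt(mean(perf[1, ]), 0.45)
  expect_lt(mean(perf[1, ]), 0.55)
  expect_gt(mean(perf[2, ]), 0.45)
  expect_lt(mean(perf[2, ]), 0.55)
})

test_that("inner selection never sees the held-out fold", {
  fe <- generateCohort(synthConfig(nLow = 15, nHigh = 15, nRegions = 8,
                                   effectSize = 1, seed = 55))
  X <- featureMatrix(fe)
  y <- phenotypes(fe)$episodes
  seed <- 29
  # reproduce the repeat-1 fold assignment, then corrupt the rows of
  # outer fold 1: fold 1's own training data are untouched, so its
  # inner feature selection must be identical
  set.seed(connstab:::repeatSeed(seed, 1))
  fold <- connstab:::stratifiedFolds(y, 3)
  X2 <- X
  X2[fold == 1, ] <- matrix(rnorm(sum(fold == 1) * ncol(X), sd = 5),
                            sum(fold == 1), ncol(X))
  cvA <- nestedCV(X, y, repeats = 1, seed = seed)
  cvB <- nestedCV(X2, y, repeats = 1, seed = seed)
  expect_identical(cvA@selectionLog[[1]][[1]], cvB@selectionLog[[1]][[1]])
})

test_that("fold losses are impossible for adequate classes, else error", {
  cc <- noiseCohort(n = 10, p = 4)
  yBad <- factor(rep(c("a", "b"), c(2, 8)))
  expect_error(nestedCV(cc$X, yBad, repeats = 1), "at least 3")
})

test_that("best-threshold choice maximizes accuracy, ties prefer sparser", {
  perfs <- list(`500` = fakePerformance(c(0.70, 0.72)),
                `750` = fakePerformance(c(0.73, 0.742)))
  pick <- selectBestThreshold(perfs)
  expect_identical(pick$threshold, 750L)
  expect_identical(pick$table$threshold, c(500L, 750L))

  single <- selectBestThreshold(perfs["500"])
  expect_identical(single$threshold, 500L)

  tied <- list(`500` = fakePerformance(c(0.7, 0.7)),
               `700` = fakePerformance(c(0.7, 0.7)))
  expect_identical(selectBestThreshold(tied)$threshold, 700L)
})

test_that("major features obey the strict repeat-count rule with direction", {
  feats <- paste0("f", 1:3)
  n <- 30
  y <- factor(rep(c("low", "high"), each = n / 2),
              levels = c("low", "high"))
  X <- cbind(f1 = ifelse(y == "high", 1, -1) + rnorm(n, sd = 0.1),
             f2 = ifelse(y == "high", -1, 1) + rnorm(n, sd = 0.1),
             f3 = rnorm(n))
  info <- data.frame(feature = feats, network_i = c("DMN", "MON", "SC"),
                     network_j = c("FPN", "MON", "DMN"))
  # f1 in all folds of all 100 repeats; f2 in exactly 90 repeats
  # (majority of folds); f3 never in a majority
  log <- lapply(1:100, function(r) {
    list(c("f1", if (r <= 90) "f2"),
         c("f1", if (r <= 90) "f2", "f3"),
         c("f1"))
  })
  cv <- fakePerformance(rep(0.7, 100), log = log, positive = "high")
  mf <- majorFeatures(cv, X, y, minRepeats = 90, info = info)
  tab <- majorFeatureTable(mf)
  expect_identical(tab$feature, "f1")       # 90 exactly is excluded
  expect_identical(tab$count, 100L)
  expect_identical(tab$direction, 1L)
  expect_identical(tab$network_i, "DMN")

  # inclusive rule when one fewer repeat is demanded
  mf89 <- majorFeatureTable(majorFeatures(cv, X, y, minRepeats = 89,
                                          info = info))
  expect_setequal(mf89$feature, c("f1", "f2"))
  expect_identical(mf89$direction[mf89$feature == "f2"], -1L)

  expect_error(majorFeatures(fakePerformance(0.7), X, y), "empty")
})

test_that("performance comparison is a pooled t test with symmetry", {
  a <- fakePerformance(rep(0.7, 50))
  expect_identical(comparePerformance(a, a),
                   list(statistic = 0, parameter = 98, p.value = 1))

  set.seed(6)
  b <- fakePerformance(0.7 + rnorm(100, sd = 1e-3))
  c2 <- fakePerformance(0.8 + rnorm(100, sd = 1e-3))
  cmp <- comparePerformance(b, c2)
  expect_lt(cmp$p.value, 1e-10)
  rev <- comparePerformance(c2, b)
  expect_equal(rev$statistic, -cmp$statistic)
  expect_equal(rev$p.value, cmp$p.value)

  expect_error(comparePerformance(a, fakePerformance(rep(0.9, 10))),
               "zero variance")
})
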