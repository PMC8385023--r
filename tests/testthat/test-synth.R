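test_that("cohort sizes, labels and validation follow the configuration", {
  fe <- generateCohort(synthConfig(nLow = 43, nHigh = 55, nRegions = 8,
                                   seed = 1))
  g <- table(phenotypes(fe)$episodes)
  expect_identical(as.integer(g[c("low", "high")]), c(43L, 55L))
  expect_identical(ncol(fe), 98L)
  expect_identical(nrow(fe), 28L)          # 8*7/2 edges

  expect_error(synthConfig(nRegions = 4, nInformative = 100),
               "nInformative")
  expect_error(synthConfig(cognitionR2 = 1.2), "cognitionR2")
  expect_error(synthConfig(effectSize = -1), "effectSize")
  expect_error(synthConfig(nLow = 0), "nLow")
})

test_that("identical configuration and seed give an identical cohort", {
  cfg <- synthConfig(nRegions = 10, covariateConfounding = 0.2, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(as.data.frame(phenotypes(a)),
                   as.data.frame(phenotypes(b)))
  expect_identical(plantedTruth(a), plantedTruth(b))
})

test_that("zero effect size leaves no group difference", {
  fe <- generateCohort(synthConfig(nLow = 5000, nHigh = 5000,
                                   nRegions = 6, nInformative = 3,
                                   effectSize = 0, seed = 12))
  X <- featureMatrix(fe)
  g <- phenotypes(fe)$episodes == "high"
  se <- sqrt(apply(X[g, ], 2, var) / sum(g) +
               apply(X[!g, ], 2, var) / sum(!g))
  diffs <- abs(colMeans(X[g, ]) - colMeans(X[!g, ]))
  expect_true(all(diffs < 3 * se))
})

test_that("planted effects carry their sign and magnitude", {
  cfg <- synthConfig(nRegions = 12, nInformative = 8, effectSize = 1.5,
                     seed = 31)
  fe <- generateCohort(cfg)
  X <- featureMatrix(fe)
  g <- phenotypes(fe)$episodes == "high"
  tr <- plantedTruth(fe)
  observed <- colMeans(X[g, tr$feature, drop = FALSE]) -
    colMeans(X[!g, tr$feature, drop = FALSE])
  expect_identical(unname(sign(observed)), as.numeric(tr$direction))
  # non-planted edges have no systematic shift (pooled z test)
  other <- setdiff(colnames(X), tr$feature)
  z <- (colMeans(X[g, other]) - colMeans(X[!g, other])) /
    sqrt(0.25^2 / sum(g) + 0.25^2 / sum(!g))
  expect_lt(max(abs(z)), 4.5)
})

test_that("null features yield t statistics following the t distribution", {
  fe <- generateCohort(synthConfig(nLow = 49, nHigh = 49, nRegions = 46,
                                   effectSize = 0, seed = 77))
  X <- featureMatrix(fe)
  expect_gte(ncol(X), 1000)
  g <- phenotypes(fe)$episodes == "high"
  tstat <- apply(X, 2, function(x) t.test(x[g], x[!g],
                                          var.equal = TRUE)$statistic)
  ks <- ks.test(tstat, pt, df = 96)
  expect_gt(ks$p.value, 0.01)
})

test_that("cognition scores realize the configured R squared", {
  cfg <- synthConfig(nLow = 1000, nHigh = 1000, nRegions = 10,
                     nInformative = 5, cognitionR2 = 0.6, seed = 5)
  fe <- generateCohort(cfg)
  X <- featureMatrix(fe)[, plantedTruth(fe)$feature]
  for (task in c("wlt_retention", "wlt_immediate")) {
    r2 <- summary(lm(phenotypes(fe)[[task]] ~ X))$r.squared
    expect_equal(r2, 0.6, tolerance = 0.03 / 0.6)
  }
})

test_that("time series reproduce the target correlation structure", {
  # identity target: zero-feature cohort
  ph <- data.frame(subject_id = c("A", "B"), age = c(30, 40),
                   sex = c("female", "male"))
  pairs <- connstab:::edgePairs(6)
  info <- data.frame(feature = connstab:::edgeNames(pairs), kind = "edge",
                     i = pairs[, "i"], j = pairs[, "j"])
  zeroFe <- FeatureExperiment(matrix(0, 2, nrow(pairs),
                                     dimnames = list(NULL, info$feature)),
                              info, ph)
  ts <- generateTimeseries(zeroFe, tsLength = 500, seed = 8)
  cm <- connectivityMatrix(ts[["A"]])
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)

  # a single strong edge at r = 0.8
  pairs3 <- connstab:::edgePairs(3)
  info3 <- data.frame(feature = connstab:::edgeNames(pairs3),
                      kind = "edge", i = pairs3[, "i"], j = pairs3[, "j"])
  oneEdge <- FeatureExperiment(
    matrix(c(atanh(0.8), 0, 0), 1, 3,
           dimnames = list(NULL, info3$feature)),
    info3, ph[1, , drop = FALSE])
  ts2 <- generateTimeseries(oneEdge, tsLength = 2000, seed = 9)
  expect_equal(connectivityMatrix(ts2[["A"]])[1, 2], 0.8,
               tolerance = 0.03 / 0.8)

  # the acquisition length after dropping initial volumes passes cleanly
  expect_no_warning(generateTimeseries(zeroFe, tsLength = 192, seed = 2))
})

test_that("non-positive-definite targets demand shrinkage", {
  fe <- generateCohort(synthConfig(nLow = 3, nHigh = 3, nRegions = 20,
                                   noiseSD = 1, seed = 3))
  expect_error(generateTimeseries(fe, tsLength = 50, seed = 1),
               "shrinkage")
  expect_silent(ts <- generateTimeseries(fe, tsLength = 50, shrink = 0.9,
                                         seed = 1))
  expect_identical(dim(ts[[1]]), c(50L, 20L))
})

test_that("fisher-z features recomputed from long series match the cohort", {
  fe <- generateCohort(synthConfig(nLow = 6, nHigh = 6, nRegions = 8,
                                   noiseSD = 0.1, seed = 14))
  ts <- generateTimeseries(fe, tsLength = 1000, seed = 15)
  parc <- S4Vectors::metadata(fe)$parcellation
  rebuilt <- buildFeatures(ts, as.data.frame(phenotypes(fe)), parc)
  r <- cor(as.vector(featureMatrix(rebuilt)), as.vector(featureMatrix(fe)))
  expect_gt(r, 0.9)
})
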