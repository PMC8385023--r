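makePhen <- function(fd) {
  data.frame(subject_id = sprintf("S%03d", seq_along(fd)), mean_fd = fd)
}

test_that("motion QC keeps subjects at or below the FD threshold", {
  fd <- c(runif(98, 0.02, 0.19), runif(14, 0.21, 0.5))
  expect_message(kept <- filterMotion(makePhen(fd)), "14 of 112")
  expect_identical(nrow(kept), 98L)

  allStill <- makePhen(rep(0, 10))
  expect_message(expect_identical(nrow(filterMotion(allStill)), 10L))

  one <- makePhen(c(0, 0.01))
  expect_message(k0 <- filterMotion(one, fdThreshold = 0))
  expect_identical(k0$subject_id, "S001")

  miss <- makePhen(c(0.1, NA, 0.1))
  expect_error(filterMotion(miss), "S002")
})

test_that("connectivity is a valid correlation matrix with named errors", {
  set.seed(5)
  ts <- matrix(rnorm(2000 * 4), 2000, 4,
               dimnames = list(NULL, paste0("r", 1:4)))
  ts[, 2] <- ts[, 1]
  cm <- connectivityMatrix(ts)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), setNames(rep(1, 4), paste0("r", 1:4)))
  # independent columns: null bound 3/sqrt(T)
  offd <- abs(cm[3, 4])
  expect_lt(offd, 0.07)
  ts[, 3] <- -ts[, 1]
  expect_equal(connectivityMatrix(ts)[1, 3], -1)
  ts[, 4] <- 2
  expect_error(connectivityMatrix(ts), "r4")
  expect_error(connectivityMatrix(ts[1:2, ]), "3 time points")
})

test_that("fisher z is atanh with clipping, odd and increasing", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.76159), 1, tolerance = 1e-4)
  expect_equal(fisherZ(-0.5), -0.5493, tolerance = 1e-4)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisherZ(r), 0.5 * log((1 + r) / (1 - r)),
               tolerance = 1e-12)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_true(is.finite(fisherZ(1)))
  expect_error(fisherZ(1.2), "\\[-1, 1\\]")
})

test_that("vectorization is row-major upper triangle with network pairs", {
  m4 <- devectorizeMatrix(1:6, 4)
  v <- vectorizeMatrix(m4)
  expect_identical(unname(v$values), as.numeric(1:6))
  expect_identical(v$info$feature[1:3], c("edge_1_2", "edge_1_3",
                                          "edge_1_4"))

  parc <- data.frame(region_id = 1:4, network = c("DMN", "MON", "FPN",
                                                  "SC"))
  v2 <- vectorizeMatrix(m4, parc)
  expect_identical(v2$info$network_i[1], "DMN")
  expect_identical(v2$info$network_j[1], "MON")

  big <- matrix(0, 268, 268)
  expect_identical(length(vectorizeMatrix(big)$values), 35778L)

  asym <- m4; asym[1, 2] <- asym[1, 2] + 1e-6
  expect_error(vectorizeMatrix(asym), "asymmetric")
})

test_that("vectorize and devectorize are mutually inverse", {
  set.seed(9)
  for (R in c(3, 5, 12)) {
    vals <- rnorm(R * (R - 1) / 2)
    expect_equal(unname(vectorizeMatrix(devectorizeMatrix(vals, R))$values),
                 vals)
  }
})

test_that("residualization removes covariate structure", {
  set.seed(13)
  n <- 80
  cov <- data.frame(age = runif(n, 20, 60),
                    sex = rbinom(n, 1, 0.4))
  X <- cbind(a = 2 * cov$age + 5,
             b = rnorm(n) + 0.3 * cov$age,
             c = rnorm(n))
  R <- residualizeFeatures(X, cov)
  expect_lt(max(abs(R[, "a"])), 1e-8)
  expect_lt(abs(cor(R[, "b"], cov$age)), 1e-10)
  # column "a" is residual numerical noise; orthogonality is meaningful
  # for the non-degenerate features
  expect_lt(max(abs(cor(R[, c("b", "c")], cbind(cov$age, cov$sex)))),
            1e-8)

  # fold-safe mode: coefficients come from training rows only
  tr <- 1:40
  R1 <- residualizeFeatures(X, cov, mode = "fold_safe", train = tr)
  X2 <- X; X2[41:80, ] <- X2[41:80, ] + 100   # perturb test rows only
  R2 <- residualizeFeatures(X2, cov, mode = "fold_safe", train = tr)
  expect_equal(R1[tr, ], R2[tr, ])            # train residuals unchanged
  expect_equal(R2[41:80, ] - R1[41:80, ],
               matrix(100, 40, 3, dimnames = dimnames(R1[41:80, ])))

  expect_error(residualizeFeatures(X, transform(cov, sex = 0)), "rank")
  expect_error(residualizeFeatures(X, cov, mode = "fold_safe"), "train")
})

test_that("FeatureExperiment round-trips through residualization flag", {
  fe <- generateCohort(synthConfig(nRegions = 8, seed = 2))
  expect_false(isResidualized(fe))
  fr <- residualizeFeatures(fe)
  expect_true(isResidualized(fr))
  ph <- as.data.frame(phenotypes(fr))
  mx <- featureMatrix(fr)
  expect_lt(max(abs(cor(mx, ph$age))), 1e-8)
})

test_that("morphometric features are z-scored before pooling", {
  fe <- generateCohort(synthConfig(nRegions = 6, seed = 3),
                       morphometry = TRUE)
  fm <- mergeMorphometry(fe, S4Vectors::metadata(fe)$morphometry)
  info <- as.data.frame(featureInfo(fm))
  expect_identical(sum(info$kind == "morph"), 12L)
  vals <- featureMatrix(fm)[, info$kind == "morph"]
  expect_equal(unname(colMeans(vals)), rep(0, 12), tolerance = 1e-12)
  expect_equal(unname(apply(vals, 2, sd)), rep(1, 12), tolerance = 1e-12)
  expect_identical(info$measure[info$kind == "morph"][1], "volume")
})

test_that("cohort files round-trip through the plain-text readers", {
  fe <- generateCohort(synthConfig(nRegions = 6, nLow = 5, nHigh = 6,
                                   seed = 4))
  dir <- withr::local_tempdir()
  exportCohort(fe, dir)
  back <- readFeatureTable(dir)
  expect_equal(featureMatrix(back), featureMatrix(fe))
  parc <- readParcellation(file.path(dir, "parcellation.csv"))
  expect_identical(nrow(parc), 6L)
})
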