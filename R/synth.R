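#' Generate a synthetic two-group cohort
#'
#' Builds a cohort with the statistical structure the downstream analysis
#' assumes: connectivity features generated directly on the residual
#' Fisher-z scale as Gaussians, a small set of planted edges whose group
#' means differ by `effectSize` standard deviations (sign chosen at
#' random per edge), optional leakage of standardized age and centred sex
#' into every feature, and five verbal-memory scaled scores linearly
#' driven by the planted edges at a configured R-squared. The noise SD of
#' the cognition scores is solved in closed form from `cognitionR2` and
#' the realized variance of the linear predictor, so R-squared recovery is
#' an exact target. The cohort is a deterministic function of the
#' configuration (including its seed).
#'
#' The phenotype table carries the subgroup labels the classification
#' stages consume (`episodes` is the label tied to the planted features;
#' `hospitalizations`, `suicide`, `psychosis` and `diagnosis` are drawn
#' independently of the features), symptom scores, medication flags,
#' mood state, illness duration and mean framewise displacement. Mean FD
#' is drawn below typical exclusion levels: the cohort emulates a
#' post-QC sample.
#'
#' @param config a [SynthConfig-class], see [synthConfig()].
#' @param morphometry if `TRUE`, also generate a morphometric table
#'   (volume and thickness per region, no group signal) stored in the
#'   cohort metadata for [mergeMorphometry()].
#' @return A [FeatureExperiment-class] with `plantedTruth()` and
#'   [cognitionWeights()] metadata, plus the parcellation table in
#'   `metadata(x)$parcellation`.
#' @examples
#' fe <- generateCohort(synthConfig(nRegions = 10, seed = 7))
#' fe
#' @export
generateCohort <- function(config, morphometry = FALSE) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  set.seed(config@seed)

  nLow <- config@nLow; nHigh <- config@nHigh
  n <- nLow + nHigh
  R <- config@nRegions
  pairs <- edgePairs(R)
  p <- nrow(pairs)
  feat <- edgeNames(pairs)

  parc <- canonicalParcellation(R, config@nNetworks)
  netOf <- parc$network

  # planted differential edges with random signed direction
  truthIdx <- sort(sample.int(p, config@nInformative))
  sign <- sample(c(-1, 1), config@nInformative, replace = TRUE)
  delta <- config@effectSize * config@noiseSD

  group <- factor(rep(c("low", "high"), c(nLow, nHigh)),
                  levels = c("low", "high"))
  gshift <- ifelse(group == "high", 0.5, -0.5)

  X <- matrix(rnorm(n * p, sd = config@noiseSD), n, p,
              dimnames = list(NULL, feat))
  for (k in seq_along(truthIdx))
    X[, truthIdx[k]] <- X[, truthIdx[k]] + gshift * sign[k] * delta

  # nuisance covariates, optionally leaking into the features
  age <- truncatedNormal(n, 38, 13, 18, 70)
  sex <- rbinom(n, 1, 0.3)                       # 1 = male
  if (config@covariateConfounding != 0) {
    leak <- config@covariateConfounding *
      (as.vector(scale(age)) + (sex - mean(sex)))
    X <- X + leak
  }

  # cognition: y = Xw + eps, with Var(eps) solved from the realized
  # Var(Xw) so that Var(Xw)/Var(y) equals cognitionR2
  w <- numeric(p); names(w) <- feat
  w[truthIdx] <- sign
  linpred <- as.vector(X %*% w)
  r2 <- config@cognitionR2
  if (r2 > 0 && var(linpred) > 0) {
    sdEps <- sqrt(var(linpred) * (1 - r2) / r2)
  } else {
    linpred <- numeric(n)
    sdEps <- 1
  }
  wltTasks <- c("immediate", "delayed", "slope", "recognition", "retention")
  wlt <- vapply(wltTasks, function(t) {
    y <- linpred + rnorm(n, sd = sdEps)
    10 + 3 * as.vector(scale(y))                  # scaled-score units
  }, numeric(n))
  colnames(wlt) <- paste0("wlt_", wltTasks)

  ph <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    episodes = group,
    hospitalizations = factor(sample(c("never", "more"), n, TRUE),
                              levels = c("never", "more")),
    suicide = factor(sample(c("no", "yes"), n, TRUE),
                     levels = c("no", "yes")),
    psychosis = factor(sample(c("no", "yes"), n, TRUE),
                       levels = c("no", "yes")),
    diagnosis = factor(sample(c("BDI", "BDII", "mixed"), n, TRUE,
                              prob = c(51, 43, 4) / 98),
                       levels = c("BDI", "BDII", "mixed")),
    age = age,
    sex = factor(ifelse(sex == 1, "male", "female"),
                 levels = c("female", "male")),
    ymrs = pmax(0, rnorm(n, 3.2, 4.8)),
    madrs = pmax(0, rnorm(n, 11.5, 10.3)),
    panss = pmax(30, rnorm(n, 41.5, 13)),
    duration = pmax(0.5, rnorm(n, 12, 8)),
    mood_state = factor(sample(c("euthymic", "depressive", "manic",
                                 "mixed"), n, TRUE,
                               prob = c(0.5, 0.3, 0.1, 0.1))),
    med_atypical = rbinom(n, 1, 0.7) == 1,
    med_antidep = rbinom(n, 1, 0.4) == 1,
    med_moodstab = rbinom(n, 1, 0.6) == 1,
    mean_fd = runif(n, 0.03, 0.18),
    stringsAsFactors = FALSE
  )
  ph <- cbind(ph, as.data.frame(wlt))

  info <- DataFrame(feature = feat, kind = "edge",
                    i = pairs[, "i"], j = pairs[, "j"],
                    network_i = netOf[pairs[, "i"]],
                    network_j = netOf[pairs[, "j"]])

  md <- list(
    truth = data.frame(feature = feat[truthIdx], direction = sign,
                       delta = sign * delta, stringsAsFactors = FALSE),
    cognition_weights = w,
    parcellation = parc,
    config = config
  )
  if (morphometry) {
    md$morphometry <- data.frame(
      subject_id = ph$subject_id,
      matrix(c(rnorm(n * R, 5000, 800), rnorm(n * R, 2.5, 0.2)), n, 2 * R,
             dimnames = list(NULL, c(sprintf("volume_%d", seq_len(R)),
                                     sprintf("thickness_%d", seq_len(R))))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }

  FeatureExperiment(X, info, ph, residualized = FALSE, metadata = md)
}

# Region -> network lookup; the eight canonical whole-brain network names
# are used when nNetworks == 8, generic labels otherwise.
canonicalParcellation <- function(R, nNetworks) {
  nets <- if (nNetworks == 8)
    c("MFN", "FPN", "DMN", "SC", "MON", "VisI", "VisII", "VA")
  else sprintf("N%d", seq_len(nNetworks))
  data.frame(region_id = seq_len(R),
             region_name = sprintf("region_%03d", seq_len(R)),
             network = rep_len(nets, R), stringsAsFactors = FALSE)
}

truncatedNormal <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate per-subject ROI time series matching a cohort
#'
#' For each subject, a target correlation matrix is formed by inverting
#' the Fisher transform of the subject's edge features, and a T-by-R
#' Gaussian series with exactly that population correlation is drawn.
#' Sample correlations (and hence Fisher-z features recomputed with
#' [buildFeatures()]) converge to the cohort's feature matrix as T grows.
#'
#' Dense random z-matrices need not be positive definite; `shrink`
#' applies linear shrinkage toward the identity,
#' `C* = (1 - shrink) C + shrink I`, before factorization.
#'
#' @param cohort a [FeatureExperiment-class] whose edge features cover a
#'   full `R x R` connectome.
#' @param tsLength time points per subject; defaults to the generating
#'   configuration's `tsLength` when present, else 192.
#' @param shrink shrinkage weight in `[0, 1)` toward the identity.
#' @param seed RNG seed (`NULL` = current stream).
#' @return Named list of `tsLength x R` matrices, one per subject.
#' @export
generateTimeseries <- function(cohort, tsLength = NULL, shrink = 0,
                               seed = NULL) {
  stopifnot(is(cohort, "FeatureExperiment"))
  info <- featureInfo(cohort)
  edge <- info$kind == "edge"
  if (!any(edge)) stop("cohort has no edge features")
  R <- max(info$j[edge])
  if (sum(edge) != R * (R - 1) / 2)
    stop("edge features do not cover a full connectome")
  if (is.null(tsLength)) {
    cfg <- metadata(cohort)$config
    tsLength <- if (!is.null(cfg)) cfg@tsLength else 192L
  }
  Z <- featureMatrix(cohort)[, which(edge), drop = FALSE]
  ord <- order(info$i[edge] * (R + 1L) + info$j[edge])

  withSeed(seed, {
    out <- lapply(seq_len(nrow(Z)), function(s) {
      C <- devectorizeMatrix(tanh(Z[s, ord]), R)
      diag(C) <- 1
      if (shrink > 0) C <- (1 - shrink) * C + shrink * diag(R)
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch))
        stop("target correlation matrix for subject ", s,
             " is not positive definite; increase 'shrink' ",
             "(linear shrinkage toward the identity)", call. = FALSE)
      matrix(rnorm(tsLength * R), tsLength, R) %*% ch
    })
    names(out) <- rownames(Z)
    out
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `phenotypes.csv`, `features.csv` (subjects x features, first
#' column `subject_id`), `feature_info.csv`, `parcellation.csv` and, for
#' synthetic cohorts, `truth.json`.
#'
#' @param cohort a [FeatureExperiment-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
exportCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "FeatureExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(phenotypes(cohort)),
            file.path(dir, "phenotypes.csv"), row.names = FALSE)
  fm <- data.frame(subject_id = phenotypes(cohort)$subject_id,
                   featureMatrix(cohort), check.names = FALSE)
  write.csv(fm, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(as.data.frame(featureInfo(cohort)),
            file.path(dir, "feature_info.csv"), row.names = FALSE)
  md <- metadata(cohort)
  if (!is.null(md$parcellation))
    write.csv(md$parcellation, file.path(dir, "parcellation.csv"),
              row.names = FALSE)
  if (!is.null(md$truth))
    jsonlite::write_json(md$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
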