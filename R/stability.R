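#' Draw one bootstrap resample of subjects
#'
#' Draws `floor(fraction * n)` subject indices, with replacement by
#' default (so a 90% resample of 98 subjects contains 88 draws).
#'
#' @param n cohort size (>= 1).
#' @param fraction resample size as a proportion of `n` (0 < fraction <= 1).
#' @param replace draw with replacement? (`FALSE` gives subsampling
#'   without replacement; at `fraction = 1` that is a permutation).
#' @param seed RNG seed (`NULL` = current stream).
#' @return Integer vector of subject indices (a multiset when
#'   `replace = TRUE`).
#' @export
bootstrapResample <- function(n, fraction = 0.9, replace = TRUE,
                              seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  m <- max(1L, floor(fraction * n))
  withSeed(seed, sample.int(n, m, replace = replace))
}

#' Bootstrap-aggregated mRMR selection frequencies
#'
#' Repeats `B` times: resample subjects (redrawing, with a log, any
#' resample that loses a class), run [mrmrSelect()] on the resampled rows
#' and count which features enter the top `kPerRun`. The per-feature
#' count over resamples measures selection stability; thresholding it
#' (see [accumulateThresholds()]) yields the candidate feature sets for
#' classification.
#'
#' @param X subjects-by-features matrix or [FeatureExperiment-class].
#' @param y binary labels (or phenotype column name for a
#'   `FeatureExperiment`).
#' @param B number of bootstrap resamples.
#' @param fraction resample fraction, see [bootstrapResample()].
#' @param kPerRun features selected per resample.
#' @param replace resample with replacement?
#' @param scheme,bins discretization, see [discretizeVector()].
#' @param seed RNG seed for the whole run.
#' @return A [SelectionCounts-class].
#' @export
setGeneric("runBootstrapSelection",
  function(X, y, B = 1000, fraction = 0.9, kPerRun = 50, replace = TRUE,
           scheme = "sd3", bins = 4, seed = NULL)
    standardGeneric("runBootstrapSelection"))

#' @rdname runBootstrapSelection
#' @export
setMethod("runBootstrapSelection", "matrix",
  function(X, y, B = 1000, fraction = 0.9, kPerRun = 50, replace = TRUE,
           scheme = "sd3", bins = 4, seed = NULL) {
    y <- checkBinaryY(y)
    if (length(y) != nrow(X)) stop("length(y) must match rows of X")
    kPerRun <- min(kPerRun, ncol(X))
    feat <- colnames(X)
    if (is.null(feat)) feat <- as.character(seq_len(ncol(X)))
    counts <- setNames(integer(ncol(X)), feat)
    redraws <- 0L
    withSeed(seed, {
      for (b in seq_len(B)) {
        repeat {
          idx <- bootstrapResample(nrow(X), fraction, replace)
          if (nlevels(droplevels(y[idx])) == 2) break
          redraws <- redraws + 1L
        }
        sel <- mrmrSelect(X[idx, , drop = FALSE], y[idx], kPerRun,
                          scheme = scheme, bins = bins)
        counts[sel@ranked] <- counts[sel@ranked] + 1L
      }
    })
    if (redraws > 0.1 * B)
      warning(sprintf(paste0(
        "%d of %d resamples redrawn for losing a class; class counts ",
        "are %s -- consider a larger fraction or more balanced labels"),
        redraws, B, paste(table(y), collapse = "/")))
    new("SelectionCounts", counts = counts, B = as.integer(B),
        resampleSize = as.integer(max(1, floor(fraction * nrow(X)))),
        kPerRun = as.integer(kPerRun), fraction = fraction,
        replace = replace, redraws = redraws,
        seed = as.integer(if (is.null(seed)) NA else seed))
  })

#' @rdname runBootstrapSelection
#' @export
setMethod("runBootstrapSelection", "FeatureExperiment",
  function(X, y, B = 1000, fraction = 0.9, kPerRun = 50, replace = TRUE,
           scheme = "sd3", bins = 4, seed = NULL) {
    lab <- colData(X)[[y]]
    if (is.null(lab)) stop("no phenotype column '", y, "'")
    runBootstrapSelection(featureMatrix(X), lab, B = B,
                          fraction = fraction, kPerRun = kPerRun,
                          replace = replace, scheme = scheme, bins = bins,
                          seed = seed)
  })

#' Default selection-count threshold grid
#'
#' Proportions 0.15 to 0.95 in steps of 0.05 of the number of resamples
#' `B`; at `B = 1000` this is the grid 150, 200, ..., 950.
#'
#' @param B number of bootstrap resamples.
#' @param from,to,by proportions of `B`.
#' @return Integer thresholds.
#' @export
defaultThresholds <- function(B, from = 0.15, to = 0.95, by = 0.05) {
  unique(as.integer(round(seq(from, to, by) * B)))
}

#' Accumulate feature sets over count thresholds
#'
#' For each threshold `t`, the accumulated set is every feature selected
#' in strictly more than `t` resamples. Sets are nested and their sizes
#' non-increasing in `t`.
#'
#' @param counts a [SelectionCounts-class].
#' @param thresholds integer thresholds within `0..B`; defaults to
#'   [defaultThresholds()].
#' @return A [ThresholdSweep-class]; `sweepTable()` gives the
#'   size-versus-threshold table.
#' @export
accumulateThresholds <- function(counts, thresholds = NULL) {
  stopifnot(is(counts, "SelectionCounts"))
  if (is.null(thresholds)) thresholds <- defaultThresholds(counts@B)
  thresholds <- sort(unique(as.integer(thresholds)))
  if (any(thresholds < 0) || any(thresholds > counts@B))
    stop("thresholds must lie in 0..B")
  cnt <- counts@counts
  sets <- lapply(thresholds, function(t) names(cnt)[cnt > t])
  new("ThresholdSweep", thresholds = thresholds, sets = sets,
      B = counts@B)
}

#' Restrict a sweep to dimensionality-admissible thresholds
#'
#' To keep the feature count below the sample size seen by the learner
#' (the curse of dimensionality), only thresholds whose accumulated set
#' is no larger than `cap` proceed to classification. The default cap is
#' `floor(2/3 * nSubjects)` — the size of the largest outer-training fold
#' under 3-fold cross-validation.
#'
#' @param sweep a [ThresholdSweep-class].
#' @param nSubjects cohort size entering classification.
#' @param cap optional explicit cap overriding the default.
#' @return The admissible [ThresholdSweep-class] (thresholds whose sets
#'   fit the cap).
#' @export
capByDimensionality <- function(sweep, nSubjects, cap = NULL) {
  stopifnot(is(sweep, "ThresholdSweep"))
  if (is.null(cap)) cap <- floor(2 * nSubjects / 3)
  ok <- lengths(sweep@sets) <= cap
  if (!any(ok))
    stop("no admissible threshold: every accumulated set exceeds ", cap,
         " features; use a higher threshold grid")
  new("ThresholdSweep", thresholds = sweep@thresholds[ok],
      sets = sweep@sets[ok], B = sweep@B)
}
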