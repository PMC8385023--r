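#' Binary classification metrics
#'
#' Accuracy, sensitivity and specificity from hard predictions, and AUC
#' from continuous scores by the rank (Mann-Whitney) formulation, in
#' which tied scores count 1/2.
#'
#' @param yTrue true labels (two classes, both present).
#' @param yPred predicted labels.
#' @param scores continuous decision values, larger meaning more
#'   `positiveClass`.
#' @param positiveClass the label whose detection defines sensitivity.
#' @return Named numeric vector: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
computeMetrics <- function(yTrue, yPred, scores, positiveClass) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (!positiveClass %in% yTrue)
    stop("positive class absent from y_true; sensitivity undefined")
  if (length(unique(yTrue)) < 2)
    stop("only one class present in y_true; specificity undefined")
  pos <- yTrue == positiveClass
  sens <- mean(yPred[pos] == positiveClass)
  spec <- mean(yPred[!pos] != positiveClass)
  r <- rank(scores)
  npos <- sum(pos); nneg <- sum(!pos)
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  c(accuracy = mean(yPred == yTrue), sensitivity = sens,
    specificity = spec, auc = auc)
}

repeatSeed <- function(master, r) (master + 7919L * r) %% 2147483647L

# Orient e1071 decision values so larger means more `positiveClass`.
svmScores <- function(pred, positiveClass) {
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == positiveClass) dv[, 1] else -dv[, 1]
}

#' Repeated nested cross-validated SVM-RBF classification
#'
#' Each repeat draws a stratified outer split (default 3-fold). Within
#' every outer-training fold, mRMR re-ranks the candidate features on the
#' training subjects only and keeps the top `retainFraction`; the SVM-RBF
#' hyperparameters are then tuned by stratified inner cross-validation
#' (default 10-fold) over a cost-by-gamma grid scored by mean inner
#' accuracy (grid ties keep the first grid point). The tuned model is
#' refit on the outer-training fold and evaluated on the held-out fold;
#' metrics are averaged over the outer folds, giving one row per repeat.
#' Inner selection and tuning never touch outer-test rows.
#'
#' The gamma grid is `gammaMult / (p * var)`, with `p` the retained
#' feature count and `var` the overall variance of the training feature
#' values.
#'
#' @param X subjects-by-features matrix (already restricted to one
#'   accumulated feature set) or a [FeatureExperiment-class].
#' @param y binary labels (or a phenotype column name).
#' @param repeats number of repeats.
#' @param outerFolds,innerFolds fold counts; every class needs at least
#'   `outerFolds` members.
#' @param retainFraction fraction of the candidate features the inner
#'   mRMR re-ranking keeps.
#' @param costGrid,gammaMult SVM-RBF tuning grid.
#' @param positiveClass label defining sensitivity (default: the second
#'   factor level).
#' @param scheme,bins discretization for the inner mRMR.
#' @param seed master seed; repeat `r` reseeds deterministically at
#'   `(seed + 7919 r) mod (2^31 - 1)`.
#' @param threshold optional selection-count threshold recorded with the
#'   result.
#' @return A [CVPerformance-class] with the per-repeat metrics and the
#'   per-fold inner-selection log.
#' @export
setGeneric("nestedCV",
  function(X, y, repeats = 100, outerFolds = 3, innerFolds = 10,
           retainFraction = 0.8, costGrid = c(0.01, 0.1, 1, 10, 100),
           gammaMult = c(0.25, 0.5, 1, 2, 4), positiveClass = NULL,
           scheme = "sd3", bins = 4, seed = NULL, threshold = NA)
    standardGeneric("nestedCV"))

#' @rdname nestedCV
#' @export
setMethod("nestedCV", "matrix",
  function(X, y, repeats = 100, outerFolds = 3, innerFolds = 10,
           retainFraction = 0.8, costGrid = c(0.01, 0.1, 1, 10, 100),
           gammaMult = c(0.25, 0.5, 1, 2, 4), positiveClass = NULL,
           scheme = "sd3", bins = 4, seed = NULL, threshold = NA) {
    y <- checkBinaryY(y)
    if (length(y) != nrow(X)) stop("length(y) must match rows of X")
    if (min(table(y)) < outerFolds)
      stop("every class needs at least ", outerFolds,
           " subjects for stratified ", outerFolds, "-fold splits")
    if (is.null(positiveClass)) positiveClass <- levels(y)[2]
    if (!positiveClass %in% levels(y))
      stop("positiveClass '", positiveClass, "' is not a level of y")
    feat <- colnames(X)
    if (is.null(feat)) feat <- as.character(seq_len(ncol(X)))

    rows <- vector("list", repeats)
    log <- vector("list", repeats)
    withSeed(seed, {
      for (r in seq_len(repeats)) {
        if (!is.null(seed)) set.seed(repeatSeed(seed, r))
        fold <- stratifiedFolds(y, outerFolds)
        fm <- matrix(0, outerFolds, 4)
        flog <- vector("list", outerFolds)
        for (f in seq_len(outerFolds)) {
          tr <- which(fold != f); te <- which(fold == f)
          keep <- seq_len(ncol(X))
          if (ncol(X) >= 2 && retainFraction < 1) {
            k <- max(1L, ceiling(retainFraction * ncol(X)))
            keep <- mrmrSelect(X[tr, , drop = FALSE], y[tr], k,
                               scheme = scheme, bins = bins)@ranked
          }
          flog[[f]] <- feat[keep]
          Xtr <- X[tr, keep, drop = FALSE]
          Xte <- X[te, keep, drop = FALSE]
          v <- var(as.vector(Xtr))
          gBase <- if (is.finite(v) && v > 0) 1 / (ncol(Xtr) * v)
                   else 1 / ncol(Xtr)
          ifold <- stratifiedFolds(y[tr], innerFolds)
          best <- c(cost = costGrid[1], gamma = gammaMult[1] * gBase)
          bestAcc <- -1
          for (C in costGrid) for (g in gammaMult * gBase) {
            acc <- 0; used <- 0
            for (k2 in seq_len(innerFolds)) {
              itr <- which(ifold != k2); ite <- which(ifold == k2)
              if (!length(ite) ||
                  nlevels(droplevels(y[tr][itr])) < 2) next
              m <- svm(Xtr[itr, , drop = FALSE], y[tr][itr],
                       kernel = "radial", cost = C, gamma = g,
                       scale = FALSE)
              acc <- acc + mean(predict(m, Xtr[ite, , drop = FALSE]) ==
                                  y[tr][ite])
              used <- used + 1
            }
            acc <- acc / max(used, 1)
            if (acc > bestAcc) {
              bestAcc <- acc
              best <- c(cost = C, gamma = g)
            }
          }
          m <- svm(Xtr, y[tr], kernel = "radial", cost = best["cost"],
                   gamma = best["gamma"], scale = FALSE)
          pred <- predict(m, Xte, decision.values = TRUE)
          fm[f, ] <- computeMetrics(y[te], pred,
                                    svmScores(pred, positiveClass),
                                    positiveClass)
        }
        rows[[r]] <- colMeans(fm)
        log[[r]] <- flog
      }
    })
    per <- as.data.frame(do.call(rbind, rows))
    colnames(per) <- c("accuracy", "sensitivity", "specificity", "auc")
    per <- cbind(rep = seq_len(repeats), per)
    new("CVPerformance", perRepeat = per, positiveClass = positiveClass,
        threshold = as.integer(threshold), selectionLog = log,
        seed = as.integer(if (is.null(seed)) NA else seed))
  })

#' @rdname nestedCV
#' @export
setMethod("nestedCV", "FeatureExperiment",
  function(X, y, repeats = 100, outerFolds = 3, innerFolds = 10,
           retainFraction = 0.8, costGrid = c(0.01, 0.1, 1, 10, 100),
           gammaMult = c(0.25, 0.5, 1, 2, 4), positiveClass = NULL,
           scheme = "sd3", bins = 4, seed = NULL, threshold = NA) {
    lab <- colData(X)[[y]]
    if (is.null(lab)) stop("no phenotype column '", y, "'")
    nestedCV(featureMatrix(X), lab, repeats = repeats,
             outerFolds = outerFolds, innerFolds = innerFolds,
             retainFraction = retainFraction, costGrid = costGrid,
             gammaMult = gammaMult, positiveClass = positiveClass,
             scheme = scheme, bins = bins, seed = seed,
             threshold = threshold)
  })

#' Pick the threshold with the best mean accuracy
#'
#' @param perfs named list of [CVPerformance-class] results, one per
#'   evaluated selection-count threshold (names are the thresholds).
#' @return List with `threshold` (ties resolve to the larger threshold,
#'   i.e. the smaller feature set) and `table`, the per-threshold mean/SD
#'   accuracy table.
#' @export
selectBestThreshold <- function(perfs) {
  if (!length(perfs)) stop("no evaluated thresholds")
  thr <- as.integer(names(perfs))
  if (anyNA(thr)) stop("perfs must be named by integer threshold")
  acc <- vapply(perfs, function(p) mean(p@perRepeat$accuracy), 0)
  sdv <- vapply(perfs, function(p) sd(p@perRepeat$accuracy), 0)
  ord <- order(thr)
  tab <- data.frame(threshold = thr[ord], mean_accuracy = acc[ord],
                    sd_accuracy = sdv[ord], row.names = NULL)
  best <- max(thr[acc == max(acc)])
  list(threshold = best, table = tab)
}

#' Extract major features from a nested-CV selection log
#'
#' A feature counts once per repeat when the inner mRMR retained it in a
#' majority of the outer-training folds (configurable to any or all
#' folds); features with count strictly greater than `minRepeats` form
#' the major-feature set. Each is annotated with the direction of its
#' group difference — positive when the positive class has the higher
#' mean value — and, for connectivity edges, the network pair it
#' connects.
#'
#' @param cv a [CVPerformance-class] holding the selection log (usually
#'   from the best threshold's run).
#' @param X the feature data the log refers to (matrix or
#'   [FeatureExperiment-class]) for the direction computation.
#' @param y binary labels (or phenotype column name).
#' @param minRepeats strict repeat-count threshold (default 90, paired
#'   with 100 repeats; scale it with `repeats`).
#' @param foldRule how fold-level selections aggregate into a repeat.
#' @param info optional per-feature descriptor table (taken from a
#'   `FeatureExperiment` automatically).
#' @return A [MajorFeatureSet-class].
#' @export
majorFeatures <- function(cv, X, y, minRepeats = 90,
                          foldRule = c("majority", "any", "all"),
                          info = NULL) {
  stopifnot(is(cv, "CVPerformance"))
  foldRule <- match.arg(foldRule)
  log <- cv@selectionLog
  if (!length(log) || !length(log[[1]]))
    stop("empty selection log")
  if (is(X, "FeatureExperiment")) {
    if (is.null(info)) info <- as.data.frame(featureInfo(X))
    lab <- colData(X)[[y]]
    if (is.null(lab)) stop("no phenotype column '", y, "'")
    y <- lab
    X <- featureMatrix(X)
  }
  y <- checkBinaryY(y)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  pos <- as.character(y) == cv@positiveClass

  need <- switch(foldRule, majority = function(k, nf) k > nf / 2,
                 any = function(k, nf) k >= 1,
                 all = function(k, nf) k == nf)
  repCount <- table(unlist(lapply(log, function(folds) {
    k <- table(unlist(folds))
    names(k)[need(k, length(folds))]
  })))
  major <- names(repCount)[repCount > minRepeats]
  major <- major[order(match(major, colnames(X)))]

  dirn <- vapply(major, function(f) {
    x <- X[, f]
    as.integer(sign(mean(x[pos]) - mean(x[!pos])))
  }, 0L)
  tab <- data.frame(feature = major,
                    count = as.integer(repCount[major]),
                    direction = dirn, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(info) && all(c("network_i", "network_j") %in%
                            colnames(info))) {
    m <- match(tab$feature, info$feature)
    tab$network_i <- info$network_i[m]
    tab$network_j <- info$network_j[m]
  }
  new("MajorFeatureSet", table = tab,
      minRepeats = as.integer(minRepeats),
      nRepeats = length(log))
}

#' Compare two classifications' per-repeat accuracies
#'
#' Independent-samples pooled-variance t test on the per-repeat accuracy
#' vectors of two [CVPerformance-class] results. Identical constant
#' vectors compare as no difference (`t = 0`, `p = 1`); constant vectors
#' with different means carry no within-group variance to test against
#' and raise an error.
#'
#' @param a,b [CVPerformance-class] objects with at least 2 repeats each.
#' @return List with `statistic` (t), `parameter` (df) and `p.value`.
#' @export
comparePerformance <- function(a, b) {
  stopifnot(is(a, "CVPerformance"), is(b, "CVPerformance"))
  x <- a@perRepeat$accuracy; z <- b@perRepeat$accuracy
  if (length(x) < 2 || length(z) < 2)
    stop("both runs need at least 2 repeats")
  if (sd(x) == 0 && sd(z) == 0) {
    if (mean(x) == mean(z))
      return(list(statistic = 0, parameter = length(x) + length(z) - 2,
                  p.value = 1))
    stop("zero variance in both accuracy vectors")
  }
  ht <- t.test(x, z, var.equal = TRUE)
  list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
       p.value = ht$p.value)
}
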