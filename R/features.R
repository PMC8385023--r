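#' Exclude high-motion subjects
#'
#' Removes subjects whose mean framewise displacement exceeds the
#' threshold; subjects with `mean_fd <= fdThreshold` are kept, matching an
#' exclusion rule stated as "mean FD > threshold removed".
#'
#' @param x a phenotype `data.frame` (column `mean_fd`) or a
#'   [FeatureExperiment-class].
#' @param fdThreshold threshold in millimetres (default 0.2).
#' @return Object of the same class restricted to retained subjects; the
#'   number excluded is reported via `message()`.
#' @export
setGeneric("filterMotion", function(x, fdThreshold = 0.2)
  standardGeneric("filterMotion"))

#' @rdname filterMotion
#' @export
setMethod("filterMotion", "data.frame", function(x, fdThreshold = 0.2) {
  fd <- checkMeanFD(x)
  keep <- fd <= fdThreshold
  message(sum(!keep), " of ", length(keep),
          " subjects excluded for mean FD > ", fdThreshold, " mm")
  x[keep, , drop = FALSE]
})

#' @rdname filterMotion
#' @export
setMethod("filterMotion", "FeatureExperiment", function(x,
                                                        fdThreshold = 0.2) {
  fd <- checkMeanFD(as.data.frame(colData(x)))
  keep <- fd <= fdThreshold
  message(sum(!keep), " of ", length(keep),
          " subjects excluded for mean FD > ", fdThreshold, " mm")
  x[, keep]
})

checkMeanFD <- function(ph) {
  if (!"mean_fd" %in% colnames(ph)) stop("phenotypes lack 'mean_fd'")
  fd <- ph$mean_fd
  if (anyNA(fd)) {
    who <- ph$subject_id[is.na(fd)]
    stop("mean_fd missing for subject(s): ", paste(who, collapse = ", "))
  }
  if (any(fd < 0)) stop("mean_fd must be non-negative")
  fd
}

#' Pearson connectivity matrix of an ROI time series
#'
#' @param ts numeric `T x R` matrix (time points by regions), `T >= 3`.
#' @return Symmetric `R x R` correlation matrix with unit diagonal.
#' @export
connectivityMatrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("constant time series in region(s): ", paste(lab, collapse = ", "))
  }
  cor(ts)
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` beforehand so perfect
#' correlations map to a large finite value.
#'
#' @param r correlations in `[-1, 1]` (vector or matrix).
#' @return Same shape on the z scale.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order — (1,2), (1,3),
#' ..., (1,R), (2,3), ... — yielding `R(R-1)/2` features named
#' `edge_i_j`, each annotated with the network pair of its endpoints.
#'
#' @param mat symmetric `R x R` matrix (asymmetry beyond 1e-8 is an
#'   error).
#' @param parcellation optional data.frame with `region_id`, `network`
#'   (and optionally `region_name`) covering all `R` regions.
#' @return List with `values` (named numeric vector) and `info`
#'   (per-feature descriptor data.frame).
#' @export
vectorizeMatrix <- function(mat, parcellation = NULL) {
  mat <- as.matrix(mat)
  R <- nrow(mat)
  if (ncol(mat) != R) stop("matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8)
    stop("matrix is asymmetric beyond 1e-8")
  pairs <- edgePairs(R)
  vals <- mat[pairs]
  names(vals) <- edgeNames(pairs)
  info <- data.frame(feature = names(vals), kind = "edge",
                     i = pairs[, "i"], j = pairs[, "j"],
                     stringsAsFactors = FALSE)
  if (!is.null(parcellation)) {
    checkParcellation(parcellation, R)
    netOf <- parcellation$network[match(seq_len(R),
                                        parcellation$region_id)]
    info$network_i <- netOf[info$i]
    info$network_j <- netOf[info$j]
  }
  list(values = vals, info = info)
}

#' @describeIn vectorizeMatrix inverse: rebuild the symmetric matrix
#'   (zero diagonal) from a row-major strict-upper-triangle vector.
#' @param values numeric vector of length `R(R-1)/2`.
#' @param R number of regions.
#' @export
devectorizeMatrix <- function(values, R) {
  if (length(values) != R * (R - 1) / 2)
    stop("length of 'values' does not match R(R-1)/2")
  m <- matrix(0, R, R)
  pairs <- edgePairs(R)
  m[pairs] <- values
  m[pairs[, c(2, 1), drop = FALSE]] <- values
  m
}

checkParcellation <- function(parcellation, R = NULL) {
  need <- c("region_id", "network")
  if (!all(need %in% colnames(parcellation)))
    stop("parcellation must have columns region_id and network")
  ids <- sort(parcellation$region_id)
  if (!identical(as.integer(ids), seq_len(length(ids))))
    stop("region ids must be contiguous 1..R")
  if (anyNA(parcellation$network))
    stop("every region needs a network")
  if (!is.null(R) && length(ids) < R)
    stop("parcellation covers ", length(ids), " regions, need ", R)
  invisible(TRUE)
}

#' Build a FeatureExperiment from time series or correlation matrices
#'
#' Runs connectivity (for time series), Fisher r-to-z and vectorization
#' per subject and assembles the feature table row-per-subject.
#'
#' @param data named list (by subject id) of `T x R` time-series matrices
#'   or of `R x R` correlation matrices (`type = "correlation"`).
#' @param phenotypes phenotype data.frame; its `subject_id` order defines
#'   row order and must match `names(data)`.
#' @param parcellation region/network lookup (see [vectorizeMatrix()]).
#' @param type `"timeseries"` (default) or `"correlation"`.
#' @return A [FeatureExperiment-class] (not residualized).
#' @export
buildFeatures <- function(data, phenotypes, parcellation = NULL,
                          type = c("timeseries", "correlation")) {
  type <- match.arg(type)
  if (is.null(names(data)) || !setequal(names(data), phenotypes$subject_id))
    stop("names(data) must match phenotypes$subject_id")
  data <- data[phenotypes$subject_id]
  rows <- lapply(data, function(d) {
    cm <- if (type == "timeseries") connectivityMatrix(d) else as.matrix(d)
    diag(cm) <- 0          # self-connectivity is not a feature
    vectorizeMatrix(fisherZ(cm), parcellation)
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  FeatureExperiment(values, rows[[1]]$info, phenotypes)
}

#' Regress age and sex out of every feature
#'
#' `mode = "whole_sample"` fits one OLS per feature on the full sample and
#' returns its residuals — the whole-sample covariate control that
#' precedes feature selection in the original analysis (a known source of
#' train/test leakage, kept for fidelity). `mode = "fold_safe"` fits the
#' covariate model on training subjects only and applies those
#' coefficients to everyone, for leakage-free workflows.
#'
#' @param x a [FeatureExperiment-class] or a subjects-by-features matrix.
#' @param covariates data.frame with `age` and `sex` (factor or 0/1);
#'   taken from the phenotypes when `x` is a `FeatureExperiment`.
#' @param mode `"whole_sample"` or `"fold_safe"`.
#' @param train integer/logical index of training subjects (required for
#'   `fold_safe`).
#' @return Same class as `x` with residualized values (and, for
#'   `FeatureExperiment`, the `residualized` flag set).
#' @export
setGeneric("residualizeFeatures",
  function(x, covariates = NULL, mode = c("whole_sample", "fold_safe"),
           train = NULL)
    standardGeneric("residualizeFeatures"))

#' @rdname residualizeFeatures
#' @export
setMethod("residualizeFeatures", "matrix",
  function(x, covariates = NULL, mode = c("whole_sample", "fold_safe"),
           train = NULL) {
    mode <- match.arg(mode)
    D <- covariateDesign(covariates, nrow(x))
    fitRows <- if (mode == "whole_sample") seq_len(nrow(x)) else {
      if (is.null(train)) stop("mode 'fold_safe' requires 'train'")
      if (is.logical(train)) which(train) else as.integer(train)
    }
    Dt <- D[fitRows, , drop = FALSE]
    q <- qr(Dt)
    if (q$rank < ncol(Dt)) stop("covariate design is rank deficient")
    beta <- qr.coef(q, x[fitRows, , drop = FALSE])
    x - D %*% beta
  })

#' @rdname residualizeFeatures
#' @export
setMethod("residualizeFeatures", "FeatureExperiment",
  function(x, covariates = NULL, mode = c("whole_sample", "fold_safe"),
           train = NULL) {
    mode <- match.arg(mode)
    ph <- as.data.frame(colData(x))
    res <- residualizeFeatures(featureMatrix(x), ph, mode = mode,
                               train = train)
    out <- x
    assay(out, withDimnames = FALSE) <- t(res)
    out@residualized <- TRUE
    validObject(out)
    out
  })

covariateDesign <- function(covariates, n) {
  if (is.null(covariates) || !all(c("age", "sex") %in% colnames(covariates)))
    stop("covariates must provide 'age' and 'sex'")
  if (nrow(covariates) != n) stop("covariate rows must match subjects")
  if (anyNA(covariates$age) || anyNA(covariates$sex))
    stop("covariates must be complete")
  sex <- covariates$sex
  if (is.factor(sex) || is.character(sex))
    sex <- as.integer(factor(sex)) - 1L
  cbind(intercept = 1, age = as.numeric(covariates$age),
        sex = as.numeric(sex))
}

#' Append z-scored morphometric features
#'
#' Each morphometric column (regional volume or cortical thickness) is
#' z-scored across subjects before concatenation with the connectivity
#' z-values, so both feature kinds enter the common selection pool on a
#' comparable scale.
#'
#' @param x a [FeatureExperiment-class].
#' @param morph data.frame with `subject_id` plus columns named
#'   `volume_<region>` / `thickness_<region>`.
#' @return A [FeatureExperiment-class] with the morph features appended.
#' @export
mergeMorphometry <- function(x, morph) {
  stopifnot(is(x, "FeatureExperiment"))
  if (!"subject_id" %in% colnames(morph)) stop("morph needs 'subject_id'")
  m <- match(phenotypes(x)$subject_id, morph$subject_id)
  if (anyNA(m)) stop("morphometry missing for some subjects")
  vals <- as.matrix(morph[m, setdiff(colnames(morph), "subject_id"),
                          drop = FALSE])
  vals <- scale(vals)
  if (anyNA(vals)) stop("constant or missing morphometric column")
  parts <- strsplit(colnames(vals), "_", fixed = TRUE)
  info <- DataFrame(feature = paste0("morph_", colnames(vals)),
                    kind = "morph",
                    i = NA_integer_, j = NA_integer_,
                    network_i = NA_character_, network_j = NA_character_,
                    measure = vapply(parts, `[`, "", 1L),
                    region = as.integer(vapply(parts, `[`, "", 2L)))
  old <- featureInfo(x)
  for (cn in c("network_i", "network_j"))
    if (!cn %in% colnames(old)) old[[cn]] <- NA_character_
  old$measure <- NA_character_
  old$region <- NA_integer_
  FeatureExperiment(cbind(featureMatrix(x), `colnames<-`(vals, info$feature)),
                    rbind(old[, colnames(info)], info),
                    as.data.frame(phenotypes(x)),
                    residualized = isResidualized(x),
                    metadata = metadata(x))
}

#' Readers for the plain-text interchange formats
#'
#' `readPhenotypes()` reads a phenotype CSV; `readParcellation()` reads
#' and validates a `region_id,region_name,network` CSV;
#' `readTimeseries()` reads one subject's headerless `T x R` TSV;
#' `readFeatureTable()` reads a `features.csv`/`feature_info.csv` pair
#' written by [exportCohort()] back into a [FeatureExperiment-class].
#'
#' @param path file path (for `readFeatureTable`, the directory).
#' @return See each description.
#' @export
readPhenotypes <- function(path) {
  ph <- read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% colnames(ph)) stop("phenotype CSV lacks subject_id")
  ph
}

#' @rdname readPhenotypes
#' @export
readParcellation <- function(path) {
  parc <- read.csv(path, stringsAsFactors = FALSE)
  checkParcellation(parc)
  parc
}

#' @rdname readPhenotypes
#' @export
readTimeseries <- function(path) {
  as.matrix(read.csv(path, sep = "\t", header = FALSE))
}

#' @rdname readPhenotypes
#' @export
readFeatureTable <- function(path) {
  ph <- readPhenotypes(file.path(path, "phenotypes.csv"))
  fm <- read.csv(file.path(path, "features.csv"), check.names = FALSE)
  info <- read.csv(file.path(path, "feature_info.csv"),
                   stringsAsFactors = FALSE)
  vals <- as.matrix(fm[, setdiff(colnames(fm), "subject_id"),
                       drop = FALSE])
  if (!identical(fm$subject_id, ph$subject_id))
    stop("subject order differs between features.csv and phenotypes.csv")
  FeatureExperiment(vals, info, ph)
}
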