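#' FeatureExperiment: subjects-by-features container
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with features (connectivity
#' edges on the Fisher-z scale, or z-scored morphometric measures) as rows
#' and subjects as columns; phenotypes live in `colData` and per-feature
#' descriptors (`kind`, edge endpoints `i < j`, network pair, or
#' morphometric region/measure) in `rowData`.
#'
#' @slot residualized logical; `TRUE` once age/sex effects have been
#'   regressed out of every feature.
#' @export
setClass("FeatureExperiment",
  contains = "SummarizedExperiment",
  slots = c(residualized = "logical"),
  prototype = prototype(residualized = FALSE)
)

setValidity("FeatureExperiment", function(object) {
  msg <- character()
  if (length(object@residualized) != 1L)
    msg <- c(msg, "'residualized' must be a single logical")
  if (nrow(object) > 0L) {
    a <- assay(object)
    if (anyNA(a))
      msg <- c(msg, "feature values contain NA/NaN")
    rd <- rowData(object)
    if (!all(c("feature", "kind") %in% colnames(rd)))
      msg <- c(msg, "rowData must contain 'feature' and 'kind' columns")
    else {
      edge <- rd$kind == "edge"
      if (any(edge)) {
        i <- rd$i[edge]; j <- rd$j[edge]
        if (anyNA(i) || anyNA(j) || any(i >= j) || any(i < 1L))
          msg <- c(msg, "edge descriptors must satisfy 1 <= i < j")
      }
    }
  }
  if (ncol(object) > 0L) {
    ph <- colData(object)
    if (!"subject_id" %in% colnames(ph))
      msg <- c(msg, "colData must contain 'subject_id'")
    else if (anyDuplicated(ph$subject_id))
      msg <- c(msg, "subject_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureExperiment
#'
#' @param values numeric matrix, subjects in rows and features in columns
#'   (the natural orientation of a feature table; it is transposed into the
#'   assay so the container follows the features-by-subjects convention).
#' @param info data.frame/DataFrame of per-feature descriptors with at
#'   least columns `feature` (unique id) and `kind` (`"edge"` or
#'   `"morph"`); edges carry `i`, `j`, `network_i`, `network_j`.
#' @param phenotypes data.frame with one row per subject, containing at
#'   least `subject_id`.
#' @param residualized logical flag, see [residualizeFeatures()].
#' @param metadata optional list stored as container metadata.
#' @return A [FeatureExperiment-class] object.
#' @export
FeatureExperiment <- function(values, info, phenotypes,
                              residualized = FALSE, metadata = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  info <- DataFrame(info)
  phenotypes <- DataFrame(phenotypes, check.names = FALSE)
  if (nrow(info) != ncol(values))
    stop("'info' must describe exactly one row per feature column")
  if (nrow(phenotypes) != nrow(values))
    stop("'phenotypes' must have one row per subject row of 'values'")
  a <- t(values)
  rownames(a) <- info$feature
  colnames(a) <- phenotypes$subject_id
  se <- SummarizedExperiment(assays = list(z = a), rowData = info,
                             colData = phenotypes, metadata = metadata)
  new("FeatureExperiment", se, residualized = isTRUE(residualized))
}

#' @describeIn FeatureExperiment feature values as a subjects-by-features
#'   matrix (rows named by subject id, columns by feature id).
#' @param x a `FeatureExperiment`.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "FeatureExperiment"))
  t(assay(x))
}

#' @describeIn FeatureExperiment per-feature descriptor table.
#' @export
featureInfo <- function(x) {
  stopifnot(is(x, "FeatureExperiment"))
  rowData(x)
}

#' @describeIn FeatureExperiment phenotype table (one row per subject).
#' @export
phenotypes <- function(x) {
  stopifnot(is(x, "FeatureExperiment"))
  colData(x)
}

#' @describeIn FeatureExperiment has age/sex residualization been applied?
#' @export
isResidualized <- function(x) {
  stopifnot(is(x, "FeatureExperiment"))
  x@residualized
}

#' @describeIn FeatureExperiment planted truth of a synthetic cohort
#'   (`NULL` for real data): data.frame of informative feature ids with
#'   signed direction.
#' @export
plantedTruth <- function(x) metadata(x)$truth

#' @describeIn FeatureExperiment per-feature cognition weights of a
#'   synthetic cohort (`NULL` for real data).
#' @export
cognitionWeights <- function(x) metadata(x)$cognition_weights

setMethod("show", "FeatureExperiment", function(object) {
  cat("FeatureExperiment:", ncol(object), "subjects x", nrow(object),
      "features\n")
  kinds <- table(rowData(object)$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n")
  cat("  residualized:", object@residualized, "\n")
  if (!is.null(metadata(object)$truth))
    cat("  synthetic cohort with", nrow(metadata(object)$truth),
        "planted features\n")
})

# ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the
#' study design the pipeline targets: two clinically defined subgroups of
#' 43 and 55 subjects, a connectome parcellated into regions grouped into
#' eight networks, a small set of edges whose Fisher-z connectivity
#' differs between the groups, age/sex nuisance structure, and verbal
#' memory scores linearly driven by the differential edges.
#'
#' @slot nLow,nHigh subjects in the fewer/more-occurrences groups.
#' @slot nRegions,nNetworks parcellation size (default 30 regions for
#'   desk-scale runs; use 268 for full-scale).
#' @slot nInformative number of planted differential edges.
#' @slot effectSize standardized group mean difference (Cohen's d) of each
#'   planted edge on the residual z-scale.
#' @slot covariateConfounding coefficient with which standardized age and
#'   centred sex leak into every feature.
#' @slot cognitionR2 proportion of cognition variance carried by the
#'   planted edges (0 <= R2 < 1).
#' @slot noiseSD within-group SD of each feature on the z-scale.
#' @slot tsLength time points per subject when generating time series.
#' @slot seed RNG seed; the cohort is a deterministic function of the
#'   configuration.
#' @export
setClass("SynthConfig", slots = c(
  nLow = "integer", nHigh = "integer", nRegions = "integer",
  nNetworks = "integer", nInformative = "integer",
  effectSize = "numeric", covariateConfounding = "numeric",
  cognitionR2 = "numeric", noiseSD = "numeric",
  tsLength = "integer", seed = "integer"
))

setValidity("SynthConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msg <- character()
  for (f in c("nLow", "nHigh", "nRegions", "nNetworks", "nInformative",
              "tsLength")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msg <- c(msg, bad(f, "must be a single count >= 1"))
  }
  if (!length(msg)) {
    maxEdges <- object@nRegions * (object@nRegions - 1L) / 2
    if (object@nInformative > maxEdges)
      msg <- c(msg, bad("nInformative",
                        sprintf("exceeds %d possible edges", maxEdges)))
  }
  if (is.na(object@effectSize) || object@effectSize < 0)
    msg <- c(msg, bad("effectSize", "must be >= 0"))
  if (is.na(object@cognitionR2) || object@cognitionR2 < 0 ||
      object@cognitionR2 >= 1)
    msg <- c(msg, bad("cognitionR2", "must be in [0, 1)"))
  if (is.na(object@noiseSD) || object@noiseSD <= 0)
    msg <- c(msg, bad("noiseSD", "must be > 0"))
  if (length(msg)) msg else TRUE
})

#' @describeIn SynthConfig constructor with study-design defaults.
#' @param nLow,nHigh,nRegions,nNetworks,nInformative,effectSize,covariateConfounding,cognitionR2,noiseSD,tsLength,seed
#'   see the corresponding slots.
#' @export
synthConfig <- function(nLow = 43, nHigh = 55, nRegions = 30,
                        nNetworks = 8, nInformative = 10,
                        effectSize = 1.5, covariateConfounding = 0,
                        cognitionR2 = 0.6, noiseSD = 0.25,
                        tsLength = 192, seed = 1) {
  new("SynthConfig", nLow = as.integer(nLow), nHigh = as.integer(nHigh),
      nRegions = as.integer(nRegions), nNetworks = as.integer(nNetworks),
      nInformative = as.integer(nInformative),
      effectSize = as.numeric(effectSize),
      covariateConfounding = as.numeric(covariateConfounding),
      cognitionR2 = as.numeric(cognitionR2), noiseSD = as.numeric(noiseSD),
      tsLength = as.integer(tsLength), seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0(
    "SynthConfig: %d + %d subjects, %d regions / %d networks\n",
    "  %d informative edges at d = %.2f (noise SD %.2f), confounding %.2f\n",
    "  cognition R2 = %.2f, T = %d, seed = %d\n"),
    object@nLow, object@nHigh, object@nRegions, object@nNetworks,
    object@nInformative, object@effectSize, object@noiseSD,
    object@covariateConfounding, object@cognitionR2, object@tsLength,
    object@seed))
})

# ---------------------------------------------------------------------------

#' Result of one mRMR ranking
#'
#' @slot ranked integer column indices in selection order.
#' @slot features character feature ids in selection order.
#' @slot scores data.frame with per-step relevance `V` (bits), redundancy
#'   `W` (mean MI against the already-selected set, bits; `NA` at step 1)
#'   and their quotient `MIQ`.
#' @export
setClass("SelectionResult", slots = c(
  ranked = "integer", features = "character", scores = "data.frame"
))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (anyDuplicated(object@ranked))
    msg <- c(msg, "ranked indices contain duplicates")
  if (length(object@features) != length(object@ranked))
    msg <- c(msg, "features and ranked differ in length")
  if (nrow(object@scores) != length(object@ranked))
    msg <- c(msg, "scores must have one row per selected feature")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@ranked), "features ranked\n")
  print(head(object@scores, 5))
  if (nrow(object@scores) > 5) cat("  ...\n")
})

#' @describeIn SelectionResult feature ids in selection order.
#' @param x a `SelectionResult`.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@features
}

#' @describeIn SelectionResult per-step V/W/MIQ score table.
#' @export
selectionScores <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@scores
}

# ---------------------------------------------------------------------------

#' Bootstrap selection frequencies
#'
#' @slot counts named integer vector: for each feature, the number of
#'   bootstrap resamples in which mRMR selected it (0..B).
#' @slot B number of bootstrap resamples.
#' @slot resampleSize subjects drawn per resample.
#' @slot kPerRun features selected per resample.
#' @slot fraction resample fraction of the cohort.
#' @slot replace with replacement?
#' @slot redraws resamples redrawn because a class was lost.
#' @slot seed RNG seed.
#' @export
setClass("SelectionCounts", slots = c(
  counts = "integer", B = "integer", resampleSize = "integer",
  kPerRun = "integer", fraction = "numeric", replace = "logical",
  redraws = "integer", seed = "integer"
))

setValidity("SelectionCounts", function(object) {
  msg <- character()
  if (any(object@counts < 0L) || any(object@counts > object@B))
    msg <- c(msg, "counts must lie in 0..B")
  if (is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by feature")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionCounts", function(object) {
  cat(sprintf(
    "SelectionCounts: %d features, B = %d resamples of %d subjects (K = %d)\n",
    length(object@counts), object@B, object@resampleSize, object@kPerRun))
  cat("  count range:", min(object@counts), "-", max(object@counts),
      "; redraws:", object@redraws, "\n")
})

#' @describeIn SelectionCounts named per-feature selection counts.
#' @param x a `SelectionCounts`.
#' @export
selectionCounts <- function(x) {
  stopifnot(is(x, "SelectionCounts"))
  x@counts
}

# ---------------------------------------------------------------------------

#' Threshold sweep over selection counts
#'
#' For each count threshold t, the accumulated feature set
#' \{features selected in more than t resamples\} (strict >). Sets are
#' nested and sizes non-increasing in t.
#'
#' @slot thresholds ordered integer thresholds.
#' @slot sets list of character vectors, one accumulated set per threshold.
#' @slot B number of resamples behind the counts.
#' @export
setClass("ThresholdSweep", slots = c(
  thresholds = "integer", sets = "list", B = "integer"
))

setValidity("ThresholdSweep", function(object) {
  msg <- character()
  if (length(object@sets) != length(object@thresholds))
    msg <- c(msg, "one accumulated set required per threshold")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msg <- c(msg, "thresholds must be strictly increasing")
  sizes <- lengths(object@sets)
  if (any(diff(sizes) > 0L))
    msg <- c(msg, "set sizes must be non-increasing in the threshold")
  if (length(object@sets) > 1L)
    for (k in seq_len(length(object@sets) - 1L))
      if (!all(object@sets[[k + 1L]] %in% object@sets[[k]])) {
        msg <- c(msg, "accumulated sets must be nested")
        break
      }
  if (length(msg)) msg else TRUE
})

#' @describeIn ThresholdSweep table of set size against threshold.
#' @param x a `ThresholdSweep`.
#' @export
sweepTable <- function(x) {
  stopifnot(is(x, "ThresholdSweep"))
  data.frame(threshold = x@thresholds, n_features = lengths(x@sets))
}

#' @describeIn ThresholdSweep accumulated feature set at one threshold.
#' @param threshold one of the sweep's thresholds.
#' @export
accumulatedSet <- function(x, threshold) {
  stopifnot(is(x, "ThresholdSweep"))
  k <- match(as.integer(threshold), x@thresholds)
  if (is.na(k)) stop("threshold ", threshold, " not in the sweep")
  x@sets[[k]]
}

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep over B =", object@B, "resamples\n")
  print(sweepTable(object), row.names = FALSE)
})

# ---------------------------------------------------------------------------

#' Repeated nested-CV classification performance
#'
#' @slot perRepeat data.frame with one row per repeat: accuracy,
#'   sensitivity, specificity and AUC averaged over the outer folds.
#' @slot positiveClass label treated as positive for sensitivity.
#' @slot threshold selection-count threshold whose accumulated feature set
#'   was classified (NA when not applicable).
#' @slot selectionLog list (per repeat) of lists (per outer fold) of the
#'   feature ids the inner mRMR re-ranking retained.
#' @slot seed master seed of the repeat loop.
#' @export
setClass("CVPerformance", slots = c(
  perRepeat = "data.frame", positiveClass = "character",
  threshold = "integer", selectionLog = "list", seed = "integer"
))

setValidity("CVPerformance", function(object) {
  msg <- character()
  need <- c("accuracy", "sensitivity", "specificity", "auc")
  if (!all(need %in% colnames(object@perRepeat)))
    msg <- c(msg, "perRepeat must contain accuracy/sensitivity/specificity/auc")
  else {
    m <- as.matrix(object@perRepeat[, need])
    if (any(m < 0 | m > 1, na.rm = TRUE))
      msg <- c(msg, "metrics must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CVPerformance mean and SD of each metric over repeats.
#' @param x a `CVPerformance`.
#' @export
performanceSummary <- function(x) {
  stopifnot(is(x, "CVPerformance"))
  need <- c("accuracy", "sensitivity", "specificity", "auc")
  data.frame(metric = need,
             mean = vapply(need, function(m) mean(x@perRepeat[[m]]), 0),
             sd = vapply(need, function(m) sd(x@perRepeat[[m]]), 0),
             row.names = NULL)
}

#' @describeIn CVPerformance per-repeat metric table.
#' @export
performanceByRepeat <- function(x) {
  stopifnot(is(x, "CVPerformance"))
  x@perRepeat
}

setMethod("show", "CVPerformance", function(object) {
  cat(sprintf("CVPerformance: %d repeats (positive class '%s'%s)\n",
              nrow(object@perRepeat), object@positiveClass,
              if (is.na(object@threshold)) ""
              else sprintf(", threshold %d", object@threshold)))
  s <- performanceSummary(object)
  cat(sprintf("  %s = %.3f +/- %.3f\n", s$metric, s$mean, s$sd), sep = "")
})

# ---------------------------------------------------------------------------

#' Major features of a classification
#'
#' Features re-selected in more than `minRepeats` of the nested-CV repeats
#' (strict >), with the direction of the group difference and the network
#' pair they connect.
#'
#' @slot table data.frame: feature, repeat count, direction (+1 when the
#'   positive class has the higher residualized mean), network pair.
#' @slot minRepeats the strict repeat-count threshold applied.
#' @slot nRepeats repeats available in the log.
#' @export
setClass("MajorFeatureSet", slots = c(
  table = "data.frame", minRepeats = "integer", nRepeats = "integer"
))

setMethod("show", "MajorFeatureSet", function(object) {
  cat(sprintf("MajorFeatureSet: %d features selected > %d of %d repeats\n",
              nrow(object@table), object@minRepeats, object@nRepeats))
  if (nrow(object@table)) print(head(object@table, 10), row.names = FALSE)
})

#' @describeIn MajorFeatureSet the major-feature table.
#' @param x a `MajorFeatureSet`.
#' @export
majorFeatureTable <- function(x) {
  stopifnot(is(x, "MajorFeatureSet"))
  x@table
}
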