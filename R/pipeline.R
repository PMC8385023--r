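#' Assemble and validate a pipeline configuration
#'
#' A single validated configuration drives [runPipeline()] end to end.
#' Either `synth` (a [SynthConfig-class]) or `inputDir` (a directory in
#' the [exportCohort()] layout) supplies the cohort.
#'
#' @param synth [SynthConfig-class] for synthetic cohorts, or `NULL`.
#' @param inputDir directory with `phenotypes.csv` / `features.csv` /
#'   `feature_info.csv`, or `NULL`.
#' @param label phenotype column defining the two subgroups.
#' @param classLevels optional pair of label levels to keep (subjects
#'   with other levels — e.g. a mixed phenotype under a diagnosis split —
#'   are excluded).
#' @param positiveClass label level defining sensitivity (default: the
#'   second retained level).
#' @param fdThreshold mean-FD exclusion threshold in mm.
#' @param residualMode `"whole_sample"` (whole-sample age/sex control) or
#'   `"fold_safe"`; see [residualizeFeatures()].
#' @param B,fraction,kPerRun,replace bootstrap-selection parameters, see
#'   [runBootstrapSelection()].
#' @param thresholds selection-count thresholds (`NULL` =
#'   [defaultThresholds()]).
#' @param repeats,outerFolds,innerFolds,retainFraction,costGrid,gammaMult
#'   nested-CV parameters, see [nestedCV()].
#' @param minRepeatsFraction major-feature rule: a feature is major when
#'   its repeat count strictly exceeds `round(minRepeatsFraction *
#'   repeats)`.
#' @param fdrLevel FDR level reported alongside the q values.
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @param outDir output directory (`NULL` = no files written).
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(synth = synthConfig(), inputDir = NULL,
                           label = "episodes", classLevels = NULL,
                           positiveClass = NULL, fdThreshold = 0.2,
                           residualMode = c("whole_sample", "fold_safe"),
                           B = 1000, fraction = 0.9, kPerRun = 50,
                           replace = TRUE, thresholds = NULL,
                           repeats = 100, outerFolds = 3,
                           innerFolds = 10, retainFraction = 0.8,
                           costGrid = c(0.01, 0.1, 1, 10, 100),
                           gammaMult = c(0.25, 0.5, 1, 2, 4),
                           minRepeatsFraction = 0.9, fdrLevel = 0.05,
                           seed = 1, outDir = NULL) {
  residualMode <- match.arg(residualMode)
  if (is.null(synth) && is.null(inputDir))
    stop("provide either 'synth' or 'inputDir'")
  if (!is.null(synth)) {
    stopifnot(is(synth, "SynthConfig"))
    validObject(synth)
  }
  stopifnot(B >= 1, fraction > 0, fraction <= 1, kPerRun >= 1,
            repeats >= 1, outerFolds >= 2, innerFolds >= 2,
            retainFraction > 0, retainFraction <= 1,
            minRepeatsFraction >= 0, minRepeatsFraction <= 1,
            fdrLevel > 0, fdrLevel < 1)
  if (!is.null(classLevels) && length(classLevels) != 2)
    stop("classLevels must name exactly two levels")
  cfg <- list(synth = synth, inputDir = inputDir, label = label,
              classLevels = classLevels, positiveClass = positiveClass,
              fdThreshold = fdThreshold, residualMode = residualMode,
              B = as.integer(B), fraction = fraction,
              kPerRun = as.integer(kPerRun), replace = replace,
              thresholds = thresholds, repeats = as.integer(repeats),
              outerFolds = as.integer(outerFolds),
              innerFolds = as.integer(innerFolds),
              retainFraction = retainFraction, costGrid = costGrid,
              gammaMult = gammaMult,
              minRepeatsFraction = minRepeatsFraction,
              fdrLevel = fdrLevel, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

configAsList <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$synth)) {
    s <- out$synth
    out$synth <- sapply(slotNames(s), function(f) slot(s, f),
                        simplify = FALSE)
  }
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Accepts the structure written into the run manifest, so a manifest
#' round-trips into an identical run.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$config)) raw <- raw$config   # accept a manifest
  if (!is.null(raw$synth)) raw$synth <- do.call(synthConfig, raw$synth)
  raw <- raw[intersect(names(raw), names(formals(pipelineConfig)))]
  do.call(pipelineConfig, raw)
}

#' Run the full subtype-classification pipeline
#'
#' Executes, in order: cohort acquisition (synthetic or from disk),
#' motion QC, age/sex residualization, bootstrap-aggregated mRMR
#' selection, threshold sweep with the dimensionality cap, repeated
#' nested-CV SVM classification of every admissible threshold set (sets
#' need at least 2 features), best-threshold choice, major-feature
#' extraction, cognition regression on the best accumulated set,
#' confound screening of the repeatedly selected features, and the
#' demographic comparison. All stages draw their seeds deterministically
#' from the master seed, so a rerun with the same configuration is
#' identical. When `outDir` is set, each stage writes a CSV/JSON artifact
#' stamped with the manifest hash; on a stage failure the partial
#' outputs of this run are removed and the error names the stage.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, a list with the cohort, counts, sweep, admissible
#'   sweep, per-threshold performances, best-threshold choice, major
#'   features, regression/confound/demographic tables and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  written <- character(0)
  manifest <- list(package = "connstab",
                   version = as.character(packageVersion("connstab")),
                   config = configAsList(config))
  # the hash identifies the scientific configuration, not where it is run
  hashed <- manifest$config[setdiff(names(manifest$config), "outDir")]
  hash <- fnv1a(jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA))
  manifest$hash <- hash

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    if (is.null(config$outDir)) return(invisible(NULL))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$outDir, file)
    con <- file(path, "w")
    writeLines(paste0("# connstab run ", hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    invisible(path)
  }

  cohort <- stage("cohort", {
    if (!is.null(config$synth)) {
      s <- config$synth
      s@seed <- subSeed(config$seed, "synth")
      generateCohort(s)
    } else readFeatureTable(config$inputDir)
  })

  cohort <- stage("motion_qc", filterMotion(cohort, config$fdThreshold))
  cohort <- stage("residualize",
                  residualizeFeatures(cohort, mode = config$residualMode))

  lab <- colData(cohort)[[config$label]]
  if (is.null(lab)) stop("pipeline stage 'labels' failed: no column '",
                         config$label, "'")
  lab <- factor(lab)
  keepLv <- config$classLevels
  if (is.null(keepLv)) keepLv <- levels(droplevels(lab))
  if (length(keepLv) != 2)
    stop("pipeline stage 'labels' failed: label '", config$label,
         "' has levels ", paste(levels(droplevels(lab)), collapse = "/"),
         "; give 'classLevels' to pick two")
  keep <- !is.na(lab) & lab %in% keepLv
  cohort <- cohort[, keep]
  y <- factor(as.character(lab[keep]), levels = keepLv)
  positiveClass <- if (is.null(config$positiveClass)) keepLv[2]
                   else config$positiveClass
  X <- featureMatrix(cohort)
  emit(as.data.frame(phenotypes(cohort)), "phenotypes.csv")

  counts <- stage("bootstrap_selection",
    runBootstrapSelection(X, y, B = config$B, fraction = config$fraction,
                          kPerRun = config$kPerRun,
                          replace = config$replace,
                          seed = subSeed(config$seed, "bootstrap")))
  emit(data.frame(feature = names(selectionCounts(counts)),
                  count = selectionCounts(counts)), "counts.csv")

  sweep <- stage("threshold_sweep",
                 accumulateThresholds(counts, config$thresholds))
  emit(sweepTable(sweep), "sweep.csv")
  admissible <- stage("dimensionality_cap",
                      capByDimensionality(sweep, ncol(cohort)))

  evalThr <- admissible@thresholds[lengths(admissible@sets) >= 2]
  if (!length(evalThr))
    stop("pipeline stage 'classification' failed: no admissible ",
         "threshold set has >= 2 features")
  perfs <- stage("classification", {
    out <- lapply(seq_along(evalThr), function(k) {
      set <- accumulatedSet(admissible, evalThr[k])
      nestedCV(X[, set, drop = FALSE], y, repeats = config$repeats,
               outerFolds = config$outerFolds,
               innerFolds = config$innerFolds,
               retainFraction = config$retainFraction,
               costGrid = config$costGrid, gammaMult = config$gammaMult,
               positiveClass = positiveClass,
               seed = subSeed(config$seed, "cv") + k,
               threshold = evalThr[k])
    })
    names(out) <- evalThr
    out
  })
  best <- stage("best_threshold", selectBestThreshold(perfs))
  emit(best$table, "performance_by_threshold.csv")
  emit(performanceByRepeat(perfs[[as.character(best$threshold)]]),
       "per_repeat_performance.csv")

  minRep <- round(config$minRepeatsFraction * config$repeats)
  major <- stage("major_features",
    majorFeatures(perfs[[as.character(best$threshold)]], X, y,
                  minRepeats = minRep,
                  info = as.data.frame(featureInfo(cohort))))
  emit(majorFeatureTable(major), "major_features.csv")

  bestSet <- accumulatedSet(admissible, best$threshold)
  regression <- stage("cognition_regression", {
    if (any(grepl("^wlt_", colnames(colData(cohort)))) &&
        length(bestSet) < ncol(cohort) - 1)
      regressCognition(cohort, bestSet)
    else NULL
  })
  if (!is.null(regression)) emit(regression, "cognition_regression.csv")

  screenSet <- if (nrow(majorFeatureTable(major)))
    majorFeatureTable(major)$feature else bestSet
  confounds <- stage("confound_screen",
                     tryCatch(confoundScreen(cohort, screenSet),
                              error = function(e) NULL))
  if (!is.null(confounds)) emit(confounds, "confounds.csv")

  demographics <- stage("demographics",
    groupCompareDemographics(cbind(as.data.frame(phenotypes(cohort)),
                                   .group = y), ".group"))
  emit(demographics, "demographics.csv")

  if (!is.null(config$outDir)) {
    path <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, path)
  }

  invisible(list(cohort = cohort, counts = counts, sweep = sweep,
                 admissible = admissible, performances = perfs,
                 best = best, majorFeatures = major,
                 regression = regression, confounds = confounds,
                 demographics = demographics, manifest = manifest))
}
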