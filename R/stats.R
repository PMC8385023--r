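#' Benjamini-Hochberg q values
#'
#' Step-up FDR adjustment with monotonicity enforcement (the classic BH
#' procedure, as implemented by [stats::p.adjust()]).
#'
#' @param p p values in `[0, 1]`.
#' @return q values, same length.
#' @export
fdrBH <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Regress cognition scores on selected features
#'
#' One multiple linear regression per verbal-memory task: the task's
#' scaled score on all selected features jointly, reporting the
#' proportion of variance explained (R-squared), the overall-F p value
#' and its BH q value across the tasks of the family. Rows with a
#' missing score are dropped per task (complete-case) and the retained n
#' reported.
#'
#' @param x a [FeatureExperiment-class] or subjects-by-features matrix.
#' @param features character vector of feature ids to use as predictors
#'   (e.g. an accumulated set or the major features).
#' @param scores for a `FeatureExperiment`, the phenotype column names of
#'   the tasks (default: all `wlt_*` columns); for a matrix, a named list
#'   or data.frame of score vectors.
#' @return data.frame with one row per task: `outcome`, `r2`,
#'   `f_statistic`, `p`, `q`, `n`, `p_features`.
#' @export
regressCognition <- function(x, features, scores = NULL) {
  if (is(x, "FeatureExperiment")) {
    ph <- as.data.frame(colData(x))
    if (is.null(scores))
      scores <- grep("^wlt_", colnames(ph), value = TRUE)
    sc <- ph[, scores, drop = FALSE]
    X <- featureMatrix(x)
  } else {
    X <- x
    if (is.null(scores)) stop("matrix input requires 'scores'")
    sc <- as.data.frame(scores)
  }
  miss <- setdiff(features, colnames(X))
  if (length(miss))
    stop("unknown feature(s): ", paste(head(miss, 3), collapse = ", "))
  Xf <- X[, features, drop = FALSE]
  p <- ncol(Xf)

  rows <- lapply(colnames(sc), function(task) {
    yv <- sc[[task]]
    ok <- complete.cases(yv) & complete.cases(Xf)
    if (sum(!ok))
      message(sum(!ok), " subjects dropped for missing '", task, "'")
    n <- sum(ok)
    if (n <= p + 1)
      stop("n = ", n, " subjects cannot support ", p,
           " features: need n > p + 1 (dimensionality cap)")
    fit <- lm(yv[ok] ~ Xf[ok, , drop = FALSE])
    sm <- summary(fit)
    fp <- unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE))
    data.frame(outcome = task, r2 = sm$r.squared,
               f_statistic = unname(sm$fstatistic[1]), p = fp,
               n = n, p_features = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdrBH(out$p)
  out[, c("outcome", "r2", "f_statistic", "p", "q", "n", "p_features")]
}

#' Screen selected features against clinical confounders
#'
#' For every (feature, clinical variable) pair: Pearson correlation for
#' continuous variables (illness duration, symptom scores), a
#' pooled-variance two-sample t test for binary medication flags, and a
#' one-way ANOVA across mood states. q values are BH-adjusted within
#' each variable's family (across the features of the screened set).
#' Binary variables with a degenerate split and categorical levels with
#' fewer than 2 subjects are dropped with a warning.
#'
#' @param x a [FeatureExperiment-class].
#' @param features feature ids to screen (e.g. the major features).
#' @param continuous,binary,categorical phenotype column names per
#'   statistic family; defaults follow the cohort schema of
#'   [generateCohort()].
#' @return `ConfoundReport` data.frame: `variable`, `feature`, `method`,
#'   `statistic`, `p`, `q`.
#' @export
confoundScreen <- function(x, features,
                           continuous = c("duration", "ymrs", "madrs",
                                          "panss"),
                           binary = c("med_atypical", "med_antidep",
                                      "med_moodstab"),
                           categorical = "mood_state") {
  stopifnot(is(x, "FeatureExperiment"))
  ph <- as.data.frame(colData(x))
  X <- featureMatrix(x)[, features, drop = FALSE]

  one <- function(variable, method) {
    v <- ph[[variable]]
    if (is.null(v)) {
      warning("phenotype column '", variable, "' missing; skipped")
      return(NULL)
    }
    stat <- vapply(features, function(f) {
      xf <- X[, f]
      if (method == "pearson_r") {
        ht <- cor.test(xf, v)
        c(unname(ht$estimate), ht$p.value)
      } else if (method == "t") {
        g <- droplevels(factor(v))
        if (nlevels(g) < 2 || min(table(g)) < 2)
          return(c(NA_real_, NA_real_))
        ht <- t.test(xf ~ g, var.equal = TRUE)
        c(unname(ht$statistic), ht$p.value)
      } else {
        g <- droplevels(factor(v))
        small <- names(which(table(g) < 2))
        if (length(small)) {
          g[g %in% small] <- NA
          g <- droplevels(g)
        }
        if (nlevels(g) < 2) return(c(NA_real_, NA_real_))
        sm <- anova(aov(xf[!is.na(g)] ~ g[!is.na(g)]))
        c(sm$`F value`[1], sm$`Pr(>F)`[1])
      }
    }, numeric(2))
    if (all(is.na(stat[2, ]))) {
      warning("'", variable, "' is degenerate (single level); test skipped")
      return(NULL)
    }
    pvec <- stat[2, ]
    qvec <- rep(NA_real_, length(pvec))
    qvec[!is.na(pvec)] <- fdrBH(pvec[!is.na(pvec)])
    data.frame(variable = variable, feature = features, method = method,
               statistic = stat[1, ], p = pvec, q = qvec,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  out <- c(lapply(continuous, one, method = "pearson_r"),
           lapply(binary, one, method = "t"),
           lapply(categorical, one, method = "F"))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("no testable clinical variables")
  rownames(out) <- NULL
  out
}

#' Pooled-variance t test from group summaries
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes.
#' @return List with `statistic`, `parameter` (df) and `p.value`.
#' @export
pooledTTest <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, parameter = df, p.value = 2 * pt(-abs(t), df))
}

#' Chi-square test on a 2x2 count table, no continuity correction
#'
#' @param counts 2x2 matrix of counts (groups in rows).
#' @return List with `statistic`, `parameter` and `p.value`.
#' @export
chisqNoCorrection <- function(counts) {
  ht <- chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Demographic comparison of two subgroups
#'
#' Compares the two levels of a subgroup label: pooled-variance
#' two-sample t tests for continuous variables (reported as mean and SD
#' per group) and a chi-square test without continuity correction for
#' sex. Variables missing from the table are omitted with a warning.
#' Summary statistics printed in a report can be checked directly with
#' [pooledTTest()] and [chisqNoCorrection()]; on raw data this function
#' reproduces those summary-based results exactly.
#'
#' @param phenotypes phenotype data.frame (or
#'   [FeatureExperiment-class]).
#' @param label subgroup column name (two levels after dropping unused).
#' @param continuous continuous variable names to compare.
#' @param sexColumn name of the sex column (`NULL` to skip).
#' @return data.frame with one row per variable: group summaries, test
#'   statistic and p value.
#' @export
groupCompareDemographics <- function(phenotypes, label,
                                     continuous = c("age", "ymrs",
                                                    "madrs", "panss"),
                                     sexColumn = "sex") {
  if (is(phenotypes, "FeatureExperiment"))
    phenotypes <- as.data.frame(colData(phenotypes))
  g <- droplevels(factor(phenotypes[[label]]))
  if (nlevels(g) != 2)
    stop("label '", label, "' must have exactly two levels (got ",
         nlevels(g), ")")
  keep <- !is.na(g)
  lv <- levels(g)

  rows <- list()
  for (v in continuous) {
    x <- phenotypes[[v]]
    if (is.null(x)) {
      warning("variable '", v, "' missing; omitted")
      next
    }
    x1 <- x[keep & g == lv[1]]; x2 <- x[keep & g == lv[2]]
    ht <- pooledTTest(mean(x1), sd(x1), length(x1),
                      mean(x2), sd(x2), length(x2))
    rows[[v]] <- data.frame(
      variable = v, test = "pooled_t",
      group1 = sprintf("%.2f +/- %.3f (n=%d)", mean(x1), sd(x1),
                       length(x1)),
      group2 = sprintf("%.2f +/- %.3f (n=%d)", mean(x2), sd(x2),
                       length(x2)),
      statistic = ht$statistic, p = ht$p.value, stringsAsFactors = FALSE)
  }
  if (!is.null(sexColumn)) {
    sx <- phenotypes[[sexColumn]]
    if (is.null(sx)) {
      warning("variable '", sexColumn, "' missing; omitted")
    } else {
      tab <- table(g[keep], factor(sx[keep]))
      ht <- chisqNoCorrection(as.matrix(unclass(tab)))
      rows[[sexColumn]] <- data.frame(
        variable = sexColumn, test = "chisq",
        group1 = paste(tab[1, ], collapse = "/"),
        group2 = paste(tab[2, ], collapse = "/"),
        statistic = ht$statistic, p = ht$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
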