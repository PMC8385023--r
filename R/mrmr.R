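#' Discretize a numeric vector into states
#'
#' `"sd3"` (the default used throughout selection) assigns three states
#' by cut points at the mean plus/minus one SD: `-1` when
#' `x <= mean - sd`, `+1` when `x >= mean + sd`, `0` otherwise.
#' `"quantile"` assigns `bins` equal-frequency states. Constant vectors
#' map to a single state.
#'
#' @param x finite numeric vector.
#' @param scheme `"sd3"` or `"quantile"`.
#' @param bins number of equal-frequency bins for `"quantile"`.
#' @return Integer state vector (`{-1, 0, 1}` for sd3, `1..bins` for
#'   quantile).
#' @export
discretizeVector <- function(x, scheme = c("sd3", "quantile"), bins = 4) {
  scheme <- match.arg(scheme)
  if (!all(is.finite(x))) stop("values must be finite")
  if (scheme == "sd3") {
    s <- sd(x)
    if (is.na(s) || s == 0) return(rep(0L, length(x)))
    m <- mean(x)
    st <- integer(length(x))
    st[x <= m - s] <- -1L
    st[x >= m + s] <- 1L
    st
  } else {
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(qs) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = qs, include.lowest = TRUE))
  }
}

#' @describeIn discretizeVector column-wise discretization of a
#'   subjects-by-features matrix.
#' @param X numeric matrix (subjects in rows).
#' @export
discretizeFeatures <- function(X, scheme = c("sd3", "quantile"),
                               bins = 4) {
  scheme <- match.arg(scheme)
  apply(X, 2, discretizeVector, scheme = scheme, bins = bins)
}

#' Plug-in mutual information between two discrete vectors
#'
#' `I(a; b) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the observed
#' joint table; zero-count cells contribute 0. Reported in bits;
#' non-negative.
#'
#' @param a,b equal-length vectors of discrete states (integers or
#'   factors).
#' @return Mutual information in bits.
#' @export
mutualInformation <- function(a, b) {
  if (length(a) != length(b)) stop("state vectors differ in length")
  if (length(a) == 0) stop("state vectors must be non-empty")
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  ok <- pj > 0
  max(0, sum(pj[ok] * log2(pj[ok] / outer(pa, pb)[ok])))
}

# 0-based recode of a discretized matrix for the C++ kernel.
recodeStates <- function(S) {
  S <- apply(S, 2, function(col) {
    u <- sort(unique(col))
    match(col, u) - 1L
  })
  storage.mode(S) <- "integer"
  list(states = S, nstates = apply(S, 2, max) + 1L)
}

checkBinaryY <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("response has a single class; need both classes present")
  droplevels(y)
}

#' Greedy mRMR feature ranking by mutual information quotient
#'
#' Ranks features by the minimum-redundancy maximum-relevance criterion:
#' the first feature maximizes relevance `V` (mutual information with the
#' response); each subsequent step maximizes `MIQ = V / W`, where `W` is
#' the mean mutual information between the candidate and the features
#' already selected. Candidates with `W = 0` rank above all finite
#' quotients, ordered by `V`; remaining ties break toward the lower
#' feature index. Mutual information is the plug-in estimate on
#' discretized states (see [discretizeVector()]).
#'
#' @param X subjects-by-features numeric matrix, or a
#'   [FeatureExperiment-class].
#' @param y binary response (factor/vector for matrices; the name of a
#'   phenotype column for a `FeatureExperiment`).
#' @param K number of features to rank (capped at the pool size).
#' @param scheme,bins discretization, see [discretizeVector()].
#' @return A [SelectionResult-class].
#' @export
setGeneric("mrmrSelect", function(X, y, K, scheme = "sd3", bins = 4)
  standardGeneric("mrmrSelect"))

#' @rdname mrmrSelect
#' @export
setMethod("mrmrSelect", "matrix", function(X, y, K, scheme = "sd3",
                                           bins = 4) {
  if (ncol(X) < 2) stop("need at least 2 features")
  if (K < 1) stop("K must be >= 1")
  y <- checkBinaryY(y)
  if (length(y) != nrow(X)) stop("length(y) must match rows of X")
  S <- discretizeFeatures(X, scheme = scheme, bins = bins)
  rec <- if (scheme == "sd3") {
    S <- S + 1L                       # {-1,0,1} -> 0..2, fixed state count
    storage.mode(S) <- "integer"
    list(states = S, nstates = rep(3L, ncol(S)))
  } else recodeStates(S)
  ys <- as.integer(y) - 1L
  res <- cpp_mrmr_select(rec$states, rec$nstates, ys, nlevels(y),
                         as.integer(min(K, ncol(X))))
  feat <- colnames(X)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(X)))
  new("SelectionResult", ranked = res$order,
      features = feat[res$order],
      scores = data.frame(step = seq_along(res$order),
                          feature = feat[res$order], V = res$V,
                          W = res$W, MIQ = res$MIQ))
})

#' @rdname mrmrSelect
#' @export
setMethod("mrmrSelect", "FeatureExperiment",
  function(X, y, K, scheme = "sd3", bins = 4) {
    lab <- colData(X)[[y]]
    if (is.null(lab)) stop("no phenotype column '", y, "'")
    mrmrSelect(featureMatrix(X), lab, K, scheme = scheme, bins = bins)
  })

#' Brute-force mRMR oracle
#'
#' Literal re-evaluation of the MIQ criterion: at every step all mutual
#' informations against the response and against each already-selected
#' feature are recomputed from scratch in R, with no caching or
#' incremental updates. Identical contract to [mrmrSelect()]; intended as
#' an independent correctness oracle for small pools.
#'
#' @inheritParams mrmrSelect
#' @param X subjects-by-features numeric matrix with at most 15 columns.
#' @return A [SelectionResult-class].
#' @export
mrmrBruteOracle <- function(X, y, K, scheme = "sd3", bins = 4) {
  if (ncol(X) > 15) stop("oracle refuses pools larger than 15 features")
  if (ncol(X) < 2) stop("need at least 2 features")
  if (K < 1) stop("K must be >= 1")
  y <- checkBinaryY(y)
  S <- discretizeFeatures(X, scheme = scheme, bins = bins)
  ys <- as.integer(y) - 1L
  K <- min(K, ncol(X))
  feat <- colnames(X)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(X)))

  mi12 <- function(a, b) round(mutualInformation(a, b), 12)
  selected <- integer(0)
  scores <- data.frame(step = integer(0), feature = character(0),
                       V = numeric(0), W = numeric(0), MIQ = numeric(0))
  for (step in seq_len(K)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    V <- vapply(cand, function(j) mi12(S[, j], ys), 0)
    if (step == 1) {
      pick <- cand[which.max(V)]
      scores <- rbind(scores, data.frame(
        step = step, feature = feat[pick], V = V[match(pick, cand)],
        W = NA_real_, MIQ = NA_real_))
    } else {
      W <- vapply(cand, function(j) {
        round(sum(vapply(selected, function(s) mi12(S[, j], S[, s]), 0)) /
                length(selected), 12)
      }, 0)
      inf <- W <= 0
      score <- ifelse(inf, NA, round(V / W, 9))
      pickIdx <- if (any(inf)) which(inf)[which.max(V[inf])]
                 else which.max(score)
      pick <- cand[pickIdx]
      scores <- rbind(scores, data.frame(
        step = step, feature = feat[pick], V = V[pickIdx], W = W[pickIdx],
        MIQ = if (inf[pickIdx]) Inf else score[pickIdx]))
    }
    selected <- c(selected, pick)
  }
  new("SelectionResult", ranked = as.integer(selected),
      features = feat[selected], scores = scores)
}
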