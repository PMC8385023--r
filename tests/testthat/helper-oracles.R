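# Independent oracles and tiny fixtures shared across test files.

# Literal Benjamini-Hochberg step-up: for each p_i, the minimum over all
# j with p_(j) >= p_i of p_(j) * m / j, capped at 1. Naive double loop on
# sorted values; no reliance on p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Plug-in mutual information straight from the definition, iterating over
# explicit value pairs (independent of table()/C++ routes).
miOracle <- function(a, b) {
  n <- length(a)
  tot <- 0
  for (va in unique(a)) for (vb in unique(b)) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0)
      tot <- tot + pab * log2(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  tot
}

# Small two-group feature matrix with one perfect and some noise features.
noiseCohort <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  list(X = X, y = y)
}

# Fabricate a CVPerformance with given per-repeat accuracies (and an
# optional selection log), for testing downstream operations in isolation.
fakePerformance <- function(acc, log = list(), positive = "high",
                            threshold = NA) {
  per <- data.frame(rep = seq_along(acc), accuracy = acc,
                    sensitivity = acc, specificity = acc, auc = acc)
  new("CVPerformance", perRepeat = per, positiveClass = positive,
      threshold = as.integer(threshold), selectionLog = log,
      seed = NA_integer_)
}

fakeCounts <- function(counts, B) {
  new("SelectionCounts",
      counts = stats::setNames(as.integer(counts), names(counts)),
      B = as.integer(B), resampleSize = 10L, kPerRun = 5L,
      fraction = 0.9, replace = TRUE, redraws = 0L, seed = NA_integer_)
}
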