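# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the current RNG stream untouched).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One master seed fans out to named per-stage sub-seeds (documented
# counter scheme); kept below 2^31 - 1.
subSeed <- function(master, stage) {
  offsets <- c(synth = 1L, timeseries = 2L, bootstrap = 3L, cv = 4L,
               null = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage '", stage, "'")
  (as.integer(master) + 99991L * offsets[[stage]]) %% 2147483647L
}

# Strict-upper-triangle edge enumeration, row-major: (1,2), (1,3), ...,
# (1,R), (2,3), ...  This ordering is the package-wide contract for
# vectorized connectivity features.
edgePairs <- function(R) {
  stopifnot(R >= 2)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R),
              use.names = FALSE)
  cbind(i = i, j = j)
}

edgeNames <- function(pairs) sprintf("edge_%d_%d", pairs[, "i"], pairs[, "j"])

# 31-bit polynomial rolling hash of a character scalar; used to stamp
# run manifests (all intermediates stay exactly representable).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Stratified k-fold assignment: returns an integer fold id per observation.
# Each class is shuffled and dealt round-robin, so fold class counts differ
# by at most one; with n >= k per class every fold contains every class.
stratifiedFolds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
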