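# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pearson p-values for a matrix of correlation coefficients computed on n
# observations (two-sided t test on the r -> t transform).
cor_pvals <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

# Row-wise k nearest neighbor indices (self excluded) from a dense distance
# matrix; always returns an n x k matrix, also for k = 1.
knn_indices <- function(dd, k) {
  n <- nrow(dd)
  m <- vapply(seq_len(n), function(i) order(dd[i, ])[2:(k + 1)], integer(k))
  if (k == 1) matrix(m, ncol = 1) else t(m)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
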