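# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic entry points route through this so that no
# function leaves a footprint on the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Row-major linear neuron index (1-based, row 1 / col 1 at top-left).
neuron_index <- function(row, col, n_cols) {
  (as.integer(row) - 1L) * as.integer(n_cols) + as.integer(col)
}

# Inverse of neuron_index(): matrix with columns row, col.
neuron_rowcol <- function(index, n_cols) {
  index <- as.integer(index)
  cbind(row = (index - 1L) %/% n_cols + 1L,
        col = (index - 1L) %% n_cols + 1L)
}

# Squared Euclidean distances between the rows of x (n x p) and the rows of
# y (m x p), returned as an n x m matrix. Negative round-off is clamped.
rowwise_dist2 <- function(x, y) {
  d2 <- matrix(rowSums(x * x), nrow(x), nrow(y)) +
    matrix(rowSums(y * y), nrow(x), nrow(y), byrow = TRUE) -
    2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# Deterministic per-stage seed derived from the master seed and a stage name,
# so adding stages never shifts the streams of existing ones.
stage_seed <- function(master_seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
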