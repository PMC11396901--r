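#' Pairwise sample correlation map
#'
#' Pearson correlation between the samples' metagene vectors (the portrait
#' columns). Blocks of high correlation correspond to groups of samples
#' with similar expression landscapes.
#'
#' @param model A `som_model`.
#' @return Symmetric `n_samples x n_samples` correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation_map <- function(model) {
  stopifnot(inherits(model, "som_model"))
  sds <- apply(model$metagenes, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance metagene vector for sample(s): ",
         paste(colnames(model$metagenes)[sds == 0], collapse = ", "))
  stats::cor(model$metagenes)
}

#' Select a sample cluster count by silhouette
#'
#' Average-linkage hierarchical clustering on the correlation distance
#' `1 - r`; `k` is chosen from `k_range` by the maximum mean silhouette
#' width (ties to the smaller k). When the distances are degenerate
#' (essentially all-zero, so silhouettes are undefined), the smallest k in
#' the range is returned as a documented fallback.
#'
#' @param correlation Correlation matrix from [sample_correlation_map()].
#' @param k_range Candidate cluster counts, within `[2, n_samples - 1]`.
#' @return List with `k`, `labels` (named integer vector) and `silhouette`
#'   (mean width per candidate k).
#' @export
cluster_count <- function(correlation, k_range = 2:6) {
  n <- nrow(correlation)
  if (n < 3) stop("need at least 3 samples to cluster")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n_samples - 1]")
  d <- stats::as.dist(1 - correlation)
  hc <- stats::hclust(d, method = "average")
  if (max(d) < 1e-8) {
    k <- min(k_range)
    return(list(k = k,
                labels = stats::setNames(stats::cutree(hc, k),
                                         rownames(correlation)),
                silhouette = stats::setNames(rep(NA_real_, length(k_range)),
                                             k_range)))
  }
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  k <- k_range[which.max(sil)]
  list(k = k,
       labels = stats::setNames(stats::cutree(hc, k), rownames(correlation)),
       silhouette = stats::setNames(sil, k_range))
}

# Symmetric orthogonalization (W W^T)^(-1/2) W.
sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# Fixed-point negentropy ICA (symmetric decorrelation, tanh contrast) on an
# already-whitened n x k matrix Z. Deterministic given the seed.
fast_ica <- function(Z, seed, max_iter = 1000, tol = 1e-10) {
  k <- ncol(Z)
  n <- nrow(Z)
  W <- sym_orth(with_seed(seed, matrix(stats::rnorm(k * k), k, k)))
  for (it in seq_len(max_iter)) {
    S <- Z %*% t(W)
    G <- tanh(S)
    W1 <- sym_orth(crossprod(G, Z) / n -
                     diag(colMeans(1 - G^2), k) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Independent component coordinates of the samples
#'
#' Each sample is represented by its metagene vector; the sample cloud is
#' centered, whitened to `k` principal dimensions and unmixed by
#' fixed-point negentropy ICA (tanh contrast, symmetric decorrelation).
#' Because ICA is order- and sign-ambiguous, components are ordered by
#' descending explained variance of their back-projection into metagene
#' space and oriented so the largest-magnitude score is positive. When
#' metadata is supplied, each component is matched to the design factor
#' (cultivar, condition or timepoint) with which its scores correlate most
#' strongly (point-biserial for the two-level factors, Spearman against day
#' for timepoint).
#'
#' @param model A `som_model`.
#' @param k Number of components (must not exceed the sample-cloud rank).
#' @param seed Integer seed for the ICA starting point.
#' @param metadata Optional sample metadata for factor matching.
#' @return List with `ic_coords` (`n_samples x k`, columns IC1..ICk),
#'   `explained` (variance of each back-projection), `whitened` (the
#'   whitened sample matrix) and `unmixing` (the orthonormal unmixing
#'   matrix, so `ic_coords == whitened %*% t(unmixing)`), and — when
#'   metadata is given — `factor_match` (data frame: component, factor, r).
#' @export
independent_components <- function(model, k = 3, seed = 1, metadata = NULL) {
  stopifnot(inherits(model, "som_model"))
  X <- t(model$metagenes)           # samples x neurons
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = min(n, k + 5), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the data rank (", rank, ")")
  Z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n - 1)
  W <- fast_ica(Z, seed = seed)
  S <- Z %*% t(W)
  # mixing back to metagene space for explained-variance ordering
  M <- solve(crossprod(S), crossprod(S, Xc))
  expl <- rowSums(M^2)
  ord <- order(expl, decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]
  expl <- expl[ord]
  for (i in seq_len(k)) {
    j <- which.max(abs(S[, i]))
    if (S[j, i] < 0) {
      S[, i] <- -S[, i]
      W[i, ] <- -W[i, ]
    }
  }
  dimnames(S) <- list(rownames(X), paste0("IC", seq_len(k)))
  out <- list(ic_coords = S, explained = stats::setNames(expl, colnames(S)),
              whitened = Z, unmixing = W)
  if (!is.null(metadata)) {
    md <- metadata[match(rownames(X), metadata$sample_id), , drop = FALSE]
    out$factor_match <- match_factors(S, md)
  }
  out
}

# Best-correlated design factor per component: point-biserial r for binary
# factors, Spearman against the day value (or timepoint rank) otherwise.
match_factors <- function(scores, metadata) {
  factors <- list(
    cultivar = as.numeric(factor(metadata$cultivar)),
    condition = as.numeric(factor(metadata$condition)),
    timepoint = if (!is.null(metadata$day) && !anyNA(metadata$day))
      metadata$day else as.numeric(factor(metadata$timepoint)))
  do.call(rbind, lapply(colnames(scores), function(comp) {
    rs <- vapply(names(factors), function(f) {
      v <- factors[[f]]
      if (stats::sd(v) == 0) return(0)
      if (f == "timepoint")
        stats::cor(scores[, comp], v, method = "spearman")
      else stats::cor(scores[, comp], v)
    }, numeric(1))
    best <- which.max(abs(rs))
    data.frame(component = comp, factor = names(factors)[best],
               r = unname(rs[best]), stringsAsFactors = FALSE)
  }))
}

#' Second-level sample SOM
#'
#' Trains a small batch SOM on the samples' metagene vectors (samples as
#' data points) and reports each sample's best-matching cell, projecting
#' the sample-similarity structure onto a two-dimensional grid.
#'
#' @param model A `som_model`.
#' @param grid_rows,grid_cols Lattice size of the second-level map
#'   (default 10 x 10; more than 40 x 40 draws a warning).
#' @param n_epochs Batch epochs for the small map.
#' @param seed Integer seed (random init of the second-level map).
#' @return Data frame with `sample_id`, `row`, `col` and the linear `cell`
#'   index.
#' @export
sample_som <- function(model, grid_rows = 10, grid_cols = 10, n_epochs = 30,
                       seed = 1) {
  stopifnot(inherits(model, "som_model"))
  if (grid_rows > 40 || grid_cols > 40)
    warning("sample SOM grid larger than 40 x 40 is rarely useful")
  X <- t(model$metagenes)
  Xc <- sweep(X, 2, colMeans(X))
  cfg <- som_config(rows = grid_rows, cols = grid_cols, n_epochs = n_epochs,
                    radius_start = max(grid_rows, grid_cols) / 2,
                    radius_end = 0.5, init = "random", seed = seed)
  fit <- batch_som(Xc, cfg)
  rc <- neuron_rowcol(fit$assignment, grid_cols)
  data.frame(sample_id = rownames(X), row = rc[, "row"], col = rc[, "col"],
             cell = fit$assignment, stringsAsFactors = FALSE)
}
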