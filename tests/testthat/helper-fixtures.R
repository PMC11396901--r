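# Shared fixtures, all generated in code.

# Small planted-module dataset: full 36-sample design, 6 modules of
# `per_module` genes plus background, suitable for fast end-to-end tests.
small_synth <- function(per_module = 40, n_genes = 6 * per_module + 400,
                        noise_sd = 0.2, seed = 1) {
  design <- generate_design()
  gen <- generate_expression(design, n_genes = n_genes,
                             archetypes = default_archetypes(per_module),
                             noise_sd = noise_sd, seed = seed)
  list(design = design, expression = gen$expression, truth = gen$truth)
}

# A small trained model on the small synthetic data (memoized per session).
small_model_cache <- new.env(parent = emptyenv())
small_trained <- function() {
  if (is.null(small_model_cache$fit)) {
    syn <- small_synth()
    expr <- center_genes(syn$expression)
    model <- train_som(expr, som_config(rows = 10, cols = 10, n_epochs = 30,
                                        seed = 1))
    small_model_cache$fit <- list(syn = syn, expr = expr, model = model)
  }
  small_model_cache$fit
}

# Random centered expression matrix.
random_centered <- function(n_genes = 50, n_samples = 8, seed = 42) {
  v <- with_seed_test(seed, matrix(rnorm(n_genes * n_samples), n_genes,
                                   n_samples))
  dimnames(v) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  center_genes(expression_matrix(v))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Hand-built som_model for tests that need full control of the metagenes.
manual_model <- function(metagenes, rows, cols, assignment = NULL) {
  stopifnot(nrow(metagenes) == rows * cols)
  if (is.null(assignment))
    assignment <- stats::setNames(integer(0), character(0))
  cfg <- structure(list(rows = as.integer(rows), cols = as.integer(cols),
                        n_epochs = 1L, radius_start = 1, radius_end = 0.5,
                        init = "pca_plane", seed = 1L),
                   class = "som_config")
  structure(list(config = cfg,
                 metagenes = metagenes,
                 assignment = assignment,
                 error_trace = numeric(0)),
            class = "som_model")
}

# Brute-force 8-neighborhood flood fill, used as the segmentation oracle.
flood_components <- function(fg_index, n_rows, n_cols) {
  remaining <- sort(fg_index)
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      if (!(cur %in% remaining)) next
      remaining <- setdiff(remaining, cur)
      comp <- c(comp, cur)
      r <- (cur - 1) %/% n_cols + 1
      c <- (cur - 1) %% n_cols + 1
      for (dr in -1:1) for (dc in -1:1) {
        nr <- r + dr; nc <- c + dc
        if ((dr | dc) && nr >= 1 && nr <= n_rows && nc >= 1 && nc <= n_cols) {
          nb <- (nr - 1) * n_cols + nc
          if (nb %in% remaining) queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Exact hypergeometric upper tail by combinatorial enumeration (independent
# of phyper): P[X >= k] = sum_j C(K,j) C(N-K,n-j) / C(N,n).
hyper_tail_enum <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
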