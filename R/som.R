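#' SOM training configuration
#'
#' Parameters for the batch self-organizing map. The lattice defaults to
#' 40 x 40 = 1600 neurons (metagenes). Training is batch-mode with a
#' Gaussian neighborhood whose radius decays linearly from `radius_start`
#' (default half the larger lattice side) to `radius_end` over `n_epochs`
#' epochs; the batch rule makes the result deterministic given the
#' initialization.
#'
#' @param rows,cols Lattice dimensions; `rows * cols >= 4`.
#' @param n_epochs Number of batch epochs.
#' @param radius_start,radius_end Gaussian neighborhood radii in lattice
#'   units; `radius_start >= radius_end > 0`.
#' @param init `"pca_plane"` (metagenes seeded on the plane of the first two
#'   principal axes of the gene cloud, which fixes the map orientation) or
#'   `"random"` (i.i.d. N(0, 0.1^2) entries drawn with `seed`).
#' @param seed Integer seed (used by `"random"` init only; `"pca_plane"` is
#'   already deterministic).
#' @return An object of class `som_config`.
#' @export
som_config <- function(rows = 40, cols = 40, n_epochs = 50,
                       radius_start = max(rows, cols) / 2,
                       radius_end = 0.5,
                       init = c("pca_plane", "random"),
                       seed = 1) {
  init <- match.arg(init)
  if (rows * cols < 2) stop("lattice needs at least 2 neurons")
  if (!(radius_start >= radius_end && radius_end > 0))
    stop("need radius_start >= radius_end > 0")
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_epochs = as.integer(n_epochs),
                 radius_start = radius_start, radius_end = radius_end,
                 init = init, seed = as.integer(seed)),
            class = "som_config")
}

# Batch-SOM workhorse on a plain data matrix (points in rows). Returns
# metagenes (n_neurons x p), 1-based row-major BMU assignment and the
# per-epoch quantization-error trace (measured after each epoch's update).
batch_som <- function(x, config) {
  m <- config$rows * config$cols
  n <- nrow(x)
  p <- ncol(x)
  grid <- neuron_rowcol(seq_len(m), config$cols)
  lat2 <- rowwise_dist2(grid, grid)

  M <- if (config$init == "pca_plane") {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sv <- svd(xc, nu = 0, nv = min(2, p))
    v1 <- sv$v[, 1]
    if (v1[which.max(abs(v1))] < 0) v1 <- -v1
    v2 <- if (ncol(sv$v) >= 2) sv$v[, 2] else rep(0, p)
    if (any(v2 != 0) && v2[which.max(abs(v2))] < 0) v2 <- -v2
    s1 <- if (nrow(xc) > 1) stats::sd(xc %*% v1) else 0
    s2 <- if (nrow(xc) > 1 && any(v2 != 0)) stats::sd(xc %*% v2) else 0
    if (!is.finite(s1)) s1 <- 0
    if (!is.finite(s2)) s2 <- 0
    a <- if (config$cols > 1) seq(-1, 1, length.out = config$cols) else 0
    b <- if (config$rows > 1) seq(-1, 1, length.out = config$rows) else 0
    matrix(mu, m, p, byrow = TRUE) +
      outer(a[grid[, "col"]] * s1, v1) +
      outer(b[grid[, "row"]] * s2, v2)
  } else {
    with_seed(config$seed, matrix(stats::rnorm(m * p, sd = 0.1), m, p))
  }

  trace <- numeric(config$n_epochs)
  d2 <- rowwise_dist2(x, M)
  bmu <- max.col(-d2, ties.method = "first")
  for (e in seq_len(config$n_epochs)) {
    r <- if (config$n_epochs == 1) config$radius_end else
      config$radius_start +
        (config$radius_end - config$radius_start) * (e - 1) / (config$n_epochs - 1)
    H <- exp(-lat2 / (2 * r * r))
    sums <- rowsum(x, group = bmu)
    A <- matrix(0, m, p)
    A[as.integer(rownames(sums)), ] <- sums
    cnt <- tabulate(bmu, nbins = m)
    num <- H %*% A
    den <- drop(H %*% cnt)
    upd <- den > 1e-300
    M[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    d2 <- rowwise_dist2(x, M)
    bmu <- max.col(-d2, ties.method = "first")
    trace[e] <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
  }
  list(metagenes = M, assignment = bmu, error_trace = trace)
}

#' Train the metagene SOM
#'
#' Distributes the genes of a centered expression matrix over the neuron
#' lattice: each neuron's metagene is the neighborhood-weighted mean profile
#' of the genes it collects, and each gene is assigned to its best matching
#' unit (Euclidean-nearest metagene, ties to the lowest row-major index).
#' Neurons left without genes keep their neighborhood-smoothed metagene and
#' simply carry an empty gene list.
#'
#' @param x A gene-centered `expression_matrix` with at least 2 samples.
#' @param config A `som_config`.
#' @return An object of class `som_model`: `config`, `metagenes`
#'   (`n_neurons x n_samples`, sample IDs as colnames), `assignment` (named
#'   integer vector, gene to 1-based row-major neuron index) and
#'   `error_trace` (mean gene-to-metagene distance per epoch).
#' @export
train_som <- function(x, config = som_config()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(config, "som_config"))
  if (!x$centered) stop("train_som() expects a gene-centered matrix; run center_genes()")
  if (ncol(x$values) < 2) stop("need at least 2 samples")
  if (config$rows * config$cols < 4)
    stop("the metagene lattice needs at least 4 neurons")
  fit <- batch_som(x$values, config)
  colnames(fit$metagenes) <- colnames(x$values)
  structure(list(config = config,
                 metagenes = fit$metagenes,
                 assignment = stats::setNames(fit$assignment, rownames(x$values)),
                 error_trace = fit$error_trace),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d lattice, %d genes, %d samples, final QE %.4g\n",
              x$config$rows, x$config$cols, length(x$assignment),
              ncol(x$metagenes), utils::tail(x$error_trace, 1)))
  invisible(x)
}

#' Best matching unit of a profile
#'
#' @param model A `som_model`.
#' @param profile Numeric vector of length `n_samples`.
#' @return The 1-based row-major index of the Euclidean-nearest metagene
#'   (ties resolved to the lowest index).
#' @export
best_matching_unit <- function(model, profile) {
  stopifnot(inherits(model, "som_model"))
  if (length(profile) != ncol(model$metagenes))
    stop("profile length ", length(profile), " != number of samples ",
         ncol(model$metagenes))
  d2 <- rowSums(sweep(model$metagenes, 2, profile)^2)
  which.min(d2)
}

#' Mean quantization error of a model on a matrix
#'
#' Mean Euclidean distance between each gene's profile and its assigned
#' metagene — the SOM training diagnostic.
#'
#' @param model A `som_model`.
#' @param x An `expression_matrix` (or plain matrix with matching rownames)
#'   over the model's samples.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, x) {
  v <- if (inherits(x, "expression_matrix")) x$values else x
  if (ncol(v) != ncol(model$metagenes)) stop("sample dimension mismatch")
  genes <- rownames(v)
  if (is.null(genes) || !all(genes %in% names(model$assignment)))
    stop("matrix genes do not match the model's assignment table")
  mg <- model$metagenes[model$assignment[genes], , drop = FALSE]
  mean(sqrt(rowSums((v - mg)^2)))
}

#' Save or restore a SOM model archive
#'
#' The archive is a directory with a documented plain-text layout:
#' `config.json`, `metagenes.tsv` (neurons in rows, row-major order),
#' `assignment.tsv` (gene, neuron, row, col) and `error_trace.tsv`.
#'
#' @param model A `som_model`.
#' @param path Directory to create or read.
#' @return `som_save` returns `path` invisibly; `som_load` the restored
#'   `som_model`.
#' @export
som_save <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  mg <- model$metagenes
  rownames(mg) <- sprintf("n%04d", seq_len(nrow(mg)))
  write_expression(expression_matrix(mg), file.path(path, "metagenes.tsv"))
  rc <- neuron_rowcol(model$assignment, model$config$cols)
  utils::write.table(
    data.frame(gene = names(model$assignment),
               neuron = unname(model$assignment),
               row = rc[, "row"], col = rc[, "col"]),
    file.path(path, "assignment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("epoch\tquantization_error",
               sprintf("%d\t%.17g", seq_along(model$error_trace),
                       model$error_trace)),
             file.path(path, "error_trace.tsv"))
  invisible(path)
}

#' @rdname som_save
#' @export
som_load <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "config.json"),
                             simplifyVector = TRUE)
  config <- som_config(rows = cfg$rows, cols = cfg$cols,
                       n_epochs = cfg$n_epochs,
                       radius_start = cfg$radius_start,
                       radius_end = cfg$radius_end,
                       init = cfg$init, seed = cfg$seed)
  mg <- load_expression(file.path(path, "metagenes.tsv"))$values
  rownames(mg) <- NULL
  asg <- utils::read.delim(file.path(path, "assignment.tsv"),
                           stringsAsFactors = FALSE)
  tr <- utils::read.delim(file.path(path, "error_trace.tsv"))
  structure(list(config = config, metagenes = mg,
                 assignment = stats::setNames(as.integer(asg$neuron), asg$gene),
                 error_trace = tr$quantization_error),
            class = "som_model")
}
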