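test_that("training fits degenerate inputs exactly", {
  # a single gene: its BMU metagene converges to the gene profile
  v <- matrix(c(1, -1, 0.5, -0.5), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  em <- expression_matrix(v - rowMeans(v), centered = TRUE)
  model <- train_som(em, som_config(rows = 2, cols = 2, n_epochs = 20))
  bmu <- model$assignment[["g1"]]
  expect_lt(sqrt(sum((model$metagenes[bmu, ] - em$values[1, ])^2)), 1e-6)

  # duplicated gene rows land on the same neuron
  r <- random_centered(20, 6, seed = 2)
  dup <- r$values[rep(1:10, 2), ]
  rownames(dup) <- sprintf("g%02d", 1:20)
  em2 <- expression_matrix(dup, centered = TRUE)
  m2 <- train_som(em2, som_config(rows = 4, cols = 4, n_epochs = 15))
  expect_identical(unname(m2$assignment[1:10]), unname(m2$assignment[11:20]))
})

test_that("training validates its input", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_error(train_som(expression_matrix(v), som_config(4, 4)), "center")
  expect_error(expression_matrix(matrix(c(1, NaN), 1, 2,
                                        dimnames = list("g", c("a", "b")))),
               "non-finite")
  expect_error(som_config(rows = 4, cols = 4, radius_start = 1,
                          radius_end = 2), "radius")
})

test_that("zero-noise archetype groups occupy disjoint neuron sets", {
  syn <- small_synth(per_module = 20, n_genes = 200, noise_sd = 0, seed = 1)
  expr <- center_genes(syn$expression)
  model <- train_som(expr, som_config(rows = 8, cols = 8, n_epochs = 25))
  truth <- syn$truth$labels
  sets <- lapply(LETTERS[1:6], function(m)
    unique(model$assignment[names(truth)[truth == m]]))
  for (i in 1:5) for (j in (i + 1):6)
    expect_length(intersect(sets[[i]], sets[[j]]), 0)

  # oracle: nearest-centroid grouping agrees with the SOM assignment —
  # all copies of one archetype share one BMU set, and each gene's assigned
  # metagene is its nearest
  d2 <- as.matrix(dist(rbind(expr$values, model$metagenes)))
  n <- nrow(expr$values)
  gene_to_neuron <- d2[1:n, (n + 1):(n + nrow(model$metagenes))]
  nearest <- apply(gene_to_neuron, 1, which.min)
  expect_identical(unname(nearest), unname(model$assignment))
})

test_that("best_matching_unit equals the exhaustive-search oracle", {
  fit <- small_trained()
  model <- fit$model
  expect_identical(best_matching_unit(model, model$metagenes[17, ]), 17L)

  flat <- manual_model(matrix(1, 9, 4,
                              dimnames = list(NULL, paste0("s", 1:4))),
                       3, 3)
  expect_identical(best_matching_unit(flat, rep(0, 4)), 1L)

  profiles <- with_seed_test(8, matrix(rnorm(100 * 36), 100, 36))
  for (i in 1:100) {
    d2 <- rowSums(sweep(model$metagenes, 2, profiles[i, ])^2)
    expect_identical(best_matching_unit(model, profiles[i, ]),
                     which.min(d2))
  }
  expect_error(best_matching_unit(model, 1:5), "length")
})

test_that("quantization error matches direct computation and monotonicity", {
  fit <- small_trained()
  model <- fit$model
  # genes equal to their metagenes -> zero error
  mg <- model$metagenes[model$assignment, ]
  rownames(mg) <- names(model$assignment)
  expect_equal(quantization_error(model, mg), 0)

  base <- quantization_error(model, fit$expr)
  noisy <- fit$expr$values + with_seed_test(3,
    matrix(rnorm(length(fit$expr$values), sd = 0.5),
           nrow(fit$expr$values)))
  expect_gt(quantization_error(model, noisy), base)

  # direct norm for one gene
  g <- fit$expr$values[5, , drop = FALSE]
  expect_equal(quantization_error(model, g),
               sqrt(sum((g - model$metagenes[model$assignment[5], ])^2)))
})

test_that("training is deterministic and its error trace is non-increasing", {
  syn <- small_synth(per_module = 15, n_genes = 300, seed = 4)
  expr <- center_genes(syn$expression)
  cfg <- som_config(rows = 6, cols = 6, n_epochs = 20, seed = 11)
  m1 <- train_som(expr, cfg)
  m2 <- train_som(expr, cfg)
  expect_identical(m1$metagenes, m2$metagenes)
  expect_identical(m1$assignment, m2$assignment)
  expect_true(all(diff(m1$error_trace) <= 1e-9))

  r1 <- train_som(expr, som_config(rows = 6, cols = 6, n_epochs = 20,
                                   init = "random", seed = 11))
  r2 <- train_som(expr, som_config(rows = 6, cols = 6, n_epochs = 20,
                                   init = "random", seed = 11))
  expect_identical(r1$metagenes, r2$metagenes)
  expect_true(all(diff(r1$error_trace) <= 1e-9))
})

test_that("correlated gene pairs sit closer on the lattice than anti-correlated", {
  fit <- small_trained()
  model <- fit$model
  truth <- fit$syn$truth$labels
  a <- names(truth)[truth == "A"][1:15]
  b <- names(truth)[truth == "B"][1:15]
  cors <- cor(t(fit$expr$values[c(a, b), ]))
  rc <- cbind((model$assignment - 1) %/% model$config$cols,
              (model$assignment - 1) %% model$config$cols)
  rownames(rc) <- names(model$assignment)
  lattice_dist <- function(g1, g2)
    sqrt(sum((rc[g1, ] - rc[g2, ])^2))
  pos <- neg <- numeric(0)
  for (i in seq_along(c(a, b))) for (j in seq_len(i - 1)) {
    gi <- c(a, b)[i]; gj <- c(a, b)[j]
    if (cors[gi, gj] > 0.95) pos <- c(pos, lattice_dist(gi, gj))
    if (cors[gi, gj] < -0.95) neg <- c(neg, lattice_dist(gi, gj))
  }
  expect_gt(length(pos), 10)
  expect_gt(length(neg), 10)
  expect_lt(mean(pos), mean(neg))
})

test_that("model archives restore to an identical model", {
  fit <- small_trained()
  dir <- withr::local_tempdir()
  som_save(fit$model, file.path(dir, "som"))
  back <- som_load(file.path(dir, "som"))
  expect_equal(back$metagenes, unname(fit$model$metagenes),
               ignore_attr = TRUE)
  expect_identical(back$assignment, fit$model$assignment)
  expect_equal(back$error_trace, fit$model$error_trace)
  expect_equal(back$config$rows, fit$model$config$rows)
})
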