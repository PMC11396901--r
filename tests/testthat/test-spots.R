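test_that("summary maps equal brute-force per-neuron statistics", {
  mg <- with_seed_test(21, matrix(rnorm(25 * 4), 25, 4,
                                  dimnames = list(NULL, paste0("s", 1:4))))
  model <- manual_model(mg, 5, 5)
  over <- summary_map(model, "overexpression")
  under <- summary_map(model, "underexpression")
  vmap <- summary_map(model, "variance")
  for (k in 1:25) {
    r <- (k - 1) %/% 5 + 1
    c <- (k - 1) %% 5 + 1
    expect_equal(over$grid[r, c], max(mg[k, ]))
    expect_equal(under$grid[r, c], min(mg[k, ]))
    expect_equal(vmap$grid[r, c], var(mg[k, ]))
  }
  expect_error(summary_map(model, "bogus"), "arg")

  two <- manual_model(matrix(c(-1, 2), 1, 2,
                             dimnames = list(NULL, c("a", "b"))), 1, 1)
  expect_equal(summary_map(two, "overexpression")$grid[1, 1], 2)
  expect_equal(summary_map(two, "underexpression")$grid[1, 1], -1)

  one <- manual_model(mg[, 1, drop = FALSE], 5, 5)
  expect_equal(as.vector(t(summary_map(one, "overexpression")$grid)),
               unname(mg[, 1]))
})

make_map <- function(grid) structure(list(grid = grid, kind = "overexpression"),
                                     class = "summary_map")

test_that("spot segmentation matches a flood-fill oracle", {
  # constant map: strict threshold leaves no foreground
  expect_length(segment_spots(make_map(matrix(1, 6, 6))), 0)

  # a single 3x3 high block
  g <- matrix(0, 8, 8)
  g[3:5, 3:5] <- 5
  spots <- segment_spots(make_map(g))
  expect_length(spots, 1)
  expect_length(spots[[1]]$neurons, 9)

  # two separated blocks
  g2 <- matrix(0, 8, 8)
  g2[1:2, 1:3] <- 3
  g2[6:8, 6:8] <- 4
  spots2 <- segment_spots(make_map(g2))
  expect_length(spots2, 2)

  # random maps: component membership equals the BFS oracle
  for (s in 1:15) {
    gr <- with_seed_test(100 + s, matrix(rnorm(64), 8, 8))
    got <- segment_spots(make_map(gr), min_size = 1)
    thr <- quantile(as.vector(gr), 0.75)
    fg <- which(t(gr) > thr)
    oracle <- flood_components(fg, 8, 8)
    got_sets <- lapply(got, function(x) x$neurons)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("foreground size is monotone in the threshold quantile", {
  gr <- with_seed_test(7, matrix(rnorm(100), 10, 10))
  sizes <- sapply(c(0.5, 0.65, 0.75, 0.85, 0.95), function(q) {
    sp <- segment_spots(make_map(gr), threshold_quantile = q, min_size = 1)
    sum(vapply(sp, function(x) length(x$neurons), integer(1)))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("spot labels follow descending peaks with a lattice tie rule", {
  g <- matrix(0, 8, 8)
  g[1:2, 1:2] <- 2
  g[7:8, 7:8] <- 3
  labeled <- label_spots(segment_spots(make_map(g)))
  expect_equal(names(labeled), c("A", "B"))
  expect_equal(labeled$A$peak, 3)

  # equal peaks: the spot whose peak neuron has the lower row-major index
  # wins the earlier letter
  g2 <- matrix(0, 8, 8)
  g2[6:7, 2:3] <- 2
  g2[2:3, 6:7] <- 2
  lab2 <- label_spots(segment_spots(make_map(g2)))
  expect_equal(lab2$A$peak_neuron, 14)  # row 2, col 6
  expect_gt(lab2$B$peak_neuron, 14)

  many <- lapply(1:27, function(i)
    structure(list(label = NA, neurons = i, peak = i, peak_neuron = i,
                   genes = character(0)), class = "spot_module"))
  expect_error(label_spots(many), "threshold")
})

test_that("spot profiles average member genes and respect symmetry", {
  v <- rbind(g1 = c(1, -1, 0, 2), g2 = -c(1, -1, 0, 2), g3 = c(4, 4, 4, 4))
  colnames(v) <- paste0("s", 1:4)
  em <- expression_matrix(v, centered = TRUE)
  sp <- function(genes) structure(list(label = "X", neurons = 1L, peak = 1,
                                       peak_neuron = 1L, genes = genes),
                                  class = "spot_module")
  expect_equal(spot_profile(em, sp("g1")), v["g1", ])
  expect_equal(unname(spot_profile(em, sp(c("g1", "g2")))), rep(0, 4))
  expect_error(spot_profile(em, sp(character(0))), "empty")
  expect_error(spot_profile(em, sp("gX")), "absent")
})

test_that("spot gene lists refine the neuron assignment", {
  fit <- small_trained()
  spots <- segment_spots(summary_map(fit$model, "overexpression"), fit$model)
  for (s in spots)
    expect_true(all(fit$model$assignment[s$genes] %in% s$neurons))
})

test_that("activation calls, edges and counts follow the fraction-of-max rule", {
  prof <- rbind(S1 = c(g1 = 1.0, g2 = 0.2, g3 = 0.8),
                S2 = c(g1 = 0.9, g2 = 0.1, g3 = 0.2),
                S3 = c(g1 = -0.5, g2 = -1, g3 = -0.2))
  act <- spot_activation(prof, activation_fraction = 0.5)
  expect_equal(unname(act$active["S1", ]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(act$active["S2", ]), c(TRUE, FALSE, FALSE))
  # never active: profile max is not positive
  expect_false(any(act$active["S3", ]))
  # one co-activation edge where S1 and S2 are both active
  expect_equal(nrow(act$edges), 1)
  expect_equal(act$edges$subject, "g1")
  expect_equal(unname(act$counts), unname(colSums(act$active)))

  solo <- spot_activation(rbind(S1 = c(a = 1, b = 0.1)), 0.5)
  expect_equal(nrow(solo$edges), 0)
  expect_error(spot_activation(prof, 0), "activation_fraction")
})

test_that("activation statistics aggregate per experimental group", {
  md <- generate_design()
  n <- nrow(md)
  off <- matrix(FALSE, 2, n, dimnames = list(c("A", "B"), md$sample_id))
  act0 <- structure(list(active = off, activation_fraction = 0.5,
                         edges = data.frame(), counts = colSums(off)),
                    class = "spot_activation")
  st0 <- activation_statistics(act0, md)
  expect_true(all(st0$mean_active_spots == 0))
  expect_equal(nrow(st0), 12)

  on6 <- matrix(TRUE, 6, n,
                dimnames = list(LETTERS[1:6], md$sample_id))
  act6 <- structure(list(active = on6, activation_fraction = 0.5,
                         edges = data.frame(), counts = colSums(on6)),
                    class = "spot_activation")
  st6 <- activation_statistics(act6, md)
  expect_true(all(st6$mean_active_spots == 6))
  expect_true(all(st6$n_samples == 3))
})
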