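test_that("hypergeometric p-values equal the enumeration oracle", {
  # the fully-overlapping draw: p = 1 / C(20,5) = 1/15504
  uni <- sprintf("u%02d", 1:20)
  coll <- gene_set_collection(list(hit = uni[1:5]), universe = uni)
  res <- overrepresentation(uni[1:5], coll)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, hyper_tail_enum(20, 5, 5, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)

  # all instances on a small grid of universes N <= 25
  for (N in c(6, 11, 18, 25)) {
    u <- sprintf("g%02d", seq_len(N))
    for (K in c(2, floor(N / 3), N - 1)) {
      for (n in c(1, floor(N / 2))) {
        cset <- gene_set_collection(list(s = u[seq_len(K)]), universe = u)
        for (k in 0:min(n, K)) {
          if (n - k > N - K) next  # not constructible
          # build a query with exactly k overlap
          query <- c(u[seq_len(k)], rev(u[K + seq_len(n - k)]))
          r <- overrepresentation(query, cset)
          expect_equal(r$p, hyper_tail_enum(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("degenerate overlap cases hit the closed-form endpoints", {
  uni <- sprintf("g%02d", 1:12)
  coll <- gene_set_collection(list(whole = uni, none = uni[11:12]),
                              universe = uni)
  res <- overrepresentation(uni[1:4], coll)
  # set = universe: k = n and p = 1
  whole <- res[res$set == "whole", ]
  expect_equal(whole$k, 4)
  expect_equal(whole$p, 1)
  # zero overlap: upper tail from 0 is certain
  expect_equal(res[res$set == "none", "p"], 1)

  expect_error(overrepresentation(c("zz", "yy"), coll), "empty")
  r2 <- overrepresentation(c(uni[1:3], "absent"), coll)
  expect_equal(attr(r2, "dropped"), "absent")
  expect_equal(r2$n[1], 3)
})

test_that("BH adjustment follows the step-up formula and ignores order", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  p <- with_seed_test(13, runif(25))
  # hand-applied step-up rule
  o <- order(p)
  m <- length(p)
  ranked <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(ranked)))
  expect_equal(bh_adjust(p)[o], pmin(qs, 1))
  perm <- sample(seq_len(m))
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
})

test_that("results are ordered by p with name tie-breaks", {
  uni <- sprintf("g%02d", 1:30)
  coll <- gene_set_collection(
    list(zeta = uni[1:5], alpha = uni[1:5], mid = uni[1:10]),
    universe = uni)
  res <- overrepresentation(uni[1:5], coll)
  expect_equal(res$set[1:2], c("alpha", "zeta"))  # tied p, name order
  expect_true(all(diff(res$p) >= 0))
  expect_true(all(res$q >= res$p))
})

test_that("GMT files round-trip", {
  uni <- sprintf("g%03d", 1:50)
  coll <- gene_set_collection(list(one = uni[1:10], two = uni[5:20]),
                              description = c(one = "first", two = "second"),
                              universe = uni)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = uni)
  expect_equal(back$sets, coll$sets)
  expect_equal(unname(back$description), unname(coll$description))

  writeLines("badline\tonly-two-fields", path)
  expect_error(read_gmt(path), "malformed")
})

test_that("gene-set lattice mapping equals assignment-table lookup", {
  fit <- small_trained()
  model <- fit$model
  genes <- with_seed_test(17, sample(names(model$assignment), 50))
  mapped <- map_gene_set_to_portrait(model, genes)
  for (i in seq_len(nrow(mapped))) {
    idx <- model$assignment[[mapped$gene[i]]]
    expect_equal(mapped$neuron[i], idx)
    expect_equal(mapped$row[i], (idx - 1) %/% model$config$cols + 1)
    expect_equal(mapped$col[i], (idx - 1) %% model$config$cols + 1)
  }
  g1 <- names(model$assignment)[model$assignment == 1][1]
  if (!is.na(g1)) {
    m1 <- map_gene_set_to_portrait(model, g1)
    expect_equal(unlist(m1[1, c("row", "col")]), c(row = 1, col = 1))
  }
  expect_error(map_gene_set_to_portrait(model, c("x", "y")), "0 of 2")
  part <- map_gene_set_to_portrait(model, c(genes[1], "nope"))
  expect_equal(attr(part, "unmapped"), "nope")
})

test_that("condition colors pick the dominant group with flagged ties", {
  mg <- cbind(s1 = c(2, 0, 1, 1), s2 = c(0, 2, 1, 0))
  model <- manual_model(mg, 2, 2,
                        assignment = c(gA = 1L, gB = 2L, gT = 3L))
  ports <- list(G1 = sample_portrait(model, "s1"),
                G2 = sample_portrait(model, "s2"))
  res <- condition_color_assignment(model, ports, c("gA", "gB", "gT"))
  expect_equal(res$group[res$gene == "gA"], "G1")
  expect_equal(res$group[res$gene == "gB"], "G2")
  # tie at neuron 3 -> first group in the fixed order, flagged
  expect_equal(res$group[res$gene == "gT"], "G1")
  expect_true(res$tie[res$gene == "gT"])
  expect_false(any(res$tie[res$gene != "gT"]))

  bad <- list(G1 = ports$G1,
              G2 = structure(list(grid = matrix(0, 3, 3), subject = "x",
                                  mode = "standard"), class = "portrait"))
  expect_error(condition_color_assignment(model, bad, "gA"), "lattice")
})

test_that("planted module genes are colored by their matching condition", {
  fit <- small_trained()
  md <- fit$syn$design
  groups <- list()
  for (cu in c("MP", "SG")) for (co in c("CTRL", "STRS")) {
    ids <- md$sample_id[md$cultivar == cu & md$condition == co]
    groups[[paste(cu, co, sep = "_")]] <-
      group_mean_portrait(fit$model, ids)
  }
  truth <- fit$syn$truth$labels
  a_genes <- names(truth)[truth == "A"]
  res <- condition_color_assignment(fit$model, groups, a_genes)
  # module A is up in SG throughout: SG groups must dominate
  expect_gt(mean(grepl("^SG", res$group)), 0.9)
})

test_that("planted true sets score best for their spot gene lists", {
  fit <- small_trained()
  truth <- fit$syn$truth
  coll <- generate_gene_sets(truth, n_random_sets = 15,
                             set_size_range = c(10, 60), seed = 4)
  spots <- label_spots(segment_spots(
    summary_map(fit$model, "overexpression"), fit$model))
  expect_gt(length(spots), 0)
  for (s in spots) {
    res <- overrepresentation(s$genes, coll)
    top_true <- min(res$q[grepl("^module_", res$set)])
    expect_equal(top_true, min(res$q))
  }
})
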