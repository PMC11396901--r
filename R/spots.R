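#' Per-neuron summary maps across samples
#'
#' Collapses the metagene matrix over samples into a single lattice map:
#' `"overexpression"` is the element-wise maximum (the map on which spot
#' modules are segmented), `"underexpression"` the element-wise minimum and
#' `"variance"` the per-neuron variance across samples. On well-trained
#' maps the overexpression regions coincide with the regions of highest
#' variance.
#'
#' @param model A `som_model`.
#' @param kind One of `"overexpression"`, `"underexpression"`, `"variance"`.
#' @return An object of class `summary_map`: list with `grid`
#'   (`rows x cols`) and `kind`.
#' @export
summary_map <- function(model,
                        kind = c("overexpression", "underexpression",
                                 "variance")) {
  stopifnot(inherits(model, "som_model"))
  kind <- match.arg(kind)
  v <- switch(kind,
              overexpression = apply(model$metagenes, 1, max),
              underexpression = apply(model$metagenes, 1, min),
              variance = apply(model$metagenes, 1, stats::var))
  grid <- matrix(v, nrow = model$config$rows, ncol = model$config$cols,
                 byrow = TRUE)
  structure(list(grid = grid, kind = kind), class = "summary_map")
}

#' Segment spot modules on a summary map
#'
#' Neurons whose map value lies strictly above the `threshold_quantile`
#' quantile of the map form the foreground (the default 0.75 keeps the
#' upper quartile; a constant map therefore yields no spots). Foreground
#' neurons are grouped into connected components under 8-neighborhood
#' (diagonals connect) and components smaller than `min_size` neurons are
#' discarded as speckle. When a model is supplied each spot also collects
#' the genes assigned to its neurons.
#'
#' @param map A `summary_map` (segmentation is normally run on the
#'   overexpression map).
#' @param model Optional `som_model` supplying gene assignments.
#' @param threshold_quantile Foreground quantile in (0, 1).
#' @param min_size Minimum component size in neurons.
#' @return List of unlabeled `spot_module` objects (fields `label`,
#'   `neurons`, `peak`, `peak_neuron`, `genes`), ordered by first neuron
#'   index; the threshold used is attached as attribute `"threshold"`.
#' @export
segment_spots <- function(map, model = NULL, threshold_quantile = 0.75,
                          min_size = 4) {
  stopifnot(inherits(map, "summary_map"))
  if (!(threshold_quantile > 0 && threshold_quantile < 1))
    stop("threshold_quantile must lie in (0, 1)")
  if (min_size < 1) stop("min_size must be >= 1")
  g <- map$grid
  n_cols <- ncol(g)
  thr <- stats::quantile(as.vector(g), threshold_quantile, names = FALSE)
  fg <- which(t(g) > thr)  # t() so linear indices are row-major neuron IDs
  if (!length(fg)) return(structure(list(), threshold = thr))

  rc <- neuron_rowcol(fg, n_cols)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  edges <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    nr <- rc[, "row"] + offs$dr[i]
    nc <- rc[, "col"] + offs$dc[i]
    ok <- nr >= 1 & nr <= nrow(g) & nc >= 1 & nc <= n_cols
    nb <- neuron_index(nr[ok], nc[ok], n_cols)
    keep <- nb %in% fg
    cbind(from = fg[ok][keep], to = nb[keep])
  }))
  gr <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, "from"]),
                   to = as.character(edges[, "to"])),
    directed = FALSE,
    vertices = data.frame(name = as.character(fg)))
  comp <- igraph::components(gr)
  member <- split(as.integer(igraph::V(gr)$name), comp$membership)
  member <- Filter(function(idx) length(idx) >= min_size, member)
  member <- member[order(vapply(member, min, integer(1)))]

  gvec <- as.vector(t(g))  # value by row-major neuron index
  spots <- lapply(member, function(idx) {
    idx <- sort(idx)
    vals <- gvec[idx]
    peak <- max(vals)
    genes <- if (!is.null(model))
      names(model$assignment)[model$assignment %in% idx] else character(0)
    structure(list(label = NA_character_, neurons = idx, peak = peak,
                   peak_neuron = min(idx[vals == peak]), genes = genes),
              class = "spot_module")
  })
  names(spots) <- NULL
  structure(spots, threshold = thr)
}

#' Label spots A, B, C, ... by descending peak value
#'
#' Capital letters are assigned in order of decreasing peak map value, with
#' ties broken by the lower row-major index of the peak neuron. More than
#' 26 spots is an error (raise the segmentation threshold).
#'
#' @param spots List of `spot_module` from [segment_spots()].
#' @return The same list, labeled and reordered A, B, C, ..., named by label.
#' @export
label_spots <- function(spots) {
  if (length(spots) > 26)
    stop(length(spots), " spots exceed the A-Z labels; raise threshold_quantile")
  if (!length(spots)) return(spots)
  peaks <- vapply(spots, function(s) s$peak, numeric(1))
  tie <- vapply(spots, function(s) s$peak_neuron, numeric(1))
  ord <- order(-peaks, tie)
  out <- spots[ord]
  for (i in seq_along(out)) out[[i]]$label <- LETTERS[i]
  names(out) <- LETTERS[seq_along(out)]
  attr(out, "threshold") <- attr(spots, "threshold")
  out
}

#' Mean expression profile of a spot's genes
#'
#' @param x A centered `expression_matrix` containing the spot's genes.
#' @param spot A `spot_module` with a non-empty gene list.
#' @return Named numeric vector, one mean centered-expression value per
#'   sample.
#' @export
spot_profile <- function(x, spot) {
  stopifnot(inherits(x, "expression_matrix"), inherits(spot, "spot_module"))
  if (!length(spot$genes)) stop("spot has an empty gene list")
  missing <- setdiff(spot$genes, rownames(x$values))
  if (length(missing))
    stop("spot genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  colMeans(x$values[spot$genes, , drop = FALSE])
}

#' Profiles of all spots as a matrix
#'
#' @param x A centered `expression_matrix`.
#' @param spots Labeled spot list.
#' @return `n_spots x n_samples` matrix, rownames = spot labels.
#' @export
spot_profiles <- function(x, spots) {
  out <- t(vapply(spots, function(s) spot_profile(x, s),
                  numeric(ncol(x$values))))
  rownames(out) <- vapply(spots, function(s) s$label, character(1))
  out
}

#' Average spot profiles over sample groups
#'
#' @param profiles `n_spots x n_samples` matrix from [spot_profiles()].
#' @param metadata Sample metadata with a `sample_id` column.
#' @param by Metadata columns defining the groups.
#' @return `n_spots x n_groups` matrix; group keys join the `by` levels
#'   with "_" in metadata order of first appearance.
#' @export
group_profiles <- function(profiles, metadata,
                           by = c("cultivar", "condition", "timepoint")) {
  stopifnot(all(colnames(profiles) %in% metadata$sample_id))
  md <- metadata[match(colnames(profiles), metadata$sample_id), , drop = FALSE]
  key <- do.call(paste, c(md[by], sep = "_"))
  keys <- unique(key)
  out <- vapply(keys, function(k)
    rowMeans(profiles[, key == k, drop = FALSE]), numeric(nrow(profiles)))
  dimnames(out) <- list(rownames(profiles), keys)
  out
}

#' Spot activation calls and co-activation network
#'
#' A spot is called active in a subject (sample or group) when its profile
#' value there exceeds `activation_fraction` times the spot's maximum
#' profile value over all subjects, provided that maximum is positive; a
#' spot whose profile never rises above zero is never active. Two spots
#' active in the same subject are joined by a co-activation edge.
#'
#' @param profiles `n_spots x n_subjects` profile matrix
#'   ([spot_profiles()] or [group_profiles()]).
#' @param activation_fraction Fraction of the per-spot maximum, in (0, 1].
#' @return An object of class `spot_activation`: logical `active` matrix,
#'   `edges` data frame (spot1, spot2, subject), per-subject active-spot
#'   `counts` and the fraction used.
#' @export
spot_activation <- function(profiles, activation_fraction = 0.5) {
  if (!(activation_fraction > 0 && activation_fraction <= 1))
    stop("activation_fraction must lie in (0, 1]")
  mx <- apply(profiles, 1, max)
  active <- profiles > activation_fraction * mx
  active[mx <= 0, ] <- FALSE
  edges <- do.call(rbind, lapply(colnames(profiles), function(subj) {
    on <- rownames(profiles)[active[, subj]]
    if (length(on) < 2) return(NULL)
    pairs <- t(utils::combn(on, 2))
    data.frame(spot1 = pairs[, 1], spot2 = pairs[, 2], subject = subj,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(spot1 = character(0), spot2 = character(0),
                        subject = character(0))
  structure(list(active = active,
                 activation_fraction = activation_fraction,
                 edges = edges,
                 counts = colSums(active)),
            class = "spot_activation")
}

#' Per-group spot activation statistics
#'
#' Summarizes a sample-level activation matrix by experimental group: the
#' mean number of active spots per portrait and the frequency histogram of
#' active-spot counts.
#'
#' @param activation A `spot_activation` computed over samples.
#' @param metadata Sample metadata (`sample_id` plus the grouping columns).
#' @param by Metadata columns defining the groups.
#' @return Data frame with the grouping columns, `n_samples` and
#'   `mean_active_spots`; the count histogram (groups x active-spot count)
#'   is attached as attribute `"frequencies"`.
#' @export
activation_statistics <- function(activation, metadata,
                                  by = c("cultivar", "condition",
                                         "timepoint")) {
  stopifnot(inherits(activation, "spot_activation"))
  samples <- colnames(activation$active)
  if (!all(samples %in% metadata$sample_id))
    stop("activation subjects must be sample IDs present in metadata")
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  key <- do.call(paste, c(md[by], sep = "_"))
  counts <- activation$counts
  agg <- stats::aggregate(counts, by = c(md[by]), FUN = mean)
  names(agg)[ncol(agg)] <- "mean_active_spots"
  nper <- stats::aggregate(counts, by = c(md[by]), FUN = length)
  agg$n_samples <- nper[[ncol(nper)]]
  agg <- agg[, c(by, "n_samples", "mean_active_spots")]
  freq <- table(group = key, active_spots = counts)
  attr(agg, "frequencies") <- freq
  agg
}

#' Write spot tables to a directory
#'
#' Emits `spots.tsv` (label, neuron and gene counts, peak, member genes),
#' `spot_profiles.tsv`, `activation.tsv` and `coactivation_edges.tsv`.
#'
#' @param spots Labeled spot list.
#' @param profiles Spot profile matrix.
#' @param activation A `spot_activation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_tables <- function(spots, profiles, activation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    label = vapply(spots, function(s) s$label, character(1)),
    n_neurons = vapply(spots, function(s) length(s$neurons), integer(1)),
    n_genes = vapply(spots, function(s) length(s$genes), integer(1)),
    peak = vapply(spots, function(s) s$peak, numeric(1)),
    genes = vapply(spots, function(s) paste(s$genes, collapse = ","),
                   character(1)))
  utils::write.table(tab, file.path(dir, "spots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(label = rownames(profiles), profiles,
                                check.names = FALSE),
                     file.path(dir, "spot_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(label = rownames(activation$active),
                                activation$active * 1L, check.names = FALSE),
                     file.path(dir, "activation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(activation$edges,
                     file.path(dir, "coactivation_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
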