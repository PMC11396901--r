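#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param description Optional named character vector of set descriptions.
#' @param universe Character vector of gene IDs forming the test universe.
#'   Set members need not all lie in the universe; they are intersected at
#'   test time and the dropped counts reported.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, universe) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicated set names")
  if (!length(universe)) stop("universe is empty")
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = lapply(sets, unique),
                 description = description,
                 universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' Read or write GMT gene-set files
#'
#' Standard GMT layout: one set per line — name, description, then the
#' tab-separated member genes.
#'
#' @param path Path to a GMT file.
#' @param universe Universe for the returned collection (defaults to the
#'   union of all set members).
#' @return `read_gmt` returns a `gene_set_collection`; `write_gmt` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  desc <- stats::setNames(vapply(parts, `[`, character(1), 2), names(sets))
  gene_set_collection(sets, description = desc,
                      universe = universe %||% unique(unlist(sets)))
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Invariant to the
#' input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation of a query gene list
#'
#' For each set, the overlap `k` between the query list (size `n`, after
#' intersection with the universe) and the set (in-universe size `K`) is
#' tested against the hypergeometric upper tail
#' `p = P[X >= k]`, `X ~ Hypergeom(N, K, n)` — overrepresentation only.
#' q-values are Benjamini-Hochberg adjusted across all sets of the
#' collection; results are sorted by increasing p, ties by set name.
#'
#' @param query Character vector of query gene IDs (e.g. a spot gene list).
#' @param collection A `gene_set_collection`.
#' @param universe Optional universe override (defaults to the
#'   collection's).
#' @return Data frame with columns `set, k, n, K, N, p, q`; query IDs
#'   outside the universe are dropped and reported in attribute
#'   `"dropped"`.
#' @export
overrepresentation <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe %||% collection$universe))
  if (!length(universe)) stop("universe is empty")
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  if (!length(query))
    stop("query is empty after intersection with the universe (",
         length(dropped), " IDs dropped)")
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    # extreme overlaps underflow to 0; clamp to the smallest normal double
    p <- max(p, .Machine$double.xmin)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Map a gene set onto the SOM lattice
#'
#' Pairs each mappable gene with the lattice coordinates of its best
#' matching unit; genes absent from the model are reported separately.
#'
#' @param model A `som_model`.
#' @param genes Character vector of gene IDs.
#' @return Data frame with `gene, neuron, row, col` (1-based, row-major);
#'   unmapped IDs in attribute `"unmapped"`.
#' @export
map_gene_set_to_portrait <- function(model, genes) {
  stopifnot(inherits(model, "som_model"))
  genes <- unique(as.character(genes))
  mapped <- intersect(genes, names(model$assignment))
  if (!length(mapped))
    stop("0 of ", length(genes), " genes are present in the model")
  idx <- model$assignment[mapped]
  rc <- neuron_rowcol(idx, model$config$cols)
  out <- data.frame(gene = mapped, neuron = unname(idx),
                    row = rc[, "row"], col = rc[, "col"],
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <- setdiff(genes, mapped)
  out
}

#' Assign genes to the condition with maximal local expression
#'
#' For pathway visualization, each gene is colored by the experimental
#' group whose mean (waterline) portrait carries the highest value at the
#' gene's best matching unit. Ties go to the first group in the supplied
#' order and are flagged.
#'
#' @param model A `som_model`.
#' @param group_portraits Named list of at least two `portrait`s on the
#'   model's lattice (typically cultivar x condition means averaged over
#'   time); the list order is the documented tie-break order.
#' @param genes Character vector of gene IDs.
#' @return Data frame with `gene, group, value, tie`.
#' @export
condition_color_assignment <- function(model, group_portraits, genes) {
  stopifnot(inherits(model, "som_model"))
  if (length(group_portraits) < 2 || is.null(names(group_portraits)))
    stop("need >= 2 named group portraits")
  dims <- c(model$config$rows, model$config$cols)
  vals <- vapply(group_portraits, function(p) {
    if (!all(dim(p$grid) == dims))
      stop("group portrait lattice does not match the model")
    as.vector(t(p$grid))  # by row-major neuron index
  }, numeric(prod(dims)))
  mapped <- map_gene_set_to_portrait(model, genes)
  at <- vals[mapped$neuron, , drop = FALSE]
  best <- max.col(at, ties.method = "first")
  mx <- at[cbind(seq_len(nrow(at)), best)]
  tie <- rowSums(at == mx) > 1
  data.frame(gene = mapped$gene,
             group = names(group_portraits)[best],
             value = mx, tie = tie, stringsAsFactors = FALSE)
}
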