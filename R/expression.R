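#' Construct an expression matrix object
#'
#' A light container for a gene-level log-scale expression matrix with unique
#' gene identifiers (rows), sample identifiers (columns) and a flag recording
#' whether gene-wise centering has been applied. Missing or non-finite values
#' are rejected outright: the intended input is complete, normalized
#' (e.g. RMA) intensity data, and silent imputation would distort the
#' downstream lattice segmentation.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   both dimnames set.
#' @param centered Logical flag: have rows already been mean-centered?
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, centered = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as rownames and sample IDs as colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicated gene IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- paste0(rownames(values)[bad[, 1]], "/", colnames(values)[bad[, 2]])
    stop("missing or non-finite values at: ",
         paste(utils::head(cells, 10), collapse = ", "))
  }
  structure(list(values = values, centered = isTRUE(centered)),
            class = "expression_matrix")
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$centered) "gene-centered" else "not centered"))
  invisible(x)
}

#' Gene and sample identifiers
#' @param x An `expression_matrix` or `som_model`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "expression_matrix")) rownames(x$values)
  else if (inherits(x, "som_model")) names(x$assignment)
  else stop("unsupported object")
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  if (inherits(x, "expression_matrix")) colnames(x$values)
  else if (inherits(x, "som_model")) colnames(x$metagenes)
  else stop("unsupported object")
}

#' Read a gene-level expression matrix from TSV
#'
#' The expected layout is a header row of sample IDs and a first column of
#' gene IDs. The body must be fully numeric; missing values and duplicated
#' gene IDs are hard errors that name the offending cells or IDs.
#'
#' @param path Path to a tab-separated file.
#' @return An uncentered `expression_matrix`.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a gene-ID column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated gene IDs in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum)) {
    col <- names(body)[which(nonnum)[1]]
    vals <- suppressWarnings(as.numeric(body[[col]]))
    rows <- which(is.na(vals) & !is.na(body[[col]]))
    stop("non-numeric values in column '", col, "' at: ",
         paste(utils::head(paste0(ids[rows], "/", col), 10), collapse = ", "))
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  expression_matrix(values, centered = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip is bit-identical.
#'
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  txt <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write sample metadata
#'
#' CSV with columns `sample_id, cultivar, condition, timepoint, replicate`
#' (a numeric `day` column is kept when present).
#'
#' @param path Path to a CSV file.
#' @return A data frame, one row per sample.
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "condition", "timepoint", "replicate")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicated sample_id in metadata")
  md
}

#' @rdname load_metadata
#' @param metadata Data frame as returned by [generate_design()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a matrix to an annotation gene list
#'
#' Keeps the intersection of the matrix genes with an annotation list and
#' reports the retention percentage, `100 * kept / length(annotation)`,
#' rounded to two decimals.
#'
#' @param x An `expression_matrix`.
#' @param annotation Character vector of annotated gene IDs.
#' @return List with elements `matrix` (the filtered `expression_matrix`) and
#'   `retention_percent`.
#' @export
filter_to_annotation <- function(x, annotation) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!length(annotation)) stop("annotation list is empty")
  annotation <- unique(as.character(annotation))
  keep <- intersect(rownames(x$values), annotation)
  if (!length(keep))
    stop("no overlap between matrix genes and the annotation list")
  out <- expression_matrix(x$values[keep, , drop = FALSE],
                           centered = x$centered)
  list(matrix = out,
       retention_percent = round(100 * length(keep) / length(annotation), 2))
}

#' Center each gene across all samples
#'
#' Subtracts the per-gene mean over all samples, placing every gene on the
#' above/below-mean scale that waterline portraits visualize. Centering is
#' global (not per group): group portraits are meant to be compared against
#' the grand mean. Applying it to an already-centered matrix is a no-op with
#' a warning.
#'
#' @param x An `expression_matrix`.
#' @return A centered `expression_matrix`.
#' @export
center_genes <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$centered) {
    warning("matrix is already gene-centered; returning unchanged")
    return(x)
  }
  v <- x$values - rowMeans(x$values)
  expression_matrix(v, centered = TRUE)
}

#' Quantile-normalize sample columns
#'
#' Optional stage (off by default in the pipeline: RMA input is already
#' normalized). Every column is forced onto the common distribution of
#' per-rank means, with ties receiving the average of their ranks, via
#' [limma::normalizeQuantiles()].
#'
#' @param x An uncentered `expression_matrix`.
#' @return The normalized `expression_matrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$centered) stop("quantile normalization must precede centering")
  if (ncol(x$values) < 2) return(x)
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, centered = FALSE)
}

#' Read a GEO series-matrix text file
#'
#' Convenience reader for the series-matrix layout: metadata lines prefixed
#' with "!" are skipped and the expression block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` is parsed as a
#' TSV of sample columns.
#'
#' @param path Path to a series-matrix file.
#' @return An uncentered `expression_matrix`.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series-matrix table found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  tc <- textConnection(block)
  on.exit(close(tc), add = TRUE)
  df <- utils::read.delim(tc, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- gsub('"', "", as.character(df[[1]]))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- ids
  colnames(values) <- gsub('"', "", colnames(values))
  expression_matrix(values, centered = FALSE)
}
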