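#' Extract a sample's expression portrait
#'
#' A portrait is the lattice of metagene values for one sample, arranged as
#' a `rows x cols` matrix (row-major, matching the neuron indexing), ready
#' for rendering as an image. Extraction is lossless: reshaping the grid
#' back to a vector reproduces the metagene column.
#'
#' @param model A `som_model`.
#' @param sample_id Sample identifier present in the model.
#' @param mode `"standard"` or `"waterline"` (affects rendering only).
#' @return An object of class `portrait`: list with `grid`, `subject`, `mode`.
#' @export
sample_portrait <- function(model, sample_id, mode = "standard") {
  stopifnot(inherits(model, "som_model"))
  if (!sample_id %in% colnames(model$metagenes))
    stop("unknown sample: ", sample_id)
  grid <- matrix(model$metagenes[, sample_id],
                 nrow = model$config$rows, ncol = model$config$cols,
                 byrow = TRUE)
  structure(list(grid = grid, subject = sample_id, mode = mode),
            class = "portrait")
}

#' Mean portrait of a sample group
#'
#' Element-wise mean of the member portraits; a singleton group equals the
#' sample portrait.
#'
#' @param model A `som_model`.
#' @param sample_ids Non-empty character vector of member samples.
#' @param subject Label for the group (defaults to the IDs joined by "+").
#' @inheritParams sample_portrait
#' @return A `portrait`.
#' @export
group_mean_portrait <- function(model, sample_ids, mode = "waterline",
                                subject = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (!length(sample_ids)) stop("empty sample group")
  missing <- setdiff(sample_ids, colnames(model$metagenes))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  v <- rowMeans(model$metagenes[, sample_ids, drop = FALSE])
  grid <- matrix(v, nrow = model$config$rows, ncol = model$config$cols,
                 byrow = TRUE)
  structure(list(grid = grid,
                 subject = subject %||% paste(sample_ids, collapse = "+"),
                 mode = mode),
            class = "portrait")
}

#' Portrait color mapping
#'
#' `standard_colors()` maps values linearly over `[lo, hi]` through the
#' tertiary blue (low) - green (mid) - red (high) ramp: `lo` is pure blue
#' `(0,0,1)`, the midpoint pure green `(0,1,0)` and `hi` pure red `(1,0,0)`.
#' `waterline_colors()` uses a diverging scale centered at zero and
#' symmetric in `max_abs`: zero maps to white `(1,1,1)`, `+max_abs` to pure
#' red and `-max_abs` to pure blue, with `color(v)` and `color(-v)` mirror
#' entries of the palette. A degenerate range (`hi == lo`, or
#' `max_abs == 0`) maps everything to the palette midpoint.
#'
#' @param v Numeric vector of grid values.
#' @param lo,hi Standard-mode scaling range.
#' @param max_abs Waterline-mode symmetric scale.
#' @return `length(v) x 3` matrix of RGB values in `[0, 1]`.
#' @export
standard_colors <- function(v, lo = min(v), hi = max(v)) {
  t <- if (hi > lo) (v - lo) / (hi - lo) else rep(0.5, length(v))
  t <- pmin(pmax(t, 0), 1)
  lowhalf <- t <= 0.5
  r <- ifelse(lowhalf, 0, (t - 0.5) * 2)
  g <- ifelse(lowhalf, t * 2, 1 - (t - 0.5) * 2)
  b <- ifelse(lowhalf, 1 - t * 2, 0)
  cbind(r = r, g = g, b = b)
}

#' @rdname standard_colors
#' @export
waterline_colors <- function(v, max_abs = max(abs(v))) {
  t <- if (max_abs > 0) pmin(pmax(v / max_abs, -1), 1) else rep(0, length(v))
  r <- ifelse(t >= 0, 1, 1 + t)
  g <- 1 - abs(t)
  b <- ifelse(t >= 0, 1 - t, 1)
  cbind(r = r, g = g, b = b)
}

#' Render a portrait to a PNG file
#'
#' Standard mode scales per portrait over `[min, max]` through the
#' blue-green-red ramp; waterline mode uses the diverging red/white/blue
#' scale symmetric around zero, highlighting above/below-mean expression. A
#' fixed `range` can be supplied for cross-sample comparability (global
#' scaling); the default is per-portrait scaling.
#'
#' @param portrait A `portrait`.
#' @param path Output PNG path.
#' @param mode Override the portrait's rendering mode.
#' @param range Optional scaling override: `c(lo, hi)` in standard mode, a
#'   single positive `max_abs` in waterline mode.
#' @param upscale Integer pixel replication factor per neuron.
#' @return `path`, invisibly.
#' @export
render_portrait <- function(portrait, path, mode = NULL, range = NULL,
                            upscale = 8) {
  stopifnot(inherits(portrait, "portrait"))
  mode <- mode %||% portrait$mode
  g <- portrait$grid
  if (any(!is.finite(g))) stop("portrait grid contains non-finite values")
  rgbv <- if (mode == "waterline") {
    waterline_colors(as.vector(g),
                     max_abs = if (is.null(range)) max(abs(g)) else range[1])
  } else if (mode == "standard") {
    lo <- if (is.null(range)) min(g) else range[1]
    hi <- if (is.null(range)) max(g) else range[2]
    standard_colors(as.vector(g), lo = lo, hi = hi)
  } else stop("unknown mode: ", mode)
  arr <- array(0, dim = c(nrow(g), ncol(g), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgbv[, ch], nrow(g), ncol(g))
  ri <- rep(seq_len(nrow(g)), each = upscale)
  ci <- rep(seq_len(ncol(g)), each = upscale)
  big <- arr[ri, ci, , drop = FALSE]
  ok <- tryCatch(png::writePNG(big, target = path), error = function(e)
    stop("cannot write portrait PNG to '", path, "': ", conditionMessage(e)))
  invisible(path)
}
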