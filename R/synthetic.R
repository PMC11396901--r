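#' Default planted co-regulation module archetypes
#'
#' Six archetype profiles (labeled A-F) defined on the twelve
#' cultivar x condition x timepoint groups of the default factorial design,
#' on the centered log-expression scale with unit amplitude:
#' \describe{
#'   \item{A}{up in all SG groups, down in all MP groups}
#'   \item{B}{the sign-flipped mirror of A}
#'   \item{C}{peaks at T1 in both cultivars}
#'   \item{D}{peaks at T2 in both cultivars}
#'   \item{E}{high at T3 in SG under stress and in MP under control}
#'   \item{F}{high at T3 under stress in both cultivars}
#' }
#'
#' @param n_genes Genes planted per module (single value or named vector over
#'   A-F). Default 400, a mid-range co-regulation module size of a few
#'   hundred genes.
#' @param amplitude Absolute effect size on the centered log scale.
#' @return An object of class `module_archetypes`: list with a 6 x 12 profile
#'   matrix (rows A-F, columns group keys `cultivar_condition_timepoint`) and
#'   the per-module gene counts.
#' @export
default_archetypes <- function(n_genes = 400, amplitude = 1.0) {
  cultivar <- rep(c("MP", "SG"), each = 6)
  condition <- rep(rep(c("CTRL", "STRS"), each = 3), times = 2)
  tp <- rep(c("T1", "T2", "T3"), times = 4)
  keys <- paste(cultivar, condition, tp, sep = "_")
  A <- ifelse(cultivar == "SG", 1, -1)
  C <- as.numeric(tp == "T1")
  D <- as.numeric(tp == "T2")
  E <- as.numeric(tp == "T3" &
                    ((cultivar == "SG" & condition == "STRS") |
                       (cultivar == "MP" & condition == "CTRL")))
  FF <- as.numeric(tp == "T3" & condition == "STRS")
  profiles <- amplitude * rbind(A = A, B = -A, C = C, D = D, E = E, F = FF)
  colnames(profiles) <- keys
  if (length(n_genes) == 1) n_genes <- stats::setNames(rep(n_genes, 6), LETTERS[1:6])
  stopifnot(all(LETTERS[1:6] %in% names(n_genes)), all(n_genes >= 1))
  structure(list(profiles = profiles,
                 n_genes = as.integer(n_genes[LETTERS[1:6]])),
            class = "module_archetypes")
}

#' Generate a full-factorial time-course sample design
#'
#' Emulates a two-cultivar water-stress experiment: two cultivars, a
#' well-watered control arm (CTRL) and a stressed arm (STRS), sampled at
#' three timepoints (2, 6 and 27 days after stress onset) in three
#' biological replicates — 36 samples by default. Rows are ordered
#' cultivar, then condition, then timepoint, then replicate.
#'
#' @param cultivars,conditions Character vectors of factor levels.
#' @param timepoints Named numeric vector: labels to day values, or a plain
#'   character vector of labels (days then NA).
#' @param n_replicates Number of biological replicates per group.
#' @return Data frame with columns `sample_id, cultivar, condition,
#'   timepoint, day, replicate`.
#' @export
generate_design <- function(cultivars = c("MP", "SG"),
                            conditions = c("CTRL", "STRS"),
                            timepoints = c(T1 = 2, T2 = 6, T3 = 27),
                            n_replicates = 3) {
  if (!length(cultivars) || !length(conditions) || !length(timepoints))
    stop("invalid design: every factor needs at least one level")
  if (n_replicates < 1) stop("invalid design: n_replicates must be >= 1")
  if (is.numeric(timepoints)) {
    labels <- names(timepoints) %||% paste0("T", seq_along(timepoints))
    days <- unname(timepoints)
  } else {
    labels <- as.character(timepoints)
    days <- rep(NA_real_, length(timepoints))
  }
  d <- expand.grid(replicate = paste0("r", seq_len(n_replicates)),
                   timepoint = labels,
                   condition = conditions,
                   cultivar = cultivars,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("cultivar", "condition", "timepoint", "replicate")]
  d$day <- days[match(d$timepoint, labels)]
  d$sample_id <- paste(d$cultivar, d$condition, d$timepoint, d$replicate,
                       sep = "_")
  rownames(d) <- NULL
  d[, c("sample_id", "cultivar", "condition", "timepoint", "day", "replicate")]
}

#' Simulate a factorial time-course expression matrix with planted modules
#'
#' Module genes follow their archetype group-mean profile (broadcast to
#' replicates) plus i.i.d. Gaussian noise of sd `noise_sd`; the remaining
#' background genes are pure Gaussian noise of sd `background_sd` around
#' zero. Replicate correlation arises only through the shared group means,
#' mimicking RMA-style log-scale data. Identical seeds give bit-identical
#' output.
#'
#' @param design Sample design from [generate_design()].
#' @param n_genes Total gene count (module genes plus background).
#' @param archetypes A `module_archetypes` object.
#' @param noise_sd Replicate noise sd for module genes (log scale).
#' @param background_sd Noise sd for background genes; smaller than the
#'   archetype amplitude so modules carry the map's variance.
#' @param seed Integer seed; the RNG state of the caller is untouched.
#' @return List with `expression` (uncentered `expression_matrix`) and
#'   `truth` (a `synthetic_truth`: gene labels, archetypes, sds, seed).
#' @export
generate_expression <- function(design,
                                n_genes = 12000,
                                archetypes = default_archetypes(),
                                noise_sd = 0.2,
                                background_sd = 0.1,
                                seed = 1) {
  stopifnot(inherits(archetypes, "module_archetypes"))
  if (noise_sd < 0 || background_sd < 0) stop("noise sds must be >= 0")
  labels <- rownames(archetypes$profiles)
  per_module <- archetypes$n_genes
  n_module <- sum(per_module)
  if (n_genes < n_module)
    stop("n_genes (", n_genes, ") is below the planted module capacity (",
         n_module, ")")
  keys <- paste(design$cultivar, design$condition, design$timepoint, sep = "_")
  missing <- setdiff(keys, colnames(archetypes$profiles))
  if (length(missing))
    stop("archetypes lack profiles for groups: ",
         paste(unique(missing), collapse = ", "))

  ids <- sprintf("g%05d", seq_len(n_genes))
  gene_label <- c(rep(labels, times = per_module),
                  rep("background", n_genes - n_module))
  base <- matrix(0, n_genes, nrow(design))
  mod <- gene_label != "background"
  base[mod, ] <- archetypes$profiles[gene_label[mod], keys, drop = FALSE]
  sd_vec <- ifelse(mod, noise_sd, background_sd)
  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_genes * nrow(design)), n_genes, nrow(design))
    base + z * sd_vec
  })
  dimnames(values) <- list(ids, design$sample_id)
  truth <- structure(list(labels = stats::setNames(gene_label, ids),
                          archetypes = archetypes,
                          noise_sd = noise_sd,
                          background_sd = background_sd,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(expression = expression_matrix(values, centered = FALSE),
       truth = truth)
}

#' Serialize / restore planted-module ground truth
#'
#' @param truth A `synthetic_truth` object.
#' @param path JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the restored
#'   `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    labels = as.list(truth$labels),
    archetype_profiles = apply(truth$archetypes$profiles, 1, as.list,
                               simplify = FALSE),
    archetype_groups = colnames(truth$archetypes$profiles),
    archetype_n_genes = as.list(stats::setNames(truth$archetypes$n_genes,
                                                rownames(truth$archetypes$profiles))),
    noise_sd = truth$noise_sd,
    background_sd = truth$background_sd,
    seed = truth$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  profiles <- t(vapply(p$archetype_profiles, function(row) unlist(row),
                       numeric(length(p$archetype_groups))))
  rownames(profiles) <- names(p$archetype_profiles)
  colnames(profiles) <- p$archetype_groups
  arch <- structure(list(profiles = profiles,
                         n_genes = as.integer(unlist(p$archetype_n_genes))),
                    class = "module_archetypes")
  names(arch$n_genes) <- names(p$archetype_n_genes)
  structure(list(labels = unlist(p$labels),
                 archetypes = arch,
                 noise_sd = p$noise_sd,
                 background_sd = p$background_sd,
                 seed = as.integer(p$seed)),
            class = "synthetic_truth")
}

#' Build a gene-set collection from planted-module truth
#'
#' One "true" set per planted module (its exact membership) plus
#' `n_random_sets` uniform random draws from the gene universe, for testing
#' overrepresentation calls against known positives.
#'
#' @param truth A `synthetic_truth` object.
#' @param n_random_sets Number of random decoy sets.
#' @param set_size_range Length-2 integer range for random set sizes.
#' @param seed Integer seed.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
generate_gene_sets <- function(truth, n_random_sets = 20,
                               set_size_range = c(20, 200), seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  universe <- names(truth$labels)
  if (!length(universe)) stop("truth is empty")
  if (max(set_size_range) > length(universe))
    stop("random set size exceeds the universe")
  modules <- setdiff(sort(unique(truth$labels)), "background")
  sets <- lapply(modules, function(m) universe[truth$labels == m])
  names(sets) <- paste0("module_", modules)
  desc <- stats::setNames(paste("planted module", modules), names(sets))
  if (n_random_sets > 0) {
    rnd <- with_seed(seed, {
      sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                      n_random_sets, replace = TRUE)
      lapply(sizes, function(s) sample(universe, s))
    })
    names(rnd) <- sprintf("random_%02d", seq_len(n_random_sets))
    desc <- c(desc, stats::setNames(rep("random decoy set", n_random_sets),
                                    names(rnd)))
    sets <- c(sets, rnd)
  }
  gene_set_collection(sets, description = desc, universe = universe)
}
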