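#' Default pipeline configuration
#'
#' A pipeline run is driven by a single nested configuration (storable as
#' YAML) covering data input or synthetic generation, preprocessing, SOM
#' training, spot segmentation, sample-space analysis, enrichment and
#' rendering. Every stochastic stage derives its seed deterministically
#' from the master `seed` and the stage name, so runs with the same config
#' are bit-identical and adding stages does not shift existing streams.
#'
#' @param output_dir Run output directory.
#' @param seed Master seed.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(output_dir, seed = 1) {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    input = NULL,
    synthetic = list(n_genes = 12000L, genes_per_module = 400L,
                     noise_sd = 0.2, background_sd = 0.1,
                     n_random_sets = 20L),
    preprocess = list(quantile_normalize = FALSE),
    som = list(rows = 40L, cols = 40L, n_epochs = 50L),
    spots = list(threshold_quantile = 0.75, min_size = 4L,
                 activation_fraction = 0.5),
    sample_space = list(n_components = 3L, k_min = 2L, k_max = 6L,
                        grid_rows = 10L, grid_cols = 10L),
    render = list(portraits = TRUE, upscale = 8L)),
    class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(cfg$output_dir %||% ".",
                                  seed = cfg$seed %||% 1L)
  for (nm in names(cfg)) {
    if (is.null(cfg[[nm]])) next
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(cfg[[nm]])) base[[nm]][[sub]] <- cfg[[nm]][[sub]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end portrayal pipeline
#'
#' Executes data acquisition (synthetic generation or file input),
#' preprocessing, SOM training, portrait rendering, spot segmentation and
#' activation analysis, sample-space analysis and gene-set
#' overrepresentation, writing every artifact under `output_dir` and a
#' manifest (JSON, with per-file MD5 checksums) under `report/`. Stage
#' failures abort with the stage name; partial outputs are retained. The
#' sample-space stage is skipped with a notice when fewer than three
#' samples are available.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return The manifest, invisibly (list: `config`, `artifacts` data frame
#'   with relative paths and checksums, `stats`, `notes`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$output_dir
  if (is.null(out)) stop("config lacks an output_dir")

  # validate inputs before any computation
  if (!is.null(config$input)) {
    for (f in c("expression", "metadata")) {
      if (is.null(config$input[[f]]))
        stop("config input block lacks a '", f, "' path")
      if (!file.exists(config$input[[f]]))
        stop("input file does not exist: ", config$input[[f]])
    }
    for (f in c("annotation", "gene_sets")) {
      if (!is.null(config$input[[f]]) && !file.exists(config$input[[f]]))
        stop("input file does not exist: ", config$input[[f]])
    }
  }
  for (d in c("", "data", "som", "portraits", "spots", "sample_space",
              "enrichment", "report"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  stats <- list()

  truth <- NULL
  collection <- NULL
  annotation <- NULL
  if (is.null(config$input)) {
    dat <- run_stage("synthetic", {
      design <- generate_design()
      sy <- config$synthetic
      gen <- generate_expression(
        design,
        n_genes = sy$n_genes,
        archetypes = default_archetypes(n_genes = sy$genes_per_module),
        noise_sd = sy$noise_sd, background_sd = sy$background_sd,
        seed = stage_seed(config$seed, "synthetic"))
      sets <- generate_gene_sets(gen$truth, n_random_sets = sy$n_random_sets,
                                 seed = stage_seed(config$seed, "gene_sets"))
      write_expression(gen$expression, file.path(out, "data/expression.tsv"))
      write_metadata(design, file.path(out, "data/metadata.csv"))
      write_truth(gen$truth, file.path(out, "data/truth.json"))
      write_gmt(sets, file.path(out, "data/gene_sets.gmt"))
      list(expression = gen$expression, metadata = design,
           truth = gen$truth, collection = sets)
    })
    truth <- dat$truth
    collection <- dat$collection
  } else {
    dat <- run_stage("input", {
      expr <- load_expression(config$input$expression)
      md <- load_metadata(config$input$metadata)
      if (!setequal(md$sample_id, colnames(expr$values)))
        stop("metadata sample IDs do not match the expression columns")
      if (!is.null(config$input$annotation))
        annotation <- readLines(config$input$annotation)
      if (!is.null(config$input$gene_sets))
        collection <- read_gmt(config$input$gene_sets,
                                universe = rownames(expr$values))
      list(expression = expr, metadata = md)
    })
  }
  expr <- dat$expression
  metadata <- dat$metadata

  expr <- run_stage("preprocess", {
    if (!is.null(annotation)) {
      flt <- filter_to_annotation(expr, annotation)
      stats$retention_percent <- flt$retention_percent
      expr <- flt$matrix
    }
    if (isTRUE(config$preprocess$quantile_normalize))
      expr <- quantile_normalize(expr)
    center_genes(expr)
  })

  model <- run_stage("som", {
    cfg <- som_config(rows = config$som$rows, cols = config$som$cols,
                      n_epochs = config$som$n_epochs,
                      seed = stage_seed(config$seed, "som"))
    m <- train_som(expr, cfg)
    som_save(m, file.path(out, "som"))
    m
  })
  stats$final_quantization_error <- utils::tail(model$error_trace, 1)

  if (isTRUE(config$render$portraits)) run_stage("portraits", {
    up <- config$render$upscale
    for (s in sample_ids(model))
      render_portrait(sample_portrait(model, s), mode = "standard",
                      file.path(out, "portraits", paste0(s, ".png")),
                      upscale = up)
    groups <- unique(metadata[c("cultivar", "condition")])
    for (i in seq_len(nrow(groups))) {
      ids <- metadata$sample_id[
        metadata$cultivar == groups$cultivar[i] &
          metadata$condition == groups$condition[i]]
      key <- paste(groups$cultivar[i], groups$condition[i], sep = "_")
      render_portrait(
        group_mean_portrait(model, ids, subject = key),
        mode = "waterline",
        file.path(out, "portraits", paste0("group_", key, ".png")),
        upscale = up)
    }
  })

  spot_out <- run_stage("spots", {
    over <- summary_map(model, "overexpression")
    for (kind in c("overexpression", "underexpression", "variance")) {
      sm <- if (kind == "overexpression") over else summary_map(model, kind)
      utils::write.table(sm$grid, file.path(out, "spots",
                                            paste0(kind, "_map.tsv")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    spots <- label_spots(segment_spots(
      over, model,
      threshold_quantile = config$spots$threshold_quantile,
      min_size = config$spots$min_size))
    if (!length(spots)) stop("no spots found at the configured threshold")
    profiles <- spot_profiles(expr, spots)
    act <- spot_activation(profiles, config$spots$activation_fraction)
    write_spot_tables(spots, profiles, act, file.path(out, "spots"))
    gstats <- activation_statistics(act, metadata)
    utils::write.table(gstats, file.path(out, "spots",
                                         "activation_statistics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(spots = spots, profiles = profiles, activation = act,
         statistics = gstats)
  })
  stats$n_spots <- length(spot_out$spots)
  stats$spot_sizes <- stats::setNames(
    vapply(spot_out$spots, function(s) length(s$neurons), integer(1)),
    names(spot_out$spots))
  stats$spot_gene_counts <- stats::setNames(
    vapply(spot_out$spots, function(s) length(s$genes), integer(1)),
    names(spot_out$spots))
  stats$mean_active_spots <- mean(spot_out$activation$counts)

  if (ncol(expr$values) >= 3) {
    ss <- run_stage("sample_space", {
      cc <- sample_correlation_map(model)
      utils::write.table(cc, file.path(out, "sample_space/correlation.tsv"),
                         sep = "\t", quote = FALSE)
      cl <- cluster_count(cc, seq(config$sample_space$k_min,
                                  config$sample_space$k_max))
      ica <- independent_components(
        model, k = config$sample_space$n_components,
        seed = stage_seed(config$seed, "ica"), metadata = metadata)
      utils::write.table(
        data.frame(sample_id = rownames(ica$ic_coords), ica$ic_coords),
        file.path(out, "sample_space/ic_coords.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ica$factor_match,
                         file.path(out, "sample_space/factor_match.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pos <- sample_som(model, config$sample_space$grid_rows,
                        config$sample_space$grid_cols,
                        seed = stage_seed(config$seed, "sample_som"))
      utils::write.table(pos, file.path(out, "sample_space/sample_som.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(clusters = cl, ica = ica)
    })
    stats$cluster_k <- ss$clusters$k
    stats$factor_match <- ss$ica$factor_match
  } else {
    notes <- c(notes,
               "sample-space analysis skipped: fewer than 3 samples")
  }

  if (!is.null(collection)) run_stage("enrichment", {
    for (s in spot_out$spots) {
      res <- overrepresentation(s$genes, collection)
      utils::write.table(
        res, file.path(out, "enrichment",
                       paste0("spot_", s$label, "_overrepresentation.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }) else notes <- c(notes, "enrichment skipped: no gene-set collection")

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "report/manifest.json"))
  manifest <- list(
    package = "portraitSOM",
    config = unclass(config),
    artifacts = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(out, files))),
      stringsAsFactors = FALSE),
    stats = stats,
    notes = notes)
  jsonlite::write_json(manifest, file.path(out, "report/manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Summarize a pipeline run as a text report
#'
#' Reads a manifest (object or `manifest.json` path), checks that the
#' listed artifacts exist, and writes a plain-text report covering gene
#' retention, spot count/sizes/gene counts, per-group activation and the
#' IC factor-match table.
#'
#' @param manifest Manifest list from [run_pipeline()] or path to a
#'   `manifest.json`.
#' @param output_dir Run directory (inferred when `manifest` is a path).
#' @return Character vector of report lines (also written to
#'   `report/report.txt` when `output_dir` is known); missing artifacts are
#'   listed instead of summarized.
#' @export
summarize_run <- function(manifest, output_dir = NULL) {
  if (is.character(manifest)) {
    output_dir <- output_dir %||% dirname(dirname(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  lines <- c("portraitSOM run summary", "=======================")
  if (!is.null(output_dir)) {
    present <- file.exists(file.path(output_dir, manifest$artifacts$path))
    if (!all(present)) {
      lines <- c(lines, "INCOMPLETE RUN - missing artifacts:",
                 paste(" -", manifest$artifacts$path[!present]))
      return(lines)
    }
  }
  st <- manifest$stats
  if (!is.null(st$retention_percent))
    lines <- c(lines, sprintf("Annotation retention: %.2f%%",
                              st$retention_percent))
  lines <- c(lines,
             sprintf("Final quantization error: %.4g",
                     st$final_quantization_error),
             sprintf("Spot modules: %d", st$n_spots),
             sprintf("  %s: %d neurons, %d genes",
                     names(st$spot_sizes), unlist(st$spot_sizes),
                     unlist(st$spot_gene_counts)),
             sprintf("Mean active spots per sample portrait: %.2f",
                     st$mean_active_spots))
  if (!is.null(st$cluster_k)) {
    lines <- c(lines, sprintf("Selected sample clusters: %d", st$cluster_k),
               "Independent component factor matches:")
    fm <- st$factor_match
    lines <- c(lines, sprintf("  %s -> %s (r = %.3f)",
                              fm$component, fm$factor, fm$r))
  }
  if (length(manifest$notes))
    lines <- c(lines, paste("Note:", unlist(manifest$notes)))
  if (!is.null(output_dir))
    writeLines(lines, file.path(output_dir, "report/report.txt"))
  lines
}
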