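#' Configuration of a full analysis run
#'
#' Exactly one of `input_path` (a fixation TSV/CSV on disk) or `sim_config`
#' (a [simulation_config()] generating the data) must be given.
#'
#' @param input_path Path to a fixation table, or `NULL`.
#' @param dialect File dialect for `input_path`.
#' @param sim_config A [simulation_config()], or `NULL`.
#' @param geometry A [screen_geometry()].
#' @param grid A [bin_grid()].
#' @param bounds Picture rectangle for [filter_out_of_bounds()]; `NULL` =
#'   full screen.
#' @param alpha Cluster-forming threshold.
#' @param B Number of permutations.
#' @param scheme Permutation scheme label.
#' @param term Tested design term for the temporal analysis.
#' @param posthoc_family Contrast family for post-hocs.
#' @param seed Seed for every random stage.
#' @param output_dir Directory for TSV outputs, or `NULL` to skip writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_path = NULL, dialect = "tsv", sim_config = NULL,
                       geometry = screen_geometry(), grid = bin_grid(),
                       bounds = NULL, alpha = 0.05, B = 5000,
                       scheme = "within_participant_cells",
                       term = "interaction",
                       posthoc_family = "timepoint_within_stimulation",
                       seed = 1, output_dir = NULL) {
  if (is.null(input_path) == is.null(sim_config)) {
    stop("exactly one of input_path and sim_config must be set", call. = FALSE)
  }
  if (!is.null(input_path) && !file.exists(input_path)) {
    stop("input file not found: ", input_path, call. = FALSE)
  }
  structure(list(input_path = input_path, dialect = dialect,
                 sim_config = sim_config, geometry = geometry, grid = grid,
                 bounds = bounds, alpha = alpha, B = B, scheme = scheme,
                 term = term, posthoc_family = posthoc_family, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; `geometry`,
#' `grid` and `effect`/`simulate` blocks are expanded into their
#' constructors. Keys not given keep the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("input_path", "dialect", "alpha", "B", "scheme", "term",
                "posthoc_family", "seed", "output_dir")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$geometry)) args$geometry <- do.call(screen_geometry, y$geometry)
  if (!is.null(y$grid)) args$grid <- do.call(bin_grid, y$grid)
  if (!is.null(y$bounds)) args$bounds <- as.numeric(y$bounds)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$effect)) sim$effect <- do.call(injected_effect, sim$effect)
    if (!is.null(args$geometry)) sim$geometry <- args$geometry
    if (!is.null(args$grid)) sim$grid <- args$grid
    args$sim_config <- do.call(simulation_config, sim)
  }
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full spatio-temporal analysis pipeline
#'
#' Reproduces the analysis order of the study design: ingest (or simulate)
#' fixations, exclude fixations outside the picture area, model the
#' average gaze position (pre-post and baseline-covariate mixed models),
#' then run the temporal cluster-mass permutation analysis on the 100-ms
#' bin series, and finally fit the window post-hoc mixed model for every
#' cluster with `p_perm < alpha`. Identical config and seed yield an
#' identical bundle.
#'
#' @param config A [run_config()].
#' @return A list of class `gaze_pipeline_bundle` with elements
#'   `exclusion`, `fixation_summary`, `cells`, `prepost`, `baseline`,
#'   `binstats`, `clusters`, `permutation`, `window_results`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- stage("ingest", {
    if (!is.null(config$input_path)) {
      read_fixation_table(config$input_path, dialect = config$dialect,
                          geometry = config$geometry)
    } else {
      simulate_dataset(config$sim_config)
    }
  })
  filtered <- stage("exclusion", filter_out_of_bounds(table, config$bounds))
  fsum <- stage("fixation_summary", fixation_summary(filtered$kept))
  cells <- stage("average_gaze", average_gaze_table(filtered$kept))
  prepost <- stage("prepost_model", fit_prepost_model(
    cells, posthoc_family = config$posthoc_family))
  baseline <- stage("baseline_model", fit_baseline_model(cells))
  series <- stage("binning", bin_fixations(filtered$kept, config$grid))
  perm <- stage("permutation", permutation_null(
    series, B = config$B, seed = config$seed, scheme = config$scheme,
    term = config$term, alpha = config$alpha))
  window_results <- stage("window_posthoc", {
    sig <- perm$clusters[!is.na(perm$clusters$p_perm) &
                           perm$clusters$p_perm < config$alpha, , drop = FALSE]
    lapply(seq_len(nrow(sig)), function(i) {
      window_posthoc(filtered$kept,
                     c(sig$start_ms[i], sig$end_ms[i]), config$grid)
    })
  })
  bundle <- structure(list(exclusion = list(
    excluded_fraction = filtered$excluded_fraction,
    n_kept = nrow(filtered$kept)),
    fixation_summary = fsum, cells = cells, prepost = prepost,
    baseline = baseline, binstats = perm$binstats,
    clusters = perm$clusters, permutation = perm,
    window_results = window_results, config = config),
    class = "gaze_pipeline_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

tsv_write <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
}

#' Write the pipeline bundle as TSV tables plus a plain-text summary
#'
#' Emits `cells.tsv`, `binstats.tsv`, `clusters.tsv`, model term tables,
#' and `summary.txt` into `dir`. Cluster rows report both pixel and degree
#' units using the linear conversion.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gaze_pipeline_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- attr(bundle$cells, "geometry")
  cells <- as.data.frame(bundle$cells)
  cells$mean_x_deg <- px_to_deg(cells$mean_x, g)
  tsv_write(cells, file.path(dir, "cells.tsv"))
  tsv_write(bundle$binstats, file.path(dir, "binstats.tsv"))
  cl <- as.data.frame(bundle$clusters)
  if (nrow(cl) > 0) {
    cl$scheme <- bundle$permutation$scheme
    cl$B <- bundle$permutation$B
    cl$seed <- bundle$permutation$seed
  }
  tsv_write(cl, file.path(dir, "clusters.tsv"))
  tsv_write(bundle$prepost$anova, file.path(dir, "prepost_anova.tsv"))
  tsv_write(bundle$baseline$anova, file.path(dir, "baseline_anova.tsv"))
  if (!is.null(bundle$prepost$posthoc)) {
    tsv_write(bundle$prepost$posthoc, file.path(dir, "prepost_posthoc.tsv"))
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("excluded fraction outside picture area: %.6f",
            bundle$exclusion$excluded_fraction),
    sprintf("fixations analysed: %d", bundle$exclusion$n_kept),
    sprintf("mean fixations per image: %.2f (SD %.2f, range %d-%d)",
            bundle$fixation_summary$per_picture_stats$mean,
            bundle$fixation_summary$per_picture_stats$sd,
            bundle$fixation_summary$per_picture_stats$range[1],
            bundle$fixation_summary$per_picture_stats$range[2]),
    sprintf("clusters (term %s, alpha %g, B %d, seed %d, scheme %s): %d",
            bundle$permutation$term, bundle$permutation$alpha,
            bundle$permutation$B, bundle$permutation$seed,
            bundle$permutation$scheme, nrow(bundle$clusters))),
    con)
  if (nrow(bundle$clusters) > 0) {
    writeLines(apply(bundle$clusters, 1, function(r) {
      sprintf("  cluster %s-%s ms, mass %.3f, p_perm %.4g",
              r[["start_ms"]], r[["end_ms"]], as.numeric(r[["mass"]]),
              as.numeric(r[["p_perm"]]))
    }), con)
  }
  invisible(dir)
}
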