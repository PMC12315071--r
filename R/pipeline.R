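## End-to-end orchestration: simulate (or read) -> survey metrics ->
## stability decomposition -> treatment models -> multigroup pSEM ->
## cascading effects, with CSV persistence at every stage boundary.

#' Default taxon-to-group map
#'
#' @param taxa Taxon table (default [default_taxa()]).
#' @return A two-column `data.frame` (`taxon_id`, `group`).
#' @export
default_group_map <- function(taxa = default_taxa()) {
  taxa[, c("taxon_id", "group")]
}

#' Assemble the tile-level analysis table
#'
#' Merges the design, time-averaged community summaries and stability
#' profiles, drops degenerate tiles, and adds the z-scored analysis
#' columns the causal model uses (`het`, `emersion`, `richness`,
#' `dominant`, `consumers`, `native`, `ephemerals`, `pop_stability`,
#' `asynchrony`, `comp_stability`, `temp_stability`).  Temporal and
#' population stability are log-transformed before z-scoring (both are
#' positive ratio-scale quantities).
#'
#' @param design A `tile_design`.
#' @param summaries Output of [summarise_tiles()].
#' @param stability Output of [stability_profiles()].
#' @return A merged `data.frame`, one row per non-degenerate tile.
#' @export
tile_table <- function(design, summaries, stability) {
  tab <- merge(merge(as.data.frame(design), summaries, by = "tile_id"),
               stability, by = "tile_id")
  n_deg <- sum(tab$degenerate)
  if (n_deg > 0) {
    message(sprintf("tile_table: dropping %d degenerate tile(s)", n_deg))
    tab <- tab[!tab$degenerate, , drop = FALSE]
  }
  tab$het <- zscore(tab$heterogeneity)
  tab$emersion <- zscore(tab$emersion_ratio)
  tab$richness <- zscore(tab$mean_richness)
  tab$dominant <- zscore(tab$cover_dominant_nonnative)
  tab$consumers <- zscore(tab$cover_consumer)
  tab$native <- zscore(tab$cover_native_barnacle)
  tab$ephemerals <- zscore(tab$cover_ephemeral_alga)
  tab$pop_stability <- zscore(log(tab$PS))
  tab$asynchrony <- zscore(stats::qlogis(pmin(pmax(tab$asynchrony, 1e-4), 1 - 1e-4)))
  tab$comp_stability <- zscore(tab$CS)
  tab$temp_stability <- zscore(log(tab$TS))
  rownames(tab) <- NULL
  tab
}

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate data) or `"csv"` (read a design
#'   and cover table written earlier).
#' @param synth A [synth_params()] object (synthetic mode).
#' @param design_args List of arguments to [generate_design()].
#' @param csv_paths Named list with `design` and `covers` paths (csv
#'   mode).
#' @param group_map Taxon-to-group map (default from the synth taxa).
#' @param sem_spec A [psem_spec()] (default [default_sem_spec()]).
#' @param lmm_transforms Optional named transforms per response.
#' @param alpha Significance level (default 0.05).
#' @param n_boot Bootstrap replicates for cascade intervals (default
#'   200; set to 0 to skip the bootstrap).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for stage CSVs, or `NULL` to keep
#'   results in memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       synth = synth_params(),
                       design_args = list(n_transects = 5L,
                                          stations_per_transect = 7L,
                                          emersion_range = c(0.1, 0.9)),
                       csv_paths = NULL,
                       group_map = NULL,
                       sem_spec = default_sem_spec(),
                       lmm_transforms = NULL,
                       alpha = 0.05, n_boot = 200L, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" &&
      (is.null(csv_paths) || !all(c("design", "covers") %in%
                                    names(csv_paths))))
    stop_("csv mode needs csv_paths = list(design = ..., covers = ...)")
  if (is.null(group_map)) group_map <- default_group_map(synth$taxa)
  structure(list(mode = mode, synth = synth, design_args = design_args,
                 csv_paths = csv_paths, group_map = group_map,
                 sem_spec = sem_spec, lmm_transforms = lmm_transforms,
                 alpha = alpha, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [run_config()] arguments;
#' `synth` and `design` sub-maps are passed to [synth_params()] and
#' [generate_design()].  Keys not given fall back to the defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$path_coefficients))
    synth_args$path_coefficients <- as.list(synth_args$path_coefficients)
  if (!is.null(synth_args$seasonal_amplitude))
    synth_args$seasonal_amplitude <- unlist(synth_args$seasonal_amplitude)
  synth <- do.call(synth_params, synth_args)
  design_args <- y$design %||% list()
  if (!is.null(design_args$emersion_range))
    design_args$emersion_range <- as.numeric(design_args$emersion_range)
  da <- list(n_transects = design_args$n_transects %||% 5L,
             stations_per_transect = design_args$stations_per_transect %||% 7L,
             emersion_range = design_args$emersion_range %||% c(0.1, 0.9))
  sem <- if (!is.null(y$sem))
    psem_spec(y$sem$edges, correlated = y$sem$correlated %||% character(),
              exogenous = y$sem$exogenous %||% character(),
              group = y$sem$group) else default_sem_spec()
  run_config(mode = y$mode %||% "synthetic", synth = synth,
             design_args = da,
             csv_paths = y$csv_paths,
             sem_spec = sem,
             lmm_transforms = unlist(y$lmm_transforms),
             alpha = y$alpha %||% 0.05,
             n_boot = y$n_boot %||% 200L,
             seed = seed %||% y$seed %||% 1L,
             out_dir = y$out_dir)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> survey metrics -> stability decomposition
#' -> treatment mixed models -> multigroup piecewise SEM -> cascading
#' effects (with optional bootstrap intervals), persisting stage CSVs
#' when `out_dir` is set.  Reruns with an identical configuration are
#' bit-identical.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A list of class `run_report`: `design`, `covers`,
#'   `tile_summary`, `stability`, `tiles`, `lmm`, `sem` (a
#'   [psem()] fit), `cascades`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop_("config must be a run_config")
  seed <- config$seed

  if (config$mode == "synthetic") {
    design <- do.call(generate_design,
                      c(config$design_args, list(seed = child_seed(seed, 1L))))
    synth <- config$synth
    synth$seed <- child_seed(seed, 2L)
    covers <- simulate_covers(design, synth)
  } else {
    design <- read_design_csv(config$csv_paths$design)
    covers <- read_cover_csv(config$csv_paths$covers)
  }

  summaries <- summarise_tiles(covers, config$group_map)
  stability <- suppressMessages(stability_profiles(covers))
  tiles <- tile_table(design, summaries, stability)

  responses <- c("mean_richness", "mean_evenness",
                 "cover_dominant_nonnative", "cover_consumer",
                 "cover_native_barnacle", "cover_ephemeral_alga",
                 "TS", "CS", "PS", "asynchrony", "SA")
  responses <- intersect(responses, names(tiles))
  lmm_tab <- suppressWarnings(
    lmm_table(tiles, responses, transforms = config$lmm_transforms))

  sem <- suppressWarnings(
    psem(config$sem_spec, tiles, group = config$sem_spec$group,
         alpha = config$alpha))

  targets <- intersect(c("pop_stability", "asynchrony", "comp_stability",
                         "temp_stability"), config$sem_spec$nodes)
  casc <- if (config$n_boot > 0L) {
    suppressWarnings(bootstrap_cascades(
      config$sem_spec, tiles, source = "het", targets = targets,
      n_boot = max(config$n_boot, 100L), seed = child_seed(seed, 3L),
      group = config$sem_spec$group, alpha = config$alpha))
  } else {
    do.call(rbind, lapply(targets, function(tg)
      cascade_effect(sem, "het", tg)))
  }

  prov <- data.frame(key = c("seed", "config_hash", "mode", "n_tiles",
                             "n_singular_fits"),
                     value = c(seed, config_hash(config), config$mode,
                               nrow(tiles), sem$n_singular),
                     stringsAsFactors = FALSE)

  report <- structure(list(design = design, covers = covers,
                           tile_summary = summaries, stability = stability,
                           tiles = tiles, lmm = lmm_tab, sem = sem,
                           cascades = casc, provenance = prov),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  print(x$provenance, row.names = FALSE)
  print(x$sem)
  cat("\nCascading effects of heterogeneity:\n")
  print(x$cascades, digits = 3, row.names = FALSE)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(as.data.frame(report$design), "design")
  wr(as.data.frame(report$covers), "covers")
  wr(report$tile_summary, "tile_summary")
  wr(report$stability, "stability")
  wr(report$tiles, "tile_table")
  wr(report$lmm, "lmm_coefficients")
  wr(report$sem$edges, "sem_edges")
  if (!is.null(report$sem$claims)) wr(report$sem$claims, "sem_claims")
  if (!is.null(report$sem$C))
    wr(data.frame(C = report$sem$C$C, df = report$sem$C$df,
                  p = report$sem$C$p), "sem_global")
  wr(as.data.frame(report$cascades), "cascades")
  wr(report$provenance, "provenance")
  invisible(out_dir)
}

#' Read a tile design CSV
#' @param path File path.
#' @return A `tile_design` data.frame.
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(d, c("tile_id", "station_id", "transect_id", "heterogeneity",
                   "emersion_ratio", "zone"), "design CSV")
  d$zone <- factor(d$zone, levels = c("low", "mid", "high"))
  class(d) <- c("tile_design", "data.frame")
  d
}

#' Read a cover table CSV
#' @param path File path.
#' @return A `cover_table` data.frame.
#' @export
read_cover_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(d, c("tile_id", "census_index", "taxon_id", "cover"),
              "cover CSV")
  if (any(d$cover < 0 | d$cover > 100))
    stop_("cover values must lie in [0, 100]")
  class(d) <- c("cover_table", "data.frame")
  d
}
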