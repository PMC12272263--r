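#' Build a full run configuration
#'
#' Collects every tunable of the synthetic experiment with the documented
#' defaults: seed threshold 0.5 (>50% of field maximum), sparsity 0.01
#' (top 1%), EFSI fraction 0.5, a 6 x 6 location grid with 12 orientations,
#' human-like run length 1200 timepoints at TR 0.72 s (macaque-like: 1600
#' at TR 2.0 s). Unknown keys in `...` are rejected.
#'
#' @param species `"human"` or `"macaque"`.
#' @param ... Overrides for any configuration key; see Details.
#' @details Keys: `species`, `resolution`, `coil_radius`, `coil_segments`,
#'   `dIdt`, `n_rows`, `n_cols`, `orientations`, `n_timepoints`, `TR`,
#'   `amplitudes`, `sigma`, `rho`, `bandpass`, `band`, `seed_fraction`,
#'   `sparsity`, `efsi_fraction`, `seed_normalize`, `use_abs`, `metric`,
#'   `seed`, `output_dir`, `write_fields`, `write_connectivity`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(species = c("human", "macaque"), ...) {
  species <- match.arg(species)
  cfg <- list(
    species = species,
    resolution = 0.35,
    coil_radius = 35, coil_segments = 64L, dIdt = 1e8,
    n_rows = 6L, n_cols = 6L, orientations = seq(0, 165, by = 15),
    n_timepoints = if (species == "human") 1200L else 1600L,
    TR = if (species == "human") 0.72 else 2.0,
    amplitudes = 2, sigma = 1, rho = 0.3,
    bandpass = FALSE, band = c(0.01, 0.1),
    seed_fraction = 0.5, sparsity = 0.01, efsi_fraction = 0.5,
    seed_normalize = "sum", use_abs = FALSE, metric = "percent",
    seed = 1L, output_dir = NULL,
    write_fields = FALSE, write_connectivity = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_input("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  for (f in c("seed_fraction", "sparsity", "efsi_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop_input("configuration key '", f, "' must lie strictly in (0, 1)")
  }
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop_input("configuration key 'seed' must be a non-negative integer")
  if (!cfg$species %in% c("human", "macaque"))
    stop_input("configuration key 'species' must be 'human' or 'macaque'")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Flat YAML keys as in [run_config()]; unknown keys are rejected with the
#' offending key named.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  species <- y$species %||% "human"
  y$species <- NULL
  do.call(run_config, c(list(species = species), y))
}

# One global seed expands into per-stage child seeds by fixed offsets so
# that, e.g., changing the fMRI realisation does not perturb the mesh.
stage_seed <- function(seed, stage) {
  off <- c(mesh = 11L, parcellation = 23L, fmri = 37L)
  as.integer(seed) + off[[stage]]
}

#' Run the full synthetic targeting experiment
#'
#' Executes every stage in order: folded-patch synthesis, parcellation,
#' grid enumeration, per-placement primary fields, resting-state
#' simulation, seed extraction and weighted series, the shared mean
#' covariate, partial-correlation maps, sparsification + network
#' assignment, zone / orientation-window summaries, and the EFSI map.
#' With an output directory the interchange artifacts and a JSON
#' provenance record (config, seed, package version) are written;
#' identical config + seed reproduce identical outputs.
#'
#' @param config A [run_config()] (or the species name for defaults).
#' @param output_dir Output directory (overrides `config$output_dir`);
#'   `NULL` keeps everything in memory.
#' @param progress Print per-stage counts (placements, seed sizes, kept
#'   vertices) as the run proceeds.
#' @return List of class `pipeline_run`: `config`, `mesh`, `parcellation`,
#'   `placements`, `fields` (V x 432 matrix), `ts`, `seed_series`
#'   (placements x T), `covariate`, `conn` (V x 432), `targets`
#'   (`targeting_result` table), `summary`, `efsi`.
#' @export
run_pipeline <- function(config = run_config("human"), output_dir = NULL,
                         progress = FALSE) {
  if (is.character(config)) config <- run_config(config)
  validate_config(config)
  say <- function(...) if (progress) message(sprintf(...))

  profile <- species_profile(config$species)
  mesh <- make_folded_sheet(profile, config$resolution,
                            stage_seed(config$seed, "mesh"))
  parc <- make_parcellation(mesh, config$species,
                            stage_seed(config$seed, "parcellation"))
  say("mesh: %d vertices", n_vertices(mesh))

  grid <- build_grid(profile, mesh, config$n_rows, config$n_cols,
                     config$orientations)
  say("grid: %d placements", nrow(grid))

  coil <- coil_model(config$coil_radius, config$coil_segments, config$dIdt)
  fields <- vapply(seq_len(nrow(grid)), function(i)
    as.numeric(primary_efield(coil, grid[i, ], mesh)),
    numeric(n_vertices(mesh)))

  model <- network_signal_model(config$amplitudes, config$sigma, config$rho,
                                config$bandpass, config$band)
  ts <- simulate_rfmri(parc, model, config$n_timepoints, config$TR,
                       stage_seed(config$seed, "fmri"))

  seeds <- lapply(seq_len(ncol(fields)), function(i)
    extract_seed(fields[, i], config$seed_fraction, config$seed_normalize))
  say("seed sizes: median %d vertices",
      as.integer(stats::median(vapply(seeds, function(s) length(s$indices), 1L))))
  seed_series <- t(vapply(seeds, weighted_timeseries, ts = ts,
                          numeric(ncol(ts))))
  covariate <- make_covariate(asplit(seed_series, 1))

  conn <- vapply(seq_len(nrow(seed_series)), function(i)
    as.numeric(partial_corr_map(seed_series[i, ], ts, covariate)),
    numeric(n_vertices(mesh)))

  conn_maps <- lapply(seq_len(ncol(conn)), function(i)
    structure(conn[, i], class = "connectivity_map"))
  targets <- assign_targets(conn_maps, grid, parc, config$sparsity,
                            config$use_abs, config$metric)
  say("kept vertices per map: %d", targets$n_kept[1])
  summary <- summarize_targeting(targets)
  efsi_map <- efsi(fields, config$efsi_fraction)

  run <- structure(list(
    config = config, mesh = mesh, parcellation = parc, placements = grid,
    fields = fields, ts = ts, seed_series = seed_series,
    covariate = covariate, conn = conn, targets = targets,
    summary = summary, efsi = efsi_map
  ), class = "pipeline_run")

  out <- output_dir %||% config$output_dir
  if (!is.null(out)) write_run(run, out)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run (%s): %d vertices, %d placements\n",
              x$config$species, n_vertices(x$mesh), nrow(x$placements)))
  print(x$summary)
  invisible(x)
}

#' Write pipeline artifacts to a run directory
#'
#' Emits the plain-text interchange artifacts: `mesh.ply`,
#' `parcellation.tsv`, `placements.tsv`, `targeting_results.tsv`, the three
#' summary tables, `efsi.tsv` and `provenance.json`; per-placement field
#' and connectivity matrices are written only when the config flags
#' `write_fields` / `write_connectivity` are set (they are large).
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_ply(run$mesh, fp("mesh.ply"))
  write_parcellation(run$parcellation, fp("parcellation.tsv"))
  write_placements(run$placements, fp("placements.tsv"))
  utils::write.table(run$targets, fp("targeting_results.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$summary$overall, fp("summary_overall.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$summary$by_zone, fp("summary_by_zone.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$summary$by_zone_window,
                     fp("summary_by_zone_window.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_metric(run$efsi, fp("efsi.tsv"), "efsi_percent")
  if (isTRUE(run$config$write_fields))
    utils::write.table(run$fields, fp("fields.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  if (isTRUE(run$config$write_connectivity))
    utils::write.table(run$conn, fp("connectivity.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  prov <- list(
    package = "tmstarget",
    version = as.character(utils::packageVersion("tmstarget")),
    seed = run$config$seed,
    config = unclass(run$config)
  )
  jsonlite::write_json(prov, fp("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
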