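#' Packaged experiment configurations
#'
#' Returns the default configuration for one of the packaged protocols.
#' The defaults encode the study conditions: channel grids, probe sets,
#' stimulus durations, parameter-table column, repeat counts and the
#' front-end operating point. Every protocol accepts overrides through its
#' `cfg` argument, and [load_config()] merges a YAML/JSON file on top of
#' these defaults.
#'
#' Common keys: `grid` (channel values), `n_freq` (filterbank channels),
#' `settle_ms` (pre-stimulus settling time during which tonic populations
#' reach steady state; analyses start after it), `tail_ms` (post-stimulus
#' margin), `dt` (integration step, ms), `rate_scale` (IC ensemble rate at
#' the loudest tile, spikes/s), `seed`, `window`/`step` (PSTH, ms),
#' `fast`/`n`/`n_fast` (repeat counts), `store_sims` (keep rasters).
#'
#' @param id experiment id: `"lee"`, `"atiani_a"`, `"atiani_b"`,
#'   `"fritz"`, `"cocktail_spatial"`, `"separation_sweep"`,
#'   `"monaural_f0"`.
#' @return named list of defaults.
#' @export
experiment_config <- function(id = c("lee", "atiani_a", "atiani_b",
                                     "fritz", "cocktail_spatial",
                                     "separation_sweep", "monaural_f0")) {
  id <- match.arg(id)
  common <- list(n_freq = 64L, settle_ms = 20, tail_ms = 40, dt = 0.05,
                 seed = 1L, window = 5, step = 1, store_sims = FALSE)
  spectral <- c(common, list(stim_ms = 100, probe_stride = 1L,
                             rate_scale = 800, f_B = NULL, f_T = NULL))
  cocktail <- c(common, list(token_ms = 300, gap_ms = 100,
                             rate_scale = 800, f0_male = 115,
                             f0_female = 220, n = 20L, n_fast = 5L,
                             fast = FALSE, step = 2, corr_skip_ms = 0))
  cocktail$tail_ms <- 30
  cfg <- switch(id,
    lee = c(common, list(grid = seq(-90, 90, by = 10),
                         probes = seq(-80, 80, by = 10), stim_ms = 80,
                         rate_scale = 60, attended = 30)),
    atiani_a = c(spectral, list(target_offset = 500)),
    atiani_b = c(spectral, list(target_offset = 5000)),
    fritz = c(spectral, list(target_offset = 1200)),
    cocktail_spatial = c(cocktail,
                         list(grid = seq(-90, 90, by = 45),
                              male_az = 0, female_az = 90)),
    separation_sweep = c(cocktail,
                         list(grid = seq(0, 90, by = 15),
                              separations = seq(15, 90, by = 15))),
    monaural_f0 = c(common, list(token_ms = 300, rate_scale = 1200,
                                 compress = 0.4, f0_male = 115,
                                 f0_female = 220, n = 20L, n_fast = 5L,
                                 fast = FALSE)))
  cfg
}

#' Load an experiment configuration file
#'
#' Reads a YAML (or JSON) file with an `experiment` key naming the
#' protocol and an optional `config` section of overrides, and merges it
#' over the packaged defaults ([experiment_config()]). Unknown keys are
#' rejected with the offending name; unknown experiment ids are rejected
#' naming the valid set.
#'
#' @param path configuration file.
#' @return list with `experiment` (id) and `config` (merged overrides,
#'   ready to pass as `cfg`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(raw$experiment))
    stop("config must name an 'experiment'")
  ids <- eval(formals(experiment_config)$id)
  if (!raw$experiment %in% ids)
    stop("unknown experiment '", raw$experiment, "'; expected one of: ",
         paste(ids, collapse = ", "))
  defaults <- experiment_config(raw$experiment)
  overrides <- raw$config %||% list()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys in ", path, ": ",
         paste(paste0("config/", unknown), collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  list(experiment = raw$experiment, config = cfg)
}

#' Run a packaged experiment by id
#'
#' Dispatches to the matching `run_*` protocol with the supplied config
#' overrides.
#' @param id experiment id (see [experiment_config()]).
#' @param cfg config overrides.
#' @return the protocol's `aim_experiment`.
#' @export
run_experiment <- function(id, cfg = list()) {
  switch(id,
         lee = run_lee(cfg = cfg),
         atiani_a = run_atiani("a", cfg = cfg),
         atiani_b = run_atiani("b", cfg = cfg),
         fritz = run_fritz(cfg = cfg),
         cocktail_spatial = run_cocktail_spatial(cfg = cfg),
         separation_sweep = run_separation_sweep(cfg = cfg),
         monaural_f0 = run_monaural_f0(cfg = cfg),
         stop("unknown experiment '", id, "'"))
}

#' Write an experiment's manifest and metrics
#'
#' Serialises the manifest (config snapshot, seed, version, timestamp) and
#' the scalar/tabular metrics of an `aim_experiment` as JSON next to each
#' other, sufficient to re-execute the run exactly.
#'
#' @param exp an `aim_experiment`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(exp$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  metrics <- exp[setdiff(names(exp),
                         c("manifest", "sims", "rasters", "surfaces"))]
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", force = TRUE)
  if (!is.null(exp$surfaces))
    for (nm in names(exp$surfaces)) {
      s <- exp$surfaces[[nm]]
      write_rate_matrix(s$rate, s$time, s$probe_values,
                        file.path(dir, paste0("surface_", nm, ".csv")))
    }
  invisible(dir)
}
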