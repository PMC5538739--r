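#' Default run configuration
#'
#' One structured configuration drives the end-to-end pipeline: the climate
#' envelope, crop and soil parameters, the sowing-day grid and number of
#' historical weather years used to initialise the knowledge pool, the
#' still-good-yield threshold, the scenario set scored against the pool, and
#' all RNG seeds. The defaults reproduce the package's reference experiment:
#' a 46-day sowing window (DOY 283-328) over 30 historical weather years
#' (1,380 what-if seasons), sgy 69.17 dt/ha, and ten 20-year future weather
#' realizations scored against the resulting pool.
#'
#' @param climate list of [climate_params()] overrides.
#' @param crop list of [crop_params()] overrides.
#' @param soil list of [soil_profile()] overrides.
#' @param sowing_doys sowing-day grid for the historical what-if runs.
#' @param history_years number of historical weather years to generate; the
#'   last year only completes the final seasons, so `history_years - 1`
#'   sowing years enter the grid.
#' @param sgy still-good-yield threshold, dt/ha.
#' @param scenario_doy sowing day used for scenario seasons.
#' @param scenarios data frame with columns `name`, `delta_temp`,
#'   `precip_factor`, `n_years`; default: ten same-climate realizations of
#'   20 future years each.
#' @param seed master seed; scenario seeds are derived as `seed + 1000 * i`.
#' @param include_bbch score BBCH as an observed parameter.
#' @return a `run_config` list.
#' @export
run_config <- function(climate = list(), crop = list(), soil = list(),
                       sowing_doys = 283:328, history_years = 31,
                       sgy = 69.17, scenario_doy = 290,
                       scenarios = NULL, seed = 1, include_bbch = TRUE) {
  if (is.null(scenarios)) {
    scenarios <- data.frame(name = sprintf("%02d", seq(0, 99, by = 11)),
                            delta_temp = 0, precip_factor = 1, n_years = 20,
                            stringsAsFactors = FALSE)
  }
  need <- c("name", "delta_temp", "precip_factor", "n_years")
  if (!all(need %in% names(scenarios))) {
    stop_invalid("run_config: scenarios needs columns ", paste(need, collapse = ", "))
  }
  structure(list(
    climate = do.call(climate_params, climate),
    crop = do.call(crop_params, crop),
    soil = do.call(soil_profile, soil),
    sowing_doys = as.integer(sowing_doys),
    history_years = as.integer(history_years),
    sgy = sgy, scenario_doy = as.integer(scenario_doy),
    scenarios = scenarios, seed = as.integer(seed),
    include_bbch = isTRUE(include_bbch)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any subset of the [run_config()] arguments may appear in the file;
#' omitted entries keep their defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("climate", "crop", "soil")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$crop) && !is.null(y$crop$tt_stages)) {
    args$crop$tt_stages <- unlist(y$crop$tt_stages)
  }
  for (f in c("sowing_doys", "history_years", "sgy", "scenario_doy",
              "seed", "include_bbch")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$scenarios)) {
    args$scenarios <- do.call(rbind, lapply(y$scenarios, function(s) {
      as.data.frame(s, stringsAsFactors = FALSE)
    }))
  }
  do.call(run_config, args)
}

#' Run the full pipeline: history grid, pool, scenario scoring, summary
#'
#' Generates the historical weather series, simulates the sowing-day grid,
#' initialises the knowledge pool at the configured still-good-yield
#' threshold, then generates and scores every scenario's future seasons
#' against that pool and summarises them into the comparative
#' mean-standard-deviation table. All artifacts are written under `outdir`:
#' `weather.csv`, `pool.json`, `ranges.csv`, `scores_<scenario>.csv`,
#' `summary.csv` and a `manifest.json` recording seeds, grid, sgy and the
#' quantile convention. Runs are reproducible: identical configuration and
#' seeds give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `pool`, `scores` (named list of data
#'   frames), `summary` and `paths`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("ars_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  spec <- op_spec(config$soil, include_bbch = config$include_bbch)

  say("generating ", config$history_years, " historical weather years (seed ",
      config$seed, ")")
  weather <- generate_weather(config$climate, config$history_years, config$seed)
  write_weather(weather, file.path(outdir, "weather.csv"))

  say("simulating grid: ", length(config$sowing_doys), " sowing DOYs x ",
      config$history_years - 1L, " years")
  traces <- build_grid(weather, config$sowing_doys, config$crop, config$soil)
  pool <- build_pool(traces, config$sgy, spec)
  write_pool(pool, file.path(outdir, "pool.json"))
  write_csv_strict(ranges_report(pool), file.path(outdir, "ranges.csv"))
  say("pool: ", pool$n_kept, "/", pool$n_traces, " seasons at or above sgy ",
      config$sgy, " dt/ha")

  scores <- list()
  scen_list <- list()
  for (i in seq_len(nrow(config$scenarios))) {
    sc <- config$scenarios[i, ]
    seed_i <- config$seed + 1000L * i
    params_i <- climate_shift(config$climate, sc$delta_temp, sc$precip_factor)
    w_i <- generate_weather(params_i, sc$n_years + 1L, seed_i,
                            station_label = sc$name)
    yrs <- sort(unique(w_i$year))
    tr_i <- lapply(yrs[-length(yrs)], function(y) {
      simulate_season(w_i, y, config$scenario_doy, config$crop, config$soil)
    })
    s_i <- score_seasons(tr_i, pool)
    write_scores(s_i, file.path(outdir, paste0("scores_", sc$name, ".csv")))
    scores[[sc$name]] <- s_i
    scen_list[[sc$name]] <- list(yields = s_i$yield, ars = s_i$total)
    say("scenario ", sc$name, ": mean yield ",
        sprintf("%.1f", mean(s_i$yield)), " dt/ha, mean ARS ",
        sprintf("%.2f", mean(s_i$total)))
  }

  summary_tab <- compare_scenarios(scen_list, config$sgy)
  write_csv_strict(summary_tab, file.path(outdir, "summary.csv"))

  manifest <- list(
    package = "arscore",
    version = as.character(utils::packageVersion("arscore")),
    seed = config$seed,
    sgy = config$sgy,
    sowing_doys = range(config$sowing_doys),
    n_doys = length(config$sowing_doys),
    history_years = config$history_years,
    n_traces = pool$n_traces,
    n_kept = pool$n_kept,
    quantile_convention = pool$provenance$quantile_type,
    scenario_seeds = config$seed + 1000L * seq_len(nrow(config$scenarios))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(pool = pool, scores = scores, summary = summary_tab,
                 paths = list(outdir = outdir)))
}

#' Build a deterministic miniature dataset for tests and examples
#'
#' Writes a small weather series, a tiny sowing grid with its traces, the
#' resulting knowledge pool and a synthetic 73-record survey (13 of them
#' highly sensitive) under `dir`. All content is a pure function of `seed`.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("ars_fix_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  climate <- climate_params()
  crop <- crop_params()
  soil <- soil_profile()

  weather <- generate_weather(climate, 6, seed, station_label = "fixture")
  write_weather(weather, file.path(dir, "weather.csv"))

  traces <- build_grid(weather, c(285, 300, 315), crop, soil)
  write_traces(traces, file.path(dir, "traces"))

  # sgy low enough that the tiny grid keeps >= 4 seasons per (OP, parameter)
  pool <- build_pool(traces, sgy = 40, spec = op_spec(soil))
  write_pool(pool, file.path(dir, "pool.json"))

  survey <- with_seed(seed, synth_survey(n = 73, n_high = 13, avy_region = 71.4))
  write_csv_strict(survey, file.path(dir, "survey.csv"))

  invisible(list(weather = weather, traces = traces, pool = pool,
                 survey = survey, dir = dir))
}

# Synthetic elicitation sample with an exact number of high-sensitive
# farmers (sgy > avy_farm > avy_region); remaining records sit in the other
# quadrants. Values are dt/ha on the scale of regional winter-wheat yields.
synth_survey <- function(n = 73, n_high = 13, avy_region = 71.4) {
  stopifnot(n_high <= n)
  id <- sprintf("F%03d", seq_len(n))
  high <- seq_len(n) <= n_high
  avy_farm <- ifelse(high,
                     avy_region + stats::runif(n, 1, 10),
                     avy_region + stats::runif(n, -15, 8))
  sgy <- ifelse(high,
                avy_farm + stats::runif(n, 0.5, 6),
                avy_farm - stats::runif(n, 0.5, 20))
  sgy <- pmax(sgy, 30)
  py <- pmax(sgy, avy_farm) + stats::runif(n, 5, 25)
  data.frame(farmer_id = id, crop = "winter_wheat",
             py = round(py, 1), sgy = round(sgy, 1),
             avy_farm = round(avy_farm, 1), stringsAsFactors = FALSE)
}
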