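#' Run the full remoteness analysis from one configuration
#'
#' Orchestrates the whole pipeline: generate (or load) the landscape,
#' derive streams from the DEM, build a cost surface and solve travel
#' time per scenario, disaggregate population, compute the remoteness
#' index per zone, simulate (or load) mortality, and fit the Poisson
#' GLM. All stage outputs are written under `out_dir` in plain-text
#' formats (ESRI ASCII rasters, GeoJSON vectors, CSV tables, YAML
#' results) together with a manifest of checksums, so a re-run with the
#' same configuration and seed is byte-identical.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `simulate` (list of generator parameters: `size`, `zones`, `towns`,
#'   `dwellings`, `beta0`, `beta_remoteness`, `beta_season`,
#'   `births_per_zone`, `years`), `scenarios` (list of
#'   `list(mode, season)`), `threshold_min`, `stream_threshold`,
#'   `barrier_order_min`, `population_method` (`"infra"` or
#'   `"points"`), `glm_response` (`"mmr"` or `"deaths_offset"`),
#'   `seed`, `out_dir`.
#' @param quiet suppress per-stage log lines.
#' @return a list with the manifest and all in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (length(cfg$scenarios) == 0) stop("`scenarios` must be non-empty")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf("[emoc-access] %s", sprintf(fmt, ...)))
  }
  stages <- character(0)
  run_stage <- function(name, expr) {
    log_stage("stage %s", name)
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  sim <- cfg$simulate
  region <- run_stage("generate", simulate_region(
    size = sim$size, n_zones = sim$zones, n_towns = sim$towns,
    n_dwellings = sim$dwellings, seed = cfg$seed))

  hydro <- run_stage("hydrology",
                     derive_streams(region$dem, cfg$stream_threshold))

  scen_names <- vapply(cfg$scenarios, function(s)
    paste(s$mode, s$season, sep = "_"), "")
  speeds <- default_speed_table()
  tts <- list(); pats <- list(); rems <- list()
  for (i in seq_along(cfg$scenarios)) {
    s <- cfg$scenarios[[i]]
    nm <- scen_names[i]
    sc <- scenario_config(mode = s$mode, season = s$season,
                          threshold_min = cfg$threshold_min,
                          barrier_order_min = cfg$barrier_order_min,
                          cellsize = region$dem$cellsize)
    pace <- run_stage(paste0("cost_surface:", nm),
                      build_cost_surface(region$landcover, region$roads,
                                         hydro$streams, sc, speeds))
    tt <- run_stage(paste0("travel_time:", nm), {
      src <- snap_facilities(region$facilities, pace)
      cost_distance(pace, src)
    })
    tts[[nm]] <- tt
    pop <- if (cfg$population_method == "points")
      disaggregate_points(region$census, region$dwellings$points,
                          region$zones)
    else
      disaggregate_infrastructure(region$census, region$dwellings$infra,
                                  region$zones)
    pat <- run_stage(paste0("population:", nm),
                     join_population_traveltime(pop, tt, region$zones))
    pats[[nm]] <- pat
    rems[[nm]] <- remoteness_index(pat, threshold = cfg$threshold_min)
  }

  glm_res <- NULL
  glm_data <- NULL
  iw <- grep("wet", scen_names)
  id <- grep("dry", scen_names)
  rem_wet <- if (length(iw)) rems[[iw[1]]] else NULL
  rem_dry <- if (length(id)) rems[[id[1]]] else NULL
  if (!is.null(rem_wet) && !is.null(rem_dry)) {
    glm_data <- run_stage("mortality", {
      births <- rep(sim$births_per_zone, nrow(region$census))
      coefs <- c(sim$beta0, sim$beta_remoteness, sim$beta_season)
      mort_wet <- gen_mortality(rem_wet$remoteness, 0, births, coefs,
                                years = sim$years, seed = cfg$seed + 101L)
      mort_dry <- gen_mortality(rem_dry$remoteness, 1, births, coefs,
                                years = sim$years, seed = cfg$seed + 102L)
      make_glm_dataset(rbind(mort_wet$table, mort_dry$table),
                       rem_wet, rem_dry)
    })
    if (stats::sd(glm_data$remoteness) > 0) {
      glm_res <- run_stage("glm",
                           fit_poisson_glm(glm_data,
                                           response_mode = cfg$glm_response))
    } else {
      log_stage("glm skipped: remoteness constant across zones and seasons")
    }
  }

  report <- scenario_report(pats)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    stages = stages,
    started = format(t0), finished = format(Sys.time())
  )
  if (!is.null(out_dir)) {
    write_outputs(out_dir, region, hydro, tts, pats, rems, report,
                  glm_data, glm_res)
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.yaml"))
    manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$checksums) <- files
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  log_stage("done (%d stages)", length(stages))
  list(manifest = manifest, region = region, hydrology = hydro,
       travel_time = tts, population_at_time = pats, remoteness = rems,
       report = report, glm_data = glm_data, glm = glm_res)
}

# Overlay user config on the defaults. `simulate` merges key-wise; every
# other entry (including the unnamed `scenarios` list) replaces wholesale.
merge_config <- function(default, config) {
  out <- default
  for (nm in names(config)) {
    if (nm == "simulate" && is.list(config[[nm]]))
      out$simulate <- utils::modifyList(out$simulate, config[[nm]])
    else
      out[[nm]] <- config[[nm]]
  }
  out
}

default_config <- function() {
  list(
    simulate = list(size = 512L, zones = 32L, towns = 8L, dwellings = 1598L,
                    beta0 = 5.5, beta_remoteness = 1.0, beta_season = 0.12,
                    births_per_zone = 2000L, years = 5L),
    scenarios = list(list(mode = "car", season = "dry"),
                     list(mode = "car", season = "wet"),
                     list(mode = "bus", season = "dry"),
                     list(mode = "bus", season = "wet")),
    threshold_min = 120,
    stream_threshold = 15,
    barrier_order_min = 7L,
    population_method = "infra",
    glm_response = "mmr",
    seed = 0L,
    out_dir = NULL
  )
}

write_outputs <- function(out_dir, region, hydro, tts, pats, rems, report,
                          glm_data, glm_res) {
  wg <- function(g, nm) write_grid_asc(g, file.path(out_dir, nm))
  wg(region$dem, "dem.asc")
  wg(region$landcover, "landcover.asc")
  wg(region$zones$zones, "zones.asc")
  wg(emoc_grid(region$dwellings$infra$values * 1,
               cellsize = region$dem$cellsize, xmin = region$dem$xmin,
               ymax = region$dem$ymax), "infrastructure.asc")
  wg(hydro$streams, "streams.asc")
  write_roads_geojson(region$roads, file.path(out_dir, "roads.geojson"))
  write_points_geojson(as.matrix(region$facilities[, c("x", "y")]),
                       file.path(out_dir, "facilities.geojson"),
                       properties = region$facilities[, "tier", drop = FALSE])
  write_points_geojson(region$dwellings$points,
                       file.path(out_dir, "dwellings.geojson"))
  utils::write.csv(region$census, file.path(out_dir, "census.csv"),
                   row.names = FALSE)
  for (nm in names(tts)) {
    wg(tts[[nm]], sprintf("travel_time_%s.asc", nm))
    wg(classify_zones(tts[[nm]]), sprintf("access_zones_%s.asc", nm))
    utils::write.csv(pats[[nm]],
                     file.path(out_dir,
                               sprintf("population_at_time_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(rems[[nm]],
                     file.path(out_dir, sprintf("remoteness_%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(report, file.path(out_dir, "scenario_report.csv"),
                   row.names = FALSE)
  if (!is.null(glm_data))
    utils::write.csv(glm_data, file.path(out_dir, "glm_data.csv"),
                     row.names = FALSE)
  if (!is.null(glm_res))
    yaml::write_yaml(list(
      response_mode = glm_res$response_mode,
      coefficients = as.list(glm_res$coefficients),
      se = as.list(glm_res$se),
      coefficients_raw = as.list(glm_res$coefficients_raw),
      deviance = glm_res$deviance,
      iterations = glm_res$iterations,
      standardization = glm_res$standardization
    ), file.path(out_dir, "glm_fit.yaml"))
  invisible(out_dir)
}
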