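#' Default travel-speed table
#'
#' Speeds (km/h) per land-cover/road class, transport mode and season,
#' based on local knowledge of the study district: walking speeds off
#' road (slower in the wet, slowest on rocky ground), ambulance ("car")
#' speeds on all road classes, and public-transport ("bus") speeds on
#' major roads only — in the bus scenarios local roads carry walking
#' speed, since buses do not serve them.
#'
#' @return data.frame with columns `class` (0-6), `label`, `mode`
#'   (`car`/`bus`), `season` (`wet`/`dry`), `kmh`.
#' @export
default_speed_table <- function() {
  path <- system.file("extdata", "speed_table.csv", package = "emocaccess",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Scenario configuration
#'
#' @param mode transport mode, `"car"` (ambulance on all roads) or
#'   `"bus"` (public transport on major roads, walking elsewhere).
#' @param season `"dry"` or `"wet"`.
#' @param threshold_min remoteness threshold in minutes (default 120:
#'   basic EmOC should be reachable within two hours).
#' @param barrier_order_min minimum Strahler order at which a stream
#'   cell blocks travel (default 7, i.e. order strictly greater than 6).
#' @param barrier_overrides_roads if `TRUE` (default) a barrier stream
#'   blocks travel even across road cells; set `FALSE` to treat road
#'   crossings as bridges.
#' @param barrier_seasons seasons in which barriers apply (default both).
#' @param cellsize working resolution in metres (default 50).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(mode = c("car", "bus"),
                            season = c("dry", "wet"),
                            threshold_min = 120,
                            barrier_order_min = 7L,
                            barrier_overrides_roads = TRUE,
                            barrier_seasons = c("wet", "dry"),
                            cellsize = 50) {
  mode <- match.arg(mode)
  season <- match.arg(season)
  if (threshold_min <= 0) stop("`threshold_min` must be > 0")
  if (cellsize <= 0) stop("`cellsize` must be > 0")
  structure(list(mode = mode, season = season,
                 threshold_min = threshold_min,
                 barrier_order_min = as.integer(barrier_order_min),
                 barrier_overrides_roads = barrier_overrides_roads,
                 barrier_seasons = barrier_seasons,
                 cellsize = cellsize),
            class = "scenario_config")
}

#' Burn roads into the land-cover grid
#'
#' Rasterizes the classed polylines onto the land-cover grid: any cell
#' whose square footprint the polyline crosses takes the road class;
#' where several classes collide the highest code (the fastest road)
#' wins; roads always take precedence over land cover. Idempotent.
#'
#' @param landcover land-cover [emoc_grid()] (codes 0-3).
#' @param roads an `emoc_roads` network in the same world frame.
#' @return an [emoc_grid()] with codes 0-6.
#' @export
burn_roads <- function(landcover, roads) {
  stopifnot(inherits(landcover, "emoc_grid"))
  burned <- rasterize_lines(landcover, roads$lines)
  cls <- landcover$values
  cls[burned > 0L] <- pmax(cls[burned > 0L], burned[burned > 0L])
  # roads (4-6) always beat cover (0-3), so pmax == replacement here
  emoc_grid(cls, cellsize = landcover$cellsize, xmin = landcover$xmin,
            ymax = landcover$ymax)
}

#' Apply stream barriers to a class grid
#'
#' Stream cells whose Strahler order is at least
#' `config$barrier_order_min` (default: order strictly greater than 6)
#' become barriers to travel. By default the rule is applied in both
#' seasons and overrides roads; `barrier_overrides_roads = FALSE`
#' exempts road cells (classes 4-6), treating crossings as bridges.
#' Idempotent.
#'
#' @param class_grid class [emoc_grid()] (codes 0-6) from [burn_roads()].
#' @param streams Strahler-order grid from [strahler_order()].
#' @param config a [scenario_config()].
#' @return list with `class_grid` (unchanged codes) and `barrier`
#'   (logical [emoc_grid()]).
#' @export
apply_barriers <- function(class_grid, streams, config) {
  stopifnot(inherits(class_grid, "emoc_grid"), inherits(streams, "emoc_grid"))
  stopifnot_aligned(class_grid, streams, "class and stream grids")
  barrier <- streams$values >= config$barrier_order_min
  if (!config$season %in% config$barrier_seasons)
    barrier[] <- FALSE
  if (!config$barrier_overrides_roads)
    barrier[class_grid$values >= 4L] <- FALSE
  list(class_grid = class_grid,
       barrier = emoc_grid(barrier, cellsize = class_grid$cellsize,
                           xmin = class_grid$xmin, ymax = class_grid$ymax))
}

#' Build the pace (travel-cost) grid for one scenario
#'
#' Converts class codes to pace in minutes per metre via
#' `pace = 60 / (1000 * speed_kmh)` using the scenario's column of the
#' speed table; barrier cells get the non-traversable sentinel (`Inf`).
#'
#' @param class_grid class [emoc_grid()] (codes 0-6).
#' @param speeds speed table as from [default_speed_table()].
#' @param config a [scenario_config()].
#' @param barrier optional logical [emoc_grid()] from [apply_barriers()].
#' @return a pace [emoc_grid()] (minutes per metre; `Inf` = barrier).
#' @export
build_pace <- function(class_grid, speeds = default_speed_table(), config,
                       barrier = NULL) {
  stopifnot(inherits(class_grid, "emoc_grid"))
  sel <- speeds[speeds$mode == config$mode & speeds$season == config$season, ]
  codes <- sort(unique(as.vector(class_grid$values)))
  missing <- setdiff(codes, sel$class)
  if (length(missing))
    stop(sprintf("no speed entry for class %s under mode=%s season=%s",
                 paste(missing, collapse = ", "), config$mode, config$season))
  if (any(sel$kmh <= 0)) stop("all speeds must be > 0")
  lut <- numeric(7)
  lut[sel$class + 1L] <- 60 / (1000 * sel$kmh)
  pace <- matrix(lut[class_grid$values + 1L],
                 nrow(class_grid$values), ncol(class_grid$values))
  if (!is.null(barrier)) {
    stopifnot_aligned(class_grid, barrier, "class and barrier grids")
    pace[barrier$values] <- Inf
  }
  emoc_grid(pace, cellsize = class_grid$cellsize, xmin = class_grid$xmin,
            ymax = class_grid$ymax)
}

#' Assemble the full cost surface for a scenario
#'
#' Chains [burn_roads()], [apply_barriers()] and [build_pace()].
#'
#' @inheritParams burn_roads
#' @inheritParams apply_barriers
#' @inheritParams build_pace
#' @return a pace [emoc_grid()].
#' @export
build_cost_surface <- function(landcover, roads, streams, config,
                               speeds = default_speed_table()) {
  cls <- burn_roads(landcover, roads)
  ab <- apply_barriers(cls, streams, config)
  build_pace(ab$class_grid, speeds, config, barrier = ab$barrier)
}
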