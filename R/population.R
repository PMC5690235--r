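#' Dasymetric population disaggregation
#'
#' Zone-level census totals are distributed onto the grid using ancillary
#' data: either built-infrastructure cells (each infrastructure cell of a
#' zone carries population / number-of-infrastructure-cells persons) or
#' individually mapped dwelling points (the zone total split equally
#' across its dwellings, then binned to cells). Populations are kept as
#' real numbers; rounding to whole persons would bias the remoteness
#' proportions for no benefit.
#'
#' @name population
NULL

#' Disaggregate census totals over infrastructure cells
#'
#' @param census data.frame with `zone` and `population`.
#' @param infra logical infrastructure [emoc_grid()].
#' @param zones zone map from [gen_zones()] (or a list with `zones`, `k`).
#' @param fallback `"error"` (default) rejects a populated zone with no
#'   infrastructure; `"uniform"` spreads that zone's population over all
#'   its cells with a warning.
#' @return a population [emoc_grid()] (persons per cell).
#' @export
disaggregate_infrastructure <- function(census, infra, zones,
                                        fallback = c("error", "uniform")) {
  fallback <- match.arg(fallback)
  zg <- zones$zones
  stopifnot_aligned(zg, infra, "zone and infrastructure grids")
  zv <- zg$values
  pop <- matrix(0, nrow(zv), ncol(zv))
  for (i in seq_len(nrow(census))) {
    z <- census$zone[i]
    p <- census$population[i]
    if (p == 0) next
    cells <- which(zv == z & infra$values)
    if (length(cells) == 0L) {
      if (fallback == "error")
        stop(sprintf(
          "zone %s has population %g but no infrastructure cells", z, p))
      warning(sprintf(
        "zone %s has no infrastructure cells; spreading uniformly", z))
      cells <- which(zv == z)
    }
    pop[cells] <- pop[cells] + p / length(cells)
  }
  emoc_grid(pop, cellsize = zg$cellsize, xmin = zg$xmin, ymax = zg$ymax)
}

#' Disaggregate census totals over dwelling points
#'
#' @param census data.frame with `zone` and `population`.
#' @param dwellings matrix of dwelling coordinates (x, y), world metres.
#' @param zones zone map from [gen_zones()].
#' @inheritParams disaggregate_infrastructure
#' @return a population [emoc_grid()] (persons per cell).
#' @export
disaggregate_points <- function(census, dwellings, zones,
                                fallback = c("error", "uniform")) {
  fallback <- match.arg(fallback)
  zg <- zones$zones
  zv <- zg$values
  rc <- world_to_cell(zg, dwellings[, 1], dwellings[, 2])
  if (anyNA(rc$row)) stop("dwelling points outside the grid extent")
  dz <- zv[cbind(rc$row, rc$col)]
  pop <- matrix(0, nrow(zv), ncol(zv))
  for (i in seq_len(nrow(census))) {
    z <- census$zone[i]
    p <- census$population[i]
    if (p == 0) next
    sel <- which(dz == z)
    if (length(sel) == 0L) {
      if (fallback == "error")
        stop(sprintf("zone %s has population %g but no dwellings", z, p))
      warning(sprintf("zone %s has no dwellings; spreading uniformly", z))
      cells <- which(zv == z)
      pop[cells] <- pop[cells] + p / length(cells)
      next
    }
    per_dwelling <- p / length(sel)
    for (j in sel)
      pop[rc$row[j], rc$col[j]] <- pop[rc$row[j], rc$col[j]] + per_dwelling
  }
  emoc_grid(pop, cellsize = zg$cellsize, xmin = zg$xmin, ymax = zg$ymax)
}

#' Join the population grid with travel time
#'
#' Produces the per-cell records on which the remoteness index is
#' computed: one record per populated cell with its zone, travel time
#' (minutes; `Inf` for unreachable cells) and access-zone label. Total
#' persons are preserved exactly.
#'
#' @param pop population [emoc_grid()].
#' @param tt travel-time [emoc_grid()].
#' @param zones zone map from [gen_zones()].
#' @return data.frame: `zone`, `row`, `col`, `minutes`, `zone_label`,
#'   `persons`.
#' @export
join_population_traveltime <- function(pop, tt, zones) {
  zg <- zones$zones
  stopifnot_aligned(pop, tt, "population and travel-time grids")
  stopifnot_aligned(pop, zg, "population and zone grids")
  sel <- which(pop$values > 0, arr.ind = TRUE)
  minutes <- tt$values[sel]
  labels <- zone_labels()[classify_zones(tt)$values[sel]]
  out <- data.frame(
    zone = zg$values[sel],
    row = sel[, 1], col = sel[, 2],
    minutes = minutes,
    zone_label = labels,
    persons = pop$values[sel]
  )
  out[order(out$zone, out$row, out$col), , drop = FALSE]
}
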