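# Line rasterization: a cell is marked when the polyline crosses its
# square footprint (supercover traversal), not by centre-line sampling,
# so diagonal roads never drop cells and break network connectivity.

# All grid cells crossed by one segment, as a (row, col) data.frame.
cells_on_segment <- function(g, x0, y0, x1, y1) {
  cs <- g$cellsize
  dx <- x1 - x0; dy <- y1 - y0
  ts <- c(0, 1)
  if (dx != 0) {
    jr <- sort(c((x0 - g$xmin) / cs, (x1 - g$xmin) / cs))
    js <- seq(ceiling(jr[1]), floor(jr[2]))
    ts <- c(ts, ((g$xmin + js * cs) - x0) / dx)
  }
  if (dy != 0) {
    ir <- sort(c((g$ymax - y0) / cs, (g$ymax - y1) / cs))
    is <- seq(ceiling(ir[1]), floor(ir[2]))
    ts <- c(ts, ((g$ymax - is * cs) - y0) / dy)
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  rc <- world_to_cell(g, x0 + mid * dx, y0 + mid * dy)
  unique(rc[!is.na(rc$row), , drop = FALSE])
}

# Rasterize a set of classed polylines onto the grid geometry of `g`.
# Returns an integer matrix: 0 where nothing was burned, otherwise the
# highest class code among intersecting lines (fastest road wins).
rasterize_lines <- function(g, lines, warn_outside = TRUE) {
  burned <- matrix(0L, nrow(g$values), ncol(g$values))
  ext <- grid_extent(g)
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    xs <- ln$coords[, 1]; ys <- ln$coords[, 2]
    if (all(xs < ext[["xmin"]]) || all(xs > ext[["xmax"]]) ||
        all(ys < ext[["ymin"]]) || all(ys > ext[["ymax"]])) {
      if (warn_outside)
        warning(sprintf("polyline %d lies outside the grid extent; ignored",
                        li))
      next
    }
    for (s in seq_len(nrow(ln$coords) - 1L)) {
      rc <- cells_on_segment(g, xs[s], ys[s], xs[s + 1], ys[s + 1])
      idx <- cbind(rc$row, rc$col)
      burned[idx] <- pmax(burned[idx], ln$class)
    }
  }
  burned
}

# Distance (m, octile metric) from every cell centre to the nearest road
# cell, via the rasterized network: a unit-pace multi-source Dijkstra,
# which scales to district-sized grids. Used by the dwelling generator.
distance_to_roads <- function(g, roads) {
  burned <- rasterize_lines(g, roads$lines, warn_outside = FALSE)
  road_cells <- which(t(burned) > 0L) - 1L  # 0-based row-major
  if (length(road_cells) == 0L) stop("road network rasterizes to no cells")
  unit_pace <- matrix(1, nrow(g$values), ncol(g$values))
  d <- cost_distance_cpp(unit_pace, as.integer(road_cells), g$cellsize)
  emoc_grid(d, cellsize = g$cellsize, xmin = g$xmin, ymax = g$ymax)
}
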