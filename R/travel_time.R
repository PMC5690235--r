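#' Snap facilities to traversable cells
#'
#' Maps each facility point to the nearest non-barrier cell centre within
#' a Chebyshev radius of `max_snap` cells, so every cost-distance source
#' lies on traversable ground. Errors (naming the facility) when no
#' traversable cell is within reach.
#'
#' @param facilities data.frame with `x`, `y` (and optionally `tier`).
#' @param pace pace [emoc_grid()] (`Inf` = barrier).
#' @param max_snap search radius in cells (Chebyshev).
#' @return data.frame with `row`, `col` of the snapped source cells.
#' @export
snap_facilities <- function(facilities, pace, max_snap = 3L) {
  if (nrow(facilities) < 1) stop("at least one facility is required")
  v <- pace$values
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_integer_, nrow(facilities), 2)
  for (i in seq_len(nrow(facilities))) {
    rc <- world_to_cell(pace, facilities$x[i], facilities$y[i])
    if (is.na(rc$row))
      stop(sprintf("facility %d at (%g, %g) lies outside the grid",
                   i, facilities$x[i], facilities$y[i]))
    r0 <- rc$row; c0 <- rc$col
    found <- FALSE
    for (rad in 0:max_snap) {
      rows <- max(1L, r0 - rad):min(nr, r0 + rad)
      cols <- max(1L, c0 - rad):min(nc, c0 + rad)
      sub <- expand.grid(row = rows, col = cols)
      sub <- sub[pmax(abs(sub$row - r0), abs(sub$col - c0)) == rad, ]
      ok <- is.finite(v[cbind(sub$row, sub$col)])
      if (any(ok)) {
        cand <- sub[ok, , drop = FALSE]
        # nearest by true centre distance, then row-major for determinism
        cx <- pace$xmin + (cand$col - 0.5) * pace$cellsize
        cy <- pace$ymax - (cand$row - 0.5) * pace$cellsize
        d2 <- (cx - facilities$x[i])^2 + (cy - facilities$y[i])^2
        ord <- order(d2, cand$row, cand$col)
        out[i, ] <- c(cand$row[ord[1]], cand$col[ord[1]])
        found <- TRUE
        break
      }
    }
    if (!found)
      stop(sprintf(
        "facility %d at (%g, %g): no traversable cell within %d cells",
        i, facilities$x[i], facilities$y[i], max_snap))
  }
  data.frame(row = out[, 1], col = out[, 2])
}

#' Multi-source cost-distance travel time
#'
#' Shortest accumulated travel time (minutes) from every cell to its
#' nearest source over the 8-connected grid, with edge cost
#' `distance x (pace_a + pace_b) / 2` and diagonal distance
#' `sqrt(2) x cellsize` — the standard raster cost-distance semantics.
#' Barrier cells and cells enclosed by barriers are unreachable (`Inf`).
#'
#' @param pace pace [emoc_grid()] (minutes per metre, `Inf` = barrier).
#' @param sources data.frame with `row`, `col` from [snap_facilities()].
#' @return travel-time [emoc_grid()] in minutes (0 at sources).
#' @export
cost_distance <- function(pace, sources) {
  stopifnot(inherits(pace, "emoc_grid"))
  if (nrow(sources) < 1) stop("at least one source is required")
  nc <- ncol(pace$values)
  idx <- as.integer((sources$row - 1L) * nc + (sources$col - 1L))
  tt <- cost_distance_cpp(pace$values, idx, pace$cellsize)
  emoc_grid(tt, cellsize = pace$cellsize, xmin = pace$xmin, ymax = pace$ymax)
}

#' Travel-time zone labels
#' @export
zone_labels <- function() c("0-30", "30-60", "60-90", "90-120", ">120")

#' Classify travel time into the five access zones
#'
#' Zones: 0-30, 30-60, 60-90, 90-120 and >120 minutes, with intervals
#' closed on the right, so exactly 120 minutes falls in the 90-120 zone —
#' "remote" means strictly more than two hours. Unreachable cells are
#' remote: a population that cannot reach care at all is remote by
#' definition.
#'
#' @param tt travel-time [emoc_grid()] (minutes).
#' @return an [emoc_grid()] of zone codes 1-5 (see [zone_labels()]).
#' @export
classify_zones <- function(tt) {
  stopifnot(inherits(tt, "emoc_grid"))
  v <- tt$values
  if (any(v < 0, na.rm = TRUE)) stop("negative travel times")
  z <- matrix(5L, nrow(v), ncol(v))
  z[v <= 120] <- 4L
  z[v <= 90] <- 3L
  z[v <= 60] <- 2L
  z[v <= 30] <- 1L
  emoc_grid(z, cellsize = tt$cellsize, xmin = tt$xmin, ymax = tt$ymax)
}
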