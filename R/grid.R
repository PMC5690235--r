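#' Georeferenced grid
#'
#' The carrier type for every raster layer in the package: a numeric (or
#' integer/logical) matrix plus a minimal affine geometry — square cells of
#' `cellsize` metres, top-left world corner at (`xmin`, `ymax`), row 1 the
#' northernmost row. All layers of one analysis must share shape and
#' geometry exactly; no reprojection is ever attempted.
#'
#' @param values matrix of cell values (row 1 = north).
#' @param cellsize cell edge length in metres (default 50, the working
#'   resolution of the travel-time model).
#' @param xmin,ymax world coordinates of the top-left grid corner (metres).
#' @return an object of class `emoc_grid`.
#' @export
emoc_grid <- function(values, cellsize = 50, xmin = 0, ymax = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  if (is.null(ymax)) ymax <- nrow(values) * cellsize
  structure(
    list(values = values, cellsize = cellsize,
         xmin = xmin, ymax = ymax),
    class = "emoc_grid"
  )
}

#' @export
print.emoc_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<emoc_grid> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] (m)\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymax - nrow(v) * x$cellsize, x$ymax))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d non-finite\n",
                min(fin), max(fin), sum(!is.finite(v))))
  invisible(x)
}

#' @export
dim.emoc_grid <- function(x) dim(x$values)

grid_extent <- function(g) {
  c(xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$cellsize,
    ymin = g$ymax - nrow(g$values) * g$cellsize, ymax = g$ymax)
}

#' World coordinates of all cell centres
#' @param g an `emoc_grid`.
#' @return data.frame with `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  data.frame(
    row = rc$row, col = rc$col,
    x = g$xmin + (rc$col - 0.5) * g$cellsize,
    y = g$ymax - (rc$row - 0.5) * g$cellsize
  )
}

#' Map world points to grid cells
#'
#' Cell footprints are half-open: a point on a shared edge belongs to the
#' cell to its south-east, so border dwellings are assigned deterministically.
#'
#' @param g an `emoc_grid`.
#' @param x,y world coordinates (metres).
#' @return data.frame with `row`, `col`; NA for points outside the extent.
#' @export
world_to_cell <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$xmin) / g$cellsize) + 1L
  row <- floor((g$ymax - y) / g$cellsize) + 1L
  bad <- row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)) ||
      a$cellsize != b$cellsize || a$xmin != b$xmin || a$ymax != b$ymax)
    stop(sprintf(
      "%s are not aligned: [%d x %d @ %g m, origin (%g, %g)] vs [%d x %d @ %g m, origin (%g, %g)]",
      what, nrow(a$values), ncol(a$values), a$cellsize, a$xmin, a$ymax,
      nrow(b$values), ncol(b$values), b$cellsize, b$xmin, b$ymax))
  invisible(TRUE)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# Every generator funnels through this so it is a pure function of its
# arguments including the seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
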