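#' Synthetic study landscapes
#'
#' Generators for internally consistent synthetic study regions — terrain,
#' land cover, a three-tier road network, administrative zones, EmOC
#' facilities, dwellings and census/mortality tables — with known ground
#' truth, so every stage of the accessibility pipeline can be exercised
#' and tested without the original district's (unpublished) geodata.
#'
#' All generators are pure functions of their arguments including `seed`.
#'
#' @name synthetic_landscape
NULL

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (off in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # clamp at edges
      out <- out + k[off + r + 1L] * mat[idx, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

#' Generate a synthetic digital elevation model
#'
#' Gaussian-smoothed white noise: a white-noise field is smoothed with a
#' Gaussian kernel whose width scales with `roughness` and the grid size,
#' then rescaled to span `relief` metres. This is a stand-in for SRTM-type
#' elevation input: it has no drainage realism beyond what smoothing
#' induces, but yields pit-fillable terrain with dendritic D8 networks.
#'
#' @param size grid edge length in cells (>= 8).
#' @param roughness correlation-length control in (0, 1]; larger values
#'   give broader landforms.
#' @param seed RNG seed.
#' @param relief elevation range in metres (default 500).
#' @param cellsize cell size in metres (default 50, the model resolution).
#' @return a DEM [emoc_grid()] (metres).
#' @export
gen_dem <- function(size, roughness = 0.5, seed = 0L, relief = 500,
                    cellsize = 50) {
  if (!is.numeric(size) || length(size) != 1L || size < 8)
    stop("`size` must be a single integer >= 8")
  if (!is.numeric(roughness) || roughness <= 0 || roughness > 1)
    stop("`roughness` must be in (0, 1]")
  size <- as.integer(size)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(size * size), size, size)
    sm <- gaussian_smooth(noise, sigma = max(1, roughness * size / 8))
    rng <- range(sm)
    elev <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) * relief else sm * 0
    emoc_grid(elev, cellsize = cellsize)
  })
}

#' Generate land cover from terrain
#'
#' Emulates a four-class vegetation map (0 grass, 1 forest, 2 scrub,
#' 3 rocky) by cutting a blend of normalized elevation and smoothed noise
#' at fixed quantiles: forest occupies the valley floors, scrub and grass
#' the mid-slopes, rocky ground the high tops. On a flat DEM the classes
#' are noise-driven. All four classes are present on grids of 32 x 32 and
#' up under the default proportions.
#'
#' @param dem a DEM [emoc_grid()].
#' @param seed RNG seed.
#' @param proportions target class shares in the order forest, scrub,
#'   grass, rocky (low to high terrain score); must sum to 1.
#' @return an [emoc_grid()] of class codes 0-3.
#' @export
gen_landcover <- function(dem, seed = 0L,
                          proportions = c(forest = 0.30, scrub = 0.25,
                                          grass = 0.30, rocky = 0.15)) {
  stopifnot(inherits(dem, "emoc_grid"))
  if (abs(sum(proportions) - 1) > 1e-8) stop("`proportions` must sum to 1")
  e <- dem$values
  rng <- range(e)
  nelev <- if (diff(rng) > 0) (e - rng[1]) / diff(rng) else e * 0
  with_seed(seed, {
    noise <- gaussian_smooth(matrix(stats::rnorm(length(e)), nrow(e)), 2)
    nrng <- range(noise)
    nnoise <- (noise - nrng[1]) / diff(nrng)
    score <- 0.6 * nelev + 0.4 * nnoise
    qs <- stats::quantile(score, cumsum(proportions)[1:3], names = FALSE)
    cls <- matrix(0L, nrow(e), ncol(e))          # grass by default
    cls[score <= qs[3]] <- 0L
    cls[score <= qs[2]] <- 2L                    # scrub
    cls[score <= qs[1]] <- 1L                    # forest
    cls[score > qs[3]] <- 3L                     # rocky
    emoc_grid(cls, cellsize = dem$cellsize, xmin = dem$xmin,
              ymax = dem$ymax)
  })
}

#' Generate a three-tier road network
#'
#' Towns are sampled uniformly within the grid extent (with a margin); the
#' national spine (class 6) is the polyline through the towns ordered
#' along the first principal axis of their coordinates, which guarantees a
#' connected network without route optimization. Provincial branches
#' (class 5) leave the spine at towns; local feeder roads (class 4) leave
#' the provincial branches. Every town lies on the spine.
#'
#' @param dem a DEM [emoc_grid()] supplying the extent.
#' @param n_towns number of towns (>= 2).
#' @param seed RNG seed.
#' @return an `emoc_roads` object: `$lines` is a list of
#'   `list(coords, class)` with vertices in world metres.
#' @export
gen_roads <- function(dem, n_towns = 5L, seed = 0L) {
  stopifnot(inherits(dem, "emoc_grid"))
  if (n_towns < 2) stop("`n_towns` must be >= 2")
  ext <- grid_extent(dem)
  mar <- 0.08 * min(ext[["xmax"]] - ext[["xmin"]], ext[["ymax"]] - ext[["ymin"]])
  with_seed(seed, {
    tx <- stats::runif(n_towns, ext[["xmin"]] + mar, ext[["xmax"]] - mar)
    ty <- stats::runif(n_towns, ext[["ymin"]] + mar, ext[["ymax"]] - mar)
    towns <- cbind(tx, ty)
    # order towns along the first principal axis
    ctr <- sweep(towns, 2L, colMeans(towns))
    pc1 <- svd(ctr)$v[, 1]
    ord <- order(ctr %*% pc1)
    spine <- towns[ord, , drop = FALSE]
    lines <- list(list(coords = spine, class = 6L))
    n_branch <- max(0L, n_towns - 2L)
    rand_pt <- function() c(stats::runif(1, ext[["xmin"]] + mar, ext[["xmax"]] - mar),
                            stats::runif(1, ext[["ymin"]] + mar, ext[["ymax"]] - mar))
    prov_ends <- list()
    for (b in seq_len(n_branch)) {
      from <- spine[sample.int(nrow(spine), 1L), ]
      to <- rand_pt()
      lines[[length(lines) + 1L]] <- list(coords = rbind(from, to), class = 5L)
      prov_ends[[b]] <- rbind(from, to)
    }
    for (b in seq_len(n_branch)) {
      seg <- prov_ends[[b]]
      t0 <- stats::runif(1, 0.3, 1)            # departure point along branch
      from <- seg[1, ] + t0 * (seg[2, ] - seg[1, ])
      to <- rand_pt()
      lines[[length(lines) + 1L]] <- list(coords = rbind(from, to), class = 4L)
    }
    structure(list(lines = lines, towns = spine), class = "emoc_roads")
  })
}

#' Generate administrative zones
#'
#' A nearest-seed (Voronoi-style) partition of the grid in cell space:
#' `k` seed cells are sampled without replacement and every cell takes the
#' id (1..k) of its nearest seed centre, ties to the lowest id. The
#' pipeline only ever consumes a zone raster, so no polygon boundaries are
#' constructed.
#'
#' @param grid_shape c(nrows, ncols), or an [emoc_grid()] template.
#' @param k number of zones (1 <= k <= number of cells).
#' @param seed RNG seed.
#' @param cellsize,xmin,ymax grid geometry when `grid_shape` is a vector.
#' @return list with `zones` (integer [emoc_grid()] of ids) and `k`.
#' @export
gen_zones <- function(grid_shape, k, seed = 0L, cellsize = 50, xmin = 0,
                      ymax = NULL) {
  if (inherits(grid_shape, "emoc_grid")) {
    tpl <- grid_shape
  } else {
    nr <- grid_shape[1]; nc <- grid_shape[2]
    tpl <- emoc_grid(matrix(0, nr, nc), cellsize = cellsize, xmin = xmin,
                     ymax = ymax)
  }
  n <- length(tpl$values)
  if (k < 1 || k > n) stop(sprintf("`k` must be between 1 and %d", n))
  with_seed(seed, {
    seeds <- sample.int(n, k)
    nr <- nrow(tpl$values)
    sr <- (seeds - 1L) %% nr + 1L
    sc <- (seeds - 1L) %/% nr + 1L
    cc <- expand.grid(row = seq_len(nr), col = seq_len(ncol(tpl$values)))
    d2 <- outer(cc$row, sr, "-")^2 + outer(cc$col, sc, "-")^2
    ids <- max.col(-d2, ties.method = "first")
    zones <- matrix(ids, nr, ncol(tpl$values))
    list(zones = emoc_grid(zones, cellsize = tpl$cellsize, xmin = tpl$xmin,
                           ymax = tpl$ymax),
         k = as.integer(k))
  })
}

#' Generate EmOC facilities on the road network
#'
#' Facilities are placed on the major-road network (provincial and
#' national classes), emulating clinics offering basic EmOC and a
#' hospital offering comprehensive EmOC. Candidate sites are points
#' densified along class-5/6 polylines at one-cell spacing.
#'
#' @param roads an `emoc_roads` network.
#' @param n_basic,n_comprehensive facility counts (total >= 1).
#' @param seed RNG seed.
#' @param spacing candidate spacing along roads in metres (default 50).
#' @return data.frame with `x`, `y`, `tier`.
#' @export
gen_facilities <- function(roads, n_basic = 4L, n_comprehensive = 1L,
                           seed = 0L, spacing = 50) {
  if (n_basic < 0 || n_comprehensive < 0) stop("facility counts must be >= 0")
  total <- n_basic + n_comprehensive
  if (total < 1) stop("at least one facility is required")
  cand <- do.call(rbind, lapply(roads$lines, function(ln) {
    if (ln$class < 5L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(ln$coords) - 1L), function(s) {
      a <- ln$coords[s, ]; b <- ln$coords[s + 1, ]
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
      cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    }))
  }))
  if (is.null(cand) || nrow(cand) < total)
    stop("not enough major-road sites to place the requested facilities")
  with_seed(seed, {
    pick <- cand[sample.int(nrow(cand), total), , drop = FALSE]
    data.frame(x = pick[, 1], y = pick[, 2],
               tier = rep(c("comprehensive", "basic"),
                          c(n_comprehensive, n_basic)))
  })
}

#' Generate dwellings clustered near roads, and the infrastructure grid
#'
#' Dwelling points are drawn by rejection sampling with acceptance
#' probability `0.02 + 0.98 * exp(-d / decay)` where `d` is the distance
#' to the nearest road cell: density decays with distance to roads, as
#' settlement does in the study region. The built-infrastructure grid is
#' definitional — a cell is infrastructure iff it contains at least one
#' dwelling. The whole set is resampled (bounded retries) until every
#' zone holds at least one infrastructure cell, so the census
#' disaggregation is well defined.
#'
#' @param roads an `emoc_roads` network.
#' @param zones zone map from [gen_zones()].
#' @param n_points number of dwellings (default 1598, a realistic count
#'   for one sub-district mapped dwelling by dwelling).
#' @param decay e-folding distance of the settlement density in metres.
#' @param seed RNG seed.
#' @param max_retry resampling bound for the coverage constraint.
#' @return list with `points` (matrix x,y), `infra` (logical
#'   [emoc_grid()]) and `dist_road` (distance raster, metres).
#' @export
gen_dwellings <- function(roads, zones, n_points = 1598L, decay = 300,
                          seed = 0L, max_retry = 20L) {
  if (n_points < 1) stop("`n_points` must be >= 1")
  if (decay <= 0) stop("`decay` must be > 0")
  zg <- zones$zones
  dmap <- distance_to_roads(zg, roads)
  ext <- grid_extent(zg)
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      pts <- matrix(numeric(0), 0, 2)
      guard <- 0L
      while (nrow(pts) < n_points && guard < 1000L) {
        guard <- guard + 1L
        m <- max(64L, 4L * (n_points - nrow(pts)))
        x <- stats::runif(m, ext[["xmin"]], ext[["xmax"]])
        y <- stats::runif(m, ext[["ymin"]], ext[["ymax"]])
        rc <- world_to_cell(zg, x, y)
        ok <- !is.na(rc$row)
        d <- dmap$values[cbind(rc$row[ok], rc$col[ok])]
        accept <- stats::runif(sum(ok)) < 0.02 + 0.98 * exp(-d / decay)
        pts <- rbind(pts, cbind(x[ok][accept], y[ok][accept]))
      }
      pts <- pts[seq_len(n_points), , drop = FALSE]
      rc <- world_to_cell(zg, pts[, 1], pts[, 2])
      infra <- matrix(FALSE, nrow(zg$values), ncol(zg$values))
      infra[unique(cbind(rc$row, rc$col))] <- TRUE
      covered <- sort(unique(zg$values[infra]))
      if (length(covered) == zones$k) {
        return(list(
          points = pts,
          infra = emoc_grid(infra, cellsize = zg$cellsize, xmin = zg$xmin,
                            ymax = zg$ymax),
          dist_road = dmap
        ))
      }
    }
    stop(sprintf(
      "could not place dwellings so that all %d zones have infrastructure within %d retries",
      zones$k, max_retry))
  })
}

#' Generate maternal deaths from a known Poisson model
#'
#' The mortality generator inverts the analysis model: per zone and year,
#' deaths ~ Poisson(births x exp(b0 + b_r * r_z + b_s * s) / 100000),
#' where `r_z` is the zone's true remoteness index and `s` the season
#' flag (dry = 1, wet = 0). The generating coefficients are returned in a
#' truth record so parameter recovery can be tested.
#'
#' @param zone_remoteness per-zone remoteness in `[0, 1]`.
#' @param season_flag 0 (wet) or 1 (dry).
#' @param births_per_zone live births per zone per year (> 0).
#' @param coefficients c(intercept, remoteness effect, season effect) on
#'   the log-MMR scale; the default intercept exp(5.5) ~ 245 deaths per
#'   100,000 live births is typical of high-mortality districts.
#' @param years number of years simulated (default 5).
#' @param seed RNG seed.
#' @return list with `table` (zone, year, season, deaths, births) and
#'   `truth` (coefficients, remoteness, seed).
#' @export
gen_mortality <- function(zone_remoteness, season_flag, births_per_zone,
                          coefficients = c(5.5, 1.0, 0.12), years = 5L,
                          seed = 0L) {
  if (any(births_per_zone <= 0)) stop("births must be > 0")
  if (years < 1) stop("`years` must be >= 1")
  if (!season_flag %in% c(0, 1)) stop("`season_flag` must be 0 or 1")
  nz <- length(zone_remoteness)
  stopifnot(length(births_per_zone) == nz)
  rate <- exp(coefficients[1] + coefficients[2] * zone_remoteness +
                coefficients[3] * season_flag) / 1e5
  with_seed(seed, {
    tab <- do.call(rbind, lapply(seq_len(years), function(yr) {
      deaths <- stats::rpois(nz, births_per_zone * rate)
      data.frame(zone = seq_len(nz), year = yr, season = season_flag,
                 deaths = pmin(deaths, births_per_zone),
                 births = births_per_zone)
    }))
    list(table = tab,
         truth = list(coefficients = coefficients,
                      remoteness = zone_remoteness,
                      season = season_flag, seed = seed))
  })
}

#' Default census table for a synthetic region
#'
#' Total population split across zones proportionally to infrastructure
#' cells with multiplicative noise; female fraction 0.5 and a fertile
#' (15-45 y) fraction of 0.43 of the female population, the figure
#' reported for the study province.
#'
#' @param zones zone map from [gen_zones()].
#' @param infra infrastructure grid from [gen_dwellings()].
#' @param total_population persons in the whole region.
#' @param female_fraction,fertile_fraction demographic fractions.
#' @param seed RNG seed.
#' @return data.frame: `zone`, `population`, `female_fraction`,
#'   `fertile_fraction`.
#' @export
gen_census <- function(zones, infra, total_population = 100000,
                       female_fraction = 0.5, fertile_fraction = 0.43,
                       seed = 0L) {
  k <- zones$k
  n_inf <- tabulate(zones$zones$values[infra$values], nbins = k)
  with_seed(seed, {
    w <- pmax(n_inf, 1) * exp(stats::rnorm(k, 0, 0.3))
    pop <- total_population * w / sum(w)
    data.frame(zone = seq_len(k), population = pop,
               female_fraction = female_fraction,
               fertile_fraction = fertile_fraction)
  })
}

#' Generate a complete synthetic study region
#'
#' Convenience wrapper chaining the individual generators with seeds
#' derived from one master seed.
#'
#' @param size grid edge (cells); `n_zones`, `n_towns`, `n_dwellings` as
#'   in the individual generators.
#' @param seed master seed.
#' @param ... passed on to [gen_dem()].
#' @return list with components `dem`, `landcover`, `roads`, `zones`,
#'   `facilities`, `dwellings`, `census`.
#' @export
simulate_region <- function(size = 64L, n_zones = 8L, n_towns = 5L,
                            n_dwellings = 800L, seed = 0L, ...) {
  s <- as.integer(seed)
  dem <- gen_dem(size, seed = s, ...)
  lc <- gen_landcover(dem, seed = s + 1L)
  roads <- gen_roads(dem, n_towns = n_towns, seed = s + 2L)
  zones <- gen_zones(dem, k = n_zones, seed = s + 3L)
  fac <- gen_facilities(roads, seed = s + 4L)
  dw <- gen_dwellings(roads, zones, n_points = n_dwellings, seed = s + 5L)
  census <- gen_census(zones, dw$infra, seed = s + 6L)
  list(dem = dem, landcover = lc, roads = roads, zones = zones,
       facilities = fac, dwellings = dw, census = census, seed = s)
}
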