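test_that("DEM generation is deterministic, seed-sensitive and validated", {
  a <- gen_dem(64, roughness = 0.5, seed = 0)
  b <- gen_dem(64, roughness = 0.5, seed = 0)
  c <- gen_dem(64, roughness = 0.5, seed = 1)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_error(gen_dem(4), ">= 8")
  tiny <- gen_dem(8, roughness = 1.0, seed = 7)
  expect_identical(dim(tiny$values), c(8L, 8L))
  expect_true(all(is.finite(tiny$values)))
  expect_gt(diff(range(tiny$values)), 0)
})

test_that("land cover uses codes 0-3 with all classes on medium grids", {
  dem <- gen_dem(64, seed = 0)
  lc <- gen_landcover(dem, seed = 0)
  expect_true(all(lc$values %in% 0:3))
  expect_identical(sort(unique(as.vector(lc$values))), 0:3)
  counts <- tabulate(lc$values + 1L, nbins = 4)
  expect_true(all(counts > 0))
  expect_identical(gen_landcover(dem, seed = 0)$values, lc$values)
  flat <- emoc_grid(matrix(0, 16, 16))
  expect_true(all(gen_landcover(flat, seed = 0)$values %in% 0:3))
})

test_that("road networks are classed, connected, and town-covering", {
  dem <- gen_dem(64, seed = 2)
  expect_error(gen_roads(dem, n_towns = 1), ">= 2")
  two <- gen_roads(dem, n_towns = 2, seed = 0)
  expect_length(two$lines, 1L)
  expect_identical(two$lines[[1]]$class, 6L)
  expect_identical(nrow(two$lines[[1]]$coords), 2L)

  net <- gen_roads(dem, n_towns = 6, seed = 3)
  classes <- sort(unique(vapply(net$lines, `[[`, 0L, "class")))
  expect_identical(classes, c(4L, 5L, 6L))
  # connectivity: rasterized cells form one 8-connected component
  burned <- emocaccess:::rasterize_lines(dem, net$lines)
  cells <- which(burned > 0, arr.ind = TRUE)
  visited <- rep(FALSE, nrow(cells))
  key <- paste(cells[, 1], cells[, 2])
  lookup <- stats::setNames(seq_len(nrow(cells)), key)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    for (dr in -1:1) for (dc in -1:1) {
      j <- lookup[paste(cells[i, 1] + dr, cells[i, 2] + dc)]
      if (!is.na(j) && !visited[j]) {
        visited[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  expect_true(all(visited))
})

test_that("zones partition the grid with all ids present", {
  z1 <- gen_zones(c(8, 8), k = 1, seed = 0)
  expect_true(all(z1$zones$values == 1L))
  z <- gen_zones(c(32, 32), k = 4, seed = 0)
  expect_identical(sort(unique(as.vector(z$zones$values))), 1:4)
  expect_identical(length(z$zones$values), 1024L)
  expect_error(gen_zones(c(4, 4), k = 17), "between 1 and")
})

test_that("facilities are placed on major roads with requested tiers", {
  dem <- gen_dem(64, seed = 5)
  roads <- gen_roads(dem, n_towns = 5, seed = 5)
  fac <- gen_facilities(roads, n_basic = 4, n_comprehensive = 1, seed = 1)
  expect_identical(nrow(fac), 5L)
  expect_identical(sum(fac$tier == "basic"), 4L)
  expect_identical(sum(fac$tier == "comprehensive"), 1L)
  expect_error(gen_facilities(roads, 0, 0), "at least one")
  # each facility within one cell of a class-5/6 polyline
  burned <- emocaccess:::rasterize_lines(dem, Filter(function(l) l$class >= 5,
                                                     roads$lines))
  major <- which(burned > 0, arr.ind = TRUE)
  rc <- world_to_cell(dem, fac$x, fac$y)
  for (i in seq_len(nrow(fac))) {
    cheb <- min(pmax(abs(major[, 1] - rc$row[i]),
                     abs(major[, 2] - rc$col[i])))
    expect_lte(cheb, 1)
  }
  expect_identical(gen_facilities(roads, 4, 1, seed = 1), fac)
})

test_that("dwellings cluster near roads and define the infrastructure grid", {
  dem <- gen_dem(48, seed = 9)
  roads <- gen_roads(dem, n_towns = 5, seed = 9)
  zones <- gen_zones(dem, k = 4, seed = 9)
  dw <- gen_dwellings(roads, zones, n_points = 300, decay = 300, seed = 2)
  expect_identical(nrow(dw$points), 300L)
  # infrastructure iff >= 1 dwelling (definitional)
  rc <- world_to_cell(zones$zones, dw$points[, 1], dw$points[, 2])
  manual <- matrix(FALSE, 48, 48)
  manual[unique(cbind(rc$row, rc$col))] <- TRUE
  expect_identical(dw$infra$values, manual)
  # every zone has infrastructure
  expect_identical(sort(unique(zones$zones$values[dw$infra$values])), 1:4)
  # clustering: mean road distance below that of uniform points
  set.seed(2)
  ext <- emocaccess:::grid_extent(dem)
  ux <- runif(300, ext[["xmin"]], ext[["xmax"]])
  uy <- runif(300, ext[["ymin"]], ext[["ymax"]])
  dmap <- dw$dist_road$values
  rcu <- world_to_cell(dem, ux, uy)
  d_dw <- mean(dmap[cbind(rc$row, rc$col)])
  d_un <- mean(dmap[cbind(rcu$row, rcu$col)])
  expect_lt(d_dw, d_un)
})

test_that("the default dwelling count emits 1598 points", {
  dem <- gen_dem(96, seed = 4, cellsize = 100)
  roads <- gen_roads(dem, n_towns = 5, seed = 4)
  zones <- gen_zones(dem, k = 4, seed = 4)
  dw <- gen_dwellings(roads, zones, seed = 4)
  expect_identical(nrow(dw$points), 1598L)
})

test_that("mortality generator matches its Poisson model and records truth", {
  r <- runif(32)
  births <- rep(5000, 32)
  m <- gen_mortality(r, 0, births, coefficients = c(5.5, 0, 0),
                     years = 5, seed = 1)
  expect_identical(m$table,
                   gen_mortality(r, 0, births, c(5.5, 0, 0), 5, 1)$table)
  expect_true(all(m$table$deaths <= m$table$births))
  # with no covariate effects the pooled MMR estimates exp(b0)
  pooled <- 1e5 * sum(m$table$deaths) / sum(m$table$births)
  expect_lt(abs(pooled - exp(5.5)) / exp(5.5),
            3 / sqrt(sum(m$table$deaths)))
  # positive remoteness effect shows up as positive rank correlation
  m2 <- gen_mortality(r, 0, births, coefficients = c(5.5, 1.5, 0),
                      years = 5, seed = 7)
  mmr_z <- vapply(split(m2$table, m2$table$zone),
                  function(s) 1e5 * sum(s$deaths) / sum(s$births), 0)
  expect_gt(cor(r, mmr_z[as.character(1:32)], method = "spearman"), 0)
  expect_error(gen_mortality(r, 0, rep(-1, 32), years = 5), "births")
  expect_identical(m$truth$coefficients, c(5.5, 0, 0))
})
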