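# A small fixed landscape shared by the disaggregation tests.
pop_fixture <- function() {
  zones <- gen_zones(c(16, 16), k = 3, seed = 5)
  infra <- matrix(FALSE, 16, 16)
  set.seed(5)
  infra[sample(256, 40)] <- TRUE
  # guarantee every zone at least one infrastructure cell
  for (z in 1:3) {
    cells <- which(zones$zones$values == z)
    if (!any(infra[cells])) infra[cells[1]] <- TRUE
  }
  census <- data.frame(zone = 1:3, population = c(1000, 0, 2500),
                       female_fraction = 0.5, fertile_fraction = 0.43)
  list(zones = zones,
       infra = emoc_grid(infra, cellsize = 50),
       census = census)
}

test_that("infrastructure disaggregation divides zone totals evenly", {
  fx <- pop_fixture()
  pop <- disaggregate_infrastructure(fx$census, fx$infra, fx$zones)
  zv <- fx$zones$zones$values
  for (z in 1:3) {
    total <- sum(pop$values[zv == z])
    expect_equal(total, fx$census$population[z], tolerance = 1e-9)
    cells <- zv == z & fx$infra$values
    if (fx$census$population[z] > 0) {
      expect_equal(unique(pop$values[cells]),
                   fx$census$population[z] / sum(cells))
      expect_true(all(pop$values[zv == z & !fx$infra$values] == 0))
    } else {
      expect_true(all(pop$values[zv == z] == 0))
    }
  }
})

test_that("a populated zone without infrastructure errors unless uniform fallback", {
  fx <- pop_fixture()
  infra <- fx$infra
  infra$values[fx$zones$zones$values == 1] <- FALSE
  expect_error(disaggregate_infrastructure(fx$census, infra, fx$zones),
               "zone 1")
  expect_warning(
    pop <- disaggregate_infrastructure(fx$census, infra, fx$zones,
                                       fallback = "uniform"),
    "uniform")
  zv <- fx$zones$zones$values
  expect_equal(sum(pop$values[zv == 1]), 1000, tolerance = 1e-9)
  expect_equal(length(unique(pop$values[zv == 1])), 1L)
})

test_that("point disaggregation splits equally and bins to cells", {
  zones <- gen_zones(c(4, 4), k = 1, seed = 0, cellsize = 50)
  census <- data.frame(zone = 1, population = 400)
  # two dwellings in one cell, two in distinct cells
  dw <- rbind(c(30, 30), c(40, 40), c(120, 120), c(180, 60))
  pop <- disaggregate_points(census, dw, zones)
  expect_equal(sum(pop$values), 400, tolerance = 1e-9)
  rc <- world_to_cell(zones$zones, dw[, 1], dw[, 2])
  expect_equal(pop$values[rc$row[1], rc$col[1]], 200)  # shared cell
  expect_equal(pop$values[rc$row[3], rc$col[3]], 100)
  # single dwelling carries the whole zone
  pop1 <- disaggregate_points(data.frame(zone = 1, population = 250),
                              dw[1, , drop = FALSE], zones)
  expect_equal(max(pop1$values), 250)
})

test_that("point method equals infrastructure method at one dwelling per cell", {
  fx <- pop_fixture()
  cells <- which(fx$infra$values, arr.ind = TRUE)
  g <- fx$infra
  dw <- cbind(g$xmin + (cells[, 2] - 0.5) * g$cellsize,
              g$ymax - (cells[, 1] - 0.5) * g$cellsize)
  pop_i <- disaggregate_infrastructure(fx$census, fx$infra, fx$zones)
  pop_p <- disaggregate_points(fx$census, dw, fx$zones)
  expect_equal(pop_p$values, pop_i$values, tolerance = 1e-12)
})

test_that("disaggregation is invariant to zone relabeling", {
  fx <- pop_fixture()
  pop <- disaggregate_infrastructure(fx$census, fx$infra, fx$zones)
  relab <- c(3L, 1L, 2L)
  zones2 <- fx$zones
  zones2$zones$values <- matrix(relab[fx$zones$zones$values], 16, 16)
  census2 <- fx$census
  census2$zone <- relab[census2$zone]
  pop2 <- disaggregate_infrastructure(census2, fx$infra, zones2)
  expect_equal(pop2$values, pop$values, tolerance = 1e-12)
})

test_that("joining with travel time preserves totals and labels remoteness", {
  fx <- pop_fixture()
  pop <- disaggregate_infrastructure(fx$census, fx$infra, fx$zones)
  tt <- emoc_grid(matrix(45, 16, 16), cellsize = 50)
  tt$values[1, 1] <- Inf   # an unreachable populated cell, if populated
  pat <- join_population_traveltime(pop, tt, fx$zones)
  expect_equal(sum(pat$persons), sum(pop$values), tolerance = 1e-9)
  expect_identical(nrow(pat), sum(pop$values > 0))
  expect_true(all(pat$zone_label[is.infinite(pat$minutes)] == ">120"))
  expect_true(all(pat$zone_label[is.finite(pat$minutes)] == "30-60"))
  # single populated cell gives exactly one record
  solo <- emoc_grid(matrix(0, 16, 16), cellsize = 50)
  solo$values[4, 7] <- 123
  pat1 <- join_population_traveltime(solo, tt, fx$zones)
  expect_identical(nrow(pat1), 1L)
  expect_equal(pat1$minutes, 45)
  expect_equal(pat1$persons, 123)
})
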