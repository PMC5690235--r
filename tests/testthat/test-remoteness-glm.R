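test_that("remoteness index is the strict >threshold population share", {
  pat <- data.frame(zone = c(1, 1, 2, 3),
                    minutes = c(100, 130, 120, Inf),
                    zone_label = c("90-120", ">120", "90-120", ">120"),
                    persons = c(70, 30, 50, 10))
  rt <- remoteness_index(pat)
  expect_equal(rt$remoteness, c(0.30, 0, 1))
  expect_true(all(rt$defined))
  expect_true(all(rt$remoteness >= 0 & rt$remoteness <= 1))
  # exactly 120 minutes is NOT remote (more than two hours is strict)
  expect_equal(rt$remoteness[rt$zone == 2], 0)
  # zero-population zone flagged undefined
  pat0 <- rbind(pat, data.frame(zone = 4, minutes = 10, zone_label = "0-30",
                                persons = 0))
  rt0 <- remoteness_index(pat0)
  expect_false(rt0$defined[rt0$zone == 4])
  expect_true(is.na(rt0$remoteness[rt0$zone == 4]))
})

test_that("fertile women remote applies the census fractions", {
  rt <- data.frame(zone = 1:2, persons_total = c(20000, 5000),
                   persons_remote = c(10000, 0),
                   remoteness = c(0.5, 0), defined = TRUE)
  census <- data.frame(zone = 1:2, female_fraction = 0.5,
                       fertile_fraction = 0.43)
  out <- fertile_women_remote(rt, census)
  expect_equal(out$fertile_women_remote, c(2150, 0))
  census$fertile_fraction <- 0
  expect_equal(fertile_women_remote(rt, census)$fertile_women_remote,
               c(0, 0))
})

test_that("2-SD standardization has the closed form and round-trips", {
  s <- standardize_2sd(c(0, 1))
  expect_equal(s$z, c(-1, 1) / (2 * sqrt(2)), tolerance = 1e-12)
  x <- rnorm(50, 3, 2)
  st <- standardize_2sd(x)
  expect_equal(sd(st$z), 0.5, tolerance = 1e-12)
  expect_equal(st$z * 2 * st$sd + st$mean, x, tolerance = 1e-12)
  expect_error(standardize_2sd(rep(1, 5)), "constant")
})

test_that("intercept-only Poisson fit returns the log of the mean", {
  fit <- emocaccess:::irls_poisson(c(1, 2, 3), cbind(rep(1, 3)))
  expect_equal(fit$beta, log(2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("deaths-offset mode agrees with an independent GLM fit", {
  set.seed(42)
  n <- 32
  r <- runif(n)
  data <- do.call(rbind, lapply(0:1, function(s) {
    births <- round(runif(n, 1500, 6000))
    mu <- births * exp(5.5 + 1.2 * r + 0.15 * s) / 1e5
    data.frame(zone = 1:n, season = s, remoteness = r,
               deaths = rpois(n, mu), births = births,
               mmr = NA_real_)
  }))
  data$mmr <- 1e5 * data$deaths / data$births
  fit <- fit_poisson_glm(data, response_mode = "deaths_offset")
  z <- standardize_2sd(data$remoteness)$z
  ref <- stats::glm(deaths ~ z + season, family = poisson,
                    offset = log(births / 1e5), data = cbind(data, z = z))
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-8)
  expect_lt(max(abs(fit$se - summary(ref)$coefficients[, 2])), 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
})

test_that("raw-scale coefficients invert the 2-SD standardization", {
  set.seed(7)
  n <- 24
  r <- runif(n)
  births <- rep(4000, n)
  data <- do.call(rbind, lapply(0:1, function(s) {
    mu <- births * exp(5.5 + 1.0 * r + 0.1 * s) / 1e5
    data.frame(zone = 1:n, season = s, remoteness = r,
               deaths = rpois(n, mu), births = births, mmr = NA_real_)
  }))
  data$mmr <- 1e5 * data$deaths / data$births
  fit <- fit_poisson_glm(data, response_mode = "deaths_offset")
  sdr <- fit$standardization$sd
  expect_equal(fit$coefficients[["remoteness_2sd"]],
               fit$coefficients_raw[["remoteness"]] * 2 * sdr,
               tolerance = 1e-10)
  # refit on raw remoteness with an ordinary GLM: raw scale must agree
  ref <- stats::glm(deaths ~ remoteness + season, family = poisson,
                    offset = log(births / 1e5), data = data)
  expect_lt(max(abs(fit$coefficients_raw - coef(ref))), 1e-7)
})

test_that("rank-deficient designs and non-positive-variance inputs fail loudly", {
  data <- data.frame(zone = 1:8, season = 0, remoteness = runif(8),
                     deaths = 1:8, births = 1000, mmr = 1)
  # season constant -> rank deficient
  expect_error(fit_poisson_glm(data, response_mode = "deaths_offset"),
               "rank deficient")
})

test_that("the mmr response mode solves the quasi-likelihood score equations", {
  set.seed(11)
  n <- 16
  r <- runif(n)
  data <- do.call(rbind, lapply(0:1, function(s) {
    mmr <- exp(5.6 + 0.8 * r + 0.1 * s) * exp(rnorm(n, 0, 0.05))
    data.frame(zone = 1:n, season = s, remoteness = r,
               deaths = NA_real_, births = NA_real_, mmr = mmr)
  }))
  fit <- fit_poisson_glm(data, response_mode = "mmr")
  z <- standardize_2sd(data$remoteness)$z
  X <- cbind(1, z, data$season)
  mu <- exp(drop(X %*% fit$coefficients))
  score <- crossprod(X, data$mmr - mu)
  expect_lt(max(abs(score)), 1e-6)
  expect_true(fit$converged)
})

test_that("the mortality generator plus GLM recovers known coefficients", {
  truth <- c(5.5, 1.0, 0.12)
  r <- seq(0.02, 0.9, length.out = 32)
  births <- rep(20000, 32)
  mw <- gen_mortality(r, 0, births, truth, years = 5, seed = 21)
  md <- gen_mortality(r, 1, births, truth, years = 5, seed = 22)
  rt <- function(rem) data.frame(zone = 1:32, remoteness = rem)
  data <- make_glm_dataset(rbind(mw$table, md$table), rt(r), rt(r))
  fit <- fit_poisson_glm(data, response_mode = "deaths_offset")
  raw <- fit$coefficients_raw
  se_raw <- c(fit$se[1], fit$se[2] / (2 * fit$standardization$sd), fit$se[3])
  expect_lt(abs(raw[["remoteness"]] - truth[2]), 3 * se_raw[2])
  expect_lt(abs(raw[["season"]] - truth[3]), 3 * se_raw[3])
})

test_that("scenario report shares sum to one", {
  fx_zone <- gen_zones(c(8, 8), k = 2, seed = 1)
  pop <- emoc_grid(matrix(runif(64), 8, 8), cellsize = 50)
  tt <- emoc_grid(matrix(runif(64, 0, 200), 8, 8), cellsize = 50)
  pat <- join_population_traveltime(pop, tt, fx_zone)
  rep1 <- scenario_report(list(test = pat))
  expect_equal(sum(rep1[1, zone_labels()]), 1, tolerance = 1e-9)
})
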