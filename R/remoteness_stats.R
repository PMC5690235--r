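#' Remoteness index per zone
#'
#' The remoteness index of a zone is the proportion of its population
#' whose travel time to the nearest EmOC facility is strictly greater
#' than the threshold (default 120 minutes — "more than two hours").
#' Unreachable cells (`Inf`) count as remote. Zones with zero population
#' get `NA` and are flagged, to be excluded from regression.
#'
#' @param pat per-cell records from [join_population_traveltime()].
#' @param threshold threshold in minutes (> 0, default 120).
#' @return data.frame: `zone`, `persons_total`, `persons_remote`,
#'   `remoteness`, `defined`.
#' @export
remoteness_index <- function(pat, threshold = 120) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  zones <- sort(unique(pat$zone))
  tot <- vapply(zones, function(z) sum(pat$persons[pat$zone == z]), 0)
  rem <- vapply(zones, function(z)
    sum(pat$persons[pat$zone == z & pat$minutes > threshold]), 0)
  idx <- ifelse(tot > 0, rem / tot, NA_real_)
  data.frame(zone = zones, persons_total = tot, persons_remote = rem,
             remoteness = idx, defined = tot > 0)
}

#' Fertile-aged women remote from care
#'
#' Converts persons remote to fertile-aged (15-45 y) women remote using
#' the census fractions: persons x female fraction x fertile fraction
#' (default 0.43 of the female population, the provincial figure).
#'
#' @param rt remoteness table from [remoteness_index()].
#' @param census data.frame with `zone`, `female_fraction`,
#'   `fertile_fraction`.
#' @return `rt` with a `fertile_women_remote` column.
#' @export
fertile_women_remote <- function(rt, census) {
  m <- match(rt$zone, census$zone)
  if (anyNA(m)) stop("zones missing from the census table")
  rt$fertile_women_remote <- rt$persons_remote *
    census$female_fraction[m] * census$fertile_fraction[m]
  rt
}

#' Standardize a covariate by two standard deviations
#'
#' `z = (x - mean(x)) / (2 * sd(x))` with the n-1 standard deviation.
#' Dividing by two standard deviations makes the coefficient of a
#' continuous covariate directly comparable with that of an untransformed
#' binary covariate, which is why binary covariates (like season) are
#' passed through unchanged.
#'
#' @param x numeric vector with positive standard deviation.
#' @return list with `z`, `mean`, `sd`.
#' @export
standardize_2sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant covariate")
  m <- mean(x)
  list(z = (x - m) / (2 * s), mean = m, sd = s)
}

#' Assemble the zone x season GLM dataset
#'
#' One row per zone and season with the scenario's remoteness index, the
#' season flag (dry = 1, wet = 0), pooled deaths and births, and the MMR.
#' The MMR is the mean over years of the yearly ratios
#' 100000 x deaths / births (pooling available via `mmr_pooling`);
#' zone-years with zero births are dropped from the mean with a warning.
#'
#' @param mortality mortality table (`zone`, `year`, `season`, `deaths`,
#'   `births`), covering both seasons.
#' @param remoteness_wet,remoteness_dry remoteness tables from
#'   [remoteness_index()] for the wet and dry scenario.
#' @param mmr_pooling `"mean_of_ratios"` (default) or `"pooled"`
#'   (total deaths / total births).
#' @return data.frame: `zone`, `season`, `remoteness`, `deaths`,
#'   `births`, `mmr`.
#' @export
make_glm_dataset <- function(mortality, remoteness_wet, remoteness_dry,
                             mmr_pooling = c("mean_of_ratios", "pooled")) {
  mmr_pooling <- match.arg(mmr_pooling)
  if (any(mortality$births == 0)) {
    warning("dropping zone-years with zero births")
    mortality <- mortality[mortality$births > 0, , drop = FALSE]
  }
  agg <- function(sub) {
    if (mmr_pooling == "mean_of_ratios")
      1e5 * mean(sub$deaths / sub$births)
    else
      1e5 * sum(sub$deaths) / sum(sub$births)
  }
  out <- do.call(rbind, lapply(split(mortality,
                                     mortality[c("zone", "season")]),
    function(sub) {
      if (nrow(sub) == 0) return(NULL)
      data.frame(zone = sub$zone[1], season = sub$season[1],
                 deaths = sum(sub$deaths), births = sum(sub$births),
                 mmr = agg(sub))
    }))
  rem <- function(tab, z) tab$remoteness[match(z, tab$zone)]
  out$remoteness <- ifelse(out$season == 0,
                           rem(remoteness_wet, out$zone),
                           rem(remoteness_dry, out$zone))
  keep <- !is.na(out$remoteness)
  out <- out[keep, c("zone", "season", "remoteness", "deaths", "births",
                     "mmr")]
  rownames(out) <- NULL
  out[order(out$zone, out$season), ]
}

# IRLS for the Poisson log-link score equations. X must be full rank.
# `offset` enters the linear predictor; `y` may be non-integer (the
# quasi-likelihood score equations are identical).
irls_poisson <- function(y, X, offset = 0, tol = 1e-10, max_iter = 100L) {
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  beta <- c(log(mean(y) + 0.1) - mean(offset), rep(0, p - 1L))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- mu
    XtWX <- crossprod(X, X * W)
    score <- crossprod(X, y - mu)
    delta <- solve(XtWX, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("IRLS did not converge in %d iterations (max |delta| = %g)",
                 max_iter, max(abs(delta))))
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  XtWX <- crossprod(X, X * mu)
  se <- sqrt(diag(solve(XtWX)))
  dev_terms <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  list(beta = beta, se = se, deviance = 2 * sum(dev_terms),
       iterations = iter, fitted = mu, converged = converged)
}

#' Fit the Poisson log-link GLM of MMR on remoteness and season
#'
#' Fits `log E[response] = b0 + b_r * z(remoteness) + b_s * season` by
#' iteratively reweighted least squares, where `z()` is the 2-SD
#' standardization. Two response modes are provided because regressing a
#' ratio under a Poisson family is ambiguous:
#'
#' * `"mmr"` (default): the response is the MMR itself (maternal deaths
#'   per 100,000 live births, averaged over years). Non-integer responses
#'   are permitted — the quasi-likelihood score equations are solved —
#'   but the reported SEs assume unit dispersion on the MMR scale.
#' * `"deaths_offset"`: the response is the pooled death count with a
#'   fixed offset `log(births / 100000)`, the statistically conventional
#'   way to model a rate; coefficients stay on the same (log-MMR) scale
#'   and the Poisson SEs are correctly calibrated.
#'
#' @param data GLM dataset from [make_glm_dataset()] (needs >= 4 rows).
#' @param response_mode `"mmr"` or `"deaths_offset"`.
#' @param dispersion `"poisson"` (unit dispersion, default) or
#'   `"quasipoisson"` (SEs scaled by the Pearson dispersion estimate).
#' @return object of class `emoc_glm`: standardized-scale and raw-scale
#'   coefficients, SEs, deviance, iterations, standardization constants.
#' @export
fit_poisson_glm <- function(data, response_mode = c("mmr", "deaths_offset"),
                            dispersion = c("poisson", "quasipoisson")) {
  response_mode <- match.arg(response_mode)
  dispersion <- match.arg(dispersion)
  if (nrow(data) < 4) stop("need at least 4 rows to fit the model")
  std <- standardize_2sd(data$remoteness)
  X <- cbind(`(Intercept)` = 1, remoteness_2sd = std$z, season = data$season)
  if (response_mode == "mmr") {
    y <- data$mmr
    offset <- rep(0, nrow(data))
  } else {
    y <- data$deaths
    offset <- log(data$births / 1e5)
  }
  fit <- irls_poisson(y, X, offset = offset)
  se <- fit$se
  disp <- 1
  if (dispersion == "quasipoisson") {
    pearson <- sum((y - fit$fitted)^2 / fit$fitted)
    disp <- pearson / (nrow(X) - ncol(X))
    se <- se * sqrt(disp)
  }
  beta <- stats::setNames(fit$beta, colnames(X))
  # raw scale: b_raw = b_std / (2 sd); intercept shifts by b_std * m / (2 sd)
  b_raw_r <- beta[["remoteness_2sd"]] / (2 * std$sd)
  raw <- c(`(Intercept)` = beta[["(Intercept)"]] - b_raw_r * std$mean,
           remoteness = b_raw_r, season = beta[["season"]])
  structure(list(
    coefficients = beta,
    se = stats::setNames(se, colnames(X)),
    coefficients_raw = raw,
    deviance = fit$deviance,
    iterations = fit$iterations,
    converged = fit$converged,
    dispersion = disp,
    response_mode = response_mode,
    standardization = list(mean = std$mean, sd = std$sd),
    n = nrow(X)
  ), class = "emoc_glm")
}

#' @export
print.emoc_glm <- function(x, ...) {
  cat(sprintf("Poisson log-link GLM (%s response), n = %d, %d IRLS iterations\n",
              x$response_mode, x$n, x$iterations))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("Deviance: %.3f; remoteness standardized by 2 x sd = %.4f\n",
              x$deviance, 2 * x$standardization$sd))
  invisible(x)
}

#' Per-scenario population shares by travel-time band
#'
#' The district-wide share of the population within 0-30, 30-60, 60-90,
#' 90-120 and >120 minutes of EmOC, per scenario; shares sum to one.
#'
#' @param pats named list of [join_population_traveltime()] outputs, one
#'   per scenario.
#' @return data.frame: `scenario`, one column per band, `remote_share`.
#' @export
scenario_report <- function(pats) {
  labs <- zone_labels()
  rows <- lapply(names(pats), function(nm) {
    pat <- pats[[nm]]
    tot <- sum(pat$persons)
    shares <- vapply(labs, function(l)
      sum(pat$persons[pat$zone_label == l]) / tot, 0)
    cbind(data.frame(scenario = nm), as.data.frame(as.list(shares),
                                                   col.names = labs,
                                                   check.names = FALSE),
          data.frame(remote_share = shares[[">120"]]))
  })
  do.call(rbind, rows)
}
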