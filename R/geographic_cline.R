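# Transect projection, sigmoid geographic cline fitting, and the temporal
# movement estimate.

#' Define a transect baseline
#'
#' The baseline is the line the hybrid-zone interface runs along (default
#' bearing 45 degrees = SW-NE). Samples are summarised by their signed
#' perpendicular distance from this line, positive on the NW side, so that
#' interface movement towards the NW is positive.
#'
#' @param lon,lat anchor point of the baseline (decimal degrees).
#' @param bearing direction of the interface line in degrees from north,
#'   in `[0, 360)`.
#' @return an object of class `transect_baseline`.
#' @export
transect_baseline <- function(lon, lat, bearing = 45) {
  if (bearing < 0 || bearing >= 360) stop("bearing must be in [0, 360)")
  structure(list(lon = lon, lat = lat, bearing = bearing),
            class = "transect_baseline")
}

# local equirectangular projection about the baseline anchor (km)
.local_km <- function(lon, lat, baseline) {
  list(east = (lon - baseline$lon) * 111.320 * cos(baseline$lat * pi / 180),
       north = (lat - baseline$lat) * 110.574)
}

#' Project samples onto the transect axis
#'
#' Computes each sample's signed perpendicular distance (km) from the baseline
#' using a local equirectangular projection about the anchor; positive on the
#' NW side of a SW-NE baseline.
#'
#' @param samples sample data frame with `lon`, `lat` columns.
#' @param baseline a [transect_baseline()].
#' @return numeric vector of distances `x` (km), one per row of `samples`.
#' @export
project_to_transect <- function(samples, baseline) {
  stopifnot(inherits(baseline, "transect_baseline"))
  v <- .local_km(samples$lon, samples$lat, baseline)
  th <- baseline$bearing * pi / 180
  # unit normal to the bearing-th line, pointing NW for th = 45
  -v$east * cos(th) + v$north * sin(th)
}

# inverse of project_to_transect: place a point at along-line coordinate s km
# and perpendicular coordinate x km; used by the simulator so true transect
# distances are exact.
transect_to_lonlat <- function(s, x, baseline) {
  th <- baseline$bearing * pi / 180
  east <- s * sin(th) - x * cos(th)
  north <- s * cos(th) + x * sin(th)
  list(lon = baseline$lon + east / (111.320 * cos(baseline$lat * pi / 180)),
       lat = baseline$lat + north / 110.574)
}

#' Sigmoid geographic cline function
#'
#' `p(x) = pmin + (pmax - pmin) / (1 + exp(-4 (x - c) / w))`. The factor 4
#' makes `w` the conventional cline width, the inverse of the maximum slope
#' of the scaled sigmoid.
#'
#' @param x transect distance (km).
#' @param pmin,pmax tail ancestry proportions.
#' @param centre cline centre c (km).
#' @param width cline width w (km, > 0).
#' @return expected ancestry proportion at `x`.
#' @export
cline_p <- function(x, pmin, pmax, centre, width) {
  pmin + (pmax - pmin) / (1 + exp(-4 * (x - centre) / width))
}

#' Fit a sigmoid geographic cline
#'
#' Box-constrained least squares of ancestry proportion `q` on transect
#' distance `x` under the four-parameter sigmoid [cline_p()], with seeded
#' multi-start to avoid local optima.
#'
#' @param x transect distances (km).
#' @param q ancestry proportions in `[0, 1]`.
#' @param restarts number of random restarts beyond the deterministic starts.
#' @param seed integer seed for the restart draws.
#' @param period optional period label carried into the result.
#' @return an object of class `geo_cline` with elements `pmin`, `pmax`,
#'   `centre`, `width`, `resid_sd`, `n`, `sse`, `degenerate`, `period`.
#' @export
fit_geographic_cline <- function(x, q, restarts = 20, seed = 1, period = NA) {
  ok <- is.finite(x) & is.finite(q)
  x <- x[ok]; q <- q[ok]
  if (length(x) < 8) stop("need at least 8 individuals to fit a cline")
  if (sd(q) < 1e-10) {
    res <- structure(list(pmin = mean(q), pmax = mean(q), centre = NA_real_,
                          width = NA_real_, resid_sd = 0, n = length(x),
                          sse = 0, degenerate = TRUE, period = period),
                     class = "geo_cline")
    warning("constant ancestry values: cline parameters unidentifiable")
    return(res)
  }
  rng <- range(x); pad <- 0.5 * diff(rng) + 1
  lower <- c(0, 0, rng[1] - pad, 1e-3)
  upper <- c(1, 1, rng[2] + pad, 4 * (diff(rng) + 1))
  obj <- function(par) {
    pr <- cline_p(x, par[1], par[2], par[3], par[4])
    sum((q - pr)^2) + 1e6 * max(0, par[1] - par[2] + 1e-4)^2
  }
  qlo <- unname(quantile(q, 0.05)); qhi <- unname(quantile(q, 0.95))
  starts <- list(
    c(qlo, qhi, median(x), diff(rng) / 4),
    c(qlo, qhi, unname(quantile(x, 0.35)), diff(rng) / 8),
    c(qlo, qhi, unname(quantile(x, 0.65)), diff(rng) / 8),
    c(0, 1, median(x), diff(rng) / 2))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (i in seq_len(restarts)) {
    starts[[length(starts) + 1]] <-
      c(runif(1, 0, 0.3), runif(1, 0.7, 1),
        runif(1, rng[1], rng[2]), runif(1, 0.02, 1) * (diff(rng) + 1))
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all cline fits failed")
  par <- best$par
  structure(list(pmin = par[1], pmax = par[2], centre = par[3],
                 width = par[4],
                 resid_sd = sqrt(best$value / max(1, length(x) - 4)),
                 n = length(x), sse = best$value,
                 degenerate = par[2] - par[1] < 1e-3,
                 period = period),
            class = "geo_cline")
}

#' @export
print.geo_cline <- function(x, ...) {
  cat(sprintf(
    "geographic cline (n = %d%s): pmin = %.3f, pmax = %.3f, centre = %.2f km, width = %.2f km\n",
    x$n, if (is.na(x$period)) "" else paste0(", period ", x$period),
    x$pmin, x$pmax, x$centre, x$width))
  if (isTRUE(x$degenerate)) cat("  [degenerate fit]\n")
  invisible(x)
}

#' Bootstrap confidence intervals for a geographic cline
#'
#' Nonparametric resampling of individuals; each resample is refitted starting
#' from the full-data estimate (plus jittered restarts). Degenerate or failed
#' resample fits are dropped and counted.
#'
#' @param x,q data as in [fit_geographic_cline()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param fit optional full-data `geo_cline` (refitted here when `NULL`).
#' @param restarts restarts per resample fit.
#' @return list with `ci` (data frame: parameter, lo, hi), `boot` (resample
#'   parameter matrix), `n_dropped`, and the full-data `fit`.
#' @export
bootstrap_cline <- function(x, q, n_boot = 1000, seed = 1, fit = NULL,
                            restarts = 2) {
  if (is.null(fit)) fit <- fit_geographic_cline(x, q, seed = seed)
  if (isTRUE(fit$degenerate)) stop("cannot bootstrap a degenerate fit")
  ok <- is.finite(x) & is.finite(q)
  x <- x[ok]; q <- q[ok]
  n <- length(x)
  rng0 <- range(x); pad <- 0.5 * diff(rng0) + 1
  lower <- c(0, 0, rng0[1] - pad, 1e-3)
  upper <- c(1, 1, rng0[2] + pad, 4 * (diff(rng0) + 1))
  par0 <- c(fit$pmin, fit$pmax, fit$centre, fit$width)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("pmin", "pmax", "centre", "width")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; qb <- q[idx]
    if (sd(qb) < 1e-10) next
    obj <- function(par) {
      pr <- cline_p(xb, par[1], par[2], par[3], par[4])
      sum((qb - pr)^2) + 1e6 * max(0, par[1] - par[2] + 1e-4)^2
    }
    best <- NULL
    for (r in 0:restarts) {
      st <- if (r == 0) par0 else
        pmin(pmax(par0 * exp(rnorm(4, 0, 0.1)) +
                    c(0, 0, rnorm(1, 0, 2), 0), lower), upper)
      f <- tryCatch(optim(st, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 300)),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    if (!is.null(best) && best$par[2] - best$par[1] >= 1e-3)
      boot[b, ] <- best$par
  }
  done <- complete.cases(boot)
  if (!any(done)) stop("all bootstrap resamples degenerate")
  ci <- t(apply(boot[done, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975)))
  list(ci = data.frame(parameter = rownames(ci), lo = ci[, 1], hi = ci[, 2],
                       row.names = NULL),
       boot = boot[done, , drop = FALSE],
       n_dropped = sum(!done), fit = fit)
}

#' Estimate hybrid-zone movement between two periods
#'
#' The shift is the difference of fitted cline centres, positive towards the
#' NW side of the transect, with the per-year rate over the sampling interval.
#' When both bootstrap objects are supplied, a 95% CI for the shift is formed
#' by differencing independently resampled draws from the two periods'
#' bootstrap centre distributions.
#'
#' @param cline1,cline2 `geo_cline` fits for the earlier and later period.
#' @param interval_years elapsed years between the periods (> 0).
#' @param boot1,boot2 optional outputs of [bootstrap_cline()] for each period.
#' @param seed seed for the CI resampling.
#' @return object of class `cline_shift`: `delta_c_km`, `rate_km_per_yr`,
#'   `interval_years`, and `ci` (lo, hi) when bootstraps were given.
#' @export
estimate_movement <- function(cline1, cline2, interval_years,
                              boot1 = NULL, boot2 = NULL, seed = 1) {
  stopifnot(inherits(cline1, "geo_cline"), inherits(cline2, "geo_cline"))
  if (isTRUE(cline1$degenerate) || isTRUE(cline2$degenerate))
    stop("cannot estimate movement from a degenerate cline fit")
  if (interval_years <= 0) stop("interval_years must be > 0")
  dc <- cline2$centre - cline1$centre
  ci <- NULL
  if (!is.null(boot1) && !is.null(boot2)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    nn <- 10000
    d <- sample(boot2$boot[, "centre"], nn, replace = TRUE) -
      sample(boot1$boot[, "centre"], nn, replace = TRUE)
    ci <- unname(quantile(d, c(0.025, 0.975)))
  }
  structure(list(delta_c_km = dc, rate_km_per_yr = dc / interval_years,
                 interval_years = interval_years, ci = ci),
            class = "cline_shift")
}

#' @export
print.cline_shift <- function(x, ...) {
  cat(sprintf("cline shift: %.2f km over %g years (%.3f km/yr)\n",
              x$delta_c_km, x$interval_years, x$rate_km_per_yr))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI for shift: [%.2f, %.2f] km\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-sample temporal comparison
#'
#' The between-period tests used on site-level ancestry summaries: Welch's
#' t test (Satterthwaite df), the Mann-Whitney U test (exact for small
#' tie-free samples, otherwise normal approximation with tie correction), or
#' a two-proportion z test without continuity correction.
#'
#' @param values1,values2 numeric observations per group; for
#'   `"two_proportion"`, length-2 vectors `c(successes, n)`.
#' @param test one of `"welch_t"`, `"mann_whitney"`, `"two_proportion"`.
#' @return list with `statistic` and two-sided `p`.
#' @export
compare_periods <- function(values1, values2,
                            test = c("welch_t", "mann_whitney",
                                     "two_proportion")) {
  test <- match.arg(test)
  if (test == "two_proportion") {
    if (length(values1) != 2 || length(values2) != 2)
      stop("two_proportion expects c(successes, n) per group")
    ht <- prop.test(c(values1[1], values2[1]), c(values1[2], values2[2]),
                    correct = FALSE)
    p1 <- values1[1] / values1[2]; p2 <- values2[1] / values2[2]
    z <- sign(p1 - p2) * sqrt(unname(ht$statistic))
    return(list(statistic = z, p = ht$p.value, test = test))
  }
  if (length(values1) < 2 || length(values2) < 2)
    stop("need at least 2 observations per group")
  if (test == "welch_t") {
    if (sd(values1) == 0 && sd(values2) == 0 &&
        mean(values1) == mean(values2))
      return(list(statistic = 0, p = 1, test = test))
    ht <- t.test(values1, values2, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
  } else {
    ht <- suppressWarnings(wilcox.test(values1, values2))
    list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
  }
}

#' Inverse-distance-weighted ancestry surface
#'
#' Interpolates per-sample ancestry onto a regular lon/lat grid for visual
#' assessment of interface position; movement itself is quantified by the
#' cline fits, not this surface. Grid nodes coincident with a sample take
#' that sample's value exactly; values are clipped to `[0, 1]`.
#'
#' @param samples sample data frame with `lon`, `lat`.
#' @param q ancestry values, one per sample.
#' @param grid list with `ncols`, `nrows`, `xll`, `yll`, `cellsize` (degrees).
#' @param power IDW power (default 2).
#' @return a [climate_grid()] holding the surface (variable `"ancestry"`).
#' @export
interpolate_ancestry_surface <- function(samples, q, grid, power = 2) {
  if (nrow(samples) < 1) stop("need at least 1 sample")
  req <- c("ncols", "nrows", "xll", "yll", "cellsize")
  if (!all(req %in% names(grid)) || grid$ncols < 1 || grid$nrows < 1 ||
      grid$cellsize <= 0)
    stop("degenerate grid spec; need ", paste(req, collapse = ", "))
  lon_c <- grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  lat_c <- grid$yll + (seq_len(grid$nrows) - 0.5) * grid$cellsize
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (i in seq_len(grid$nrows)) {
    for (j in seq_len(grid$ncols)) {
      d2 <- (samples$lon - lon_c[j])^2 + (samples$lat - lat_c[i])^2
      hit <- which(d2 < 1e-18)
      vals[i, j] <- if (length(hit)) q[hit[1]] else {
        w <- 1 / sqrt(d2)^power
        sum(w * q) / sum(w)
      }
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  # row 1 = northernmost row, matching the ASCII-grid layout
  climate_grid(vals[grid$nrows:1, , drop = FALSE], xll = grid$xll,
               yll = grid$yll, cellsize = grid$cellsize,
               variable = "ancestry")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
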