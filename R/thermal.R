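#' Fit the peaked Arrhenius function to a capacity-temperature series
#'
#' Least-squares fit of the optimum-parameterised peaked Arrhenius function
#' to Vcmax or Jmax values measured at several leaf temperatures, with the
#' deactivation energy Hd fixed (default 200 kJ mol-1) to avoid
#' over-parameterisation. `kopt` is profiled out linearly, and the remaining
#' (Topt, Ea) surface is minimised by Nelder-Mead from a multistart grid
#' (Topt in {25, 30, 35} degC, Ea in {40, 60} kJ mol-1), since 4-5 point
#' series can carry local minima.
#'
#' @param tleaf Leaf temperatures (degC), >= 4 points.
#' @param values Rates at `tleaf` (umol m-2 s-1), all > 0.
#' @param hd Fixed deactivation energy (kJ mol-1).
#' @param starts Data.frame of starting values with columns `topt` (degC) and
#'   `ea` (kJ mol-1).
#' @return An object of class `arrhenius_fit`: `kopt`, `topt` (degC), `ea`
#'   (kJ mol-1), `hd`, `sse`, `converged`, `flag` (`"ok"` or
#'   `"topt_out_of_range"` when Topt leaves [5, 50] degC).
#' @export
fit_peaked_arrhenius <- function(tleaf, values, hd = 200,
                                 starts = expand.grid(topt = c(25, 30, 35),
                                                      ea = c(40, 60))) {
  if (length(tleaf) != length(values))
    stop("invalid-input: tleaf and values differ in length")
  if (length(tleaf) < 4)
    stop("insufficient-data: >= 4 temperatures are needed with Hd fixed")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("invalid-input: all values must be finite and > 0")
  tk <- tleaf + 273.15

  obj <- function(p) {
    if (p[2] <= 1 || p[2] >= hd - 1 || p[1] < -20 || p[1] > 70) return(1e12)
    g <- peaked_arrhenius(1, p[1] + 273.15, p[2], hd, tk)
    k <- sum(values * g) / sum(g * g)
    sum((values - k * g)^2)
  }

  best <- NULL
  diagnostics <- character(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$topt[i], starts$ea[i]), obj,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-13, maxit = 800)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics[i] <- conditionMessage(fit)
      next
    }
    diagnostics[i] <- sprintf("sse %.4g (convergence %d)", fit$value, fit$convergence)
    if (fit$convergence != 0) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop(paste0("non-convergence: no start converged; ",
                paste(sprintf("start %d: %s", seq_along(diagnostics), diagnostics),
                      collapse = "; ")))
  # polish from the winning start
  ref <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-13, maxit = 800))
  if (ref$convergence == 0 && ref$value <= best$value) best <- ref

  topt <- best$par[1]; ea <- best$par[2]
  g <- peaked_arrhenius(1, topt + 273.15, ea, hd, tk)
  kopt <- sum(values * g) / sum(g * g)
  structure(list(kopt = kopt, topt = topt, ea = ea, hd = hd,
                 sse = best$value, converged = TRUE,
                 flag = if (topt < 5 || topt > 50) "topt_out_of_range" else "ok"),
            class = "arrhenius_fit")
}

#' Fit the quadratic temperature response and extract the thermal optimum
#'
#' Exact linear least squares on the polynomial basis
#' `a = c0 + c1 t + c2 t^2`, re-expressed as `b = -c2`,
#' `topt_a = -c1 / (2 c2)`, `aopt = c0 - c1^2 / (4 c2)`. A fit with
#' `c2 >= 0` has no interior optimum and is flagged (downstream analyses
#' exclude the tree).
#'
#' @param tleaf Temperatures (degC), >= 3 distinct values.
#' @param values Net photosynthesis at `tleaf` (umol m-2 s-1).
#' @return An object of class `quadratic_fit`: `aopt`, `topt_a` (degC), `b`,
#'   `sse`, `converged`, `flag` (`"ok"`, `"no_optimum"`, or
#'   `"topt_out_of_range"` when `topt_a` falls outside the measured range
#'   +/- 10 degC).
#' @export
fit_quadratic_topt <- function(tleaf, values) {
  if (length(tleaf) != length(values))
    stop("invalid-input: tleaf and values differ in length")
  ok <- is.finite(tleaf) & is.finite(values)
  tleaf <- tleaf[ok]; values <- values[ok]
  if (length(unique(tleaf)) < 3)
    stop("degenerate-fit: need >= 3 distinct temperatures")
  X <- cbind(1, tleaf, tleaf^2)
  qr_x <- qr(X)
  if (qr_x$rank < 3)
    stop("degenerate-fit: collinear design")
  cf <- unname(qr.coef(qr_x, values))
  resid <- values - X %*% cf
  sse <- sum(resid^2)
  c0 <- cf[1]; c1 <- cf[2]; c2 <- cf[3]
  # curvature indistinguishable from zero (relative to the response scale)
  # means no interior optimum
  if (c2 >= -1e-10 * max(1, abs(c0))) {
    return(structure(list(aopt = NA_real_, topt_a = NA_real_, b = -c2,
                          sse = sse, converged = FALSE, flag = "no_optimum"),
                     class = "quadratic_fit"))
  }
  topt_a <- -c1 / (2 * c2)
  flag <- if (topt_a < min(tleaf) - 10 || topt_a > max(tleaf) + 10)
    "topt_out_of_range" else "ok"
  structure(list(aopt = c0 - c1^2 / (4 * c2), topt_a = topt_a, b = -c2,
                 sse = sse, converged = TRUE, flag = flag),
            class = "quadratic_fit")
}

#' Summarise plot air temperature over the pre-measurement window
#'
#' Filters a timestamped air-temperature series to the photosynthetically
#' active daytime hours (default 09:00-15:00, start-inclusive/end-exclusive)
#' over the `window_days` full days strictly before the measurement date, and
#' returns the mean and maximum of the retained values.
#'
#' @param climate Data.frame with columns `timestamp` (POSIXct or ISO-8601
#'   character, local time) and `air_temp_c`.
#' @param measurement_date Date (or coercible) of the measurement day.
#' @param window_days Number of preceding days (default 10).
#' @param daily_hours Numeric length-2, local decimal hours retained
#'   (default `c(9, 15)`).
#' @return A list of class `climate_summary`: `window` (start/end dates),
#'   `daily_hours`, `mean_t`, `max_t`, `n`, `coverage`.
#' @export
summarize_climate <- function(climate, measurement_date, window_days = 10,
                              daily_hours = c(9, 15)) {
  ts <- climate$timestamp
  if (!inherits(ts, "POSIXct")) {
    # parse the full date-time format first: base R otherwise locks onto the
    # format of the first element, and a midnight stamp ("2017-06-12") would
    # silently strip the time of day from every row
    p <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    na <- is.na(p)
    p[na] <- as.POSIXct(ts[na], tz = "UTC")
    ts <- p
  }
  if (any(diff(as.numeric(ts)) <= 0))
    stop("invalid-input: timestamps must be strictly increasing")
  md <- as.Date(measurement_date)
  day <- as.Date(ts, tz = "UTC")
  lt <- as.POSIXlt(ts, tz = "UTC")
  hfrac <- lt$hour + lt$min / 60 + lt$sec / 3600
  keep <- hfrac >= daily_hours[1] & hfrac < daily_hours[2] &
    day >= md - window_days & day <= md - 1
  n <- sum(keep)
  if (n == 0)
    stop("empty-window: no samples in the requested window")
  step <- stats::median(diff(as.numeric(ts)))
  expected <- window_days * (daily_hours[2] - daily_hours[1]) * 3600 / step
  coverage <- n / expected
  if (coverage < 0.5)
    warning(sprintf("coverage warning: only %.0f%% of expected samples in window",
                    100 * coverage))
  structure(list(window = c(start = md - window_days, end = md - 1),
                 daily_hours = daily_hours,
                 mean_t = mean(climate$air_temp_c[keep]),
                 max_t = max(climate$air_temp_c[keep]),
                 n = n, coverage = coverage),
            class = "climate_summary")
}

#' Net photosynthesis at a growth temperature from a fitted quadratic
#'
#' Evaluates the fitted quadratic temperature response at the (mean or
#' maximum) growth temperature. Negative values are returned as-is (net A
#' may be negative) but flagged via an attribute.
#'
#' @param fit A converged [fit_quadratic_topt()] result.
#' @param t Growth temperature (degC). Vectorised.
#' @return A at `t` (umol m-2 s-1), with attribute `negative` marking
#'   below-zero values.
#' @export
compute_ag <- function(fit, t) {
  if (!isTRUE(fit$converged))
    stop("invalid-input: quadratic fit did not converge (no optimum)")
  a <- quadratic_a(fit$aopt, fit$topt_a, fit$b, t)
  attr(a, "negative") <- a < 0
  a
}

#' Exceedance of the thermal optimum by growth temperature
#'
#' Returns `mean growth temperature - topt_a`; positive values mean the
#' prevailing daytime air temperature exceeds the thermal optimum of net
#' photosynthesis.
#'
#' @param climate A [summarize_climate()] result.
#' @param fit A converged [fit_quadratic_topt()] result.
#' @return Delta-MeanTg (degC).
#' @export
compute_delta_mean_tg <- function(climate, fit) {
  if (!isTRUE(fit$converged))
    stop("invalid-input: quadratic fit did not converge (no optimum)")
  climate$mean_t - fit$topt_a
}

#' Recompute net photosynthesis at a fixed Ci/Ca ratio (A70) and its optimum
#'
#' Removes stomatal variation from the temperature response by recomputing A
#' at `Ci = 0.7 * growth Ca` (280 or 560 ppm for ambient / elevated CO2) at
#' every measured leaf temperature, using the per-temperature fitted Vcmax,
#' Jmax, Rday and TPU, then fits the quadratic temperature response to the
#' resulting A70 series.
#'
#' @param fits Data.frame with one row per leaf temperature: columns
#'   `tleaf_c`, `vcmax`, `jmax`, `rday`, and optionally `tpu` (NA disables
#'   the TPU state at that temperature).
#' @param growth_ca Growth CO2 (umol mol-1).
#' @param constants A [kinetic_constants()] object.
#' @param ci_ca_ratio Operating Ci/Ca ratio (default 0.7).
#' @return A list with `series` (data.frame `tleaf_c`, `ci`, `a70`,
#'   `limitation`) and `fit` (a `quadratic_fit` on the A70 series).
#' @export
compute_a70_topt <- function(fits, growth_ca, constants = kinetic_constants(),
                             ci_ca_ratio = 0.7) {
  ci <- ci_ca_ratio * growth_ca
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    tpu_i <- if ("tpu" %in% names(fits)) fits$tpu[i] else NA_real_
    net_a(ci, fits$vcmax[i], fits$jmax[i], fits$rday[i],
          tleaf = fits$tleaf_c[i],
          tpu = if (is.na(tpu_i)) Inf else tpu_i,
          constants = constants)
  })
  res <- do.call(rbind, rows)
  series <- data.frame(tleaf_c = fits$tleaf_c, ci = ci,
                       a70 = res$a, limitation = res$limitation)
  list(series = series, fit = fit_quadratic_topt(series$tleaf_c, series$a70))
}
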