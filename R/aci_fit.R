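#' Fit one A-Ci curve by the bilinear method
#'
#' Estimates apparent Vcmax, Jmax and Rday (and TPU when expressed) from a
#' single CO2-response curve by the bilinear method: points are sorted by Ci
#' and every admissible partition into a low-Ci (Rubisco-limited) and a
#' high-Ci (RuBP-regeneration-limited) segment is scored. For each partition,
#' (i) A is regressed on `x1 = (Ci - Gamma*) / (Ci + Kc (1 + O/Ko))` over the
#' low segment, giving `Vcmax` (slope) and `Rday` (minus the intercept);
#' (ii) with Rday fixed, `A + Rday` is regressed through the origin on
#' `x2 = (Ci - Gamma*) / (Ci + 2 Gamma*)` over the high segment, giving
#' `Jmax/4`. The partition minimising the total SSE of the reconstructed
#' piecewise model `min(Ac, Aj)` wins.
#'
#' TPU is fitted only when the mean of A over the two highest-Ci steps falls
#' below the Aj prediction by more than one standard error (residual SE of
#' the high segment / sqrt(2)); then `TPU = (mean top-segment A + Rday) / 3`.
#'
#' @param ci Intercellular CO2 per point (umol mol-1).
#' @param a Net assimilation per point (umol m-2 s-1).
#' @param tleaf Leaf temperature of the curve (degC).
#' @param constants A [kinetic_constants()] object.
#' @param min_seg Minimum points per segment (default 3).
#' @param fit_tpu Attempt TPU detection? Default `TRUE`.
#' @return An object of class `aci_fit`: a list with `vcmax`, `jmax`, `rday`,
#'   `tpu` (NA when not expressed), `transition_ci`, `sse`, `limitation`
#'   (per-point labels, Ci-sorted), `n_points`, `rday_clamped`, and the sorted
#'   `data`.
#' @export
fit_aci_bilinear <- function(ci, a, tleaf, constants = kinetic_constants(),
                             min_seg = 3, fit_tpu = TRUE) {
  if (length(ci) != length(a)) stop("invalid-input: ci and a differ in length")
  ok <- is.finite(ci) & is.finite(a)
  ci <- ci[ok]; a <- a[ok]
  n <- length(ci)
  if (n < 6 || sum(ci < 300) < 3 || sum(ci > 500) < 3)
    stop("degenerate-curve: need >= 6 points with >= 3 below Ci 300 and >= 3 above Ci 500")
  ord <- order(ci)
  ci <- ci[ord]; a <- a[ord]

  gs <- arrhenius_scaled(constants$gammastar25, constants$ea_gammastar, tleaf, constants)
  kc <- arrhenius_scaled(constants$kc25, constants$ea_kc, tleaf, constants)
  ko <- arrhenius_scaled(constants$ko25, constants$ea_ko, tleaf, constants)
  km <- kc * (1 + constants$oxygen / ko)
  x1 <- (ci - gs) / (ci + km)
  x2 <- (ci - gs) / (ci + 2 * gs)

  best <- NULL
  for (k in seq(min_seg, n - min_seg)) {
    lo <- seq_len(k)
    hi <- seq.int(k + 1, n)
    mx <- mean(x1[lo]); ma <- mean(a[lo])
    sxx <- sum((x1[lo] - mx)^2)
    if (sxx <= .Machine$double.eps) next
    vcmax <- sum((x1[lo] - mx) * (a[lo] - ma)) / sxx
    rday <- -(ma - vcmax * mx)
    clamped <- FALSE
    if (rday < 0) {
      # nonphysical intercept: clamp and refit the slope through the origin
      rday <- 0
      vcmax <- sum(a[lo] * x1[lo]) / sum(x1[lo]^2)
      clamped <- TRUE
    }
    jq <- sum((a[hi] + rday) * x2[hi]) / sum(x2[hi]^2)  # Jmax / 4
    # below the compensation point the Rubisco branch applies (the pointwise
    # minimum would unphysically pick Aj there)
    ahat <- ifelse(ci < gs, vcmax * x1, pmin(vcmax * x1, jq * x2)) - rday
    sse <- sum((a - ahat)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, vcmax = vcmax, rday = rday, jq = jq,
                   sse = sse, clamped = clamped)
  }
  if (is.null(best))
    stop("degenerate-curve: no admissible partition")
  if (best$vcmax <= 0 || best$jq <= 0)
    stop(sprintf(paste0("fit-failure: negative capacity estimate ",
                        "(vcmax = %.3g, jmax = %.3g) at tleaf %.1f"),
                 best$vcmax, 4 * best$jq, tleaf))
  if (best$clamped)
    warning("negative Rday intercept clamped to 0")

  vcmax <- best$vcmax; rday <- best$rday; jmax <- 4 * best$jq
  transition_ci <- mean(ci[c(best$k, best$k + 1)])

  tpu <- NA_real_
  if (fit_tpu && n >= 2) {
    hi <- seq.int(best$k + 1, n)
    top <- c(n - 1, n)
    aj_hat <- best$jq * x2 - rday
    res_hi <- a[hi] - aj_hat[hi]
    rse <- sqrt(sum(res_hi^2) / max(1, length(hi) - 1))
    if (mean(aj_hat[top]) - mean(a[top]) > rse / sqrt(2))
      tpu <- (mean(a[top]) + rday) / 3
  }

  branches <- cbind(Ac = vcmax * x1 - rday,
                    Aj = best$jq * x2 - rday,
                    ATPU = if (is.na(tpu)) rep(Inf, n) else rep(3 * tpu, n))
  lab <- colnames(branches)[apply(branches, 1, which.min)]
  lab[ci < gs] <- "Ac"

  structure(list(vcmax = vcmax, jmax = jmax, rday = rday, tpu = tpu,
                 transition_ci = transition_ci, sse = best$sse,
                 limitation = lab, n_points = n,
                 rday_clamped = best$clamped,
                 data = data.frame(ci = ci, a = a)),
            class = "aci_fit")
}

#' Extract net photosynthesis at the tree's growth CO2
#'
#' Averages the measured A over all curve steps whose chamber CO2 lies within
#' `tolerance` of the growth CO2 (the measurement protocol visits Ca = 400
#' twice; both visits are used).
#'
#' @param curve A data.frame with columns `ca_ppm` and `a_umol_m2_s`
#'   (one A-Ci curve).
#' @param growth_ca Growth CO2 (umol mol-1), e.g. 400 or 800.
#' @param tolerance Matching tolerance (ppm), default 25.
#' @return Mean A over matching steps (umol m-2 s-1).
#' @export
extract_growth_a <- function(curve, growth_ca, tolerance = 25) {
  hit <- abs(curve$ca_ppm - growth_ca) <= tolerance
  if (!any(hit)) {
    id <- paste(unique(curve$tree_id), collapse = ",")
    tl <- paste(unique(curve$tleaf_c), collapse = ",")
    stop(sprintf("missing-step: no Ca within %g ppm of %g (tree %s, tleaf %s)",
                 tolerance, growth_ca, id, tl))
  }
  mean(curve$a_umol_m2_s[hit])
}

#' Fit every A-Ci curve in a measurement table
#'
#' Groups a long per-point table (one row per A-Ci step) by tree, month and
#' leaf temperature and applies [fit_aci_bilinear()] to each curve. Curves
#' that fail to fit are excluded with a warning and flagged in the output
#' (never silently imputed); this most often affects the noisy 45 degC
#' curves.
#'
#' @param curves Data.frame with columns `plot_id`, `species`,
#'   `co2_treatment`, `warming_offset_c`, `tree_id`, `month`, `tleaf_c`,
#'   `step_index`, `ca_ppm`, `ci_ppm`, `a_umol_m2_s`.
#' @param constants A [kinetic_constants()] object.
#' @param ... Passed to [fit_aci_bilinear()].
#' @return Data.frame, one row per (tree, month, tleaf): design columns plus
#'   `vcmax`, `jmax`, `rday`, `tpu`, `transition_ci`, `sse`, `n_points`,
#'   `flag` (`"ok"` or the failure message).
#' @export
fit_aci_table <- function(curves, constants = kinetic_constants(), ...) {
  key <- interaction(curves$plot_id, curves$tree_id, curves$month,
                     curves$tleaf_c, drop = TRUE)
  out <- lapply(split(curves, key), function(g) {
    meta <- g[1, c("plot_id", "species", "co2_treatment", "warming_offset_c",
                   "tree_id", "month", "tleaf_c")]
    fit <- tryCatch(
      suppressWarnings(fit_aci_bilinear(g$ci_ppm, g$a_umol_m2_s,
                                        tleaf = g$tleaf_c[1],
                                        constants = constants, ...)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("curve dropped (%s %s %s tleaf %.1f): %s",
                      meta$plot_id, meta$tree_id, meta$month, meta$tleaf_c,
                      conditionMessage(fit)))
      cbind(meta, data.frame(vcmax = NA_real_, jmax = NA_real_,
                             rday = NA_real_, tpu = NA_real_,
                             transition_ci = NA_real_, sse = NA_real_,
                             n_points = nrow(g),
                             flag = conditionMessage(fit)))
    } else {
      cbind(meta, data.frame(vcmax = fit$vcmax, jmax = fit$jmax,
                             rday = fit$rday, tpu = fit$tpu,
                             transition_ci = fit$transition_ci,
                             sse = fit$sse, n_points = fit$n_points,
                             flag = "ok"))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
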