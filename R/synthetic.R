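#' Default acclimation relations for a species
#'
#' Linear acclimation relations (intercept, slope per degC warming, additive
#' CO2 offset, and CO2-specific slope change) for the thermal optimum of net
#' photosynthesis (`topt_a`), the optima of the biochemical capacities
#' (`topt_v`, `topt_j`) and the peak rate (`aopt`), together with the
#' curvature parameter and capacity scale defaults. The shipped values encode
#' the acclimation structure observed in the warming x CO2 enclosure
#' experiment the generator emulates (e.g. tamarack ToptA = 23.2 + 0.26 x
#' warming, +3 degC under elevated CO2; spruce ToptA = 23.3 + 0.35 x
#' warming with no CO2 effect).
#'
#' @param species `"tamarack"` or `"black_spruce"`.
#' @return A named list of relations and scalar defaults.
#' @export
default_acclimation <- function(species = c("tamarack", "black_spruce")) {
  species <- match.arg(species)
  rel <- function(intercept, slope, co2_offset = 0, co2_slope_delta = 0)
    list(intercept = intercept, slope = slope, co2_offset = co2_offset,
         co2_slope_delta = co2_slope_delta)
  if (species == "tamarack") {
    list(topt_a = rel(23.2, 0.26, co2_offset = 3.0),
         aopt   = rel(7.9, 0.26, co2_offset = 3.0),
         topt_v = rel(33.0, 0.35),
         topt_j = rel(31.8, 0.26),
         b_base = 0.011, b_co2_ratio = 1.86,
         ea_v = 55, ea_j = 40, kopt_v = 60, kopt_j = 110)
  } else {
    list(topt_a = rel(23.3, 0.35),
         aopt   = rel(6.4, 0.10, co2_offset = -0.1, co2_slope_delta = 0.44),
         topt_v = rel(30.6, 0.44),
         topt_j = rel(28.6, 0.55),
         b_base = 0.011, b_co2_ratio = 1.0,
         ea_v = 55, ea_j = 40, kopt_v = 55, kopt_j = 100)
  }
}

#' Configuration of a synthetic warming x CO2 experiment
#'
#' Describes the experimental design (10 plots = 5 warming offsets x 2 CO2
#' atmospheres, 1-4 trees per plot, two monthly campaigns), the measurement
#' protocol (A-Ci curves at 5 leaf temperatures x the 11-step Ca sequence),
#' the per-species acclimation relations used as ground truth, and the noise
#' structure.
#'
#' @param species `"tamarack"` or `"black_spruce"`.
#' @param warming_levels Warming offsets above ambient (degC).
#' @param co2_levels Named growth Ca per CO2 treatment (umol mol-1).
#' @param trees_per_plot Trees sampled per plot (1-4).
#' @param months Campaign months.
#' @param tleaf_set Leaf temperatures of the A-Ci curves (degC).
#' @param ca_steps The 11-step chamber CO2 sequence (umol mol-1).
#' @param acclimation Acclimation relations, see [default_acclimation()].
#' @param sigma_a Gaussian noise on measured A (umol m-2 s-1).
#' @param cv_capacity Relative (multiplicative) noise on capacities, Aopt
#'   and b.
#' @param sigma_topt Plot-level Gaussian noise on thermal-optimum truths
#'   (degC).
#' @param sigma_tree Tree-level Gaussian noise on thermal-optimum truths
#'   (degC).
#' @param sigma_aopt Plot-level noise on the Aopt truth (umol m-2 s-1).
#' @param month_offset Additive August-minus-June shift applied to the
#'   thermal-optimum truths (degC), centred so the configured intercepts
#'   remain the across-month means.
#' @param ci_ca_ratio Operating Ci/Ca ratio of the constant-ratio stomatal
#'   model used when generating curves.
#' @param rday25 Day respiration at 25 degC (umol m-2 s-1).
#' @param q10 Q10 of the Rday temperature scaling.
#' @param tpu25 Triose-phosphate use at 25 degC (umol m-2 s-1); `NULL`
#'   disables the TPU limitation (the default keeps round-trips in the
#'   two-state regime the bilinear fitter targets).
#' @param hd Deactivation energy of the capacity temperature response
#'   (kJ mol-1).
#' @param constants A [kinetic_constants()] object.
#' @param climate_mean Ambient daily-mean air temperature (degC).
#' @param climate_amplitude Diurnal half-amplitude (degC), peak at 15:00.
#' @param sigma_weather SD of shared weather deviations (degC).
#' @param measurement_dates Named (by month) measurement dates.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(species = "tamarack",
                             warming_levels = c(0, 2.25, 4.5, 6.75, 9),
                             co2_levels = c(aCO2 = 400, eCO2 = 800),
                             trees_per_plot = 3,
                             months = c("June", "August"),
                             tleaf_set = c(15, 25, 32.5, 40, 45),
                             ca_steps = c(400, 300, 200, 50, 400, 500, 600,
                                          800, 1200, 1600, 2000),
                             acclimation = default_acclimation(species),
                             sigma_a = 0.5, cv_capacity = 0.05,
                             sigma_topt = 0.5, sigma_tree = 0.3,
                             sigma_aopt = 0.3,
                             month_offset = 0.5,
                             ci_ca_ratio = 0.7,
                             rday25 = 1, q10 = 2, tpu25 = NULL,
                             hd = 200,
                             constants = kinetic_constants(),
                             climate_mean = 16, climate_amplitude = 7,
                             sigma_weather = 1.5,
                             measurement_dates = c(June = "2017-06-24",
                                                   August = "2017-08-22")) {
  if (length(ca_steps) != 11)
    stop("config error: ca_steps must have length 11")
  if (anyDuplicated(warming_levels))
    stop("config error: warming levels must be distinct")
  if (any(c(sigma_a, cv_capacity, sigma_topt, sigma_tree, sigma_aopt,
            sigma_weather) < 0))
    stop("config error: noise SDs must be >= 0")
  if (trees_per_plot < 1 || trees_per_plot > 4)
    stop("config error: trees_per_plot must be in 1..4")
  structure(list(species = species, warming_levels = warming_levels,
                 co2_levels = co2_levels, trees_per_plot = trees_per_plot,
                 months = months, tleaf_set = tleaf_set, ca_steps = ca_steps,
                 acclimation = acclimation, sigma_a = sigma_a,
                 cv_capacity = cv_capacity, sigma_topt = sigma_topt,
                 sigma_tree = sigma_tree, sigma_aopt = sigma_aopt,
                 month_offset = month_offset, ci_ca_ratio = ci_ca_ratio,
                 rday25 = rday25, q10 = q10, tpu25 = tpu25, hd = hd,
                 constants = constants, climate_mean = climate_mean,
                 climate_amplitude = climate_amplitude,
                 sigma_weather = sigma_weather,
                 measurement_dates = measurement_dates),
            class = "synthetic_config")
}

relation_value <- function(rel, warming, eco2) {
  rel$intercept + rel$slope * warming +
    (rel$co2_offset + rel$co2_slope_delta * warming) * as.numeric(eco2)
}

#' Generate the plot and tree roster
#'
#' 10 plots (every warming offset crossed with both CO2 atmospheres), the
#' configured number of trees per plot, both campaign months. Deterministic
#' given the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Data.frame: `plot_id`, `warming_offset_c`, `co2_treatment`,
#'   `growth_ca`, `species`, `tree_id`, `month`.
#' @export
generate_design <- function(config, seed = 1) {
  set.seed(seed)
  plots <- expand.grid(warming_offset_c = config$warming_levels,
                       co2_treatment = names(config$co2_levels),
                       stringsAsFactors = FALSE)
  plots$plot_id <- sprintf("P%02d", seq_len(nrow(plots)))
  plots$growth_ca <- unname(config$co2_levels[plots$co2_treatment])
  roster <- merge(plots,
                  expand.grid(tree = seq_len(config$trees_per_plot),
                              month = config$months,
                              stringsAsFactors = FALSE))
  roster$tree_id <- paste0(roster$plot_id, "-T", roster$tree)
  roster$species <- config$species
  roster <- roster[order(roster$plot_id, roster$tree_id, roster$month),
                   c("plot_id", "warming_offset_c", "co2_treatment",
                     "growth_ca", "species", "tree_id", "month")]
  rownames(roster) <- NULL
  roster
}

#' Generate per-plot air-temperature series
#'
#' Half-hourly series covering the 10 days before (and including) each
#' measurement date: an ambient diurnal sinusoid (peak at 15:00) plus shared
#' weather deviations, offset by each plot's warming treatment. Because the
#' weather term is shared across plots (the enclosures sit in one bog), the
#' daytime-mean difference between a warmed plot and the ambient plot equals
#' the warming offset exactly.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param window_days Days of record before each measurement date.
#' @return Data.frame: `plot_id`, `timestamp` (POSIXct, UTC-encoded local
#'   time), `air_temp_c`.
#' @export
generate_climate <- function(config, seed = 1, window_days = 12) {
  set.seed(seed)
  md <- as.Date(config$measurement_dates)
  t0 <- as.POSIXct(paste(min(md) - window_days, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(md), "23:30:00"), tz = "UTC")
  ts <- seq(t0, t1, by = 1800)
  lt <- as.POSIXlt(ts, tz = "UTC")
  h <- lt$hour + lt$min / 60
  base <- config$climate_mean +
    config$climate_amplitude * cos(2 * pi * (h - 15) / 24)
  day_idx <- as.integer(as.Date(ts, tz = "UTC"))
  day_idx <- day_idx - min(day_idx) + 1
  daily <- stats::rnorm(max(day_idx), 0, config$sigma_weather)
  jitter <- stats::rnorm(length(ts), 0, config$sigma_weather / 4)
  ambient <- base + daily[day_idx] + jitter
  plots <- expand.grid(warming_offset_c = config$warming_levels,
                       co2_treatment = names(config$co2_levels),
                       stringsAsFactors = FALSE)
  plots$plot_id <- sprintf("P%02d", seq_len(nrow(plots)))
  out <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    data.frame(plot_id = plots$plot_id[i], timestamp = ts,
               air_temp_c = ambient + plots$warming_offset_c[i])
  }))
  rownames(out) <- NULL
  out
}

#' Generate per-tree ground-truth thermal parameters
#'
#' True parameters follow the configured linear acclimation relations
#' (intercept + slope x warming + CO2 offset), plus a centred month shift on
#' the thermal optima, plot-level noise (shared across a plot's trees and
#' months) and tree-level noise. Capacity scales (`kopt_v`, `kopt_j`), Aopt
#' and b carry multiplicative tree-level noise of CV `cv_capacity`.
#'
#' @param config A [synthetic_config()].
#' @param roster A [generate_design()] result.
#' @param seed Integer seed.
#' @return Data.frame, one row per tree x month, with all true parameters.
#' @export
generate_tree_truth <- function(config, roster, seed = 1) {
  set.seed(seed)
  acc <- config$acclimation
  # deterministic sanity check on the relations over the design range
  for (nm in c("topt_a", "topt_v", "topt_j")) {
    v <- relation_value(acc[[nm]],
                        rep(config$warming_levels, 2),
                        rep(c(FALSE, TRUE), each = length(config$warming_levels)))
    if (any(v < 5 | v > 50))
      stop(sprintf("config error: %s relation leaves [5, 50] degC", nm))
  }
  plots <- unique(roster$plot_id)
  trees <- unique(roster[, c("plot_id", "tree_id")])$tree_id
  plot_eps <- function(sd) stats::setNames(stats::rnorm(length(plots), 0, sd), plots)
  tree_eps <- function(sd) stats::setNames(stats::rnorm(length(trees), 0, sd), trees)
  pe <- list(topt_a = plot_eps(config$sigma_topt),
             topt_v = plot_eps(config$sigma_topt),
             topt_j = plot_eps(config$sigma_topt),
             aopt = plot_eps(config$sigma_aopt))
  te <- list(topt_a = tree_eps(config$sigma_tree),
             topt_v = tree_eps(config$sigma_tree),
             topt_j = tree_eps(config$sigma_tree),
             aopt = tree_eps(0))
  mult <- function() stats::setNames(
    exp(stats::rnorm(length(trees), 0, config$cv_capacity)), trees)
  m_aopt <- mult(); m_b <- mult(); m_kv <- mult(); m_kj <- mult()

  tr <- roster
  eco2 <- tr$co2_treatment == "eCO2"
  msh <- ifelse(tr$month == "August", config$month_offset / 2,
                -config$month_offset / 2)
  tr$topt_a <- relation_value(acc$topt_a, tr$warming_offset_c, eco2) + msh +
    pe$topt_a[tr$plot_id] + te$topt_a[tr$tree_id]
  tr$topt_v <- relation_value(acc$topt_v, tr$warming_offset_c, eco2) + msh +
    pe$topt_v[tr$plot_id] + te$topt_v[tr$tree_id]
  tr$topt_j <- relation_value(acc$topt_j, tr$warming_offset_c, eco2) + msh +
    pe$topt_j[tr$plot_id] + te$topt_j[tr$tree_id]
  tr$aopt <- (relation_value(acc$aopt, tr$warming_offset_c, eco2) +
                pe$aopt[tr$plot_id]) * m_aopt[tr$tree_id]
  tr$b <- acc$b_base * ifelse(eco2, acc$b_co2_ratio, 1) * m_b[tr$tree_id]
  tr$ea_v <- acc$ea_v
  tr$ea_j <- acc$ea_j
  tr$kopt_v <- acc$kopt_v * m_kv[tr$tree_id]
  tr$kopt_j <- acc$kopt_j * m_kj[tr$tree_id]
  tr$rday25 <- config$rday25
  tr$tpu25 <- if (is.null(config$tpu25)) NA_real_ else config$tpu25
  rownames(tr) <- NULL
  tr
}

#' Generate noisy A-Ci curves from the ground truth
#'
#' For every tree x month x leaf temperature, capacities follow the peaked
#' Arrhenius temperature response of that tree's truth and Rday scales with
#' a Q10 of 2; stomatal behaviour is a constant Ci/Ca ratio. The capacity
#' pair is then rescaled jointly (preserving the Jmax/Vcmax ratio and hence
#' the A-Ci shape) so that net A at the growth-CO2 Ci equals the tree's
#' quadratic temperature-response truth exactly; this pins the generated
#' ToptA/Aopt/b ground truth into the curves while keeping full FvCB
#' structure in the Ci direction. Effective per-temperature capacities are
#' returned alongside the curves for recovery scoring. Finally Gaussian
#' noise `sigma_a` is added to every A.
#'
#' @param truth A [generate_tree_truth()] result.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `curves` (long per-point table in the `aci_curves.csv`
#'   schema) and `capacities` (per tree x month x tleaf effective truth:
#'   `vcmax_true`, `jmax_true`, `rday_true`, `tpu_true`, `a_growth_true`).
#' @export
generate_aci_curves <- function(truth, config, seed = 1) {
  set.seed(seed)
  cst <- config$constants
  nt <- length(config$tleaf_set)
  g <- truth[rep(seq_len(nrow(truth)), each = nt), ]
  g$tleaf_c <- rep(config$tleaf_set, nrow(truth))
  tk <- g$tleaf_c + 273.15

  vc <- peaked_arrhenius(g$kopt_v, g$topt_v + 273.15, g$ea_v, config$hd, tk)
  jm <- peaked_arrhenius(g$kopt_j, g$topt_j + 273.15, g$ea_j, config$hd, tk)
  rday_t <- g$rday25 * config$q10^((g$tleaf_c - 25) / 10)
  tpu_t <- g$tpu25 * config$q10^((g$tleaf_c - 25) / 10)
  aq <- g$aopt - g$b * (g$tleaf_c - g$topt_a)^2

  gs <- arrhenius_scaled(cst$gammastar25, cst$ea_gammastar, g$tleaf_c, cst)
  kc <- arrhenius_scaled(cst$kc25, cst$ea_kc, g$tleaf_c, cst)
  ko <- arrhenius_scaled(cst$ko25, cst$ea_ko, g$tleaf_c, cst)
  km <- kc * (1 + cst$oxygen / ko)
  gi <- config$ci_ca_ratio * g$growth_ca
  mb <- pmin(vc * (gi - gs) / (gi + km), (jm / 4) * (gi - gs) / (gi + 2 * gs))
  s <- (aq + rday_t) / mb
  if (any(s <= 0))
    stop("config error: quadratic truth implies non-positive gross A; ",
         "lower b or raise aopt")
  g$vcmax_true <- s * vc
  g$jmax_true <- s * jm
  g$rday_true <- rday_t
  g$tpu_true <- tpu_t
  g$a_growth_true <- aq

  ns <- length(config$ca_steps)
  pts <- g[rep(seq_len(nrow(g)), each = ns), ]
  pts$step_index <- rep(seq_len(ns), nrow(g))
  pts$ca_ppm <- rep(config$ca_steps, nrow(g))
  pts$ci_ppm <- config$ci_ca_ratio * pts$ca_ppm
  gs_p <- arrhenius_scaled(cst$gammastar25, cst$ea_gammastar, pts$tleaf_c, cst)
  kc_p <- arrhenius_scaled(cst$kc25, cst$ea_kc, pts$tleaf_c, cst)
  ko_p <- arrhenius_scaled(cst$ko25, cst$ea_ko, pts$tleaf_c, cst)
  ac <- pts$vcmax_true * (pts$ci_ppm - gs_p) /
    (pts$ci_ppm + kc_p * (1 + cst$oxygen / ko_p)) - pts$rday_true
  aj <- (pts$jmax_true / 4) * (pts$ci_ppm - gs_p) /
    (pts$ci_ppm + 2 * gs_p) - pts$rday_true
  at <- ifelse(is.na(pts$tpu_true), Inf, 3 * pts$tpu_true)
  # Rubisco limits below the compensation point; the min rule applies above
  a0 <- ifelse(pts$ci_ppm < gs_p, ac, pmin(ac, aj, at))
  pts$a_umol_m2_s <- a0 + stats::rnorm(nrow(pts), 0, config$sigma_a)

  cols <- c("plot_id", "species", "co2_treatment", "warming_offset_c",
            "tree_id", "month", "tleaf_c", "step_index", "ca_ppm",
            "ci_ppm", "a_umol_m2_s")
  curves <- pts[, cols]
  rownames(curves) <- NULL
  caps <- g[, c("plot_id", "species", "co2_treatment", "warming_offset_c",
                "tree_id", "month", "tleaf_c", "vcmax_true", "jmax_true",
                "rday_true", "tpu_true", "a_growth_true")]
  rownames(caps) <- NULL
  list(curves = curves, capacities = caps)
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: design roster, plot climate series, per-tree ground
#' truth and noisy A-Ci curves, all a pure function of `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param climate Generate the climate series too? Default `TRUE`.
#' @return List: `design`, `climate` (or NULL), `truth`, `curves`,
#'   `capacities`, `config`, `seed`.
#' @export
generate_experiment <- function(config = synthetic_config(), seed = 1,
                                climate = TRUE) {
  design <- generate_design(config, seed)
  clim <- if (climate) generate_climate(config, seed + 1) else NULL
  truth <- generate_tree_truth(config, design, seed + 2)
  cur <- generate_aci_curves(truth, config, seed + 3)
  list(design = design, climate = clim, truth = truth,
       curves = cur$curves, capacities = cur$capacities,
       config = config, seed = seed)
}
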