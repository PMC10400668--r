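#' Validate a per-point A-Ci table (and optionally a climate table)
#'
#' Checks column presence, value ranges and the expected
#' 5-temperature x 11-step curve structure. Range violations are errors
#' (fatal in [run_pipeline()]); structural deviations (curves without 11
#' steps, trees missing the 45 degC curve) are warnings.
#'
#' @param curves A-Ci table in the `aci_curves.csv` schema.
#' @param climate Optional climate table (`plot_id`, `timestamp`,
#'   `air_temp_c`).
#' @return List with data.frames `errors` (`row`, `problem`) and `warnings`
#'   (`unit`, `problem`); both empty for a well-formed input.
#' @export
validate_inputs <- function(curves, climate = NULL) {
  req <- c("plot_id", "species", "co2_treatment", "warming_offset_c",
           "tree_id", "month", "tleaf_c", "step_index", "ca_ppm",
           "ci_ppm", "a_umol_m2_s")
  missing_cols <- setdiff(req, names(curves))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  errors <- list(); warn <- list()
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) errors[[length(errors) + 1]] <<-
        data.frame(row = idx, problem = what)
  }
  bad(!is.finite(curves$a_umol_m2_s), "non-finite A")
  bad(!is.finite(curves$ca_ppm) | curves$ca_ppm <= 0, "Ca must be > 0")
  bad(!is.finite(curves$ci_ppm) | curves$ci_ppm < 0, "Ci must be >= 0")
  bad(is.finite(curves$ci_ppm) & is.finite(curves$ca_ppm) &
        curves$ci_ppm >= curves$ca_ppm + 50, "Ci implausibly above Ca")
  bad(!is.finite(curves$tleaf_c) | curves$tleaf_c < 0 | curves$tleaf_c > 50,
      "tleaf outside [0, 50] degC")

  key <- interaction(curves$tree_id, curves$month, curves$tleaf_c, drop = TRUE)
  n_steps <- tapply(curves$step_index, key, length)
  off <- names(n_steps)[n_steps != 11]
  if (length(off)) warn[[length(warn) + 1]] <-
      data.frame(unit = off, problem = "curve does not have 11 steps")
  tkey <- interaction(curves$tree_id, curves$month, drop = TRUE)
  has45 <- tapply(curves$tleaf_c, tkey, function(x) any(x >= 44))
  if (any(!has45)) warn[[length(warn) + 1]] <-
      data.frame(unit = names(has45)[!has45],
                 problem = "missing 45 degC curve")

  if (!is.null(climate)) {
    creq <- c("plot_id", "timestamp", "air_temp_c")
    if (length(setdiff(creq, names(climate))))
      stop("validation error: climate table missing columns")
    if (any(!is.finite(climate$air_temp_c)))
      errors[[length(errors) + 1]] <-
        data.frame(row = which(!is.finite(climate$air_temp_c)),
                   problem = "non-finite air temperature")
  }
  list(errors = if (length(errors)) do.call(rbind, errors)
       else data.frame(row = integer(), problem = character()),
       warnings = if (length(warn)) do.call(rbind, warn)
       else data.frame(unit = character(), problem = character()))
}

growth_a_series <- function(curves, growth_ca_by_co2, tolerance = 25) {
  hit <- abs(curves$ca_ppm -
               unname(growth_ca_by_co2[curves$co2_treatment])) <= tolerance
  g <- curves[hit, ]
  agg <- stats::aggregate(
    a_umol_m2_s ~ plot_id + species + co2_treatment + warming_offset_c +
      tree_id + month + tleaf_c,
    data = g, FUN = mean)
  names(agg)[names(agg) == "a_umol_m2_s"] <- "a_growth"
  agg
}

#' Per-tree thermal fits: quadratic optimum, Arrhenius optima, A70, Ag
#'
#' For every tree x month: extracts net A at growth CO2 from each leaf
#' temperature's curve and fits the quadratic temperature response (ToptA,
#' Aopt, b); when per-temperature capacity fits are supplied, fits the
#' peaked Arrhenius function (Hd fixed) to the Vcmax and Jmax series (ToptV,
#' EaV, ToptJ, EaJ) and recomputes the A70 optimum; when a climate table is
#' supplied, evaluates Ag at the plot's mean daytime growth temperature and
#' the optimum exceedance Delta-MeanTg.
#'
#' @param curves Per-point A-Ci table.
#' @param config A [synthetic_config()] (supplies growth Ca levels, Hd,
#'   constants, measurement dates).
#' @param aci_fits Optional [fit_aci_table()] result.
#' @param climate Optional climate table.
#' @param window_days Climate window length (days).
#' @param daily_hours Daytime window (decimal hours).
#' @return Data.frame, one row per tree x month: design columns, `topt_a`,
#'   `aopt`, `b`, `qfit_flag`, and when available `topt_v`, `ea_v`,
#'   `topt_j`, `ea_j`, `topt_a70`, `mean_tg`, `max_tg`, `a_g`,
#'   `delta_mean_tg`.
#' @export
fit_tree_thermal <- function(curves, config, aci_fits = NULL, climate = NULL,
                             window_days = 10, daily_hours = c(9, 15)) {
  ga <- growth_a_series(curves, config$co2_levels)
  key <- interaction(ga$tree_id, ga$month, drop = TRUE)

  clim_sum <- NULL
  if (!is.null(climate)) {
    combos <- expand.grid(plot_id = unique(curves$plot_id),
                          month = unique(curves$month),
                          stringsAsFactors = FALSE)
    clim_sum <- lapply(seq_len(nrow(combos)), function(i) {
      cs <- summarize_climate(
        climate[climate$plot_id == combos$plot_id[i], ],
        config$measurement_dates[[combos$month[i]]],
        window_days = window_days, daily_hours = daily_hours)
      cbind(combos[i, ], mean_tg = cs$mean_t, max_tg = cs$max_t)
    })
    clim_sum <- do.call(rbind, clim_sum)
  }

  rows <- lapply(split(ga, key), function(g) {
    meta <- g[1, c("plot_id", "species", "co2_treatment", "warming_offset_c",
                   "tree_id", "month")]
    out <- cbind(meta, data.frame(
      topt_a = NA_real_, aopt = NA_real_, b = NA_real_, qfit_flag = "ok",
      topt_v = NA_real_, ea_v = NA_real_, topt_j = NA_real_,
      ea_j = NA_real_, topt_a70 = NA_real_,
      mean_tg = NA_real_, max_tg = NA_real_, a_g = NA_real_,
      delta_mean_tg = NA_real_))
    qf <- tryCatch(fit_quadratic_topt(g$tleaf_c, g$a_growth),
                   error = function(e) e)
    if (inherits(qf, "error")) {
      out$qfit_flag <- conditionMessage(qf)
      return(out)
    }
    out$qfit_flag <- qf$flag
    if (isTRUE(qf$converged)) {
      out$topt_a <- qf$topt_a; out$aopt <- qf$aopt; out$b <- qf$b
    } else {
      return(out)
    }

    if (!is.null(aci_fits)) {
      f <- aci_fits[aci_fits$tree_id == meta$tree_id &
                      aci_fits$month == meta$month &
                      aci_fits$flag == "ok", ]
      if (nrow(f) >= 4) {
        av <- tryCatch(fit_peaked_arrhenius(f$tleaf_c, f$vcmax, hd = config$hd),
                       error = function(e) NULL)
        aj <- tryCatch(fit_peaked_arrhenius(f$tleaf_c, f$jmax, hd = config$hd),
                       error = function(e) NULL)
        if (!is.null(av) && av$flag == "ok") {
          out$topt_v <- av$topt; out$ea_v <- av$ea
        }
        if (!is.null(aj) && aj$flag == "ok") {
          out$topt_j <- aj$topt; out$ea_j <- aj$ea
        }
      }
      if (nrow(f) >= 3) {
        a70 <- tryCatch(
          compute_a70_topt(f, unname(config$co2_levels[meta$co2_treatment]),
                           constants = config$constants,
                           ci_ca_ratio = config$ci_ca_ratio),
          error = function(e) NULL)
        if (!is.null(a70) && isTRUE(a70$fit$converged))
          out$topt_a70 <- a70$fit$topt_a
      }
    }

    if (!is.null(clim_sum)) {
      cs <- clim_sum[clim_sum$plot_id == meta$plot_id &
                       clim_sum$month == meta$month, ]
      if (nrow(cs) == 1) {
        out$mean_tg <- cs$mean_tg; out$max_tg <- cs$max_tg
        out$a_g <- as.numeric(compute_ag(qf, cs$mean_tg))
        out$delta_mean_tg <- cs$mean_tg - qf$topt_a
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Orchestrates generate -> validate -> A-Ci fitting -> thermal fitting ->
#' plot means -> mixed-model selection -> Delta-MeanTg ANOVA. Per-curve fit
#' failures are logged and excluded, never imputed. All outputs are a pure
#' function of `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param fit_capacities Run the bilinear A-Ci fits (needed for ToptV/ToptJ
#'   and A70)? Default `TRUE`.
#' @param use_climate Generate and use the climate stage (Ag, Delta-MeanTg)?
#'   Default `TRUE`.
#' @param responses Responses to run the regression stage on; defaults to
#'   every available response.
#' @param write_dir Optional directory; when given, the standard CSV tables
#'   (`aci_curves.csv`, `climate.csv`, `truth.csv`, `aci_fits.csv`,
#'   `tree_thermal.csv`, `plot_means.csv`, `regression_results.csv`,
#'   `anova_delta_tg.csv`) are written there.
#' @return A results bundle: `seed`, `truth`, `aci_fits`, `tree_thermal`,
#'   `plot_means`, `selection` (list of [select_model()] outcomes),
#'   `anova_delta_tg`, `validation`.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1,
                         fit_capacities = TRUE, use_climate = TRUE,
                         responses = NULL, write_dir = NULL) {
  exp <- generate_experiment(config, seed, climate = use_climate)
  rep <- validate_inputs(exp$curves, exp$climate)
  if (nrow(rep$errors))
    stop("validation error: ", nrow(rep$errors), " offending rows, e.g. row ",
         rep$errors$row[1], ": ", rep$errors$problem[1])

  aci_fits <- if (fit_capacities)
    suppressWarnings(fit_aci_table(exp$curves, config$constants)) else NULL
  tree_thermal <- fit_tree_thermal(exp$curves, config, aci_fits, exp$climate)

  avail <- c("topt_a", "aopt", "b", "topt_v", "topt_j", "ea_v", "ea_j",
             "topt_a70", "a_g", "delta_mean_tg")
  avail <- avail[vapply(avail, function(r)
    r %in% names(tree_thermal) && any(is.finite(tree_thermal[[r]])),
    logical(1))]
  if (is.null(responses)) responses <- avail else
    responses <- intersect(responses, avail)
  if (length(responses) == 0)
    stop("fatal: no response with any finite value")

  plot_means <- suppressWarnings(aggregate_plot_means(tree_thermal, responses))
  directional <- c(topt_a = "greater", aopt = "greater", a_g = "greater",
                   topt_a70 = "greater")
  selection <- lapply(responses, function(r) {
    d <- plot_means[plot_means$response_name == r & is.finite(plot_means$value), ]
    tryCatch(select_model(fit_candidates(d, r),
                          directional = if (r %in% names(directional))
                            directional[[r]] else "two-sided"),
             error = function(e) e)
  })
  names(selection) <- responses

  anova_tab <- NULL
  if ("delta_mean_tg" %in% responses) {
    d <- plot_means[plot_means$response_name == "delta_mean_tg" &
                      is.finite(plot_means$value), ]
    anova_tab <- anova_delta_tg(d)
  }

  bundle <- list(seed = seed, config = config, truth = exp$truth,
                 aci_fits = aci_fits, tree_thermal = tree_thermal,
                 plot_means = plot_means, selection = selection,
                 anova_delta_tg = anova_tab, validation = rep)

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(write_dir, f), row.names = FALSE)
    w(exp$curves, "aci_curves.csv")
    w(exp$climate, "climate.csv")
    w(exp$truth, "truth.csv")
    w(aci_fits, "aci_fits.csv")
    w(tree_thermal, "tree_thermal.csv")
    w(plot_means, "plot_means.csv")
    w(selection_table(selection), "regression_results.csv")
    w(anova_tab, "anova_delta_tg.csv")
  }
  bundle
}

#' Flatten selection outcomes into one results table
#'
#' @param selection Named list of [select_model()] outcomes (errors allowed;
#'   they are reported in the `note` column).
#' @return Data.frame with one row per response: selected structures,
#'   intercept, per-CO2 warming slopes and SEs, CO2 shift, one-sided p
#'   values, AIC/AICc of the selected candidate.
#' @export
selection_table <- function(selection) {
  rows <- lapply(names(selection), function(r) {
    s <- selection[[r]]
    if (inherits(s, "error") || inherits(s, "condition"))
      return(data.frame(response_name = r, random_structure = NA,
                        fixed_structure = NA, intercept = NA,
                        slope_aCO2 = NA, slope_eCO2 = NA,
                        slope_se_aCO2 = NA, slope_se_eCO2 = NA,
                        co2_intercept_shift = NA, p_warming_aCO2 = NA,
                        p_warming_eCO2 = NA, p_co2 = NA, aic = NA,
                        aicc = NA, note = conditionMessage(s)))
    ct <- s$candidates
    sel <- ct[ct$random_structure == s$random_structure &
                ct$fixed_structure == s$fixed_structure &
                ct$method == "REML", ]
    data.frame(response_name = r, random_structure = s$random_structure,
               fixed_structure = s$fixed_structure, intercept = s$intercept,
               slope_aCO2 = s$warming_slope[1], slope_eCO2 = s$warming_slope[2],
               slope_se_aCO2 = s$warming_slope_se[1],
               slope_se_eCO2 = s$warming_slope_se[2],
               co2_intercept_shift = s$co2_intercept_shift,
               p_warming_aCO2 = s$p_warming[1], p_warming_eCO2 = s$p_warming[2],
               p_co2 = s$p_co2, aic = sel$aic[1], aicc = sel$aicc[1],
               note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
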