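#' Light experiment pass: growth-CO2 extraction, quadratic fits, plot means
#'
#' Runs only the stages needed to recover ToptA, Aopt and b from a synthetic
#' experiment: curve generation, growth-CO2 A extraction, the quadratic
#' temperature-response fit per tree x month, and aggregation to plot means.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Plot-mean long data.frame for responses `topt_a`, `aopt`, `b`.
#' @keywords internal
quadratic_plot_means <- function(config, seed) {
  design <- generate_design(config, seed)
  truth <- generate_tree_truth(config, design, seed + 2)
  curves <- generate_aci_curves(truth, config, seed + 3)$curves
  ga <- growth_a_series(curves, config$co2_levels)
  rows <- lapply(split(ga, interaction(ga$tree_id, ga$month, drop = TRUE)),
                 function(g) {
    qf <- tryCatch(fit_quadratic_topt(g$tleaf_c, g$a_growth),
                   error = function(e) NULL)
    meta <- g[1, c("plot_id", "warming_offset_c", "co2_treatment",
                   "tree_id", "month")]
    if (is.null(qf) || !isTRUE(qf$converged) || qf$flag != "ok")
      return(cbind(meta, data.frame(topt_a = NA_real_, aopt = NA_real_,
                                    b = NA_real_)))
    cbind(meta, data.frame(topt_a = qf$topt_a, aopt = qf$aopt, b = qf$b))
  })
  trees <- do.call(rbind, rows)
  suppressWarnings(aggregate_plot_means(trees, c("topt_a", "aopt", "b")))
}

pm_response <- function(pm, r) {
  d <- pm[pm$response_name == r & is.finite(pm$value), ]
  d
}

#' Parameter-recovery study over seeded synthetic replicates
#'
#' Re-runs the analysis pipeline on independently seeded synthetic
#' experiments whose ground truth embeds the acclimation relations the
#' package ships (warming slopes and CO2 offsets of ToptA, the Aopt
#' response, the b elevation under elevated CO2, the ToptV/ToptJ warming
#' relations, and the ToptA-vs-ToptV/ToptJ relationships), and records the
#' estimate each replicate's regression stage recovers. Averaging the
#' per-seed estimates measures the bias of the full chain (curve noise ->
#' curve fitting -> thermal fitting -> plot means -> mixed-model selection)
#' relative to the generating truth.
#'
#' Components:
#' \describe{
#'   \item{tamarack}{full experiments; recovers the ambient-CO2 ToptA
#'     warming slope and intercept, the eCO2 ToptA offset (main-effects
#'     mixed model) and the percent elevation of b under eCO2.}
#'   \item{spruce}{full experiments; recovers the overall ToptA warming
#'     slope and intercept and the eCO2 Aopt warming slope.}
#'   \item{biochem}{spruce capacity-temperature series generated directly
#'     from the peaked Arrhenius truth (5% multiplicative value noise),
#'     fitted with Hd fixed and regressed on warming: ToptV and ToptJ
#'     warming slopes.}
#'   \item{pairs}{plot-level (ToptV, ToptA) and (ToptJ, ToptA) pairs from
#'     the tamarack ambient relations (sigma = 0.7 degC on ToptA), fitted
#'     with the month-random-intercept regression.}
#' }
#'
#' @param n_seeds Number of replicate experiments per component.
#' @param base_seed First seed; replicate r uses `base_seed + r - 1`.
#' @param components Subset of
#'   `c("tamarack", "spruce", "biochem", "pairs")`.
#' @param trees_per_plot Trees per plot in the generated experiments.
#' @return Long data.frame `seed`, `quantity`, `value` of class
#'   `recovery_study`, with the generating truth attached as attribute
#'   `truth`.
#' @export
recovery_study <- function(n_seeds = 200, base_seed = 1,
                           components = c("tamarack", "spruce",
                                          "biochem", "pairs"),
                           trees_per_plot = 3) {
  components <- match.arg(components, several.ok = TRUE)
  cfg_t <- synthetic_config("tamarack", trees_per_plot = trees_per_plot)
  cfg_s <- synthetic_config("black_spruce", trees_per_plot = trees_per_plot)
  acc_t <- cfg_t$acclimation
  acc_s <- cfg_s$acclimation
  out <- vector("list", n_seeds)

  for (r in seq_len(n_seeds)) {
    seed <- base_seed + r - 1
    vals <- c()

    if ("tamarack" %in% components) {
      pm <- quadratic_plot_means(cfg_t, seed * 10)
      cs <- fit_candidates(pm_response(pm, "topt_a"), "topt_a")
      sel <- tryCatch(select_model(cs), error = function(e) NULL)
      if (!is.null(sel)) {
        vals <- c(vals,
                  toptA_slope_tamarack_aCO2 = unname(sel$warming_slope["aCO2"]),
                  toptA_intercept_tamarack_aCO2 = sel$intercept)
      }
      me <- pick_candidate(cs, "month_intercept", "main_effects", "REML")
      if (is.null(me) || !me$estimable)
        me <- pick_candidate(cs, "none", "main_effects", "REML")
      if (!is.null(me) && me$estimable) {
        beta <- if (inherits(me$fit, "lme")) nlme::fixef(me$fit)
                else stats::coef(me$fit)
        vals <- c(vals,
                  toptA_co2_offset_tamarack = unname(beta[["co2_treatmenteCO2"]]))
      }
      bpm <- pm_response(pm, "b")
      mb <- tapply(bpm$value, bpm$co2_treatment, mean)
      vals <- c(vals,
                b_co2_elevation_pct_tamarack =
                  unname(100 * (mb[["eCO2"]] / mb[["aCO2"]] - 1)))
    }

    if ("spruce" %in% components) {
      pm <- quadratic_plot_means(cfg_s, seed * 10 + 1)
      sel <- tryCatch(select_model(fit_candidates(pm_response(pm, "topt_a"),
                                                  "topt_a")),
                      error = function(e) NULL)
      if (!is.null(sel))
        vals <- c(vals,
                  toptA_slope_spruce = unname(mean(sel$warming_slope)),
                  toptA_intercept_spruce = sel$intercept)
      sela <- tryCatch(select_model(fit_candidates(pm_response(pm, "aopt"),
                                                   "aopt")),
                       error = function(e) NULL)
      if (!is.null(sela))
        vals <- c(vals,
                  aopt_slope_spruce_eCO2 = unname(sela$warming_slope["eCO2"]))
    }

    if ("biochem" %in% components) {
      vals <- c(vals, biochem_slopes(cfg_s, seed * 10 + 2))
    }

    if ("pairs" %in% components) {
      vals <- c(vals, paired_relation_slopes(acc_t, seed * 10 + 3))
    }

    out[[r]] <- data.frame(seed = seed, quantity = names(vals),
                           value = unname(vals))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  truth <- c(toptA_slope_tamarack_aCO2 = acc_t$topt_a$slope,
             toptA_intercept_tamarack_aCO2 = acc_t$topt_a$intercept,
             toptA_co2_offset_tamarack = acc_t$topt_a$co2_offset,
             b_co2_elevation_pct_tamarack = 100 * (acc_t$b_co2_ratio - 1),
             toptA_slope_spruce = acc_s$topt_a$slope,
             toptA_intercept_spruce = acc_s$topt_a$intercept,
             aopt_slope_spruce_eCO2 = acc_s$aopt$slope + acc_s$aopt$co2_slope_delta,
             toptV_slope_spruce = acc_s$topt_v$slope,
             toptJ_slope_spruce = acc_s$topt_j$slope,
             toptA_toptV_slope_tamarack = 0.57,
             toptA_toptJ_slope_tamarack = 0.75)
  structure(res, truth = truth, class = c("recovery_study", "data.frame"))
}

# ToptV/ToptJ warming-slope recovery from capacity-temperature series
# generated directly from the peaked Arrhenius truth (the biochemical
# optima are derived from fitted capacities, so curve noise enters through
# the capacity values, modelled as 5% multiplicative).
biochem_slopes <- function(config, seed) {
  design <- generate_design(config, seed)
  truth <- generate_tree_truth(config, design, seed + 2)
  set.seed(seed + 4)
  tk <- config$tleaf_set + 273.15
  fit_one <- function(kopt, topt, ea) {
    v <- peaked_arrhenius(kopt, topt + 273.15, ea, config$hd, tk) *
      (1 + stats::rnorm(length(tk), 0, 0.05))
    f <- tryCatch(fit_peaked_arrhenius(config$tleaf_set, pmax(v, 1e-3),
                                       hd = config$hd),
                  error = function(e) NULL)
    if (is.null(f) || f$flag != "ok") NA_real_ else f$topt
  }
  truth$topt_v_hat <- mapply(fit_one, truth$kopt_v, truth$topt_v, truth$ea_v)
  truth$topt_j_hat <- mapply(fit_one, truth$kopt_j, truth$topt_j, truth$ea_j)
  pm <- suppressWarnings(
    aggregate_plot_means(truth, c("topt_v_hat", "topt_j_hat")))
  slope_of <- function(r) {
    sel <- tryCatch(
      select_model(fit_candidates(pm_response(pm, r), r),
                   directional = "two-sided"),
      error = function(e) NULL)
    if (is.null(sel)) NA_real_ else unname(mean(sel$warming_slope))
  }
  c(toptV_slope_spruce = slope_of("topt_v_hat"),
    toptJ_slope_spruce = slope_of("topt_j_hat"))
}

# Plot-level paired-optimum relationships (ToptA vs ToptV / ToptJ) for the
# tamarack ambient relations, 20 plot-equivalents x 2 months.
paired_relation_slopes <- function(acc, seed, n_plots = 20,
                                   sigma_y = 0.7) {
  set.seed(seed)
  w <- rep(c(0, 2.25, 4.5, 6.75, 9), length.out = n_plots)
  month <- rep(c("June", "August"), each = n_plots)
  wv <- rep(w, 2)
  one <- function(x_int, x_slope, rel_slope, rel_int) {
    x <- x_int + x_slope * wv + stats::rnorm(length(wv), 0, 0.7)
    y <- rel_int + rel_slope * x + stats::rnorm(length(wv), 0, sigma_y)
    fit_paired_relation(x, y, month)$slope
  }
  c(toptA_toptV_slope_tamarack = one(acc$topt_v$intercept, acc$topt_v$slope,
                                     0.57, 4.4),
    toptA_toptJ_slope_tamarack = one(acc$topt_j$intercept, acc$topt_j$slope,
                                     0.75, -0.62))
}

#' Summarise a recovery study against its generating truth
#'
#' @param study A [recovery_study()] result.
#' @return Data.frame: `quantity`, `truth`, `mean`, `sd`, `n`, `bias`.
#' @export
summarize_recovery <- function(study) {
  truth <- attr(study, "truth")
  agg <- stats::aggregate(value ~ quantity, data = study,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(quantity = agg$quantity,
                    truth = unname(truth[agg$quantity]),
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = agg$value[, "n"])
  out$bias <- out$mean - out$truth
  out
}
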