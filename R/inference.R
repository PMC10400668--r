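#' Aggregate per-tree thermal summaries to plot means
#'
#' The experiment is analysed on plot means (n = 1-4 trees per plot), one
#' value per plot x month x response.
#'
#' @param trees Data.frame with columns `plot_id`, `warming_offset_c`,
#'   `co2_treatment`, `month`, and one or more numeric response columns.
#' @param responses Character vector of response column names; defaults to
#'   every numeric column not in the design.
#' @return Long data.frame: `plot_id`, `warming_offset_c`, `co2_treatment`,
#'   `month`, `response_name`, `value`, `n_trees`. NA tree values (failed
#'   fits excluded upstream) are dropped from the mean; plots with no valid
#'   tree for a response are dropped with a warning.
#' @export
aggregate_plot_means <- function(trees, responses = NULL) {
  design <- c("plot_id", "warming_offset_c", "co2_treatment", "month")
  if (is.null(responses)) {
    responses <- setdiff(names(trees)[vapply(trees, is.numeric, logical(1))],
                         c(design, "tree_id", "n_trees"))
  }
  out <- lapply(responses, function(r) {
    g <- trees[, c(design, r)]
    names(g)[5] <- "value"
    agg <- stats::aggregate(value ~ plot_id + warming_offset_c + co2_treatment + month,
                            data = g, FUN = mean, na.action = stats::na.omit)
    cnt <- stats::aggregate(value ~ plot_id + warming_offset_c + co2_treatment + month,
                            data = g, FUN = function(x) sum(is.finite(x)),
                            na.action = NULL)
    agg$n_trees <- cnt$value[match(
      interaction(agg$plot_id, agg$month),
      interaction(cnt$plot_id, cnt$month))]
    dropped <- sum(cnt$value == 0)
    if (dropped > 0)
      warning(sprintf("%d empty plot x month cells dropped for %s", dropped, r))
    agg$response_name <- r
    agg
  })
  res <- do.call(rbind, out)
  res[, c(design[1:4], "response_name", "value", "n_trees")]
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)`; returns `Inf` when
#' `n - k - 1 <= 0`.
#'
#' @param aic Akaike information criterion.
#' @param k Number of estimated parameters (fixed effects + variances).
#' @param n Number of observations.
#' @return AICc.
#' @export
aicc <- function(aic, k, n) {
  ifelse(n - k - 1 > 0, aic + 2 * k * (k + 1) / (n - k - 1), Inf)
}

#' Fit the candidate mixed-effects regression models for one response
#'
#' Fits the full candidate grid used by the two-step selection protocol:
#' {no random structure, month random intercept} x {main effects,
#' warming-by-CO2 interaction} x {REML, ML}. Warming enters as a continuous
#' covariate (degC above ambient) and CO2 as a two-level factor. Models
#' without a random structure use generalised least squares
#' ([nlme::gls()]); models with the month intercept use [nlme::lme()] (the
#' month variance is profiled on the boundary-truncated scale, variance
#' >= 0, which the two-level month factor requires).
#'
#' @param data Plot-mean data.frame with columns `value`,
#'   `warming_offset_c`, `co2_treatment` (factor or character, two levels)
#'   and `month`.
#' @param response_name Label carried into the output.
#' @return A list of class `candidate_set`: per-candidate entries with
#'   `random_structure`, `fixed_structure`, `method`, `fit` (or NULL),
#'   `loglik`, `k`, `aic`, `aicc`, `n`, `estimable`, plus the `data` and
#'   `response_name`.
#' @export
fit_candidates <- function(data, response_name = "response") {
  if (nrow(data) < 8)
    stop("invalid-input: need >= 8 plot-mean records")
  data <- data.frame(value = data$value,
                     warming_offset_c = data$warming_offset_c,
                     co2_treatment = factor(data$co2_treatment),
                     month = factor(data$month))
  fixed_forms <- list(
    main_effects = value ~ warming_offset_c + co2_treatment,
    interaction  = value ~ warming_offset_c * co2_treatment)
  grid <- expand.grid(random_structure = c("none", "month_intercept"),
                      fixed_structure = names(fixed_forms),
                      method = c("REML", "ML"),
                      stringsAsFactors = FALSE)
  n <- nrow(data)
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    rs <- grid$random_structure[i]
    fs <- grid$fixed_structure[i]
    me <- grid$method[i]
    fit <- tryCatch({
      if (rs == "none") {
        nlme::gls(fixed_forms[[fs]], data = data, method = me)
      } else {
        if (nlevels(data$month) < 2)
          stop("month random intercept needs both months")
        nlme::lme(fixed_forms[[fs]], random = ~ 1 | month,
                  data = data, method = me,
                  control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      list(random_structure = rs, fixed_structure = fs, method = me,
           fit = NULL, loglik = NA_real_, k = NA_real_, aic = NA_real_,
           aicc = NA_real_, n = n, estimable = FALSE,
           note = conditionMessage(fit))
    } else {
      ll <- stats::logLik(fit)
      k <- attr(ll, "df")
      a <- stats::AIC(fit)
      list(random_structure = rs, fixed_structure = fs, method = me,
           fit = fit, loglik = as.numeric(ll), k = k, aic = a,
           aicc = aicc(a, k, n), n = n, estimable = TRUE, note = "")
    }
  })
  structure(list(candidates = cands, data = data,
                 response_name = response_name),
            class = "candidate_set")
}

candidate_table <- function(cs) {
  do.call(rbind, lapply(cs$candidates, function(x)
    data.frame(random_structure = x$random_structure,
               fixed_structure = x$fixed_structure, method = x$method,
               loglik = x$loglik, k = x$k, aic = x$aic, aicc = x$aicc,
               n = x$n, estimable = x$estimable)))
}

pick_candidate <- function(cs, random_structure, fixed_structure, method) {
  for (x in cs$candidates)
    if (x$random_structure == random_structure &&
        x$fixed_structure == fixed_structure && x$method == method)
      return(x)
  NULL
}

#' Two-step model selection (random structure, then fixed structure)
#'
#' Step 1 compares the month-random-intercept model against the model with
#' no random structure, both under REML with the most complex (interaction)
#' fixed structure, and keeps the lower AIC. Step 2, holding that random
#' structure, compares the main-effects and interaction fixed structures
#' under ML and keeps the lower AIC. AICc is reported alongside every
#' candidate. Ties go to the simpler model. The selected structure is
#' reported from its REML fit.
#'
#' @param cs A [fit_candidates()] result.
#' @param directional One-sided test direction for the warming slope and CO2
#'   shift (`"greater"` for responses warming/CO2 are hypothesised to
#'   increase, `"two-sided"` otherwise).
#' @return A list of class `selection_outcome`: `response_name`,
#'   `random_structure`, `fixed_structure`, `selected` (REML fit),
#'   `intercept`, `warming_slope` (named per CO2 level), `warming_slope_se`,
#'   `co2_intercept_shift`, `co2_shift_se`, `p_warming` (per CO2 level),
#'   `p_co2`, `df_resid`, and `candidates` (AIC/AICc table).
#' @export
select_model <- function(cs, directional = "greater") {
  step1 <- Filter(function(x) x$method == "REML" &&
                    x$fixed_structure == "interaction" && x$estimable,
                  cs$candidates)
  if (length(step1) == 0)
    stop("selection error: no estimable candidate for the random-structure step")
  aics <- vapply(step1, `[[`, numeric(1), "aic")
  # ties (within numerical noise) go to the simpler structure, which sorts first
  ord <- order(round(aics, 8),
               match(vapply(step1, `[[`, character(1), "random_structure"),
                     c("none", "month_intercept")))
  rs <- step1[[ord[1]]]$random_structure

  step2 <- Filter(function(x) x$method == "ML" &&
                    x$random_structure == rs && x$estimable,
                  cs$candidates)
  if (length(step2) == 0)
    stop("selection error: no estimable candidate for the fixed-structure step")
  aics2 <- vapply(step2, `[[`, numeric(1), "aic")
  ord2 <- order(round(aics2, 8),
                match(vapply(step2, `[[`, character(1), "fixed_structure"),
                      c("main_effects", "interaction")))
  fs <- step2[[ord2[1]]]$fixed_structure

  sel <- pick_candidate(cs, rs, fs, "REML")
  if (is.null(sel) || !sel$estimable)
    stop("selection error: selected structure not estimable under REML")
  fit <- sel$fit

  beta <- if (inherits(fit, "lme")) nlme::fixef(fit) else stats::coef(fit)
  V <- stats::vcov(fit)
  n <- sel$n
  p <- length(beta)
  df_resid <- n - p
  co2_lvls <- levels(cs$data$co2_treatment)
  wn <- "warming_offset_c"
  cn <- grep("^co2_treatment", names(beta), value = TRUE)
  int_n <- grep(":", names(beta), value = TRUE)

  slope <- c(beta[[wn]], beta[[wn]])
  slope_se <- rep(sqrt(V[wn, wn]), 2)
  if (length(int_n) == 1) {
    slope[2] <- beta[[wn]] + beta[[int_n]]
    slope_se[2] <- sqrt(V[wn, wn] + V[int_n, int_n] + 2 * V[wn, int_n])
  }
  names(slope) <- names(slope_se) <- co2_lvls
  co2_shift <- if (length(cn) == 1) beta[[cn]] else NA_real_
  co2_se <- if (length(cn) == 1) sqrt(V[cn, cn]) else NA_real_

  pw <- vapply(seq_along(slope), function(i) {
    if (identical(directional, "two-sided"))
      2 * stats::pt(-abs(slope[i] / slope_se[i]), df_resid)
    else one_sided_p(slope[i], slope_se[i], df_resid, directional)
  }, numeric(1))
  names(pw) <- co2_lvls
  pc <- if (is.na(co2_shift)) NA_real_ else {
    if (identical(directional, "two-sided"))
      2 * stats::pt(-abs(co2_shift / co2_se), df_resid)
    else one_sided_p(co2_shift, co2_se, df_resid, directional)
  }

  structure(list(response_name = cs$response_name,
                 random_structure = rs, fixed_structure = fs,
                 selected = fit,
                 intercept = unname(beta[["(Intercept)"]]),
                 warming_slope = slope, warming_slope_se = slope_se,
                 co2_intercept_shift = co2_shift, co2_shift_se = co2_se,
                 p_warming = pw, p_co2 = pc, df_resid = df_resid,
                 candidates = candidate_table(cs)),
            class = "selection_outcome")
}

#' One-sided t probability for a regression coefficient
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error (> 0).
#' @param df Residual degrees of freedom (>= 1).
#' @param direction `"greater"` (upper tail) or `"less"`.
#' @return One-sided p value.
#' @export
one_sided_p <- function(estimate, se, df, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (se <= 0) stop("invalid-input: se must be > 0")
  if (df < 1) stop("invalid-input: df must be >= 1")
  stats::pt(estimate / se, df, lower.tail = (direction == "less"))
}

#' Two-factor ANOVA for the optimum-exceedance metric
#'
#' Fixed-effects ANOVA of Delta-MeanTg on the warming treatment (5-level
#' factor) and CO2 treatment (2-level factor) with their interaction, using
#' type-II sums of squares (robust to the mild imbalance of 1-4 trees per
#' plot).
#'
#' @param data Data.frame with columns `value`, `warming_offset_c`,
#'   `co2_treatment`.
#' @return The type-II ANOVA table as a data.frame (`term`, `sum_sq`, `df`,
#'   `f_value`, `p_value`).
#' @export
anova_delta_tg <- function(data) {
  d <- data.frame(value = data$value,
                  warming = factor(data$warming_offset_c),
                  co2 = factor(data$co2_treatment))
  tab <- table(d$warming, d$co2)
  if (any(tab == 0))
    warning("unbalanced design: empty warming x CO2 cell; proceeding with type-II SS")
  fit <- stats::lm(value ~ warming * co2, data = d)
  an <- car::Anova(fit, type = 2, singular.ok = TRUE)
  data.frame(term = rownames(an), sum_sq = an[["Sum Sq"]], df = an[["Df"]],
             f_value = an[["F value"]], p_value = an[["Pr(>F)"]],
             row.names = NULL)
}

#' Mixed regression of one thermal optimum on another
#'
#' Used for the relationship between the optimum of net photosynthesis and
#' the optima of the underlying biochemical capacities (e.g. ToptA on
#' ToptV), fitted on plot means with a month random intercept.
#'
#' @param x Predictor optimum (degC), plot-level.
#' @param y Response optimum (degC), plot-level.
#' @param month Campaign month per record.
#' @return List with `slope`, `intercept`, `slope_se`, `p_one_sided`
#'   (positive-relationship test) and the fitted model.
#' @export
fit_paired_relation <- function(x, y, month) {
  d <- data.frame(x = x, y = y, month = factor(month))
  fit <- tryCatch(
    nlme::lme(y ~ x, random = ~ 1 | month, data = d, method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) nlme::gls(y ~ x, data = d, method = "REML"))
  beta <- if (inherits(fit, "lme")) nlme::fixef(fit) else stats::coef(fit)
  V <- stats::vcov(fit)
  df <- nrow(d) - 2
  list(slope = unname(beta[["x"]]), intercept = unname(beta[["(Intercept)"]]),
       slope_se = sqrt(V["x", "x"]),
       p_one_sided = one_sided_p(beta[["x"]], sqrt(V["x", "x"]), df),
       fit = fit)
}
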