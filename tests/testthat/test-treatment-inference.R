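make_plot_means <- function(seed, slope = 0.3, co2_shift = 0, month_shift = 0,
                            interaction = 0, sigma = 0.5, intercept = 23) {
  set.seed(seed)
  d <- expand.grid(warming_offset_c = c(0, 2.25, 4.5, 6.75, 9),
                   co2_treatment = c("aCO2", "eCO2"),
                   month = c("June", "August"), stringsAsFactors = FALSE)
  d$plot_id <- paste0("P", rep(1:10, 2))
  eco2 <- d$co2_treatment == "eCO2"
  d$value <- intercept + slope * d$warming_offset_c + co2_shift * eco2 +
    interaction * d$warming_offset_c * eco2 +
    month_shift * (d$month == "August") + rnorm(nrow(d), 0, sigma)
  d
}

test_that("plot means equal an independent group-by average", {
  set.seed(2)
  trees <- data.frame(plot_id = rep(c("P1", "P2"), each = 4),
                      warming_offset_c = rep(c(0, 9), each = 4),
                      co2_treatment = "aCO2",
                      month = rep(c("June", "August"), 4),
                      topt_a = c(22, 24, 23, 25, 26, 27, 25.5, 28))
  pm <- aggregate_plot_means(trees, "topt_a")
  # shuffled input gives the same table
  pm2 <- aggregate_plot_means(trees[sample(nrow(trees)), ], "topt_a")
  key <- with(pm, order(plot_id, month))
  key2 <- with(pm2, order(plot_id, month))
  expect_equal(pm[key, ]$value, pm2[key2, ]$value)
  for (i in seq_len(nrow(pm))) {
    sel <- trees$plot_id == pm$plot_id[i] & trees$month == pm$month[i]
    expect_equal(pm$value[i], mean(trees$topt_a[sel]))
    expect_equal(pm$n_trees[i], sum(sel))
  }
  single <- aggregate_plot_means(trees[1, ], "topt_a")
  expect_equal(single$value, 22)
  expect_equal(single$n_trees, 1)
})

test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(100, 4, 10), 108)
  expect_equal(aicc(100, 4, 5), Inf)
})

test_that("zero-noise data recover the generating slope exactly", {
  d <- make_plot_means(1, slope = 0.3, sigma = 0)
  sel <- select_model(fit_candidates(d, "x"))
  expect_equal(unname(sel$warming_slope["aCO2"]), 0.3, tolerance = 1e-8)
  expect_equal(sel$intercept, 23, tolerance = 1e-6)
})

test_that("the no-random ML log-likelihood equals the closed-form OLS value", {
  d <- make_plot_means(5, slope = 0.3, co2_shift = 1)
  cs <- fit_candidates(d, "x")
  cand <- Filter(function(x) x$random_structure == "none" &&
                   x$fixed_structure == "main_effects" && x$method == "ML",
                 cs$candidates)[[1]]
  ols <- lm(value ~ warming_offset_c + co2_treatment, data = d)
  rss <- sum(resid(ols)^2)
  n <- nrow(d)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(cand$loglik, ll, tolerance = 1e-6)
})

test_that("a strong month offset selects the random intercept", {
  hits <- vapply(1:100, function(s) {
    d <- make_plot_means(s, month_shift = 5)
    sel <- select_model(fit_candidates(d, "x"))
    sel$random_structure == "month_intercept"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("CO2-specific warming slopes select the interaction structure", {
  hits <- vapply(101:200, function(s) {
    d <- make_plot_means(s, interaction = 0.5)
    sel <- select_model(fit_candidates(d, "x"))
    sel$fixed_structure == "interaction"
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("selection is invariant to row order and response shifts", {
  d <- make_plot_means(9, slope = 0.3, co2_shift = 1, month_shift = 0.5)
  s1 <- select_model(fit_candidates(d, "x"))
  s2 <- select_model(fit_candidates(d[sample(nrow(d)), ], "x"))
  d3 <- d; d3$value <- d3$value + 100
  s3 <- select_model(fit_candidates(d3, "x"))
  expect_equal(s1$warming_slope, s2$warming_slope, tolerance = 1e-7)
  expect_equal(s1$warming_slope, s3$warming_slope, tolerance = 1e-6)
  expect_equal(s1$random_structure, s2$random_structure)
  expect_equal(s1$fixed_structure, s3$fixed_structure)
})

test_that("with zero month variance the random intercept is not preferred", {
  worse <- vapply(1:100, function(s) {
    d <- make_plot_means(300 + s, month_shift = 0, sigma = 0.5)
    cs <- fit_candidates(d, "x")
    tab <- Filter(function(x) x$method == "REML" &&
                    x$fixed_structure == "interaction", cs$candidates)
    a <- vapply(tab, `[[`, numeric(1), "aic")
    rs <- vapply(tab, `[[`, character(1), "random_structure")
    a[rs == "month_intercept"] >= a[rs == "none"] - 1e-6
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})

test_that("warming-slope estimates are unbiased at the design size", {
  slopes <- vapply(1:200, function(s) {
    d <- make_plot_means(500 + s, slope = 0.3, co2_shift = 1,
                         month_shift = 0.5)
    sel <- select_model(fit_candidates(d, "x"))
    unname(mean(sel$warming_slope))
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.3), 0.03)
})

test_that("one-sided p values follow the t distribution", {
  expect_equal(one_sided_p(0, 1, 10), 0.5)
  expect_lt(one_sided_p(100, 1, 10), 1e-10)
  # published one-tailed t-table value for t = 2.5, df = 10
  expect_lt(abs(one_sided_p(2.5, 1, 10) - 0.0157), 5e-4)
  expect_equal(one_sided_p(-1.3, 1, 7, direction = "less"),
               1 - one_sided_p(-1.3, 1, 7, direction = "greater"))
  expect_error(one_sided_p(1, 0, 10), "invalid-input")
})

test_that("the exceedance ANOVA matches a hand-computed 2x2 table", {
  # one-factor shift only: warming +0 vs +9, CO2 has no effect
  d <- data.frame(warming_offset_c = rep(c(0, 0, 9, 9), each = 2),
                  co2_treatment = rep(c("aCO2", "eCO2"), 4),
                  value = c(1, 1.2, 0.8, 0.6, 3, 3.2, 2.8, 2.6))
  tab <- anova_delta_tg(d)
  # hand ANOVA: warming SS = 8 * (mean diff / 2)^2 summed over groups
  mw <- tapply(d$value, d$warming_offset_c, mean)
  ss_w <- 4 * sum((mw - mean(d$value))^2)
  expect_equal(tab$sum_sq[tab$term == "warming"], ss_w, tolerance = 1e-10)
  expect_lt(tab$p_value[tab$term == "warming"], 0.01)
  expect_gt(tab$p_value[tab$term == "co2"], 0.05)
  # balanced decomposition: component SS sum to the total SS
  tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(tab$sum_sq), tot, tolerance = 1e-10)
})

test_that("equal cell means give zero F statistics", {
  d <- data.frame(warming_offset_c = rep(c(0, 9), each = 4),
                  co2_treatment = rep(c("aCO2", "aCO2", "eCO2", "eCO2"), 2),
                  value = rep(c(-1, 1), 4))
  tab <- anova_delta_tg(d)
  expect_equal(tab$f_value[tab$term == "warming"], 0, tolerance = 1e-12)
  expect_equal(tab$f_value[tab$term == "co2"], 0, tolerance = 1e-12)
})

test_that("paired-optimum regression recovers a known relationship", {
  set.seed(77)
  month <- rep(c("June", "August"), each = 20)
  x <- 33 + rnorm(40, 0, 1.5)
  y <- 4.4 + 0.57 * x + rnorm(40, 0, 0.3)
  f <- fit_paired_relation(x, y, month)
  expect_equal(f$slope, 0.57, tolerance = 0.1)
  expect_lt(f$p_one_sided, 1e-4)
})
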