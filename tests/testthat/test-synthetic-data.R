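test_that("the design roster reproduces the enclosure layout", {
  cfg <- synthetic_config("tamarack", trees_per_plot = 3)
  r <- generate_design(cfg, seed = 1)
  expect_equal(length(unique(r$plot_id)), 10)
  expect_equal(nrow(unique(r[, c("tree_id", "month")])), 60)
  expect_setequal(unique(r$warming_offset_c), c(0, 2.25, 4.5, 6.75, 9))
  expect_setequal(unique(r$co2_treatment), c("aCO2", "eCO2"))
  expect_identical(r, generate_design(cfg, seed = 1))
})

test_that("plot climates differ from ambient by exactly the warming offset", {
  cfg <- synthetic_config("tamarack")
  cl <- generate_climate(cfg, seed = 3)
  s0 <- summarize_climate(cl[cl$plot_id == "P01", ], "2017-06-24")
  s9 <- summarize_climate(cl[cl$plot_id == "P05", ], "2017-06-24")  # +9 aCO2
  expect_equal(s9$mean_t - s0$mean_t, 9, tolerance = 1e-10)
  expect_identical(cl, generate_climate(cfg, seed = 3))
  # noiseless ambient daytime mean matches the closed-form sinusoid average
  cfg0 <- synthetic_config("tamarack", sigma_weather = 0)
  cl0 <- generate_climate(cfg0, seed = 1)
  s <- summarize_climate(cl0[cl0$plot_id == "P01", ], "2017-06-24")
  hh <- seq(9, 14.5, by = 0.5)
  expect_equal(s$mean_t, 16 + 7 * mean(cos(2 * pi * (hh - 15) / 24)),
               tolerance = 1e-10)
})

test_that("noise-free truths follow the configured linear relations exactly", {
  acc <- default_acclimation("tamarack")
  acc$topt_a <- list(intercept = 23, slope = 0.3, co2_offset = 3,
                     co2_slope_delta = 0)
  cfg <- synthetic_config("tamarack", acclimation = acc, sigma_topt = 0,
                          sigma_tree = 0, sigma_aopt = 0, cv_capacity = 0,
                          month_offset = 0)
  tr <- generate_tree_truth(cfg, generate_design(cfg, 1), seed = 2)
  w9a <- tr$warming_offset_c == 9 & tr$co2_treatment == "aCO2"
  expect_true(all(abs(tr$topt_a[w9a] - 25.7) < 1e-12))
  for (w in unique(tr$warming_offset_c)) {
    d <- tr[tr$warming_offset_c == w, ]
    expect_equal(mean(d$topt_a[d$co2_treatment == "eCO2"]) -
                   mean(d$topt_a[d$co2_treatment == "aCO2"]), 3,
                 tolerance = 1e-12)
  }
})

test_that("generated truths regress back to the configured slope", {
  cfg <- synthetic_config("tamarack")
  rows <- do.call(rbind, lapply(1:170, function(s)
    generate_tree_truth(cfg, generate_design(cfg, s), seed = 1000 + s)))
  expect_gt(nrow(rows), 1e4)
  fit <- lm(topt_a ~ warming_offset_c + co2_treatment, data = rows)
  expect_lt(abs(unname(coef(fit)["warming_offset_c"]) -
                  cfg$acclimation$topt_a$slope), 0.01)
})

test_that("curves carry the printed 11-step Ca sequence and are seed-pure", {
  cfg <- synthetic_config("tamarack", trees_per_plot = 1)
  e1 <- generate_experiment(cfg, seed = 4, climate = FALSE)
  steps <- e1$curves[e1$curves$tree_id == e1$curves$tree_id[1] &
                       e1$curves$month == "June" & e1$curves$tleaf_c == 25, ]
  expect_equal(steps$ca_ppm[order(steps$step_index)],
               c(400, 300, 200, 50, 400, 500, 600, 800, 1200, 1600, 2000))
  expect_equal(nrow(steps), 11)
  e2 <- generate_experiment(cfg, seed = 4, climate = FALSE)
  expect_identical(e1$curves, e2$curves)
  e3 <- generate_experiment(cfg, seed = 5, climate = FALSE)
  expect_false(identical(e1$curves$a_umol_m2_s, e3$curves$a_umol_m2_s))
})

test_that("noiseless curves refit to the recorded effective capacities", {
  cfg <- synthetic_config("tamarack", trees_per_plot = 1, sigma_a = 0)
  exp <- generate_experiment(cfg, seed = 6, climate = FALSE)
  fits <- suppressWarnings(fit_aci_table(exp$curves))
  m <- merge(fits[fits$flag == "ok", ], exp$capacities,
             by = c("tree_id", "month", "tleaf_c"))
  expect_gt(nrow(m), 30)
  expect_lt(max(abs(m$vcmax - m$vcmax_true) / m$vcmax_true), 1e-3)
  # Jmax is only identifiable where the RuBP-regeneration state is expressed
  # over >= 3 steps, i.e. the true Ac/Aj crossing sits inside the Ci range
  gs <- oracle_arrhenius(42.75, 37830, m$tleaf_c)
  km <- oracle_arrhenius(404.9, 79430, m$tleaf_c) *
    (1 + 210 / oracle_arrhenius(278.4, 36380, m$tleaf_c))
  tci <- (m$jmax_true / 4 * km - 2 * gs * m$vcmax_true) /
    (m$vcmax_true - m$jmax_true / 4)
  two_state <- is.finite(tci) & tci > 250 & tci < 800
  expect_gt(sum(two_state), 10)
  expect_lt(max(abs(m$jmax[two_state] - m$jmax_true[two_state]) /
                  m$jmax_true[two_state]), 1e-3)
})

test_that("the growth-CO2 A in noiseless curves equals the quadratic truth", {
  cfg <- synthetic_config("black_spruce", trees_per_plot = 2, sigma_a = 0)
  exp <- generate_experiment(cfg, seed = 7, climate = FALSE)
  ga <- thermacclim:::growth_a_series(exp$curves, cfg$co2_levels)
  m <- merge(ga, exp$capacities, by = c("tree_id", "month", "tleaf_c"))
  expect_equal(m$a_growth, m$a_growth_true, tolerance = 1e-10)
  # and the quadratic refit returns the tree's configured truth exactly
  tr <- exp$truth
  g1 <- ga[ga$tree_id == tr$tree_id[1] & ga$month == tr$month[1], ]
  qf <- fit_quadratic_topt(g1$tleaf_c, g1$a_growth)
  expect_equal(qf$topt_a, tr$topt_a[1], tolerance = 1e-8)
  expect_equal(qf$aopt, tr$aopt[1], tolerance = 1e-8)
  expect_equal(qf$b, tr$b[1], tolerance = 1e-10)
})

test_that("the TPU state can be switched on and is expressed in curves", {
  cfg <- synthetic_config("tamarack", trees_per_plot = 1, sigma_a = 0,
                          tpu25 = 2)
  exp <- generate_experiment(cfg, seed = 9, climate = FALSE)
  one <- exp$curves[exp$curves$tree_id == exp$curves$tree_id[1] &
                      exp$curves$month == "June" &
                      exp$curves$tleaf_c == 25, ]
  expect_true(any(abs(one$a_umol_m2_s - 3 * 2) < 1e-9))
})
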