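tl5 <- c(15, 25, 32.5, 40, 45)

test_that("peaked-Arrhenius fitting recovers noiseless parameters", {
  v <- peaked_arrhenius(80, 33 + 273.15, 55, 200, tl5 + 273.15)
  f <- fit_peaked_arrhenius(tl5, v)
  expect_equal(f$topt, 33, tolerance = 1e-4)
  expect_equal(f$ea, 55, tolerance = 1e-4)
  expect_equal(f$kopt, 80, tolerance = 1e-4)
  expect_error(fit_peaked_arrhenius(c(15, 25, 35), c(30, 50, 60)),
               "insufficient-data")
})

test_that("the multistart fit matches a dense grid search", {
  set.seed(21)
  v <- peaked_arrhenius(70, 31 + 273.15, 48, 200, tl5 + 273.15) *
    (1 + rnorm(5, 0, 0.05))
  f <- fit_peaked_arrhenius(tl5, v)
  grid <- expand.grid(topt = seq(20, 45, by = 0.1), ea = seq(20, 100, by = 0.1))
  tk <- tl5 + 273.15
  sse <- mapply(function(to, ea) {
    g <- peaked_arrhenius(1, to + 273.15, ea, 200, tk)
    k <- sum(v * g) / sum(g^2)
    sum((v - k * g)^2)
  }, grid$topt, grid$ea)
  expect_lte(f$sse, min(sse) + 1e-10)
  i <- which.min(sse)
  expect_equal(f$topt, grid$topt[i], tolerance = 0.1)
  expect_equal(f$ea, grid$ea[i], tolerance = 0.2)
})

test_that("Eq-1 fits are invariant to uniform rescaling of the series", {
  set.seed(4)
  v <- peaked_arrhenius(60, 30 + 273.15, 50, 200, tl5 + 273.15) *
    (1 + rnorm(5, 0, 0.03))
  f1 <- fit_peaked_arrhenius(tl5, v)
  f2 <- fit_peaked_arrhenius(tl5, 3.7 * v)
  expect_equal(f1$topt, f2$topt, tolerance = 1e-5)
  expect_equal(f1$ea, f2$ea, tolerance = 1e-4)
  expect_equal(3.7 * f1$kopt, f2$kopt, tolerance = 1e-5)
})

test_that("quadratic fitting is exact on parabolas and flags non-peaked series", {
  y <- quadratic_a(8, 24, 0.03, tl5)
  f <- fit_quadratic_topt(tl5, y)
  expect_equal(f$aopt, 8, tolerance = 1e-10)
  expect_equal(f$topt_a, 24, tolerance = 1e-10)
  expect_equal(f$b, 0.03, tolerance = 1e-12)
  lin <- fit_quadratic_topt(tl5, 0.1 * tl5)
  expect_false(lin$converged)
  expect_equal(lin$flag, "no_optimum")
  expect_error(fit_quadratic_topt(c(20, 20, 20), c(1, 2, 3)), "degenerate-fit")
})

test_that("noisy quadratic fits equal closed-form polynomial least squares", {
  set.seed(9)
  for (i in 1:8) {
    y <- quadratic_a(8, 24, 0.03, tl5) + rnorm(5, 0, 0.5)
    f <- fit_quadratic_topt(tl5, y)
    o <- oracle_quadratic_ls(tl5, y)
    expect_equal(f$b, o$b, tolerance = 1e-9)
    expect_equal(f$topt_a, o$topt_a, tolerance = 1e-8)
    expect_equal(f$aopt, o$aopt, tolerance = 1e-8)
  }
})

test_that("climate summaries filter the daytime window correctly", {
  ts <- seq(as.POSIXct("2017-06-10 00:00", tz = "UTC"),
            as.POSIXct("2017-06-23 23:30", tz = "UTC"), by = 1800)
  const <- data.frame(timestamp = ts, air_temp_c = 20)
  s <- summarize_climate(const, "2017-06-24")
  expect_equal(s$mean_t, 20)
  expect_equal(s$max_t, 20)
  # values outside 9-15h do not contaminate the mean
  lt <- as.POSIXlt(ts, tz = "UTC")
  h <- lt$hour + lt$min / 60
  two <- data.frame(timestamp = ts,
                    air_temp_c = ifelse(h >= 9 & h < 15, 22, 10))
  expect_equal(summarize_climate(two, "2017-06-24")$mean_t, 22)
  # diurnal sinusoid: discrete mean equals the independent closed-form sum
  sine <- data.frame(timestamp = ts,
                     air_temp_c = 16 + 7 * cos(2 * pi * (h - 15) / 24))
  got <- summarize_climate(sine, "2017-06-24")$mean_t
  hh <- seq(9, 14.5, by = 0.5)
  expect_equal(got, 16 + 7 * mean(cos(2 * pi * (hh - 15) / 24)),
               tolerance = 1e-12)
  expect_error(summarize_climate(const, "2018-06-24"), "empty-window")
})

test_that("Ag and the optimum-exceedance metric follow the quadratic fit", {
  f <- fit_quadratic_topt(tl5, quadratic_a(8, 24, 0.03, tl5))
  expect_equal(as.numeric(compute_ag(f, 24)), 8)
  expect_equal(as.numeric(compute_ag(f, 29)), 8 - 0.03 * 25)
  clim <- list(mean_t = 25)
  expect_equal(compute_delta_mean_tg(list(mean_t = 25), f), 1)
  expect_equal(compute_delta_mean_tg(list(mean_t = 24), f), 0)
  # warming the climate by +9 raises the exceedance by exactly 9
  expect_equal(compute_delta_mean_tg(list(mean_t = 34), f) -
                 compute_delta_mean_tg(list(mean_t = 25), f), 9)
  # Ag never exceeds Aopt; equality only at the optimum
  tt <- seq(10, 45, by = 0.5)
  expect_true(all(compute_ag(f, tt) <= f$aopt + 1e-12))
})

test_that("A70 uses Ci = 0.7 * growth Ca and the branch-wise minimum", {
  fits <- data.frame(tleaf_c = tl5,
                     vcmax = c(25, 50, 70, 80, 60),
                     jmax = c(60, 110, 140, 150, 100),
                     rday = c(0.5, 1, 1.5, 2.2, 3),
                     tpu = NA_real_)
  r400 <- compute_a70_topt(fits, 400)
  expect_true(all(r400$series$ci == 280))
  r800 <- compute_a70_topt(fits, 800)
  expect_true(all(r800$series$ci == 560))
  # pointwise branch oracle
  for (i in seq_len(nrow(fits))) {
    expected <- min(oracle_ac(280, fits$vcmax[i], fits$rday[i], fits$tleaf_c[i]),
                    oracle_aj(280, fits$jmax[i], fits$rday[i], fits$tleaf_c[i]))
    expect_equal(r400$series$a70[i], expected, tolerance = 1e-10)
  }
  expect_s3_class(r400$fit, "quadratic_fit")
})

test_that("thermal optima are recovered within 1 degC median error under noise", {
  set.seed(31)
  n <- 200
  err_a <- err_v <- numeric(n)
  for (i in 1:n) {
    topt_a <- runif(1, 20, 27)
    # the growth-CO2 A at Ca = 400 is the mean of the protocol's two visits,
    # so its noise is sigma / sqrt(2)
    y <- quadratic_a(8, topt_a, 0.011, tl5) + rnorm(5, 0, 0.5 / sqrt(2))
    f <- fit_quadratic_topt(tl5, y)
    err_a[i] <- if (isTRUE(f$converged)) abs(f$topt_a - topt_a) else NA
    topt_v <- runif(1, 28, 38)
    v <- peaked_arrhenius(60, topt_v + 273.15, 55, 200, tl5 + 273.15) *
      (1 + rnorm(5, 0, 0.05))
    fv <- fit_peaked_arrhenius(tl5, v)
    err_v[i] <- abs(fv$topt - topt_v)
  }
  expect_lt(median(err_a, na.rm = TRUE), 1)
  expect_lt(median(err_v), 1)
})

test_that("with temperature-invariant stomata, ToptA and ToptA70 agree", {
  # constant Ci/Ca generation at growth Ca means the A70 series (at the same
  # Ci) reproduces the growth-CO2 series; optima then agree up to curve noise
  cfg <- synthetic_config("tamarack", trees_per_plot = 2, sigma_a = 0)
  exp <- generate_experiment(cfg, seed = 8, climate = FALSE)
  fits <- suppressWarnings(fit_aci_table(exp$curves))
  tt <- fit_tree_thermal(exp$curves, cfg, aci_fits = fits)
  d <- tt[is.finite(tt$topt_a) & is.finite(tt$topt_a70), ]
  expect_gt(nrow(d), 10)
  expect_lt(median(abs(d$topt_a - d$topt_a70)), 0.5)
})
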