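# Independent brute-force oracles: literal transcriptions of the model
# equations and exhaustive/closed-form references for the fitting routines.
# These deliberately share no code with the package internals.

oracle_arrhenius <- function(k25, ea, tleaf, R = 8.314) {
  Tk <- tleaf + 273.15
  k25 * exp(ea * (Tk - 298.15) / (298.15 * R * Tk))
}

oracle_peaked <- function(kopt, topt_k, ea_kj, hd_kj, tk, R = 8.314) {
  Ea <- ea_kj * 1000
  Hd <- hd_kj * 1000
  num <- Hd * exp(Ea * (tk - topt_k) / (tk * R * topt_k))
  den <- Hd - Ea * (1 - exp(Hd * (tk - topt_k) / (tk * R * topt_k)))
  kopt * num / den
}

oracle_ac <- function(ci, vcmax, rday, tleaf, O = 210,
                      gs25 = 42.75, kc25 = 404.9, ko25 = 278.4) {
  gs <- oracle_arrhenius(gs25, 37830, tleaf)
  kc <- oracle_arrhenius(kc25, 79430, tleaf)
  ko <- oracle_arrhenius(ko25, 36380, tleaf)
  vcmax * (ci - gs) / (ci + kc * (1 + O / ko)) - rday
}

oracle_aj <- function(ci, jmax, rday, tleaf, gs25 = 42.75) {
  gs <- oracle_arrhenius(gs25, 37830, tleaf)
  (jmax / 4) * (ci - gs) / (ci + 2 * gs) - rday
}

oracle_quadratic <- function(aopt, topt_a, b, t) aopt - b * (t - topt_a)^2

# exhaustive bilinear partition search, regressions via lm()
oracle_bilinear_partition <- function(ci, a, tleaf, min_seg = 3) {
  ord <- order(ci)
  ci <- ci[ord]; a <- a[ord]
  n <- length(ci)
  gs <- oracle_arrhenius(42.75, 37830, tleaf)
  kc <- oracle_arrhenius(404.9, 79430, tleaf)
  ko <- oracle_arrhenius(278.4, 36380, tleaf)
  x1 <- (ci - gs) / (ci + kc * (1 + 210 / ko))
  x2 <- (ci - gs) / (ci + 2 * gs)
  best <- NULL
  for (k in min_seg:(n - min_seg)) {
    lo <- 1:k; hi <- (k + 1):n
    m1 <- stats::lm(a[lo] ~ x1[lo])
    vcmax <- unname(stats::coef(m1)[2])
    rday <- max(0, -unname(stats::coef(m1)[1]))
    if (-unname(stats::coef(m1)[1]) < 0)
      vcmax <- unname(stats::coef(stats::lm(a[lo] ~ 0 + x1[lo]))[1])
    m2 <- stats::lm(I(a[hi] + rday) ~ 0 + x2[hi])
    jq <- unname(stats::coef(m2)[1])
    ahat <- ifelse(ci < gs, vcmax * x1, pmin(vcmax * x1, jq * x2)) - rday
    sse <- sum((a - ahat)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, vcmax = vcmax, jmax = 4 * jq, rday = rday, sse = sse)
  }
  best
}

# closed-form polynomial least squares via the normal equations
oracle_quadratic_ls <- function(t, y) {
  X <- cbind(1, t, t^2)
  cf <- solve(t(X) %*% X, t(X) %*% y)
  c2 <- cf[3]
  list(b = -c2, topt_a = -cf[2] / (2 * c2),
       aopt = cf[1] - cf[2]^2 / (4 * c2))
}

# standard noiseless 11-step test curve at a constant Ci/Ca ratio
make_test_curve <- function(vcmax = 60, jmax = 120, rday = 1, tleaf = 25,
                            tpu = Inf, ratio = 0.7) {
  ca <- c(400, 300, 200, 50, 400, 500, 600, 800, 1200, 1600, 2000)
  ci <- ratio * ca
  gs <- oracle_arrhenius(42.75, 37830, tleaf)
  ac <- oracle_ac(ci, vcmax, rday, tleaf)
  aj <- oracle_aj(ci, jmax, rday, tleaf)
  at <- if (is.finite(tpu)) 3 * tpu else Inf
  a <- ifelse(ci < gs, ac, pmin(ac, aj, at))
  data.frame(ca = ca, ci = ci, a = a)
}
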