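#' Rubisco kinetic constants and their temperature scalings
#'
#' Bundles the CO2 compensation point in the absence of day respiration
#' (Gamma*), the Michaelis constants of Rubisco for CO2 and O2, their
#' Arrhenius activation energies, the intercellular O2 concentration and the
#' universal gas constant. Defaults follow the Bernacchi et al. convention
#' used by standard A-Ci curve-fitting tools.
#'
#' @param gammastar25 Gamma* at 25 degC (umol mol-1).
#' @param ea_gammastar Activation energy of Gamma* (J mol-1).
#' @param kc25 Michaelis constant for CO2 at 25 degC (umol mol-1).
#' @param ea_kc Activation energy of Kc (J mol-1).
#' @param ko25 Michaelis constant for O2 at 25 degC (mmol mol-1).
#' @param ea_ko Activation energy of Ko (J mol-1).
#' @param oxygen Intercellular O2 concentration (mmol mol-1).
#' @param gas_constant Universal gas constant (J mol-1 K-1).
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(gammastar25 = 42.75, ea_gammastar = 37830,
                              kc25 = 404.9, ea_kc = 79430,
                              ko25 = 278.4, ea_ko = 36380,
                              oxygen = 210, gas_constant = 8.314) {
  kc <- list(gammastar25 = gammastar25, ea_gammastar = ea_gammastar,
             kc25 = kc25, ea_kc = ea_kc, ko25 = ko25, ea_ko = ea_ko,
             oxygen = oxygen, gas_constant = gas_constant)
  vals <- unlist(kc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid-input: all kinetic constants must be finite and strictly positive")
  class(kc) <- "kinetic_constants"
  kc
}

#' Arrhenius temperature scaling of a kinetic constant
#'
#' Scales a rate or constant known at 25 degC to a leaf temperature using the
#' (non-peaked) Arrhenius function
#' `k25 * exp(ea * (Tk - 298.15) / (298.15 * R * Tk))`.
#'
#' @param k25 Value at 25 degC.
#' @param ea Activation energy (J mol-1).
#' @param tleaf Leaf temperature (degC), in [-10, 60].
#' @param constants A [kinetic_constants()] object (supplies R).
#' @return The scaled value, same units as `k25`. Vectorised over `tleaf`.
#' @export
arrhenius_scaled <- function(k25, ea, tleaf, constants = kinetic_constants()) {
  if (any(!is.finite(k25)) || any(!is.finite(ea)) || any(!is.finite(tleaf)))
    stop("invalid-input: non-finite argument to arrhenius_scaled()")
  if (any(tleaf < -10 | tleaf > 60))
    stop("invalid-input: tleaf outside [-10, 60] degC")
  tk <- tleaf + 273.15
  k25 * exp(ea * (tk - 298.15) / (298.15 * constants$gas_constant * tk))
}

#' Peaked (modified) Arrhenius temperature response
#'
#' The optimum-parameterised peaked Arrhenius function used to describe the
#' temperature response of Vcmax and Jmax:
#' \deqn{f(T_k) = k_{opt} \frac{H_d \exp[E_a (T_k - T_{opt}) / (T_k R T_{opt})]}
#'   {H_d - E_a (1 - \exp[H_d (T_k - T_{opt}) / (T_k R T_{opt})])}}
#' The function equals `kopt` at `tk = topt` and, for `0 < ea < hd`, is below
#' `kopt` everywhere else.
#'
#' @param kopt Process rate at the optimum (umol m-2 s-1).
#' @param topt Optimum temperature (K).
#' @param ea Activation energy (kJ mol-1).
#' @param hd Deactivation energy (kJ mol-1); must exceed `ea`.
#' @param tk Evaluation temperature (K). Vectorised.
#' @param gas_constant Universal gas constant (J mol-1 K-1).
#' @return Rate at `tk` (umol m-2 s-1).
#' @export
peaked_arrhenius <- function(kopt, topt, ea, hd, tk, gas_constant = 8.314) {
  if (any(!is.finite(c(kopt, topt, ea, hd))) || any(!is.finite(tk)))
    stop("invalid-input: non-finite argument to peaked_arrhenius()")
  if (any(hd <= ea))
    stop("parameterization error: hd must exceed ea for a peaked response")
  if (any(tk <= 0) || any(topt <= 0))
    stop("invalid-input: temperatures must be in Kelvin ( > 0 )")
  ea_j <- ea * 1000
  hd_j <- hd * 1000
  arg <- (tk - topt) / (tk * gas_constant * topt)
  kopt * hd_j * exp(ea_j * arg) / (hd_j - ea_j * (1 - exp(hd_j * arg)))
}

#' Rubisco-limited net assimilation rate (Ac)
#'
#' \deqn{A_c = V_{cmax} (C_i - \Gamma^*) / [C_i + K_c (1 + O / K_o)] - R_{day}}
#' with Gamma*, Kc and Ko evaluated at `tleaf` via [arrhenius_scaled()].
#'
#' @param ci Intercellular CO2 (umol mol-1). Vectorised.
#' @param vcmax Maximum carboxylation rate at `tleaf` (umol m-2 s-1).
#' @param rday Daytime mitochondrial respiration (umol m-2 s-1).
#' @param tleaf Leaf temperature (degC).
#' @param constants A [kinetic_constants()] object.
#' @return Ac (umol m-2 s-1).
#' @export
ac_rate <- function(ci, vcmax, rday, tleaf, constants = kinetic_constants()) {
  gs <- arrhenius_scaled(constants$gammastar25, constants$ea_gammastar, tleaf, constants)
  kc <- arrhenius_scaled(constants$kc25, constants$ea_kc, tleaf, constants)
  ko <- arrhenius_scaled(constants$ko25, constants$ea_ko, tleaf, constants)
  vcmax * (ci - gs) / (ci + kc * (1 + constants$oxygen / ko)) - rday
}

#' RuBP-regeneration-limited net assimilation rate (Aj)
#'
#' \deqn{A_j = (J_{max}/4) (C_i - \Gamma^*) / (C_i + 2 \Gamma^*) - R_{day}}
#'
#' @param ci Intercellular CO2 (umol mol-1). Vectorised.
#' @param jmax Maximum electron transport rate at `tleaf` (umol m-2 s-1).
#' @inheritParams ac_rate
#' @return Aj (umol m-2 s-1).
#' @export
aj_rate <- function(ci, jmax, rday, tleaf, constants = kinetic_constants()) {
  gs <- arrhenius_scaled(constants$gammastar25, constants$ea_gammastar, tleaf, constants)
  (jmax / 4) * (ci - gs) / (ci + 2 * gs) - rday
}

#' Triose-phosphate-use-limited assimilation rate (ATPU)
#'
#' Returns `3 * tpu`, independent of Ci and leaf temperature. By default the
#' gross form is used (no Rday subtraction), matching the convention of the
#' three-state minimum used for A70; set `tpu_net = TRUE` to subtract `rday`
#' for consistency with the other two (net) limitation states.
#'
#' @param tpu Triose-phosphate use rate (umol m-2 s-1).
#' @param rday Daytime respiration, subtracted only when `tpu_net = TRUE`.
#' @param tpu_net Subtract `rday`? Default `FALSE`.
#' @return ATPU (umol m-2 s-1).
#' @export
atpu_rate <- function(tpu, rday = 0, tpu_net = FALSE) {
  if (any(!is.finite(tpu)) || any(tpu <= 0))
    stop("invalid-input: tpu must be finite and > 0")
  3 * tpu - if (tpu_net) rday else 0
}

#' Net assimilation as the minimum of the three FvCB limitation states
#'
#' Computes Ac, Aj and (when `tpu` is finite) ATPU and returns their pointwise
#' minimum together with the limiting state. Ties are resolved in the priority
#' order Ac > Aj > ATPU.
#'
#' @inheritParams ac_rate
#' @param jmax Maximum electron transport rate at `tleaf` (umol m-2 s-1).
#' @param tpu Triose-phosphate use (umol m-2 s-1); `Inf` or `NA` disables the
#'   TPU limitation state.
#' @param tpu_net Passed to [atpu_rate()].
#' @return A data.frame with columns `a` and `limitation`
#'   (one of `"Ac"`, `"Aj"`, `"ATPU"`).
#' @export
net_a <- function(ci, vcmax, jmax, rday, tleaf, tpu = Inf,
                  constants = kinetic_constants(), tpu_net = FALSE) {
  ac <- ac_rate(ci, vcmax, rday, tleaf, constants)
  aj <- aj_rate(ci, jmax, rday, tleaf, constants)
  if (length(tpu) == 1 && (is.na(tpu) || !is.finite(tpu))) {
    at <- rep(Inf, length(ac))
  } else {
    at <- rep(atpu_rate(tpu, rday, tpu_net), length.out = length(ac))
  }
  m <- cbind(Ac = ac, Aj = aj, ATPU = at)
  idx <- apply(m, 1, which.min)  # which.min returns the first minimum: Ac > Aj > ATPU
  data.frame(a = m[cbind(seq_along(idx), idx)],
             limitation = colnames(m)[idx],
             stringsAsFactors = FALSE)
}

#' Quadratic temperature response of net photosynthesis
#'
#' \deqn{A(T) = A_{opt} - b (T - T_{optA})^2}
#' where `b` (umol m-2 s-1 degC-2) sets the breadth of the response: larger
#' `b`, narrower curve, greater short-term temperature sensitivity.
#'
#' @param aopt Net photosynthesis at the thermal optimum (umol m-2 s-1).
#' @param topt_a Thermal optimum of net photosynthesis (degC).
#' @param b Curvature / breadth parameter (umol m-2 s-1 degC-2), `>= 0`.
#' @param t Evaluation temperature (degC). Vectorised.
#' @return A at `t` (umol m-2 s-1).
#' @export
quadratic_a <- function(aopt, topt_a, b, t) {
  if (b < 0) stop("invalid-input: curvature b must be >= 0")
  aopt - b * (t - topt_a)^2
}
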