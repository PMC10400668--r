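---
title: "Methods: thermal acclimation of photosynthesis in warmed, CO2-enriched conifers"
author: "thermacclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal acclimation of photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermacclim)
```

## The scientific question

Whole-ecosystem warming experiments on mature boreal conifers ask whether
leaf photosynthesis *acclimates*: after years at a higher growth
temperature, does the thermal optimum of net photosynthesis
($T_{optA}$) shift upward, do the underlying biochemical capacities
(maximum Rubisco carboxylation rate $V_{cmax}$, maximum electron transport
rate $J_{max}$) shift with it, and is carbon uptake at the prevailing
growth temperature maintained? `thermacclim` implements the full analysis
chain for a regression-based warming $\times$ CO~2~ design — 10 open-top
enclosures spanning warming offsets of +0, +2.25, +4.5, +6.75 and +9 °C,
crossed with ambient (~400 ppm) and elevated (~800 ppm) CO~2~ — together
with a synthetic-data generator so that every stage can be validated by
parameter recovery against known ground truth.

## Models

### FvCB photosynthesis

Net CO~2~ assimilation $A$ follows the Farquhar–von Caemmerer–Berry (FvCB)
C~3~ model as the minimum of three limitation states,

$$A_c = \frac{V_{cmax}\,(C_i - \Gamma^*)}{C_i + K_c\,(1 + O/K_o)} - R_{day},
\qquad
A_j = \frac{J_{max}}{4}\,\frac{C_i - \Gamma^*}{C_i + 2\Gamma^*} - R_{day},
\qquad
A_{TPU} = 3\,TPU,$$

with $\Gamma^*$ (CO~2~ compensation point without day respiration), $K_c$,
$K_o$ (Michaelis constants) scaled from 25 °C by the Arrhenius function
using the Bernacchi parameter set
($\Gamma^*_{25} = 42.75$ µmol mol⁻¹, $E_a$ 37 830 J mol⁻¹;
$K_{c,25} = 404.9$ µmol mol⁻¹, 79 430; $K_{o,25} = 278.4$ mmol mol⁻¹,
36 380; $O = 210$ mmol mol⁻¹), all overridable through
`kinetic_constants()`. $V_{cmax}$ and $J_{max}$ are *apparent* (on a $C_i$
basis): mesophyll conductance is deliberately out of scope.

Two conventions deserve a note:

* **$A_{TPU}$ is gross as written** (no $R_{day}$ subtraction), matching the
  three-state minimum convention used for the fixed-ratio recalculation
  below; `atpu_rate(tpu_net = TRUE)` subtracts $R_{day}$ for users who want
  all three states net.
* **Below $\Gamma^*$ the pointwise minimum is unphysical**: both net
  branches are negative there and $A_j$ is the more negative, so a literal
  minimum would label sub-compensation points RuBP-limited. Rubisco kinetics
  limit at low $C_i$, so curve generation and the bilinear reconstruction
  use the $A_c$ branch for $C_i < \Gamma^*$ and the minimum elsewhere. The
  only measured step this affects is the Ca = 50 ppm step
  ($C_i \approx 35$ at the operating ratio). `net_a()` itself implements the
  plain minimum, which is the rule used for $A_{70}$ at $C_i$ of 280/560
  ppm where the two rules coincide.

### Temperature responses

Capacity–temperature series follow the optimum-parameterised peaked
Arrhenius function

$$f(T_k) = k_{opt}\,
\frac{H_d \exp\!\left[\frac{E_a (T_k - T_{opt})}{T_k R\, T_{opt}}\right]}
     {H_d - E_a\!\left(1 - \exp\!\left[\frac{H_d (T_k - T_{opt})}{T_k R\, T_{opt}}\right]\right)},$$

evaluated in Kelvin with $R = 8.314$ J mol⁻¹ K⁻¹; $E_a$ and $H_d$ are
carried in kJ mol⁻¹ and converted internally. $H_d$ is fixed at
200 kJ mol⁻¹ for both capacities to avoid over-parameterising 4–5 point
series. The temperature response of net photosynthesis at growth CO~2~ is
the quadratic

$$A(T) = A_{opt} - b\,(T - T_{optA})^2,$$

whose breadth parameter $b$ (µmol m⁻² s⁻¹ °C⁻²) measures short-term
temperature sensitivity (larger $b$ = narrower curve).

## Fitting

**Bilinear A–Ci fitting** (`fit_aci_bilinear()`): points are sorted by
$C_i$ and every contiguous partition with at least 3 points per segment is
scored. The low segment regresses $A$ on
$x_1 = (C_i-\Gamma^*)/(C_i + K_c(1+O/K_o))$, giving $V_{cmax}$ (slope) and
$R_{day}$ (minus the intercept, clamped at 0 with a warning when the
intercept is nonphysical, in which case the slope is refit through the
origin); the high segment regresses $A + R_{day}$ through the origin on
$x_2 = (C_i-\Gamma^*)/(C_i+2\Gamma^*)$, giving $J_{max}/4$. The partition
minimising the SSE of the reconstructed piecewise model wins; the reported
transition is the midpoint of the bounding $C_i$ values. TPU limitation is
declared only when the two highest-$C_i$ steps fall below the $A_j$
prediction by more than one standard error (residual SE of the high
segment divided by $\sqrt{2}$), in which case
$TPU = (\bar{A}_{top} + R_{day})/3$. The repeated Ca = 400 step is kept in
the fit (the model is a function of $C_i$), and partitioning is on $C_i$,
not Ca. Curves need at least 6 points with 3 below $C_i$ 300 and 3 above
500; both limitation states are only identifiable when the true Ac/Aj
crossing falls inside the measured range with 3 clean points on each side,
which is why the high-temperature (45 °C) curves fail most often — those
failures are flagged and excluded downstream rather than aborting the
tree.

**Peaked-Arrhenius fitting** (`fit_peaked_arrhenius()`): $k_{opt}$ is
profiled out linearly (for fixed shape parameters the optimum scale is a
ratio of inner products), and the remaining $(T_{opt}, E_a)$ surface is
minimised by Nelder–Mead from a 3 × 2 multistart grid
($T_{opt} \in \{25, 30, 35\}$ °C, $E_a \in \{40, 60\}$ kJ mol⁻¹, relative
tolerance $10^{-13}$, with a polish restart from the winner), because
5-point series carry local minima. Fits whose optimum leaves [5, 50] °C
are flagged and excluded from downstream summaries. A consequence of
profiling: fits are exactly invariant to uniform rescaling of the series
($T_{opt}$, $E_a$ unchanged, $k_{opt}$ scales), which the tests assert.

**Quadratic fitting** (`fit_quadratic_topt()`): exact linear least squares
on the polynomial basis $a = c_0 + c_1 t + c_2 t^2$ with
$b = -c_2$, $T_{optA} = -c_1/(2c_2)$, $A_{opt} = c_0 - c_1^2/(4c_2)$.
Curvature indistinguishable from zero
($c_2 \ge -10^{-10}\max(1, |c_0|)$) means no interior optimum; the tree is
flagged and excluded rather than assigned a boundary optimum.

## Derived quantities

* **Growth-CO~2~ extraction**: the measured $A$ at the tree's growth Ca
  (400 or 800 ppm, ±25 ppm tolerance) is taken from each curve; the
  protocol visits Ca = 400 twice and both visits are averaged.
* **$A_{70}$**: to remove stomatal variation, $A$ is recomputed at
  $C_i = 0.7 \times$ growth Ca (280 or 560 ppm) at every leaf temperature
  from the per-temperature fitted $V_{cmax}$, $J_{max}$, $R_{day}$ and TPU,
  and the quadratic is refit to the $A_{70}$ series. (Arrhenius-smoothed
  parameters would be an alternative; per-temperature fits are the
  default because they add no shape assumption.)
* **Growth temperature**: plot air temperature is summarised over the
  daytime window 09:00–15:00 (start-inclusive) for the 10 full days before
  each measurement date. The 9 am–3 pm window is adopted as the
  photosynthetically active period; mean and maximum are reported, with a
  coverage warning below 50 % of expected samples.
* **$A_g$ and $\Delta MeanT_g$**: the fitted quadratic evaluated at the
  mean daytime growth temperature, and the exceedance
  $\Delta MeanT_g = \bar{T}_{growth} - T_{optA}$ (positive = air above the
  optimum).

## Treatment inference

All inference runs on plot means (1–4 trees per plot per month). Warming
enters as a continuous covariate (°C above ambient), CO~2~ as a two-level
factor, month as the candidate random intercept. Selection follows the
two-step protocol: (1) compare the month-random-intercept model
(`nlme::lme`) against no random structure (`nlme::gls`) by REML AIC under
the most complex (interaction) fixed structure; (2) holding the chosen
random structure, compare main-effects vs interaction fixed structures by
ML AIC. AICc ($AIC + 2k(k+1)/(n-k-1)$) is reported alongside every
candidate because $n = 20$ plot-mean records is small. Ties go to the
simpler model; with only two month levels the random variance is profiled
on the boundary-truncated scale (variance $\ge 0$). One-sided tests are
applied only to the directional hypotheses (warming and CO~2~ increase
$T_{optA}$, $A_{opt}$, $A_g$); other responses are two-sided. No
multiple-testing correction is applied across responses, and the
$\Delta MeanT_g$ analysis is a two-factor fixed-effects ANOVA (warming as
a 5-level factor) with type-II sums of squares, robust to the mild
imbalance of 1–4 trees per plot.

## The synthetic-data generator

`synthetic_config()` encodes the study conditions: 10 plots (5 warming
offsets × 2 CO~2~), 3 trees per plot, June and August campaigns, A–Ci
curves at 15/25/32.5/40/45 °C with the 11-step Ca sequence
400, 300, 200, 50, 400, 500, 600, 800, 1200, 1600, 2000 µmol mol⁻¹.
Ground-truth thermal parameters follow linear acclimation relations —
intercept + slope × warming + CO~2~ offset — with the shipped defaults
taken from the fitted treatment responses of the field experiment the
generator emulates (tamarack $T_{optA} = 23.2 + 0.26\,w$, +3 °C under
elevated CO~2~; spruce $T_{optA} = 23.3 + 0.35\,w$;
$T_{optV}$/$T_{optJ}$ slopes 0.35/0.26 for tamarack and 0.44/0.55 for
spruce; spruce $A_{opt}$ slopes 0.10 ambient / 0.54 elevated; an 86 %
elevation of $b$ under elevated CO~2~ in tamarack).

Design choices that matter:

* **Stomatal model**: constant $C_i/C_a = 0.7$. This matches the
  fixed-ratio reference used for $A_{70}$ and makes biochemical control of
  $T_{optA}$ exact in the generator, so optimum shifts cannot be stomatal
  artefacts.
* **Exact quadratic truth**: curves are built from peaked-Arrhenius-shaped
  capacities and then both capacities are rescaled jointly per leaf
  temperature (preserving the $J_{max}/V_{cmax}$ ratio, hence the A–Ci
  shape) so that net $A$ at the growth-CO~2~ $C_i$ equals the tree's
  quadratic truth exactly. This pins the configured $T_{optA}$, $A_{opt}$
  and $b$ into the curves — the property parameter recovery is scored
  against — at the cost of the capacity series no longer being exactly
  peaked-Arrhenius in temperature (the ideal FvCB $A(T)$ at constant
  $C_i$ is steeper than the default quadratic). The effective
  per-temperature capacities are recorded in the truth ledger, and
  capacity round-trip tests score against them. Validation of
  $T_{optV}$/$T_{optJ}$ recovery therefore uses capacity series generated
  directly from the peaked Arrhenius truth (5 % multiplicative value
  noise), which is also how per-tree capacity fits feed the optima in the
  real analysis.
* **Noise structure**: Gaussian $\sigma_A = 0.5$ µmol m⁻² s⁻¹ on every
  curve point; plot-level $\sigma = 0.5$ °C and tree-level
  $\sigma = 0.3$ °C on the thermal-optimum truths; 5 % multiplicative
  (CV) noise on capacities, $A_{opt}$ and $b$; a centred ±0.25 °C
  June/August shift on the optimum truths (so the configured intercepts
  remain across-month means) that keeps random-structure selection
  non-degenerate.
* **Curvature default**: $b = 0.011$ µmol m⁻² s⁻¹ °C⁻², chosen once so
  that the quadratic truth stays physically plausible at the 45 °C
  measurement (peak rates of 6–11 µmol m⁻² s⁻¹ and optima near 23 °C give
  $A(45) > -R_{day}(45)$ throughout the design); the elevated-CO~2~
  tamarack ratio is 1.86.
* **$R_{day}$** scales from $R_{day,25} = 1$ µmol m⁻² s⁻¹ with
  $Q_{10} = 2$; TPU is disabled by default (keeping round-trips in the
  two-state regime the bilinear fitter targets) and can be enabled via
  `tpu25`.
* **Climate**: an ambient diurnal sinusoid (mean 16 °C, half-amplitude
  7 °C, peak at 15:00) plus weather deviations *shared across plots* (the
  enclosures sit in one bog), offset by each plot's warming treatment —
  so daytime-mean differences equal the warming offsets exactly.

What the generator does *not* emulate: stomatal temperature responses
(ratio fixed), instrument drift, leaf-energy-balance decoupling, phenology
or seasonal capacity drift, and real within-curve error correlation.
Passing recovery tests therefore demonstrate that the analysis chain is
unbiased under the assumed error structure, not that field estimates are
free of these other effects.

## Validation and problem sizes

All generator outputs are pure functions of `(config, seed)`. The test
suite checks the forward equations against literal-transcription oracles
(10⁻¹⁰ relative), the bilinear partition against exhaustive enumeration,
the quadratic fit against closed-form normal equations, noiseless
round-trips through every fitter, and the behaviour of the selection
protocol under known random/fixed structures. The headline validation is
`recovery_study()`: 200 independently seeded replicate experiments per
component, each at the full design size (10 plots × 3 trees × 2 months ×
5 temperatures × 11 steps), whose mean recovered warming slopes, CO~2~
offsets, intercepts and $b$ elevation are compared to the generating
truth (slopes within ±0.05, offsets/intercepts ±0.5 °C, $b$ elevation
±10 percentage points). The paired-optimum relationships
($T_{optA}$ on $T_{optV}$/$T_{optJ}$, slopes 0.57 and 0.75) are validated
on plot-level pairs (20 plot-equivalents × 2 months,
$\sigma = 0.7$ °C on $T_{optA}$) with the month-random-intercept
regression. `scripts/acceptance.R` re-runs the same study from scratch.

## Known limitations

* The bilinear method is stagewise, not a simultaneous nonlinear fit; its
  SSE optimality is per-partition, and $J_{max}$ is unidentifiable when
  the Ac/Aj transition leaves the measured $C_i$ range (flagged, not
  guessed).
* With two random-effect levels the month variance is weakly identified;
  the selection step treats it exactly as the two-step protocol
  prescribes, but the variance estimate itself should not be
  interpreted.
* Field data ingestion assumes the documented CSV schemas
  (`aci_curves.csv`, `climate.csv`); instrument-native formats need a
  column map.
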