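---
title: "Deterministic estimation of mean annual indoor radon: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic estimation of mean annual indoor radon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonmbe)
```

## The estimation problem

Measuring long-term indoor radon is slow: passive detectors must sit in a
residence for months, at two points, and the result still depends on the
season of measurement. This package estimates the **mean annual indoor
radon concentration** of a residence deterministically, from its
administrative district, its building traits, provincial meteorological
normals and the occupants' ventilation habits — quantities available
without any in-home measurement. The chain has a physical half and a
statistical half, joined by one scalar per residence: the infiltration
factor.

## The physical model

### Compartments and mass balance

Three well-mixed compartments exchange radon: indoor air ($C_i$), the soil
under the building ($C_s$) and the radon-bearing building materials
($C_{bm}$), all in Bq m$^{-3}$. The dynamic model is linear:

$$
\begin{aligned}
\frac{dC_i}{dt} &= \{k_{d,s}(C_s - C_i) + k_a \Delta P_{s-i} C_s\}\frac{S_g}{V}
 + k_{d,bm}(C_{bm} - C_i)\frac{S_{bm}}{V} - \lambda_v (C_i - C_o) - \lambda C_i \\
\frac{dC_s}{dt} &= E_s \frac{S_g}{V}
 - \{k_{d,s}(C_s - C_i) + k_a \Delta P_{s-i} C_s\}\frac{S_g}{V} - \lambda C_s \\
\frac{dC_{bm}}{dt} &= E_{bm} \frac{S_{bm}}{V}
 - k_{d,bm}(C_{bm} - C_i)\frac{S_{bm}}{V} - \lambda C_{bm}
\end{aligned}
$$

with diffusive transfer coefficients $k_{d,s}, k_{d,bm}$ (m h$^{-1}$), the
advective coefficient $k_a$ (m Pa$^{-1}$ h$^{-1}$) driven by the
soil–indoor pressure difference $\Delta P_{s-i}$, exhalation rates
$E_s, E_{bm}$ (Bq m$^{-2}$ h$^{-1}$), geometry $S_g, S_{bm}, V$, the decay
constant $\lambda = 7.56\times 10^{-3}$ h$^{-1}$ and the ventilation rate
$\lambda_v$. The time base is hours throughout. Two modelling notes:

* The soil source term $E_s S_g / V$ is normalised by the *indoor* volume
  $V$. Physically one might expect a soil-gas volume here; the package
  implements the model as stated because the statistical pipeline never
  needs the soil compartment's absolute scale — the steady-state inversion
  eliminates it.
* Summing the three equations at equilibrium gives the closed-form indoor
  steady state
  $$ C_i = \frac{S + \lambda_v C_o - \lambda (C_s + C_{bm})}{\lambda + \lambda_v},
     \qquad S \equiv E_s\frac{S_g}{V} + E_{bm}\frac{S_{bm}}{V}, $$
  so the full parameter vector collapses into the single **infiltration
  factor** $S$ (Bq m$^{-3}$ h$^{-1}$), the combined entry concentration
  rate from soil and building materials. `simulate_dynamics()` integrates
  the dynamic system (stiff-capable `deSolve::lsoda`, rtol $10^{-8}$) and
  is validated against the direct 3×3 linear solve
  (`steady_state_solution()`) and against the closed form.

The steady state is *exactly invertible*: given a measured annual
concentration, $S = C_i(\lambda + \lambda_v) + \lambda(C_s + C_{bm}) -
\lambda_v C_o$. Negative algebraic values of $C_i$ or $S$ (physically
inconsistent inputs) are returned unchanged with a warning — clamping
would silently break the inverse identity that the whole pipeline rests
on.

### Ventilation

$$ \lambda_v = (f_t\,|T_i - T_o| + f_w u^2)\,N $$

is a stack-effect term plus a wind-pressure term, scaled by a
habit-weighted multiplier $N$. Parameters that matter:

| parameter | units | default | rationale |
|---|---|---|---|
| $f_t$ | h$^{-1}$ °C$^{-1}$ | 0.03 | with $T_i = 20$ °C and temperate monthly normals, yields an annual-mean $\lambda_v \approx 0.34$ h$^{-1}$, the centre of the physically expected 0.24–0.73 h$^{-1}$ band |
| $f_w$ | h$^{-1}$ s$^2$ m$^{-2}$ | 0.01 | wind term contributes $\sim$0.04 h$^{-1}$ at 2 m s$^{-1}$ |
| $T_i$ | °C | 20 | fixed indoor set-point; config-exposed |
| $N$ (habits) | — | low 0.8 / medium 1.0 / high 1.2 | ordinal habit categories; fully config-driven |

These are *fitting* parameters, not physical constants; studies with
measured air-exchange rates should replace them. All printed-example
tests pass them explicitly. The per-residence annual rate averages the
twelve monthly rates (mean of $\lambda_v$ over months, not $\lambda_v$ of
mean weather); averaging the concentration over months instead would be
an alternative convention — the rate average was chosen because the
regression operates on one annual $S$ per residence.

## Regional proxies

Soil radon ($C_s$) and outdoor radon ($C_o$) are not measured per
residence. The package derives proxies from record-level *winter* survey
data (winter minimises the ventilation signal): each district's weight is
GM(district)/GM(all records), and $C_s = w_d \times$ `soil_reference`;
provinces are treated identically for $C_o$. The record-count-weighted
mean of log weights is exactly zero, so the national GM is conserved.
Defaults `soil_reference = 86.52` (the national winter-survey GM itself,
Bq m$^{-3}$) and `outdoor_reference = 10` Bq m$^{-3}$ (typical outdoor
level). Because the weights are relative, the choice of reference shifts
every inverted $S$ by a near-constant amount per stratum that the
regression intercept absorbs; predictions of $C_i$ are therefore almost
insensitive to it, and the pipeline tests include noiseless runs where
this absorption is exact.

## Preprocessing

Fixed order: two-point geometric mean → seasonal correction → natural log
→ outlier screen → stratification.

* Concentrations are log-normal, so the per-residence summary of the two
  measurement points is their geometric mean, and all screening happens on
  the natural-log scale.
* Seasonal correction multiplies by a season-specific factor
  (identity defaults; the synthetic generator records the factors it used
  so round trips are exact).
* The outlier screen is a **single-pass** $|z| > 3$ rule computed within
  stratum (both threshold and scope configurable). Single-pass, because
  iterating the rule re-estimates the SD on a truncated sample and can
  cascade; within-stratum, because the four strata have visibly different
  scales and a pooled screen would preferentially flag the high-GM
  stratum. With zero variance nothing is removed.
* Strata: Type 1 = detached + groundwater, Type 2 = detached without,
  Type 3 = other + groundwater, Type 4 = other without.

## The infiltration-factor regression

Per stratum, OLS of the inverted $S$ on district greenery ratio ($X_1$,
percent, used raw — no centering), district indoor-radon GM ($X_2$, Bq
m$^{-3}$, raw scale), and dummy-coded building traits against the
reference levels *concrete*, *0–1 cracks*, *≤1 floor*. Predictor sets are
stratum-specific **metadata**, not code branches: the packaged coefficient
file records that Type 3 has no crack/floor terms and admits only
concrete/red-brick/cement-block, and Type 4 has no soil/wood levels.
Standard errors and two-sided p-values use the t distribution on the
residual degrees of freedom. Fitted models serialize to flat JSON and
predict via an explicit coefficient dot product, so a restored model is
bit-identical in prediction to a live one.

One scale caveat, flagged deliberately: the packaged reference slope on
$X_2$ ($\beta_2 \approx 2.7$ per Bq m$^{-3}$) is large relative to the
concentration scale the stratum summaries imply — with realistic district
GMs it produces $S$ values far above what typical indoor levels require.
The package implements the raw scale as documented and lets the
generator's calibration (below) absorb the mismatch; users fitting real
data should check whether their $X_2$ warrants a transformed scale.

## The synthetic generator and its calibration

`generator_config()` defines the emulated study: 233 districts in 17
provinces, a stratum mix of 25/35/5/35 % (the other-residence +
groundwater stratum is rare), district GMs log-normal around the national
winter-survey summary (GM 86.52, district-level GSD 1.5), sinusoidal
monthly temperature normals with a January minimum, residual SD 2 on $S$,
and a two-point measurement error GSD of 1.1 per point. The forward model
is the estimation chain run forwards: features → $S$ (linear predictor +
noise) → $\lambda_v$, $C_s$, $C_o$ → steady-state $C_i$ → seasonal
de-annualization → two noisy points.

**Calibration.** The reference coefficients and the per-stratum annual
GM/GSD targets (62.19/1.68, 49.71/1.78, 34.26/1.25, 44.48/1.53 Bq
m$^{-3}$) cannot both hold for arbitrary reference levels — the raw
linear predictor overshoots the concentration scale. The generator
therefore calibrates an *affine* map per stratum,
$S = a + c \cdot (\text{linear predictor}) + \varepsilon$, solving
$(a, c)$ so that the realized sample of annual $C_i$ matches the target GM
and GSD exactly. Two properties make this the right transform: the
calibrated model is still exactly linear in the design (coefficients
$a + c\beta_0, c\beta_1, \dots$, recorded in the truth file), so noiseless
end-to-end identifiability is preserved; and the two knobs map cleanly
onto the two matched moments (location and spread on the log scale). An
intercept shift alone could match the GM but not the GSD. Numerically,
the inner problem (the intercept $a$ given $c$) is solved by `uniroot`
on a domain bounded below by the positivity constraint — as $a$ approaches
the bound, one concentration approaches zero and the log mean diverges to
$-\infty$, so a root always exists; the outer problem ($c$ given the GSD
target) is solved by bisection, with slopes under which the
positivity-constrained intercept can no longer reach the GM treated as
over-dispersed. The spread at $c = 0$ (residual noise plus ventilation
and regional variation) is a floor: for the tightest stratum (GSD target
1.25) the floor sits just below the target at study scale but can exceed
it in small samples, in which case the generator matches the GM only and
warns.

Gross contaminants are planted at $\pm 6$ stratum log-SDs **from the
stratum geometric mean** — the operational meaning of "a 6-SD outlier" —
rather than shifted from each residence's own value, which would leave
residences starting low within the screen's reach.

**What the generator does not emulate.** Real geography (districts are
exchangeable), spatial correlation between neighbouring districts,
within-district heterogeneity of greenery, seasonal interaction between
ventilation habits and weather, detector-specific error structure, and
any misreporting of questionnaire items. Passing tests therefore show the
*estimation chain* is correct and well-calibrated under the model's own
assumptions; they do not show the model fits real residences.

## Validation design and problem sizes

The test battery uses: 10,000 random draws for the inversion identity
(relative error $< 10^{-12}$); 100 random parameter systems integrated to
$10^4$ h against the linear-solve fixed point (rtol $10^{-6}$); 20 seeds
× 500 rows per stratum for coefficient recovery (anchored coefficients
recovered within 3 reported SEs); an 800-residence noiseless study for
end-to-end identifiability (RMSE $< 10^{-8}$ Bq m$^{-3}$ per stratum); a
10,000-residence run for generator calibration (GM/GSD within 5 %); and
10 seeds × 1,500 residences with 3 % planted contaminants for the screen
(≥ 95 % contaminants removed, ≤ 1 % clean removed). At the default noise
the pipeline's predictions attain $R^2 \ge 0.9$ against the planted truth.

## Known limitations

* The physical transfer coefficients ($k_a$, $k_{d,s}$, $k_{d,bm}$,
  $\Delta P_{s-i}$, $E_s$, $E_{bm}$) are exercised only by the dynamic
  simulator; the statistical pipeline never identifies them — the
  inversion eliminates them by construction.
* Ventilation rests on questionnaire-reported habits; the $N$ weights are
  conventions, not measurements.
* The regression is fixed per-stratum OLS: no variable selection,
  regularization or mixed effects, by design.
* Whether outliers should be screened within stratum or pooled is a
  judgement call; the package defaults to within-stratum and exposes the
  choice.

## Dose

For exposure assessment, `annual_effective_dose(Q, F_eq, T_occ, K)`
computes the standard product $E = Q \times F \times T \times K$ of mean
annual concentration, equilibrium factor, annual residential time and the
dose conversion coefficient, e.g.

```{r dose}
annual_effective_dose(Q = 50, F_eq = 0.4, T_occ = 7000, K = 9e-9)  # Sv
```
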