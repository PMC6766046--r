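# radonmbe — mass-balance estimation of mean annual indoor radon

Radon-222 is a radioactive noble gas that seeps from soil and building
materials into homes; chronic indoor exposure is a leading cause of lung
cancer after smoking. Long-term measurement campaigns (alpha-track
detectors over months, two points per residence) are slow and costly, so
exposure assessment at population scale needs a model that predicts the
**mean annual indoor radon concentration** of a residence from things that
are cheap to know: its administrative district, building traits, and
meteorological normals. `radonmbe` is for environmental-health researchers
and radiation-protection practitioners who need such desk-scale estimates,
and for methodologists who want a fully testable implementation of the
underlying deterministic model.

## The model

Indoor radon follows a three-compartment mass balance (indoor air `Ci`,
soil `Cs`, building materials `Cbm`, all Bq m⁻³), with diffusive/advective
transfer from soil scaled by the ground-facing area `Sg/V`, diffusive
transfer from materials scaled by `Sbm/V`, ventilation exchange with
outdoor air `Co`, and radioactive decay `λ = 7.56×10⁻³ h⁻¹`. At steady
state the indoor concentration has the closed form

    Ci = (S + λv·Co − λ·(Cs + Cbm)) / (λ + λv)

where `S = Es·Sg/V + Ebm·Sbm/V` (Bq m⁻³ h⁻¹) is the **infiltration
factor** — the combined radon entry concentration rate — and the
ventilation rate is driven by meteorology and occupant habits:

    λv = (ft·|Ti − To| + fw·u²) · N        [h⁻¹]

The steady state is exactly invertible: a measured annual concentration
yields each residence's infiltration factor,

    S = Ci·(λ + λv) + λ·(Cs + Cbm) − λv·Co ,

and `S` is then modelled by stratum-specific ordinary least squares on the
district greenery ratio (X1), the district indoor-radon geometric mean
(X2) and building traits (material, cracks, floors):

    S_i = β0 + β1·X1_i + β2·X2_i + β3·Y1_i + β4·Y2_i + β5·Y3_i + ε_i

fitted separately in four strata crossing residence type (detached vs
other) with groundwater usage. Regional proxies for `Cs` (district) and
`Co` (province) come from winter-survey geometric-mean ratio weights.
Prediction composes the fitted `S` back through the steady state.

## Worked example

```r
library(radonmbe)

# ventilation rate for a spring month: Ti = 20 C, To = 2.4 C, u = 2.1 m/s
ventilation_rate(ft = 0.03, fw = 0.01, Ti = 20, To = 2.4, u = 2.1, N = 1)
#> [1] 0.5721

# infiltration factor of a measured residence
infiltration_from_measurement(Ci = 58.3, Cs = 95, Co = 9.5, lam_v = 0.57)
#> [1] 28.97    # Bq m-3 h-1 entering indoor air

# a complete synthetic study, inverted, fitted and evaluated
cfg   <- generator_config(n_residences = 2000, seed = 1)
paths <- simulate_to_dir(cfg, "study")
truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
rc  <- run_config(residences = paths["residences"], districts = paths["districts"],
                  meteo = paths["meteo"], survey = paths["survey"],
                  seasonal_factors = unlist(truth$seasonal_factors))
res <- run_pipeline(rc)
res$agreement_ci
#> Agreement of estimated vs measured values
#>  stratum    n  rmse      bias  slope intercept
#>        1  468 7.553 -0.041010 0.9477     3.635
#>        2  697 7.145  0.014260 0.9402     3.423
#>        3   91 6.474  0.018510 0.4286    20.230
#>        4  730 6.787  0.027360 0.8982     4.999
#>      all 1986 7.086  0.006244 0.9384     3.464
```

The agreement table compares measured annual concentrations with the
model's predictions per stratum: RMSE ≈ 7 Bq m⁻³ against typical levels of
40–60 Bq m⁻³, near-unit concordance slopes, and negligible bias — the
estimation chain recovers what the forward model planted, up to the
configured residual and measurement noise. 14 of 2000 records were flagged
by the log-scale outlier screen (|z| > 3 within stratum) before fitting.

A thin shell interface wraps the same functions:

```sh
radon-mbe simulate --config cfg.yaml --out data/
radon-mbe run      --config cfg.yaml --out results/
radon-mbe report   --pred results/predictions.csv
```

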