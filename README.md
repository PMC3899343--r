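# aphidRGR

Modelling the relative growth rate (RGR) of cereal aphid populations on
winter wheat from weekly field counts, daily temperature records and crop
phenology.

## The problem

Forecasting outbreaks of grain aphids (*Sitobion avenae* and relatives)
requires knowing how fast a population is growing *right now* and how
that rate responds to drivers available at forecast time.  The natural
quantity is the instantaneous relative growth rate

RGR(t) = d ln n(t) / dt    [aphids·aphid⁻¹·day⁻¹],

estimated from weekly tiller counts that are dominated by sampling noise.
`aphidRGR` is aimed at quantitative ecologists and crop-protection
modellers and implements the full chain:

1. **RGR estimation** (`estimate_rgr`): counts → ln(n+1) → cubic
   smoothing spline with leave-one-out cross-validated penalty → analytic
   derivative at the sampling dates.
2. **Response surface** (`rgr_surface`): a four-parameter nonlinear model
   of RGR as a function of mean temperature θ and Zadoks wheat stage s,

   f(θ, s) = a·θᵇ·(θmax − θ)/θmax · [1 + e^{−k(s − s_m)}]⁻¹ · [1 − e^{−(smax−s)/τ}],

   with a lethal temperature maximum (θmax = 30 °C), a terminal stage
   (smax = 92, grain ripening), a sigmoidal stage response inflecting at
   s_m and a sharp right-edge collapse (τ = 2 Zadoks units, fixed).
   An optional linear extension adds natural-enemy pressure terms
   (fungus-killed aphids and parasitoid mummies).
3. **Fitting** (`fit_rgr_model`): Gauss-Newton ordinary least squares
   with step-halving, bound handling by ratio test, multi-start
   initialisation, asymptotic standard errors and parameter
   correlations; Levenberg-Marquardt fallback.
4. **Validation** (`validate_predictions`, `anova_table`,
   `durbin_watson`, `bisector_r2`, `origin_regression`,
   `sign_error_matrix`): ANOVA partition with F test, Durbin-Watson
   autocorrelation screening, bisector and origin-constrained R²,
   residual summaries and sign-error matrices on held-out data.
5. **Synthetic surveys** (`simulate_fields`): seasonal AR(1) weather,
   degree-day Zadoks phenology, latent population dynamics driven by the
   RGR surface, and overdispersed (negative-binomial) count observation —
   so the whole pipeline is testable end to end without field data.

See the methods vignette (`vignettes/aphid-rgr-methods.Rmd`) for the
model assumptions, parameter meanings and numerical design choices.

## Worked example

Simulate a 15-field training study and a 9-field held-out study, estimate
RGR, fit the surface and validate:

```r
library(aphidRGR)

study <- simulate_fields(sim_config(), n_fields = 15, seed = 1)
rgr   <- lapply(study$surveys, estimate_rgr)
data  <- build_dataset(study$surveys, rgr, study$weather)
fit   <- fit_rgr_model(data)
fit
#> Nonlinear RGR surface fit (gn): n = 165, p = 4, SSE = 0.9749, converged in 40 iterations
#>              s_m      b      k         a
#> estimate  42.200 2.3140 0.3013 0.0003824
#> std_error  2.845 0.9934 0.1971 0.0010900

anova_table(data$rgr_obs, fit$fitted, fit$p)
#>  Source      SS  df         MS    F     P-value
#>   Total 1.42000 164 0.00865878
#>   Model 0.34143   4 0.08535710 14.1 6.96522e-10
#>   Error 0.97495 161 0.00605557

durbin_watson(fit$residuals, groups = data$field_id)
#> Durbin-Watson DW = 1.559  one-sided P(positive autocorrelation) = 0.00233 (normal approximation, n = 165)

heldout <- simulate_fields(sim_config(), n_fields = 9, seed = 1001)
rgr_h   <- lapply(heldout$surveys, estimate_rgr)
data_h  <- build_dataset(heldout$surveys, rgr_h, heldout$weather)
validate_predictions(data_h$rgr_obs, predict_dataset(fit$params, data_h))
#> Validation on 99 held-out cases
#>   bisector R2        40.14%
#>   origin slope / R2  0.952 / 40.59%
#>   residual mean/median/skewness  -0.003991 / -0.003844 / 0.0809
#>           predicted
#> observed   positive negative
#>   positive       86        0
#>   negative       13        0
#> 13 sign errors of 99 cases (13.13%)
```

Reading the output: the surface captures ~24% of the training RGR
variance (Model/Total SS) and is highly significant despite the noise
(F = 14.1); the Durbin-Watson statistic below 2 flags the expected
positive within-field autocorrelation of weekly series; on held-out
seasons the bisector R² is 40% with an origin slope near 1 (little bias)
and 13% of cases predicted in the wrong direction.  Note the strong
a–b correlation in `param_correlations(fit)` (here −1.00 to two
decimals): scale and exponent of the thermal power law are nearly
exchangeable over a narrow temperature window, so interpret the fitted
surface, not the individual pair.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/aphidrgr.R simulate --out-dir train --seed 1
Rscript inst/cli/aphidrgr.R fit --survey train/surveys.csv \
        --weather train/weather.csv --out fit.json
Rscript inst/cli/aphidrgr.R validate --fit fit.json \
        --survey test/surveys.csv --weather test/weather.csv --out val.json
```

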