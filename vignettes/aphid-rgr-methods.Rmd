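---
title: "Modelling aphid relative growth rate from field counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aphid relative growth rate from field counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidRGR)
```

## The problem

Cereal aphids such as the grain aphid *Sitobion avenae* are counted weekly
on winter wheat tillers from stem extension (Zadoks stage ~30, early May)
to grain ripening (stage ~92, mid-July).  The quantity of epidemiological
interest is not the count itself but the instantaneous **relative growth
rate** (RGR) of the population,

$$\mathrm{RGR}(t) = \frac{d\,\ln n(t)}{dt} \quad [\text{aphids aphid}^{-1}
\text{day}^{-1}],$$

which integrates reproduction, development, mortality and migration, and
which responds strongly to two drivers observable at forecast time: mean
air temperature and the phenological stage of the host crop.  `aphidRGR`
implements the full chain: estimating RGR from noisy weekly counts,
regressing it on temperature and stage with a mechanistically shaped
nonlinear surface, validating the fitted surface on held-out seasons, and
simulating realistic synthetic surveys so that every stage of the chain
is testable without access to historical field data.

## Estimating RGR: spline logarithmic derivatives

Weekly counts are extremely noisy (sampling error dominates), and naive
first differences of $\ln n$ amplify that noise.  `estimate_rgr()`
therefore proceeds in three steps:

1. transform counts to $\ln(n + 1)$ — the shift keeps zero counts at the
   season edges defined, and those zeros are retained, never trimmed;
2. smooth the log series with a penalized cubic smoothing spline
   (`stats::smooth.spline` is the engine), with the penalty chosen by
   **leave-one-out cross-validation**: the LOO prediction squared error is
   scanned on a 50-point grid of `spar` values, equally spaced in `spar`
   (log-spaced in the penalty $\lambda$) from the near-interpolation to
   the near-linear regime, and the grid optimum is refined by
   golden-section search between its neighbouring grid points.  LOO and
   generalized cross-validation are both standard here; we use ordinary
   LOO and minimise prediction squared error (formulations that
   "maximise" a CV function differ only in sign convention).  A boundary
   optimum raises a warning rather than failing;
3. evaluate the **analytic derivative** of the fitted piecewise cubic at
   the sampling dates (via its B-spline representation, not finite
   differences).

Because straight lines lie in the null space of the roughness penalty,
data that are exactly log-linear return exactly their slope for any
penalty — a useful exactness property that the test suite asserts to
machine precision.  On a noiseless weekly exponential with $r = 0.1$/day
the interior estimates are within about 1% of the truth; the residual
bias comes from count rounding and the $+1$ shift.

Each field-year is smoothed independently (no pooling), and the
derivative is reported at observation times; a dense daily grid is
available for plotting only.  Counts can be smoothed as totals over the
inspected tillers (default; the natural scale of the counting noise) or
as per-tiller densities (useful when sampling effort varies strongly
between dates) — with the season-long transform $\ln(x+1)$ the two
differ, so the choice is explicit and recorded in the output.

## The response surface

`rgr_surface()` models the deterministic RGR response to weekly mean
temperature $\theta$ (°C) and Zadoks stage $s$ as

$$f(\theta, s) = a\,\theta^{b}\,\frac{\theta_{\max}-\theta}{\theta_{\max}}
  \cdot \frac{1}{1+e^{-k (s - s_m)}}
  \cdot \left(1 - e^{-(s_{\max}-s)/\tau}\right),$$

with $f = 0$ outside $0 < \theta < \theta_{\max}$, $0 \le s < s_{\max}$.
The factors encode the field-established shape constraints:

* the temperature response rises like a power law and is pulled down
  linearly towards a **lethal maximum** $\theta_{\max} = 30$ °C, giving a
  single interior optimum at $\theta^* = b\,\theta_{\max}/(b+1)$;
* the stage response is **sigmoidal on the left** with inflexion at
  $s_m$ (crop colonisation and improving host quality up to heading) and
  **collapses on the right** as the crop approaches $s_{\max} = 92$
  (grain ripening: reproductive shutdown and emigration as nutrient
  quality falls).

Two constants are fixed before fitting ($\theta_{\max} = 30$,
$s_{\max} = 92$); four parameters are free ($s_m$, $a$, $b$, $k$).
$\tau$ (2 Zadoks units) sets how sharply the right edge falls; it is a
fixed numerical constant, not a fitted parameter, so the free-parameter
count stays at four.  Values at and beyond the lethal/terminal boundaries
are defined as 0 rather than negative: the data carry no information
there (no field season in these datasets recorded mean daily temperatures
above ~22 °C), and a bounded surface keeps the latent population
integration well-posed.  The declining branch above 22 °C is therefore
implemented but untestable against data by construction.

Natural-enemy pressure enters linearly (`rgr_with_enemies()`):
$f(\theta, s) + c_E E + c_M M$, where $E$ counts fungus-killed aphid
cadavers (Entomophthorales) and $M$ parasitoid mummies in the same
sample.

## Fitting

`fit_rgr_model()` minimises $\sum_i (\mathrm{RGR}_i - f(\theta_i, s_i))^2$
by **Gauss-Newton with step-halving**, the classical method for this kind
of nonlinear least squares.  Design choices that matter:

* the Jacobian is a central finite difference (relative step $10^{-6}$);
* bounds ($0 < s_m < s_{\max}$, $a \ge 0$, $b, k > 0$) are enforced by a
  ratio test: a step is capped at the first bound crossing and
  components pushing outward at an active bound are frozen, which avoids
  the catastrophic "clamp through the bound" accepted steps that a naive
  projection produces;
* convergence when the relative objective decrease falls below $10^{-8}$
  (maximum 200 iterations); non-convergence sets a flag, never throws;
* the objective is **multimodal**: with a narrow realized temperature
  window, a degenerate temperature-flat fit can compete with the true
  basin.  With no user start, the fitter therefore runs from a small
  start grid — $s_m$ at the 25/50/75% stage quantiles, $k \in \{0.3,
  0.7\}$, $b \in \{0.3, 1\}$, with $a$ scaled so the surface maximum
  matches the 95th percentile of observed RGR — and keeps the best
  optimum.  A Levenberg-Marquardt fallback (`method = "lm"`, via
  `minpack.lm`) is available for data where Gauss-Newton stalls;
* records are treated as independent in the objective; the
  Durbin-Watson statistic quantifies (but does not correct) the residual
  autocorrelation that weekly series within a field necessarily carry.

Asymptotic standard errors and parameter correlations come from the
inverse cross-product of the final Jacobian.  The $a$–$b$ pair is always
strongly correlated (often $|r| > 0.95$) because scale and exponent of a
power law are nearly exchangeable over a narrow thermal window — a
structural feature of the model on field designs, reported, not hidden.
A numerically singular Jacobian is reported with the offending parameter
pair.  In simulation at $\sigma = 0.03$ RGR noise, truth is covered by
$\pm 2$ standard errors in roughly 95% of replicates, but these
asymptotics are approximate for nonlinear fits and residual
autocorrelation inflates $F$ statistics; both caveats apply equally to
real data.

## Validation diagnostics

The validation toolkit judges predictions **as-is**, without refitting:

* `anova_table()` partitions sums of squares about the observed mean;
  for a nonlinear model the three sums need not be additive and are never
  reconciled.  `model_r2()` is $SS_{model}/SS_{total}$, reported in
  percent;
* `bisector_r2()` takes residuals from the line observed = predicted:
  $R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2$, with the same
  $N-1$ correction in numerator and denominator (no parameters are
  estimated from validation data, so the correction cancels; perfect
  prediction gives exactly 1, the mean gives 0, worse-than-mean goes
  negative);
* `origin_regression()` reports the slope of observed on predicted
  through the origin (near 1 = unbiased);
* `durbin_watson()` computes
  $\sum_{i\ge2}(e_i-e_{i-1})^2/\sum e_i^2$ with differences taken within
  fields only (no artificial jump terms across field boundaries).  The
  one-sided p-value uses the large-sample normal approximation
  $DW \sim N(2, 4/n)$ and is flagged approximate — it is a screening
  device, not an exact Durbin-Watson bound;
* `sign_error_matrix()` cross-classifies the sign of observed and
  predicted RGR; exact zeros count as positive by default (a flat
  population is not a decline; the convention is configurable);
* `residual_summary()` reports mean, median and adjusted Fisher-Pearson
  skewness.

## The synthetic study generator

No historical survey data ship with the package, so `simulate_fields()`
generates field-years with the statistical structure the analysis
assumes:

* **weather**: daily mean temperature = sinusoidal seasonal curve
  (annual mean 11 °C, amplitude 7.5 °C, peak near day 200 — a temperate
  western European profile) plus stationary AR(1) anomalies (sd 1.5 °C,
  lag-1 correlation 0.6), capped at 22 °C so simulated spring/summer
  means respect the warmest means such climates record; min/max offset
  symmetrically by ±5 °C;
* **phenology**: Zadoks stage advances by accumulated degree-days above
  0 °C at 20.2 °C·day per stage unit, calibrated so the noise-free
  default season runs from stage 30 on 1 May to ~91.2 by 15 July
  (grain ripening).  Driving phenology with the same temperatures that
  drive growth reproduces the diagonal temperature-stage confounding of
  real seasons.  Realized seasons spread around stage 91 by roughly
  ±1.3 stages because weather anomalies accumulate in thermal time;
* **latent population**: daily Euler integration of
  $N_{t+1} = N_t(1 + f(\theta_t, s_t))$ from 0.05 aphids/tiller.  The
  default true surface ($s_m = 45$, $a = 0.01$, $b = 1.2$, $k = 0.35$)
  gives a maximum RGR of ~0.13/day, season-mean observed RGR near 0.08
  and outbreak peaks of 20–30 aphids per tiller — the magnitudes regional
  survey programmes report.  At weekly observation spacing the Euler
  discretisation error is negligible against sampling noise.
  Immigration and emigration are not modelled separately; the surface
  absorbs them;
* **observation**: total counts over the inspected tillers (200 by
  default, within the 50–1000 operational range) are negative-binomial
  with mean density × tillers and dispersion (`size`) 10; `Inf` gives
  the Poisson limit.  Optional enemy counts are drawn the same way with
  means proportional to the aphid mean.  Dispersion 10 was chosen once
  so that the fitted surface explains roughly a quarter to a half of the
  estimated-RGR variance — the range regional field datasets exhibit —
  and is not adjusted per analysis.

What the generator deliberately does **not** emulate: spatially explicit
dynamics, explicit predator-prey feedback beyond the linear enemy terms,
autumn/winter dynamics, observer-dependent staging error, and
year-to-year variation in the true surface.  Passing tests on synthetic
data therefore demonstrate that the estimation chain is correct and
well-calibrated under the model's own assumptions, not that the model is
a complete description of any particular field system.

## Numerical and interface choices

* Internal time is days since the first sampling date of each field;
  dates are ISO-8601 throughout; CSVs are comma-separated UTF-8 with a
  mandatory header and a leading `#` metadata line carrying the package
  version, seed and a config fingerprint, so identical config + seed
  give byte-identical artifacts.
* Weekly temperature covariates are trailing 7-day means ending at the
  sampling date; windows with fewer than 7 available days use the days
  present (with a warning), and dates with no coverage are dropped with
  a logged count.
* Records pooled across fields are sorted by field then date, so fits
  are invariant to input order.  Fields are pooled unweighted into one
  regression.
* Degenerate inputs have defined behaviour: constant log-series give a
  zero derivative; an exact fit reports $F = \infty$ with a flag; an
  all-constant observed vector is rejected by `bisector_r2()`.

## Problem sizes used in the tests

The test-suite and the acceptance script run a 15-field training study
plus a 9-field held-out study (about 165 and 99 records — the scale of
the larger regional dataset), 50-replicate parameter-recovery
simulations at $n = 160$, and a 100-replicate coverage simulation; all
of this completes in well under a minute on one core.

## Known limitations

* The spline RGR estimator is biased at the season edges (derivative of
  a smoother at boundary knots); interior dates are the reliable ones.
* The surface's high-temperature branch is unconstrained by data below
  the lethal maximum minus ~8 °C.
* OLS ignores within-field autocorrelation; standard errors are
  optimistic (the Durbin-Watson output quantifies by how much the
  independence assumption is violated).
* The $a$–$b$ collinearity means individual values of $a$ and $b$ are
  poorly determined even when the fitted surface itself is stable;
  interpret the surface, not the raw pair.
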