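---
title: "Methods: exposure metrics, the count model, and the synthetic city"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure metrics, the count model, and the synthetic city}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Heat-mortality time-series studies must choose an exposure variable before
fitting anything: daily maximum temperature? minimum? a mean — and which
mean? the temperature at a fixed clock hour? Each choice samples the
diurnal temperature curve differently, and the choice is rarely examined.
`heatclock` makes the choice itself the object of study: it builds **31
daily exposure variables** from one station's sub-hourly record — the 24
top-of-hour snapshots `t00` … `t23` plus seven daily summaries — crosses
them with **lags 0–3** (exposure on the day of death through three days
before), fits one count-regression model per cell, and summarises each of
the 124 cells by a percentile-contrast relative risk.

## From raw observations to daily metrics

Raw records are timestamped temperatures at sub-hourly cadence (historical
archives range from 1 to 4+ observations per hour). Ingest converts
declared Fahrenheit to Celsius (a single internal unit avoids silent
mixing) and rejects duplicate or unparseable timestamps with line numbers.

*Missing values.* Isolated gaps — the dominant failure mode of station
archives, typically no more than a few percent of records — are filled by
linear interpolation in time between the nearest non-missing neighbours;
missing values at the series boundary are filled with the nearest value
(the conservative extension of a rule defined only for interior gaps).
Filled records stay flagged, and per-day counts are reported. A day with
any *unrecoverable* hour (no observation within the snapshot window) is
excluded from modelling rather than partially imputed.

*Day boundary and clock.* Days run midnight-to-midnight in local standard
time year-round; daylight-saving shifts are ignored by construction
(internally a fixed-offset timezone), so `t15` always means the same solar
clock hour.

*Snapshots.* For each hour *h*, the observation minimising
|timestamp − *h*:00| within a symmetric ±30-minute window is selected;
exact ties resolve to the earlier observation. The window and tie-break
are implementation choices — the underlying convention is only "nearest
the top of the hour" — chosen to be symmetric and unambiguous.

*The seven summaries.* `max` and `min` are the extremes over **all**
observations of the day, as a max/min thermometer would record them (free
to occur at any time, e.g. 1615 and 0515); `max_hr`/`min_hr` are the
extremes over only the 24 snapshots, so `min ≤ min_hr ≤ max_hr ≤ max`
always. Three mean formulations follow: `mean = (max+min)/2`,
`mean_hr = (max_hr+min_hr)/2`, and `mean24`, the average of the 24
snapshots. On days whose true extremes fall between snapshots the three
means genuinely differ — which is precisely why the formulations are
compared.

## The count model

Each cell's model for daily deaths $M_t$ is

$$\log E(M_t) = s_{\text{time}}(t;\,k_{\text{time}}) +
               s_{\text{temp}}(x_{t-\ell};\,k_{\text{temp}}),$$

with a quasi-Poisson variance $\mathrm{Var}(M_t) = \varphi\, E(M_t)$. The
time smooth (basis dimension $k_{\text{time}} = y \times a$, with $y$ the
number of years and $a = 7$ df/year in the main analysis, $a = 5$ as a
sensitivity setting) absorbs long-term trends and seasonality in
mortality; the temperature smooth is deliberately small
($k_{\text{temp}} = 4$) so the exposure-response is flexible but not
wiggly. Both smooths are **fixed-df regression splines**: no penalty, so
the model degrees of freedom are exactly
$1 + (k_{\text{time}}-1) + (k_{\text{temp}}-1)$ after each smooth's
constant direction is absorbed by the intercept.

*Basis realisation.* `spline_basis(x, k)` returns a cubic regression
spline: a B-spline basis of degree $\min(3, k-1)$ with $k-1-\text{degree}$
interior knots at quantiles of the data. With $k=2$ it degenerates to
$[1, x]$, so the model collapses to ordinary log-linear Poisson
regression (a nested-equivalence used heavily in the tests); with $k=4$
it spans all cubic polynomials. A low-rank thin-plate eigenbasis would be
an equally valid realisation of the same contract; at fixed df the
practical difference is negligible, and the polynomial-spline realisation
has exactly representable low-order behaviour, which makes the engine
testable against closed forms.

*Fitting.* Iteratively reweighted least squares (Fisher scoring for the
Poisson log-link), converging when the relative deviance change falls
below $10^{-9}$ (at most 50 iterations, with step-halving on any deviance
increase). Point estimates are the Poisson ML estimates; the
quasi-likelihood enters through the Pearson dispersion
$\hat\varphi = \sum (y_i-\hat\mu_i)^2/\hat\mu_i \,/\, (n-\text{edf})$,
which scales the coefficient covariance
$\hat\varphi\,(X^\top W X)^{-1}$. Rank-deficient designs and
non-convergence are flagged, and the grid runner records and skips such
cells (aborting only if more than 10% of cells fail).

*Diagnostics.* Each fit carries the generalized cross-validation score
$\mathrm{GCV} = n D/(n-\text{edf})^2$ with $D$ the quasi-deviance — the
conventional diagnostic form for an unpenalised quasi-likelihood fit.
Scores are comparable across cells of one analysis (same response), but
absolute values are specific to this implementation's deviance and df
conventions.

## The percentile-contrast relative risk

For each exposure variable, percentiles are empirical quantiles (linear
interpolation of order statistics, the ubiquitous type-7 convention) of
the variable's **year-round** daily values, pooled over all study years —
not summer-only. The 85th annual percentile corresponds to roughly the
55th hottest day of an average year, i.e. a typical summer day, which is
what makes it a sensible baseline. The cell's summary is

$$\mathrm{RR} = e^{m_{99} - m_{85}},\qquad
\mathrm{CI} = \exp\!\Big[(m_{99}-m_{85}) \pm
1.96\sqrt{se_{99}^2 + se_{85}^2}\Big],$$

where $m_p$ and $se_p$ are the fitted temperature-term contribution and
its delta-method standard error at the variable's $p$-th percentile. The
two standard errors are combined **in quadrature, deliberately ignoring
their covariance** — this is the conventional reporting formula, and the
package implements it verbatim as the default. Because the two term
predictions are positively correlated, the quadrature interval is
conservative (somewhat wide); a covariance-aware interval is available
behind `use_covariance = TRUE` for comparison. A subtlety worth knowing:
the point estimate and the covariance-aware CI are invariant to the
smooth's centering constant, but the quadrature CI is not — the package
uses the standard sum-to-zero (data-mean) centering, so its point-wise
standard errors match the convention used by mainstream GAM software.
Significance is declared when the CI excludes 1; **no multiple-testing
adjustment is applied across the 124 cells**, so under a null city about
5% of cells are expected to be "significant", and the cells are strongly
correlated.

Cells whose 99th and baseline percentiles coincide (degenerate exposure
distributions) are excluded with a reason rather than reported as RR 1.
The 90th-percentile baseline is a sensitivity switch: it shortens the
contrast interval, so effect estimates shrink toward the null.

Ranking is by RR descending with ties broken by lower GCV; the
minimum-GCV cell is reported separately because the best-fitting model
and the largest contrast need not coincide — RR uses only two points of
the exposure distribution while GCV integrates fit over all of it.

## The synthetic city

Health-department mortality records are not publicly deposited, so the
package validates itself on a generative stand-in with a known truth.
None of the following distributions describe any real city's data-
generating process; they are designed so that every downstream stage has
a recoverable ground truth with realistic correlation structure.

Temperature at each timestamp is a sum of:

* an annual sinusoid (mean 12 °C, half-range 8 °C, peak near 20 July) —
  a mid-latitude city of moderate seasonal range;
* a diurnal sinusoid (half-range 4 °C, peak 1600 LST, minimum in the
  early morning);
* a day-level AR(1) anomaly (stationary sd 3.5 °C, day-to-day
  autocorrelation 0.7) — synoptic-scale weather;
* an hour-level AR(1) anomaly (stationary sd 2.5 °C, e-folding time 6 h)
  — within-day weather such as frontal passages and cloud cover. Without
  this component all 24 hourly variables would be deterministic functions
  of one daily state and the hour-resolved analysis would be degenerate;
* heat-wave episodes (Poisson count, mean 3 per May–September; geometric
  duration, mean 3 days; +5 °C on affected days) — the multi-day
  autocorrelated extremes that the lag analysis needs;
* independent observation noise (sd 0.3 °C).

The anomaly and heat-wave scales were fixed once by matching the
generator's summer and extreme-day correlation structure to published
multi-city averages for station data (noon vs. 1800 LST temperature
correlation ≈ 0.83 over the full summer, dropping to ≈ 0.6 on extreme
days); the synthetic city reproduces that pair well. Its `max`–`min`
correlation stays higher than real cities show (≈ 0.8 vs ≈ 0.7), because
the generator's daily extremes share the full day-level anomaly — a known
gap between the stand-in and real diurnal asymmetry.

Daily deaths are drawn from a gamma-Poisson mixture with
$\mathrm{Var} = \varphi\,\mu$ ($\varphi = 1.3$ by default, i.e. mild
overdispersion; plain Poisson at $\varphi = 1$), baseline 40 deaths/day
(the scale of a metropolitan area of one to three million), a
winter-peaking seasonal modulation of relative amplitude 0.1, and an
injected temperature effect

$$f_{\text{true}}(x) = \beta \max(0,\, x - q_{0.85}(x)),$$

a hockey-stick on the effect-carrying variable's own scale (default:
`t15` at lag 0, slope 0.0064 per °C — sized so the true 99th-vs-85th
percentile relative risk is about 1.05). The truth ledger records
$\Delta^\ast = f_{\text{true}}(q_{99}) - f_{\text{true}}(q_{85})$
computed from the realized exposure quantiles, and
$\mathrm{RR}^\ast = e^{\Delta^\ast}$ — the exact analogue of the
estimated contrast. The hockey-stick is chosen because its truth is
computable in closed form while remaining approximable by a small
smooth.

One master seed drives everything; per-component child seeds (temperature
= 1, missing injection = 2, mortality = 3) are derived by fixed offsets
so each component is individually reproducible, and all generator
functions restore the caller's RNG state.

**What the generator does not emulate** — and hence what passing
recovery tests cannot certify about real data: humidity and apparent
temperature; multiple stations or spatial structure within the city;
demographic strata; reporting errors in the date of death;
daylight-saving clock politics; long-term climate or population trends
beyond the smooth seasonal modulation; and the asymmetric diurnal curve
of real stations (the generator's diurnal march is sinusoidal, so its
minimum falls near 0400 rather than the observed skew toward dawn).

## Validation studies and their problem sizes

The test suite validates the engine against independent oracles (an
independent quasi-Poisson implementation on the identical design, a
generic BFGS maximization of the Poisson likelihood, hand-computed
interpolated quantiles, hand Pearson correlations, a parametric bootstrap
of the contrast CI) and then runs replicate recovery studies:
50 replicate 10-year synthetic cities with the injected effect and 50
null replicates, each analysed over the full 124-cell grid at 5 df/year
(the sensitivity df setting; it halves the cost of 12,400 model fits
relative to 7 df/year, and the df choice moves estimates only slightly).
`recovery_study()` reports, per replicate, the effect-cell estimate and
CI against the truth, the top-ranked cell, the significant-cell fraction,
the 90th-baseline contrast from the same fit, and the summer vs.
extreme-day correlation directions.

Two behaviours observed in these studies deserve explicit mention as
limitations rather than bugs:

* **Attenuation.** The $k=4$ smooth under-reads a hockey-stick contrast
  slightly (the kink is smoothed), and whatever part of the effect
  variable's above-threshold variation is seasonal gets absorbed by the
  time smooth. With the episodic-heat generator the two together cost
  roughly 20% of the log-contrast on average, which is visible as
  coverage on the conservative side of the quadrature CI.
* **Argmax instability.** Neighbouring cells are strongly correlated
  (that is the point of the diagnostic), so the *identity* of the single
  top-ranked cell is a noisy statistic at realistic effect sizes
  (RR ≈ 1.05 over ten years): the top cell usually lies at the true lag
  and often near the true hour, but single-cell argmax should not be
  over-interpreted — in real analyses the hour-by-lag *pattern*, not the
  argmax, is the result. The replicate study quantifies exactly how
  often the argmax localises.

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere (quantile definition is not standardised
  in the field; alternatives differ negligibly at thousands of days).
* IRLS start: $\mu^{(0)} = y + 0.5$; convergence on relative deviance
  change $< 10^{-9}$; at most 50 iterations; step-halving on deviance
  increase.
* `years` for $k_{\text{time}}$ defaults to `round(n_days / 365.25)`.
* Ties in snapshot selection: earlier observation wins; the window is
  ±30 minutes inclusive.
* Exposure values at temperatures outside the fitted range trigger an
  extrapolation warning but are still computed (B-spline columns vanish
  outside the boundary knots, so genuine extrapolation is meaningless —
  percentile contrasts, always interior, are unaffected).
* Degenerate days (constant temperature) are legal; degenerate
  percentile sets are excluded from RR computation with a reason.
* Counts are validated non-negative and finite; an all-missing series is
  an error, not an empty result.
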