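---
title: "Grey forecasting with metabolic rolling windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey forecasting with metabolic rolling windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyroll)
```

## The problem

Annual accident-fatality records — construction deaths, traffic deaths —
are short (ten to twenty points), strictly positive, and driven by
slowly changing regimes: a long decline as safety regulation bites,
then a renewed rise as construction volume outgrows enforcement. Grey
system models were designed for exactly this "small data, incomplete
information" setting: they model the *accumulated* series, which is
smoother than the raw counts, with a first-order linear dynamic, and
need only a handful of observations per fit.

`greyroll` implements the nonhomogeneous member of this family and the
machinery that turns it (or any of its classical relatives) into a
dynamic, rolling-window forecaster with data-driven window-size
selection.

## The model family

Write $x^{(0)}(t)$, $t = 1,\dots,n$ for the observed series and
$x^{(1)}(k) = \sum_{i\le k} x^{(0)}(i)$ for its first-order
accumulation (1-AGO). All five models share the fit → simulate →
extrapolate contract; they differ in the scale they model and the
dynamic they assume.

**DNGM(1,1)** (discrete nonhomogeneous grey model) starts from the
whitening equation

$$\frac{dx^{(1)}}{dt} + A\,x^{(1)} = B\,t + C,$$

whose solution, anchored at the initial condition $x^{(1)}(1)$, is the
time response

$$x^{(1)}(t) = K e^{-A(t-1)} + \frac{B}{A}t - \frac{B}{A^2} + \frac{C}{A},
  \qquad K = x^{(1)}(1) - \frac{B}{A} + \frac{B}{A^2} - \frac{C}{A}.$$

Differencing gives the original-scale restoration
$\hat x^{(0)}(t) = (1-e^{A})K e^{-A(t-1)} + B/A$ for $t \ge 2$: a
constant plus a decaying (or growing) exponential. The exact discrete
counterpart of the whitening equation is the recursion

$$x^{(1)}(t+1) = \alpha\,x^{(1)}(t) + \beta\,t + \gamma,
  \qquad \alpha = e^{-A},\;
  \beta = \tfrac{B}{A}(1-e^{-A}),\;
  \gamma = (1-e^{-A})\!\left(\tfrac{C}{A}-\tfrac{B}{A^2}\right)+\tfrac{B}{A},$$

and estimation works on this recursion directly: the $n-1$ stacked
equations (the drift regressor is the *source* index $t$) are solved by
least squares for $(\alpha,\beta,\gamma)$, avoiding the discretisation
error that plagues estimating $(A,B,C)$ through the differential
equation. When $\alpha > 0$ and $\alpha \ne 1$ the continuous
parameters are recovered by the inverse mapping ($A = -\ln\alpha$,
...); otherwise the recursion alone is used for prediction, which is
always sufficient — `dngm_time_response()` and `dngm_restore()` then
refuse with a pointer to `simulate_static()`.

**GM(1,1)** is the classical homogeneous model: least squares on
$x^{(0)}(k) = -a\,z^{(1)}(k) + b$ with trapezoidal background values
$z^{(1)}(k) = \tfrac12(x^{(1)}(k)+x^{(1)}(k-1))$, exponential time
response, restoration by differencing. Its construction mixes a
continuous solution with a discrete estimate, which leaves a structural
bias: on an exactly geometric series with ratio $r$ it estimates
$\hat a = 2(1-r)/(1+r) = 2\tanh(a/2) \ne a$ and restores ratio
$e^{-\hat a} \ne r$. The package's tests assert this bias (restored
$0.9732$ where the datum is $1$); it is the reason the *discrete* models
exist, and the reason GM's parameter recovery and its restoration
accuracy cannot both be exact on the same data.

**DGM(1,1)**: least squares on $x^{(1)}(k+1) = \beta_1 x^{(1)}(k) +
\beta_2$; exact on geometric sequences and on constant series (whose
accumulation is arithmetic).

**IDGM(1,1)** and **DDGM(1,1)** are reconstructed from one-sentence
literature descriptions — no canonical printed equations exist — and the
forms chosen here are the plain ones: IDGM treats $x^{(1)}$ as the raw
data, accumulates again to $x^{(2)}$, fits the DGM recursion there and
restores twice (each difference pass anchored at its first observed
element); DDGM fits $x^{(0)}(k+1) = \beta_1 x^{(0)}(k) + \beta_2$ on the
raw scale with no accumulation, and consequently needs only 3 points
where the others need 4. A consequence of the IDGM construction worth
knowing: the doubly accumulated sequence of a *constant* series is
quadratic in $k$, which a first-order linear recursion cannot
interpolate, so IDGM has no exact fit on constants — its exactness
class is data whose $x^{(2)}$ follows its recursion.

## Metabolism: from static to dynamic

A static fit uses one window and extrapolates ever further from it; on
a series with a regime change it keeps predicting the old regime. The
metabolic scheme refits before every forecast: to predict index $t$,
fit on the $n$ most recent *actual* observations $t-n,\dots,t-1$,
forecast one step, slide the window, repeat. Rolling GM(1,1) is
MGM(1,1); rolling DNGM(1,1) is DNMGM(1,1). During retrospective
evaluation windows never contain earlier forecasts — predictions enter
windows only in `roll_extrapolate()`, which necessarily feeds on its
own output beyond the last observation, and says so in its contract.

The window size $n$ trades bias against variance. At the model minimum
($n = 4$ for DNGM: three equations, three unknowns) every window is
interpolated exactly, so the fit chases noise and one-step errors can
explode; large $n$ degrades toward the static model.
`optimize_window()` sweeps candidates (default 4–10, the conventional
range for short annual series), skipping infeasible sizes with a
warning rather than failing, and picks the minimum-MAPE size. MAPEs
within $10^{-9}$ percentage points are treated as tied — on an exact
process every candidate is correct to rounding and the tie rule
(smallest size wins, `ties_broken` set) would otherwise never engage —
and ties go to the smallest size because it uses the least data for
the same measured accuracy.

## Evaluation conventions

MAPE, $100 \times \mathrm{mean}(|\hat x - x|/x)$, is the single
ranking index. Two conventions matter and are embedded in every
report, because they are the main source of irreproducible MAPE
figures in this literature:

* static fits are scored in-sample over $t = 2..n$ — index 1 is
  anchored to the observation by construction and would deflate the
  average;
* rolling forecasts are scored over $t = n+1..n_{obs}$ — the first $n$
  indices are in-window, not forecast, and are reported as such.

Comparing the two therefore compares an in-sample error with a
genuinely out-of-sample one; the comparison is honest about the
dynamic models and flattering to the static ones.

## The synthetic generator

Real yearbook fatality series are not bundled; `generate_series()`
produces the regimes the models assume, so every pipeline stage is
testable offline:

* `exact_dngm` — the constant-plus-exponential family the DNGM
  restoration produces, parametrised by $(A, B, C, x^{(1)}(1))$ or,
  more readably, by `dngm_shape(first, level, rate)`;
* `exact_geometric` — the DGM/DDGM exactness class;
* `noisy_dngm` — multiplicative Gaussian noise, $x \cdot (1 +
  \varepsilon_t)$, $\varepsilon_t \sim N(0, \sigma)$, floored at
  $10^{-6}$: counts vary proportionally to level and stay positive,
  which an additive model would not guarantee. No published noise
  model exists for these series; this is the package's choice.
* `break_series` — two exact DNGM regimes concatenated at a break
  index, regime time restarting after the break.

Seeds are mandatory for noisy processes, never wall-clock derived, and
generation restores the caller's RNG state.

Two presets fix the study conditions used throughout the tests.
`fig2-like` (length 20, seed 4202, noise sd 0.03) emulates two decades
of construction-fatality counts: 14 periods declining from about 2800
toward a floor of 1500 (rate 0.18), then a gradual 6-period recovery
from about 1610 toward 2600 (rate 0.18). The level is continuous at
the break — the process parameters change, the level does not jump —
because annual records turn, they do not teleport; an earlier design
with a level jump at the break mostly measured rolling models'
whiplash on a discontinuity no real series has. The 3% noise reflects
how smooth national annual counts are. `table1-like` (length 10, seed
1001, noise sd 0.06, first 110 decaying toward 60 at rate 0.25) is
sized so that window candidates 4–9 are feasible and 10 is not,
exercising the skip path of the sweep.

What passing tests on these presets do *not* show: real series have
reporting artefacts, policy shocks and non-Gaussian jumps that no
preset emulates, and a single synthetic series at a fixed seed cannot
establish that one model *generally* beats another — only that the
mechanics behave as specified under the stated conditions.

## Numerical choices

* Estimation uses QR least squares; Cramer's rule on the normal
  equations — the historical presentation of these estimators — gives
  the same answer on well-posed systems and lives in the test suite as
  an independent oracle.
* A reciprocal condition number below $10^{-12}$ flags the fit
  `well_posed = FALSE` (e.g. a constant window, whose accumulation is
  exactly collinear with the drift regressors). The fit still returns
  — with one least-squares solution among many and a diagnostic — but
  `simulate_static()` refuses it, and rolling records the step as
  undefined, excludes it from MAPE and warns.
* Simulated values always anchor $t = 1$ to the observation; all
  restoration is by differencing the accumulated path iterated from
  that anchor.
* GM's development coefficient within $10^{-12}$ of zero degenerates
  to the linear time response (flat forecast) instead of dividing by
  $a$.
* Observed series must be strictly positive; zeros are rejected with
  the offending period named rather than epsilon-adjusted, because
  MAPE is undefined there and silent rescaling would corrupt the one
  index everything ranks by. Fitted values, by contrast, may go
  nonpositive and are not clamped.

## Known limitations

* The 3-parameter DNGM on very short noisy windows is near-collinear
  ($x^{(1)}$ is almost linear in $t$ locally), so its one-step
  forecasts have high variance; rolling it at small $n$ can lose to
  the 2-parameter rolling GM on smooth noisy series even though it
  dominates on exactly nonhomogeneous data. Window-size selection
  exists precisely to manage this, and the $n = 4$ sweep entry
  routinely shows the blow-up.
* IDGM and DDGM are reconstructions (above); results for them
  characterise these plain forms, not necessarily every published
  variant.
* One-step-ahead evaluation only; no multi-step rolling matrices, no
  irregular spacing, no missing values, no multivariate models, no
  interval grey numbers, and no optimisation of GM's background-value
  weight (fixed at ½).

## Problem sizes

The test suite and the acceptance script run at the scale the methods
are meant for: series of 10–20 points, windows of 4–10, 1000-draw
parameter sweeps for the closed-form/recursion equivalence, 200 random
windows for the estimator oracle. Everything completes in seconds.
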