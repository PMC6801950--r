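---
title: "Methods: decomposition-ensemble forecasting and fuzzy evaluation of air quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposition-ensemble forecasting and fuzzy evaluation of air quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqews)
```

`aqews` implements an air-quality early-warning pipeline for daily
concentrations of the six criteria pollutants (PM2.5, PM10, NO2, SO2, CO,
O3; micrograms per cubic metre except CO in milligrams per cubic metre).
The pipeline has two halves: a *prediction* half — ICEEMDAN decomposition
of each pollutant series, one WOA-tuned extreme learning machine per mode,
mode forecasts summed — and an *evaluation* half — fuzzy comprehensive
evaluation that grades a day's six concentrations into one of five
air-quality levels and attaches early-warning handbook advice. This
vignette explains each model, the tunable parameters, the numerical
choices that were genuinely open, and what the test suite does and does
not establish.

## Data model

A `pollutant_series` is a strictly daily, chronologically ordered record
of one pollutant with an explicit missingness mask. Missing days are
imputed by the *nearby mean*: the average of the nearest observed value on
each side, or the single nearest value at the series edges. This is the
simplest rule consistent with filling isolated gaps in an autocorrelated
series; it never alters observed values.

Supervised windows pair each day with the `window` immediately preceding
values. The per-pollutant window lengths default to PM2.5/PM10: 4,
NO2: 8, SO2: 3, CO: 8, O3: 3 (`default_windows()`), the input-variable
counts of the study design this package operationalizes. Windows are
built on raw concentrations; the ELM layer applies min–max scaling fitted
on training data only (flag `scale`, default on), because sigmoid hidden
units saturate on raw micrograms-per-cubic-metre magnitudes.

The standard train/test protocol splits two years plus one month of data
(760 days, 1 September 2016 – 30 September 2018) at 31 July 2018 into 699
training and 61 testing days; `split_series()` is inclusive on the
boundary date.

## Empirical mode decomposition

`emd()` peels off intrinsic mode functions (IMFs) by sifting: cubic-spline
envelopes through the local maxima and minima, subtract the envelope mean,
repeat until the Cauchy-type criterion
`sum((h_prev - h_new)^2) / sum(h_prev^2) < 0.2` is met (at most 100 sifts
per mode, an overall budget of 1000 sift iterations per decomposition).
Mode extraction continues while the residue still has at least one
interior maximum and one interior minimum; a constant or monotone residue
(fewer than two extrema) ends the decomposition. Extraction also stops
when the residue's standard deviation falls below `1e-12` of the input's,
which prevents numerically empty "modes" from being split off a
residue that is already zero. The classical "fewer than three extrema"
stop was considered and rejected: it cannot extract an oscillation that
completes a single period inside the record (one maximum plus one
minimum), which is exactly the slowest tone the decomposition should
still isolate.

**Envelope boundaries.** Spline envelopes need knots beyond the record's
ends. At each end, up to two extrema of each kind are reflected about a
symmetry point chosen adaptively: the outermost extremum, unless the end
sample protrudes beyond the first envelope knot, in which case the end
sample itself becomes a knot and the reflection is taken about it.
Reflected knot *values* are point-symmetric (odd) about the outermost
extremum's value, so a local trend is linearly extrapolated rather than
folded back. The even (value-copying) mirror was tried first and leaves
boundary bulges of roughly a third of the signal amplitude on a
two-tone test signal, large enough to split a slow tone between a mode
and the residue; the odd reflection reduces the boundary error by an
order of magnitude and is fixed package-wide so all tests are
deterministic.

The telescoping construction guarantees that modes plus residue
reconstruct the input to machine precision, which the suite asserts at
`1e-8` of the input standard deviation.

## ICEEMDAN

Plain EMD mixes scales when the signal's extrema density varies.
ICEEMDAN stabilizes the decomposition by estimating each stage's residue
as an ensemble average of local means of noise-perturbed copies of the
current residue:

1. draw `I` white-noise realizations `w_i` (default `I = 50`);
2. stage 1: `r1 = <M(x + beta * E1(w_i))>`, `d1 = x - r1`;
3. stage k: perturb `r_{k-1}` with `E_k(w_i)`, the k-th EMD mode of
   realization `i`, scaled to standard deviation
   `noise_scale * sd(r_{k-1})` (`noise_scale` default 0.2), and set
   `d_k = r_{k-1} - r_k`.

`M(y)` removes the first sifted mode of `y` (`M(y) = y - E1(y)`), so with
`noise_scale = 0` and `I = 1` the recursion reproduces plain EMD exactly
— a limit the suite checks. The noise modes `E_k(w_i)` are extracted
incrementally and cached, one mode per stage per realization. Each
realization is seeded separately (`seed + 7919 * i`), so appending days to
the signal leaves the first `n` noise values unchanged; decompositions of
a growing series are therefore stable, which matters for rolling
re-decomposition. The decomposition-wide sift budget (default 1000,
following the study's iteration cap, whose precise referent the source
leaves ambiguous) applies per noise-realization stream, so one ICEEMDAN
call does the same per-stream sifting work as one plain EMD call.

## Whale optimization algorithm

`woa_optimize()` minimizes a black-box function over a box. Each of
`n_agents` candidate positions is updated per iteration by one of three
moves: *shrinking encirclement* of the best position
(`x' = x* - A |C x* - x|`), *random exploration* around another agent
(same form with a random agent in place of the best), or a *logarithmic
spiral* around the best (`x' = |x* - x| e^{bl} cos(2 pi l) + x*`). The
branch is chosen per agent per iteration: probability 1/2 spiral;
otherwise encircle if `|A| < 1`, explore if `|A| >= 1`. The coefficient
`a` decays linearly from 2 to 0 (`a = 2 - 2t/T`), `A = 2 a r - a`,
`C = 2 r` with `r` uniform per agent per iteration. Choices the source
family leaves open, fixed here: spiral constant `b = 1`; `|A|` is the
Euclidean norm when the dimension exceeds one; out-of-box positions are
clamped to the box; the best-so-far is updated after all agents move.
Defaults (10 agents, 200 iterations) follow the study's settings; the
suite verifies median sphere-function convergence below `1e-3` across 20
seeds and a strict evaluation-count contract (`n_agents` evaluations at
initialization plus `n_agents` per iteration).

## Extreme learning machine

A single-hidden-layer network whose hidden weights and biases are drawn
uniform on [-1, 1] and never trained; the output weights solve
`min ||H beta - T||` through the Moore–Penrose pseudoinverse
(`MASS::ginv`), giving the minimum-norm least-squares solution in closed
form. With `L = N` hidden neurons and a full-rank hidden matrix the
network interpolates the training data exactly; the suite asserts
training RMSE below `1e-6` over full-rank draws and checks the
pseudoinverse against a normal-equations oracle. The hidden-neuron count
`L` defaults to 20 — the source reports tuning by trial and error without
printing a value, and 20 keeps `L` well below the ~700 training windows
while leaving enough capacity for the smooth mode shapes.

`train_woa_elm()` wraps the ELM in the optimizer: WOA searches the
flattened hidden parameters (`L * window + L` dimensions, box [-1, 1]);
for each candidate the output weights are re-solved on the
chronologically earlier 80% of the windows and the fitness is RMSE on the
held-out 20% tail (time-series hygiene: the validation set is always the
most recent data). The fitness function and search space are design
choices — the source states only that the optimizer finds "the best
parameters" of the network — and this split (random hidden layer searched,
closed-form output layer re-solved) is the standard hybridization
consistent with the ELM's architecture.

## The hybrid forecaster

`hybrid_fit()` decomposes the training series once and trains one
WOA-tuned ELM per mode plus one for the residue (a series with no
interior extrema yields zero modes and falls back to a single model on
the raw series). `predict()` produces rolling one-step-ahead forecasts
whose integrated value is, by construction, the exact sum of the per-mode
forecasts.

How to obtain *test-period* mode values without peeking at the future is
the genuinely open design question in this family of models. Two causal
policies are implemented:

- `mode_extension = "fixed"` (default): decompose once; each mode model
  extends its own mode recursively. Recursive forecasts are clamped to
  each mode's training range, the usual guard against runaway feedback in
  recursive neural prediction.
- `mode_extension = "refit"`: re-decompose training data plus the
  observed test history before every step and read each mode's trailing
  window from the fresh decomposition.

"Refit" looks more faithful to rolling one-step forecasting, but its
re-decomposition suffers end effects precisely at the forecast origin:
the trailing mode values the models consume are the least reliable part
of the decomposition, and in paired benchmarks the refit path is
consistently less accurate than the fixed path as well as roughly sixty
times more expensive. "Fixed" is therefore the default. Neither policy
uses future observations inside the sifting — the decomposition of the
full series including the test period, common in this literature, is
deliberately not offered, because it leaks test information into the
training windows.

An honest caveat, established by the package's own paired-seed benchmark
(20 seeds, 760-day synthetic series, 61-day test): under leakage-free
evaluation the hybrid is markedly more *stable* than a plain or WOA-tuned
ELM forecasting recursively (the single models occasionally saturate and
blow up; the hybrid never does), but it does not dominate them seed by
seed — it wins about half the pairings against a plain ELM and about
two-thirds against a WOA-ELM. The dramatic across-the-board superiority
reported for decomposition-ensemble forecasters in the applied literature
is reproducible only when the whole series, test period included, is
decomposed before windowing. Users should read published gains of that
kind with this in mind.

## Forecast metrics and model comparison

`forecast_metrics()` reports MAE, RMSE, MAPE (in percent — the source's
tables print percentages) and Theil's inequality coefficient
`TIC = RMSE / (sqrt(mean(pred^2)) + sqrt(mean(actual^2)))`, which is
scale-invariant and confined to [0, 1]. MAPE refuses zero actuals by
naming the offending index.

`dm_test()` compares two forecast-error series under absolute-error loss:
`D_i = |e_a,i| - |e_b,i|`, `DM = mean(D) / sqrt(s2 / T)` with `s2` the
(T-1)-divisor sample variance of `D`, referred to the standard normal
(two-sided). The statistic's printed form in the source is garbled; the
implementation follows the statistic's original definition, matches a
hand-computed four-point example, and is verified to hold its nominal
size (rejection rate 0.05 ± 0.02 under an equal-accuracy null with
T = 200 and 2000 replicates). No small-sample correction is applied.

## Fuzzy comprehensive evaluation

For a day's six concentrations `x_i` and the five-level limits table
`u_{i1} < ... < u_{i5}` (defaults from the Chinese air-quality grading
standard; `aq_limits()` accepts overrides):

- **Memberships** (`membership_row`): halved-trapezoidal family — level I
  saturates at 1 below `u_1` and decays linearly to 0 at `u_2`; levels
  II–IV are triangular between their neighbours; level V rises from `u_4`
  and saturates at 1 above `u_5`. Strictly between `u_1` and `u_5` the
  two adjacent nonzero memberships sum to one.
- **Weights** (`factor_weights`): multi-scale weighting
  `w_i ∝ x_i / mean_j(u_{ij})`, normalized to sum to one. The source's
  printed weight formula uses symbols it never defines; this reading —
  concentration relative to the pollutant's own five-level scale — is the
  standard multi-scale weighting in environmental-quality evaluation and
  is flagged here because no published intermediate values exist to
  confirm it digit by digit.
- **Composition** (`fce_compose`): Zadeh operator,
  `B_j = max_i min(w_i, r_ij)`.
- **Classification** (`classify_level`): maximum membership; exact ties
  resolve to the better (lower) level, matching the worked tables this
  scheme reproduces.

**A structural caveat the tests document:** the composite scheme is *not*
monotone in individual concentrations. Raising one pollutant increases
its own weight but — through normalization — lowers everyone else's, and
a composite entry capped by another pollutant's weight can drop below a
better level's membership-capped entry; min–max composition also produces
exact ties with positive probability, and the tie rule then favours the
better level. Under realistic right-skewed concentration vectors, about
1% of random single-pollutant bumps improve the assigned level (most via
ties). This is a property of the published scheme, not an implementation
artifact; the per-pollutant membership rows themselves are rigorously
monotone (cumulative membership mass only ever moves toward worse
levels), and that is what the unit suite asserts.

## Synthetic data generator

`generate_pollutants()` emulates what two years of daily urban pollutant
records look like statistically: an AR(2) persistence process (`phi =
(0.55, 0.2)`, lag-1 autocorrelation ≈ 0.7), an annual sinusoid
(winter-peaking for PM2.5, PM10, NO2, SO2, CO; summer-peaking for O3;
period 365.25 days), and white noise, combined into a standardized latent
signal and mapped onto target marginal moments (defaults: the Beijing-like
means/standard deviations, e.g. PM2.5 61.2 ± 57.5). The lognormal family
(default) exponentiates the latent signal — concentrations are strictly
positive and right-skewed, as the large max-to-mean ratios of real
records imply — and a final affine adjustment pins the sample mean and
standard deviation before clipping at zero. `inject_missing()` masks an
exact count of interior days for exercising imputation.

What the generator does *not* emulate: meteorological covariates and
regime shifts, heteroscedastic winter episodes, spatial correlation
between cities, and calendar effects. Tests passing on synthetic data
therefore establish the pipeline's mechanics and relative behaviour, not
field performance on any real city's record.

## Problem sizes used by the test and acceptance runs

The suite exercises the full study geometry (760-day series, 699/61
split, 61-day horizon, 20 paired seeds) with a reduced ICEEMDAN ensemble
(`I = 5–10`) and a reduced WOA budget (50 iterations) for the paired
benchmark, and the study's own settings (10 agents, 200 iterations)
wherever the optimizer itself is under test. These sizes are the
package's chosen trade-off between statistical resolution and a test run
that completes in minutes; the vignette records them so results are
interpreted at the scale actually computed.

## Known limitations

- Decomposition end effects remain the dominant error source for any
  causal rolling scheme; no boundary rule removes them.
- The FCE weight formula is an interpretation (see above); absolute
  composite values depend on it, though classifications are fairly
  robust.
- Forecast intervals are not provided; the models are point forecasters.
- Hourly data, multi-city joins and exogenous covariates are out of
  scope.
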