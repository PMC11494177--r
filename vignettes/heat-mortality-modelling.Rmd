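---
title: "Modelling heat-related mortality across scales with heatmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-related mortality across scales with heatmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
library(dplyr)
```

## The problem

Heat is a leading cause of preventable summer deaths, but quantifying its
burden is hard because the two data sources involved live at incompatible
resolutions. Temperature is observable daily at kilometre scale; all-cause
mortality is released by statistics offices only in coarse aggregates —
daily counts by state and sex, weekly counts by state, sex and broad age
band, weekly national counts by sex and fine age band. heatmort implements a
multi-scale strategy: a daily, district-level, age- and sex-stratified
mortality model is trained *through* the aggregation, by summing its
predictions to the exact resolution of each reporting stream and scoring the
sums against the released counts with a Poisson likelihood.

## The model

Expected all-cause deaths in district $i$, stratum $s$ (sex $\times$ 5-year
age band), day $t$ are

$$E_{i,s}(t) \;=\; b_s(t)\; \cdot\; P_{i,s}(t)\; \cdot\;
f_{g(s)}(T_{i,t})\; \cdot\; w_{\mathrm{dow}(t)},$$

where $b_s(t)$ is a spatially uniform baseline death rate per person-day,
log-linear in time (no explicit seasonal term: seasonality enters only
through temperature), $P_{i,s}(t)$ is the daily population linearly
interpolated between annual snapshots, $w$ are seven multiplicative
day-of-week reporting factors constrained to mean exactly 1, and $f$ is the
exposure-response function applied to the lag vector
$T_{i,t} = (T_t, T_{t-1}, \dots, T_{t-l})$ of daily mean temperatures
(default $l = 7$). One response function is shared per sex $\times$ broad
age group — the finest stratification jointly identifiable from the weekly
state-level (broad age) and weekly national (fine age) streams; finer ages
inherit their broad group's $f$.

Two response architectures are available:

* **exponential** — $f(T) = c + \sum_{k=1}^{d} s_k \exp(g_k(T))$ with affine
  $g_k$, mixing weights $s_k \ge 0$ and bias $c \ge 0$ enforced structurally
  through a softplus reparameterisation (never by clipping). A sum of
  exponential terms is a shape classical GAM/DLM formulations do not offer.
* **linear** — a one-dimensional convolution of kernel size $l+1$ over the
  lag window (equivalently $d$ affine maps of the lag vector) followed by a
  rectified linear layer, with a softplus output squash for non-negativity:
  $f(T) = \mathrm{softplus}\!\big(v_0 + \sum_k v_k\,\mathrm{relu}(g_k(T))\big)$.

The two architectures have complementary inductive biases, and the choice
matters for attribution. Every term of a positive exponential mixture is
strictly positive at *every* temperature, so a response that is truly flat
below some threshold and rising above it is approximated with a small but
unavoidable upward bias exactly at the threshold; because heat attribution
subtracts the prediction under a capped temperature series, that bias at the
cap eats into the estimated excess (we observe this directly in the recovery
experiments). Rectified units are exactly zero below their kinks, so the
linear variant can represent flat-below-cap responses without that bias and
is the default choice for attribution-centred analyses in this package's own
experiments; the exponential variant extrapolates more aggressively beyond
the observed temperature range.

**Training.** All enabled streams enter a pooled Poisson negative
log-likelihood $\sum (\lambda - y \log \lambda)$ with equal cell weighting
(the relative weighting of streams is not identified by any principle we
know of; equal weighting is the neutral choice). Optimisation is full-batch
Adam on analytically derived gradients — the problem has a few hundred
parameters and a few hundred thousand daily cells, so full batches are cheap
and deterministic — with an epoch cap (default 2000) and early stopping on
validation NLL (patience 50 epochs). Inside the trainer the lag inputs are
centred at the 20 °C reference; this decouples the inner weights from their
intercepts (otherwise the intercept must track $-20\sum_j A_{kj}$ along a
badly conditioned valley) and speeds convergence considerably. Exported
parameters are translated back to the natural scale, so users only ever see
$f$ as a function of raw temperatures. Intensities are floored at $10^{-8}$
inside the loss so early iterates cannot produce $\log 0$.

Because a single trained instance depends noticeably on its random
initialisation, the final predictor is an ensemble: `ensemble_size`
instances (default 20) are trained from per-instance seeds and their daily
expected deaths averaged.

**Identifiability.** Multiplying the baseline by a constant $c$ and the
response by $1/c$ leaves every prediction — and therefore the likelihood and
all attribution results — unchanged. Absolute levels of $f$ are thus
meaningless; only relative risks $f(T)/f(T_{\mathrm{cap}})$ and the excess
itself are reported, and the test suite asserts this invariance explicitly.
The baseline intercepts are initialised from crude per-stratum death rates
(national stream counts over person-days), which fixes the gauge near
$f \approx 1$ and gives the optimiser a sensible starting point.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `l` (lag window) | 7 | days | observed lag effects fade within ~3 days after a heat peak; 7 leaves headroom without inflating the parameter count |
| `d` (hidden dimension) | 8 | terms | enough exponential/rectified terms to shape a one-directional response; recovery is insensitive between 8 and 16 |
| `cap_c` | 20 | °C | conventional bound for "no heat stress" baseline conditions; also the warm-day threshold |
| `ensemble_size` | 20 | instances | averages out initialisation variance; 5 suffices for the packaged synthetic experiments |
| `lr` | 0.05 (0.01 used in the packaged experiments) | — | Adam step size; the loss is on the scale of millions, so per-parameter normalised steps matter more than the raw value |
| `epochs` / `patience` | 2000 / 50 | epochs | cap and early-stopping window on validation NLL |
| `train/validation years` | 2011–2018 / 2019–2020 | — | 80:20 temporal split; the packaged 6-year experiments use 5:1 |
| `top_k` | 10 | days | concentration statistic: share of annual excess in the k hottest-impact days |

## Attribution

Heat-related excess mortality is defined by a capped-temperature
counterfactual: the cap (default 20 °C, a conventional bound for "no heat
stress" conditions) is applied elementwise to the raw daily series *before*
lag-matrix construction, so the whole lag window is capped, and

$$\mathrm{excess}_{i,s}(t) = E_{i,s}(t \mid T) - E_{i,s}(t \mid \min(T, 20)).$$

Excess is computed per ensemble instance and averaged; since the difference
is linear in the instance predictions, averaging before or after subtraction
is equivalent (asserted in tests). Daily excess is reported unclipped — a
non-monotone fitted response can produce slightly negative values — with an
optional clip at zero for presentation. Event summaries report window
totals, per-million rates and the window's share of its calendar year;
concentration statistics report the share of the annual total carried by the
top-$k$ days (default 10) and the fraction of those days that are
*disconnected*, operationalised as having no other top-$k$ day on an
adjacent calendar day (adjacency is evaluated within the year under
analysis).

## Temperature interpolation and downscaling

District-level daily temperatures are produced from point observations
(weather stations, or climate-model grid points) by an attention-weighted
interpolator: district $i$ carries a trainable position $X_i$, bias $b_i$
and positive scale $\alpha_i$, and attends to source points $Y_j$ with
weights $w_{ij} \propto \exp(-\alpha_i\, d(X_i, Y_j))$, normalised over $j$,
where $d$ is the great-circle (haversine) distance in kilometres — a
Euclidean metric on raw degrees would distort with latitude. Its prediction
is $T_i = b_i + \sum_j w_{ij} T_j$. Positivity of $\alpha_i$ goes through a
softplus; positions initialise at the district reference points, biases at
0, $\alpha$ at 1 km⁻¹.

The fitting objective (mean squared error against reference district series
over the training 80% of an 80:20 temporal split) separates exactly by
district: each district owns its four parameters and the source points are
fixed. We therefore fit each district independently with L-BFGS-B rather
than a single joint stochastic-gradient loop — the same optimum, better
conditioned, and embarrassingly simple. Missing station values are *not*
interpolated implicitly: a utility fills them from a secondary gridded
product after subtracting the mean difference between the two sources over
their overlapping period, and prediction refuses missing inputs.

The identical mechanics serve as a statistical downscaler for climate
projections: the interpolator is fitted with the projection grid's points as
sources (against reanalysis-derived district series) and then applied to
each ensemble member. No bias correction is applied to members — a
deliberate omission (bias correction brings its own processing
uncertainties), which users should keep in mind when reading projected
absolute levels.

## Projection

For each climate-ensemble member the pipeline downscales the member's grid
temperatures, computes annual excess through the capped counterfactual with
population and baseline frozen at a reference date (end of the freeze year),
and summarises each calendar year across members by the median and the
empirical 10th/90th percentiles with linear interpolation between order
statistics. Annual excess per member is the unclipped calendar-year sum of
daily excess, matching attribution. Per-member-then-per-year percentile
aggregation is used throughout (an alternative — decadal pooling — changes
band widths but not medians appreciably). The "factor increase" diagnostic
divides the last decade's median annual excess by the first decade's.

## The synthetic study region

Real registry and reanalysis archives cannot be redistributed, so the
package ships a generator that emulates their statistical structure with
known ground truth; every downstream stage has a recovery test against that
truth. Generated are:

* an administrative hierarchy (default 4 states, 20 districts) with district
  reference coordinates, a station network, and annual 31-December
  population snapshots per sex and 5-year age band (parametric pyramid whose
  75+ share is calibrated to a configurable target, default 12%; log-normal
  district sizes around 180,000; slow log-linear drift);
* daily mean temperatures = seasonal sinusoid peaking mid-July (level
  9.5 °C, semi-amplitude 10 °C) + a smooth north-south/west-east gradient +
  a regionally shared AR(1) anomaly ($\phi = 0.7$, $\sigma = 2.2$ °C — about
  30 warm days per year nationally, in the range of recent hot German
  summers) + a constant urban heat-island offset (default up to 2 °C for a
  quarter of districts); stations observe the field with independent 0.5 °C
  noise; districts are noise-free truth;
* deaths from a known risk model
  $f_{\mathrm{true}}(T) = 1 + \beta \max(0, \sum_k w_k T_k - 20)^{1.5}$
  (geometrically decaying lag weights over 8 days, $\beta = 0.03$) applied
  to a Gompertz-type age-specific baseline with a $-0.5\%$/year trend and
  mild day-of-week factors, observed as independent Poisson draws — about
  1.1–1.8% crude annual mortality and an annual true heat excess on the
  order of 100–300 per million, comparable to published estimates for hot
  years;
* the three reporting streams as exact sums of the daily records, weekly
  ones on ISO-8601 weeks with partial edge weeks dropped (so conservation is
  exact, not approximate).

What the generator does *not* emulate: real geography or population
pyramids, spatially correlated weather beyond the single shared anomaly
(the true spatial covariance of the regional temperature field is unknown to
us; the sinusoid + gradient + AR(1) choice is a stand-in), reporting delays
or corrections, epidemic shocks (influenza, COVID-19), or cold-related
mortality. Passing recovery tests therefore demonstrates that the estimation
machinery works when the model family matches reality's structure; it does
not validate the epidemiological assumptions on real data.

**How recovery is judged.** The recovery experiments compare (a) the
ensemble's total attributed excess against the generator's ground-truth
excess (tolerance ±15%), and (b) the fitted relative-risk profile
$f(T)/f(T_{\mathrm{cap}})$ against the true one (tolerance ±10%). The risk
profile is evaluated on the *observed* temperature histories with same-day
mean in [20, 30] °C, pooled into 2 °C bins and death-weighted across the
sex × broad-age groups. Constant lag vectors (eight consecutive days at
30 °C, say) never occur in a six-year simulation of this climate — the
maximum lag-weighted effective temperature is around 28 °C — so evaluating
there would test architectural extrapolation priors rather than what the
data identify; observed histories keep the comparison inside the data
support, which is also where attribution actually reads the function.

## Numerical choices and problem sizes

* Poisson NLL drops $\log y!$ (constant in the parameters) and floors
  $\lambda$ at $10^{-8}$.
* Day-of-week factors are parameterised as $e^{\delta_k} / \overline{e^{\delta}}$,
  so their mean is exactly 1 by construction for any $\delta$.
* Weekly aggregation drops partial ISO weeks at calendar edges rather than
  padding them, keeping all conservation identities exact.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7).
* Concentration statistics break excess ties by date (earlier day wins a
  top-$k$ slot).
* The packaged experiments (tests and the acceptance script) use a
  20-district, 6-year region with a 5-instance ensemble and a 5:1 temporal
  train/validation split — large enough that the true excess signal (a few
  thousand deaths over six years against roughly half a million total) is
  recoverable, small enough to run routinely on a laptop. A 10-year region
  with the full 20-instance ensemble reproduces the same behaviour more
  slowly.

## Known limitations

* A single spatially uniform baseline and response per stratum group — the
  central simplifying assumption; fine for a climatically homogeneous
  region, wrong for continental scales.
* The exponential variant's attribution bias at the cap discussed above;
  prefer the linear variant when the excess total is the quantity of
  interest.
* Relative risks are only identified where the data contain temperature
  support; both variants extrapolate beyond the warmest observed lag
  vectors by their architectural prior (exponential growth vs. piecewise
  linear), not by evidence.
* No influenza/COVID covariates: mortality shocks unrelated to temperature
  are absorbed partly by the baseline trend and partly left as residual;
  metric-exclusion years exist for this reason.
* Frozen-baseline projections ignore demographic change unless an explicit
  demographic scenario is supplied via `apply_demographic_scenario()`, which
  holds each age band's geographical distribution at its base-year shares.
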