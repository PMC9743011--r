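---
title: "Methods: fine-root demography, interval-censored survival and spectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-root demography, interval-censored survival and spectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizodyn)
```

This vignette documents the models behind `rhizodyn`, the assumptions they
make, the tunable parameters, and the numerical and design choices that an
informed user should know before trusting the output on their own data.

## The observation process

Minirhizotron imaging yields a panel: each root is a row of statuses
(absent, live, dead, disappeared) and live lengths on a shared schedule of
imaging sessions roughly three weeks apart. Two facts drive all downstream
statistics:

* **Death times are interval-censored.** A root seen live at session day
  $s_1$ and dead (or disappeared) at the next session $s_2$ died somewhere
  in $(s_1, s_2]$. A root still live at the final session is
  right-censored.
* **Appearance times are interval-censored too.** A root absent at one
  session and live at the next appeared somewhere in between. Ages must be
  measured from some origin inside that interval. The default origin is
  the **midpoint** of the appearance interval, which is unbiased if
  appearance is uniform within it; `origin = "first-live"` uses the first
  session the root was seen, which underestimates age by up to one
  interval but matches the convention of treating detection as birth.
  The choice is recorded in the derived data (`attr(iv, "age_origin")`).

Roots reclassified from short (first-order, unbranched, absorptive) to
long (higher-order, transport) must carry the long class at every session —
the retrospective reclassification convention — and the validator rejects
trajectories that are live again after death, carry length while not live,
or change class between sessions.

Disappeared-without-dead roots are treated as **events**, with the
disappearance session closing the interval: disappearance ends visibility,
and treating such roots as censored would bias longevity upward.

## Standing length, elongation and mortality

With total frame area $A_f$ (default $46 \times 13 \times 18\,\mathrm{mm^2}
= 0.010764\ \mathrm{m^2}$ per tube):

* $l_\mathrm{area}(s) = \sum_{\text{live roots}} \ell_i(s) / A_f$
  (m m⁻²), per session;
* $\Delta l_\mathrm{area}$ over an interval = difference in
  $l_\mathrm{area}$ between consecutive sessions divided by the interval
  length in days — new appearance and elongation of existing roots both
  contribute, mortality subtracts;
* mortality over an interval = the summed lengths of roots that died in
  it, each taken **at its last live session**, divided by $A_f$. The
  disintegrating root's own measurement is unreliable, so the last live
  length is the defensible quantity;
* mortality share = cumulative dead / (live + cumulative dead), with the
  accumulation restarting at a season start when a season window is given.
  Whether the share should reset per season or accumulate across the study
  is genuinely open; resetting is the default because shares are reported
  per growing season, and passing no season accumulates instead.

These definitions satisfy an exact conservation law on fully observed
data — the change in $l_\mathrm{area}$ equals production minus mortality —
which the test suite verifies against the generator.

## Phenology detectors

All detectors operate on per-interval net increments inside a season
window and compare them with a threshold fraction (default 5%) of the sum
of the **positive** increments of that season:

* **initiation** — midpoint of the first interval whose increment reaches
  the threshold;
* **cessation** — midpoint of the second interval of the first pair of
  consecutive sub-threshold intervals; a series still growing at the last
  session is flagged `ceased_at_last` and assigned the last interval's
  midpoint;
* **max standing value** — the session day (interval end) of the maximum;
* **max rate** — the midpoint of the interval with the largest per-day
  rate.

The threshold is compared against per-interval *increments*, not per-day
rates: the two interpretations differ when intervals have unequal length,
and comparing a rate against a sum of rates is dimensionally incoherent.
`basis = "rate"` provides the rate interpretation for sensitivity
analysis. Ties break toward the earlier interval everywhere
(deterministic, conservative). Undefined events propagate as `NA`, never
as sentinel values. Because thresholds are relative, every detector is
invariant to uniform rescaling — proportioning shoot series to their
start-of-season value changes nothing.

Shoot metrics differ in one respect: height growth initiates at budburst
(an observed quantity passed through), while stem-diameter initiation uses
the cumulative rule — the midpoint of the interval in which the cumulative
increment first reaches 5% of the seasonal total. Shoot cessation is the
midpoint of the interval ending at the session where the maximum is
attained.

The root−shoot **offset** is the day of maximum root growth rate minus the
day of maximum shoot growth rate; positive values mean roots peaked later.

Degree-day sums accumulate $\max(0, T - 5\,^\circ\mathrm{C})$ per day,
optionally duty-cycle-weighted between day and night phases. Temperature
ramps are handled by supplying daily means; a sub-daily trapezoidal
integrator was considered and dropped as spurious precision at 3-week
imaging resolution.

## Turnbull NPMLE and longevity

The survival function of root lifetime is estimated nonparametrically from
intervals $(L_i, R_i]$ by Turnbull's self-consistency (EM) iteration.
Probability mass can only sit on the *innermost intervals* (maximal
intersections) of the observed intervals; the EM update is

$$s_j \leftarrow \frac{1}{n}\sum_i \frac{\alpha_{ij} s_j}{\sum_k \alpha_{ik} s_k},$$

with $\alpha_{ij}$ indicating containment of innermost interval $j$ in
observation $i$. The log-likelihood is checked to be non-decreasing at
every step. Convergence is declared when the largest mass change falls
below $10^{-8}$; the iteration cap is 100 000 because each iteration is a
single matrix product and the iteration converges slowly when the
likelihood is nearly flat across adjacent innermost intervals (a cap of
10 000 was observed to stop a bootstrap resample a factor of two short of
tolerance).

Within an innermost interval of positive width the NPMLE is non-unique;
only its values at the interval endpoints are identified. Such regions are
flagged, and all curve summaries apply the conventional ad-hoc
**descending slope** (linear interpolation) across them. Between innermost
intervals the estimate is a uniquely defined step function. Exact event
times (supplied as $L = R$) are handled as degenerate intervals,
reproducing the empirical survivor function; with right-censored-only data
the estimator reduces to Kaplan–Meier, and both reductions are tested
against independent oracles.

Summaries:

* **median** — the first $t$ with $S(t) < 0.5$ (strict), interpolating
  inside non-unique regions; undefined (`NA`, with a warning) if the curve
  never goes below 0.5, as happens under heavy right-censoring;
* **mean** — $\int_0^{h} S(t)\,dt$ with the slope convention, restricted
  to $h$ = the largest finite innermost-interval boundary by default,
  because the integral is undefined beyond a censored tail;
* **confidence intervals** — percentile bootstrap over root-level
  resamples (default $B = 3000$). The resampling unit is the individual
  root; a seedling-level cluster bootstrap is available via the `cluster`
  argument for users worried about within-seedling correlation. Percentile
  intervals were chosen over normal-theory ones because the median of an
  interval-censored fit is a non-smooth functional.

**Turnover** is $365 / \text{longevity}$ per year, reported to one decimal
by convention; both inverse-median and inverse-mean versions are in use
and both are supported.

## The k-sample logrank test

Group differences in survival are tested with scores derived from the
pooled NPMLE (Sun-type construction). With pooled masses $s_j$ on support
points $t_j$ (right endpoints of innermost intervals):

* expected deaths of subject $i$ at $t_j$:
  $w_{ij} = \alpha_{ij} s_j / \sum_k \alpha_{ik} s_k$;
* expected at-risk: $\nu_{ij} = \sum_{k \ge j} \alpha_{ik} s_k /
  \sum_k \alpha_{ik} s_k$;
* subject score: $c_i = \sum_j (w_{ij} - \nu_{ij}\, d_j / n_j)$ with
  $d_j = \sum_i w_{ij}$, $n_j = \sum_i \nu_{ij}$ — the observed-minus-
  expected logrank increments with deaths and risk sets imputed from the
  pooled estimate.

The k-sample statistic is the generalized Kruskal–Wallis form
$X^2 = (N-1)\sum_g n_g(\bar c_g - \bar c)^2 / \sum_i (c_i - \bar c)^2$,
referred to its label-permutation distribution (default, 9999
permutations) or to $\chi^2_{k-1}$ in asymptotic mode — both forms are
offered because the two are used interchangeably in practice. On tiny
inputs the permutation p-value is verified against full enumeration of
label assignments; with zero score variance (all intervals identical) the
test degenerates to $p = 1$ by construction. Type-I error at
$\alpha = 0.05$ is verified to sit at $0.05 \pm 0.02$ over 1000 null
simulations.

## CLAFIC classification of impedance spectra

A spectrum's feature vector is one derived quantity ($Z_\mathrm{Re}$,
$Z_\mathrm{Im}$, $\delta$ or $|Z|$) restricted to the 150 Hz–150 kHz
window and scaled to unit norm. Features are deliberately **uncentred**:
classical CLAFIC builds each class's subspace from the second-moment
matrix, which is what makes the $k = 1$ basis approximately the class mean
direction; centring would break that property. Normalization (on by
default, configurable) makes classification invariant to per-spectrum
scaling, i.e. to electrode contact quality rather than spectral shape.

Classification assigns the class with the largest squared projection onto
the class subspace. Projections of unit vectors lie in $[0, 1]$ and a
training vector's own-class projection is non-decreasing in $k$. Exact
ties are reported as ambiguous with all tied classes listed, rather than
broken arbitrarily; $k$ equal to the full feature dimension makes every
projection 1 and is flagged degenerate in evaluations. Success tables are
reported under both resubstitution and leave-one-out; only the latter is
an honest error estimate at these sample sizes (8 spectra per class).

## Chamber fluxes and hydraulic conductance

The chamber flux is the closed form $F_A = \frac{dC}{dt}\cdot
\frac{P M V}{R A T}$ with $dC/dt$ the OLS slope of concentration against
time over the full 6–8 min deployment (an optional deadband trims
placement artifacts), ppm read as mole fraction $\times 10^{-6}$ — the
standard volume-basis convention, required for the units to close to
g m⁻² h⁻¹. The flux is exactly linear in slope, $P$, $M$, $V$ and
inversely linear in $A$ and $T$, and the sign convention makes a falling
concentration a negative flux (soil sink).

The HPFM correction multiplies the measured conductance by
$(0.554 + 0.0225\,T)/(0.554 + 0.0225\,T_c)$ with temperatures in °C (the
unit consistent with the published 43% reduction at $T = 2$,
$T_c = 22$).

## What the generators emulate — and what they do not

`simulate_root_demography()` emulates: a two-season study timeline (105-day
growing seasons, dormancy between, day 0 = second season start) imaged
every 21 days; unimodal within-season root appearance (truncated Gaussian
bump); treatment-dependent Weibull short-root longevity (defaults: shape 2,
medians 235/200/204/234 d for Cool/Warm/ECLW/EWLC — the
constant-cool/constant-warm/switched treatments); longer-lived long roots
without treatment effect (mean 238 d); per-interval gamma length
increments (mean 2 mm); death recorded at the first session after the
latent death day and disappearance a configurable number of sessions
later. Appearance is pinned to an imaging session, so a simulated root is
first detectable exactly when it appears: recovery tests can then compare
estimated longevities against the latent truth without the left-truncation
that continuous appearance would introduce (roots dying before their first
imaging session would never be recorded, biasing longevity upward — a
caveat that applies to *real* minirhizotron data and is not removed by any
estimator in this package).

Not emulated: root-level covariance within seedlings (roots are
independent given their treatment), seasonal mortality modulation,
elongation slowing with age, mycorrhizal colonization, image-analysis
measurement error in lengths, and soil-physics feedbacks. Passing tests on
synthetic data therefore demonstrate correctness of the estimators under
the stated sampling model, not robustness to these real-data features.

`simulate_shoot_growth()` produces logistic growth on an irregular 5–9-day
schedule with Gaussian noise; `simulate_eis()` draws Cole–Cole spectra
($Z = R_\infty + (R_0 - R_\infty)/(1 + (i\omega\tau)^\alpha)$, 36
log-spaced frequencies, 90 Hz–200 kHz) with independent Gaussian noise on
the real and imaginary parts; `simulate_chamber_series()` produces linear
drifts. Every generator takes an explicit seed, uses one pseudo-random
stream, restores the caller's RNG state, and returns its ground truth.

## Numerical choices and degenerate inputs

* EM tolerance $10^{-8}$ on mass change, cap $10^5$ iterations;
  log-likelihood asserted non-decreasing each step.
* Exact times as degenerate intervals are internally widened by
  $\varepsilon = 10^{-9} \times$ data scale so one open-left/closed-right
  convention covers everything; reported boundaries are unaffected at any
  realistic tolerance.
* Ties in detectors and classifiers break toward the earlier interval /
  are flagged ambiguous, respectively.
* A zero-variance score vector (all observations indistinguishable) gives
  logrank $p = 1$; an all-`NA` bootstrap (statistic undefined on every
  resample, e.g. median under extreme censoring) yields `NA` bounds with a
  warning rather than an error; `B = 0` skips the bootstrap and flags the
  output.
* Flat growth series make initiation/cessation undefined (`NA` +
  warning); max-standing and max-rate remain defined by the tie-break.

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the full run finishes in a few
minutes while keeping Monte-Carlo noise well inside the asserted bands:
~500–1000 roots for recovery tests (the recovery of an exponential median
is replicated over 10 generator seeds, since a single draw of 500 roots
carries ~6% sampling noise in its own sample median); 1000 null
simulations × 999 permutations for logrank calibration; 500 datasets ×
199 resamples for bootstrap coverage; 8 spectra per class × 4 classes for
CLAFIC. The pipeline's default config mirrors the study design (4
treatments × 4 seedlings) with desk-scale resampling counts
(`bootstrap_B = 200`, `n_perm = 999`) that users can raise.

## Known limitations

* The NPMLE's non-unique regions make the median an interval-identified
  quantity; the descending-slope convention is an interpolation, not an
  estimate, and alternatives (left or right endpoints) can shift medians
  by up to one imaging interval.
* The logrank scores impute risk sets from the pooled NPMLE; with very
  small groups the permutation form is reliable but the asymptotic
  $\chi^2$ reference can be anticonservative.
* Turnover as inverse longevity assumes stationarity of the root
  population within the reference year.
* The bootstrap treats roots as independent; use the seedling-level
  cluster bootstrap if within-seedling correlation is a concern.
* Morphology upscaling is a pure volume ratio; it does not model
  within-container heterogeneity of rooting density.
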