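---
title: "Deciding when a Lotka-Volterra model represents microbial interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding when a Lotka-Volterra model represents microbial interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcheck)
```

## The question and the model

Generalized Lotka-Volterra (LV) models are the workhorse of microbial
community modelling: each species grows logistically, and every partner
shifts its effective capacity linearly,

$$\frac{dS_i}{dt} \;=\; r_i S_i
  \left(1 - \frac{S_i - \sum_{j \neq i} c_{ij} S_j}{K_i}\right),$$

with $r_i$ the monoculture growth rate (per hour), $K_i$ the monoculture
carrying capacity (OD600), and $c_{ij}$ the dimensionless effect of
isolate $j$ on isolate $i$ (negative for inhibition, positive for
facilitation). The model is attractive because every parameter is
measurable in simple batch experiments — but it is only a caricature of
chemically mediated interactions, and the practical question is *when*
that caricature is adequate.

This package implements an operational answer built on cell-free spent
medium (CFSM) assays. Growing isolate $i$ in the stationary-phase spent
medium of isolate $j$ exposes it to the environment that $j$ leaves
behind at density $K_j$. If interactions really are LV, growth in that
medium is again logistic with

$$K_{ij} = K_i + c_{ij} K_j, \qquad
  r_{ij} = r_i \frac{K_{ij}}{K_i},
  \qquad\text{so}\qquad \frac{r_{ij}}{K_{ij}} = \frac{r_i}{K_i}.$$

The ratio invariance is the testable consequence: across spent-medium
contexts, an isolate's $(K_{ij}, r_{ij})$ pairs must fall on a line
through the origin with slope $r_i/K_i$. A significant positive
regression whose slope matches the baseline ratio is *consistent with*
LV (necessary, not sufficient); a flat, negative, or mismatched slope
rules LV out. Conversely the assay yields the interaction coefficients
themselves, $c_{ij} = (K_{ij} - K_i)/K_j$, which can be carried into the
coculture model and confronted with measured two-species dynamics.

A note on sign conventions: one can equivalently write the interaction
term as $+c_{ij} S_j$ with inhibitory $c$ positive. We use the
subtractive form throughout, because it makes $c_{ij} = (K_{ij} -
K_i)/K_j$ hold with inhibition negative — the convention in which the
package's bundled parameter set for the *S. aureus* / *Staphylococcus*
sp. KPL1850 pair prints $c_{12} = -1.26$ and $c_{21} = -0.52$.

## Growth-curve estimation

`fit_growth()` extracts $(r, K, S_0, T_L)$ from a single well:

* **Carrying capacity** is the maximum of the smoothed OD over the
  record (median-then-mean smoothing, window 5 points by default), the
  usual proxy in batch assays. Two guards matter in practice: a
  *no-growth* flag when the curve never clears twice its pre-peak
  minimum, and a *truncated-plateau* flag when the record ends within 5%
  of its maximum while still rising faster than 2% of $K$ per hour.
* **Growth rate** comes from an ordinary least-squares fit of the
  log-transformed readings over early growth, by default readings below
  30% of $K$ (`upper_fraction = 0.3`). Two numerical choices deserve
  emphasis. First, the transform is capacity-corrected,
  $\log\!\big(S K/(K - S)\big)$, which is *exactly* linear in time for
  logistic growth; a plain $\log S$ fit over the same window
  systematically underestimates $r$ by roughly the window-averaged
  $S/K$ (about 8-10% at these settings), which would swamp the few-percent
  effects the consistency criterion cares about. For $S \ll K$ the
  transform reduces to $\log S$. Second, the lag plateau is excluded
  robustly: the plateau level is estimated as the median of the smoothed
  pre-peak readings below 15% of $K$, and the window opens once the
  smoothed curve clears twice that level. A rule keyed to the plateau
  *minimum* is not noise-robust — with additive read noise comparable to
  the inoculum OD, the minimum sits far below the plateau and flat
  points leak into the fit. If fewer than 4 points qualify the window
  widens once to 50% of $K$ and the fit is flagged; wells whose capacity
  barely exceeds the inoculum keep their $K$ estimate with the rate
  flagged as failed.
* **Lag time** is where the fitted line extrapolates back to the
  inoculum density (clipped at zero), the inoculum being the pre-growth
  plateau level.
* **Blank correction** is applied only when blank-well readings are
  supplied (their per-time median is subtracted). We deliberately do
  *not* subtract the curve's own pre-growth minimum by default: with no
  separate blank, that minimum *is* the inoculum signal, and removing it
  destroys the quantities the lag and early-rate fits need. Readings at
  or below the detection floor (0.001 OD600 by default) are excluded
  from log fits.

Replicates are fitted individually and averaged per condition
(`cfsm_records()`); the per-well table keeps flags and $R^2$ so
questionable wells can be audited.

## The consistency verdict

`fit_rk_regression()` regresses $r_{ij}$ on $K_{ij}$ (rate as response,
matching the orientation in which $r_i/K_i$ is the slope) over
spent-medium contexts, including the isolate's own spent medium. The
fresh-medium condition is *not* a regression point: it supplies the
baseline ratio the slope is compared against. Including it would anchor
a spurious positive slope even for badly non-LV panels (it is by
construction the highest-$(r, K)$ point), visibly weakening the test's
power against shuffled-capacity violations.

`lv_consistency_test()` requires three clauses: slope p-value below
`alpha` (0.05), positive slope, and slope within `slope_tolerance`
(default 0.25, exposed because no principled universal value exists) of
the baseline $r_i/K_i$. Failures carry reasons. A passing verdict is
reported as "consistent with LV", never as proof.

`habitat_quality()` condenses each conditioned environment to
$q = K_{ij}/K_i$ — the position along the correlation line ($q = 1$
fresh-medium-equivalent, $q = 0$ no growth). For the LV picture to
extend beyond pairs, responses to combined media should average;
`combined_cfsm_additivity()` tests that with a Welch comparison plus a
15% effect-size band (a bare hypothesis test would declare everything
additive at small $n$ and nothing at large $n$).

## Coculture validation

Two-species cocultures observed through total OD plus a GFP channel for
the reporter strain are deconvolved by `deconvolve_coculture()`:
the piecewise calibration (linear below 3000 fluorescence units, a
square-root branch above; constants in `gfp_calibration()`) converts
fluorescence to reporter OD and the partner is the remainder. The upper
branch is read as $-a + \sqrt{a^2 - b}$, the reading that is continuous
(to ~3%) with the linear branch. Two instrument realities are handled
explicitly: the printed calibration's codomain skips a small interval
(~0.0950-0.0977 OD), and readings landing there are mapped to the
branch threshold and flagged; and inocula below the calibration's
zero-fluorescence OD (0.00594) are representable only by extending the
linear branch to blank-subtracted negative fluorescence, which the
synthetic generator does via `invert_gfp_calibration(extrapolate =
TRUE)`.

`empirical_interaction_trace()` inverts the coculture equation point by
point,
$$\hat c_{ij}(t) = \frac{S_i - K_i + K_i \dot S_i/(r_i S_i)}{S_j},$$
which is constant and equal to $c_{ij}$ exactly when the dynamics are
LV. Derivatives are where naive numerics fail: channels are smoothed by
a moving median followed by a local-quadratic (Savitzky-Golay) filter
*on the log scale*, and $\dot S_i$ is taken as
$S_i \cdot d\log S_i/dt$ with centered differences. Both choices are
exact for exponential growth; a flat moving mean on the raw scale
inflates an exponential by $\mathcal{O}((r\,\Delta t)^2)$ per window
point (~10% at $r = 1.85$ h$^{-1}$ and 10-min sampling), an error that
is then divided by the small partner density and dominates everything.
Estimates are restricted to the exponential window — from the end of the
focal lag (plus the smoothing half-width, so the lag kink stays out of
the derivative) to 4.5 h later, the midpoint of the "first 4-5 h of
growth" — and to points with partner density above 0.005 OD600 (division
guard) and no deconvolution flag. Whether that window should be measured
from inoculation or from the end of lag is ambiguous in the source
protocols; we measure from the end of lag, since before growth starts
the left side of the equation is identically zero and carries no
information about $c$.

`fit_lv_to_coculture()` fits $(c_{12}, c_{21})$ by least squares over
both deconvolved channels of all traces jointly, with monoculture
baselines fixed. Initial densities are estimated from each trace's
pre-lag readings (median), absorbing inoculation error; traces sharing
an inoculation ratio share one simulated trajectory per objective
evaluation. The optimizer is Nelder-Mead started from the CFSM-derived
coefficients (the natural prior), with a soft penalty confining
coefficients to $[-5, 5]$. `compare_model_experiment()` reports
per-channel RMSE and sign agreement between model and empirical
coefficients.

## The synthetic-data generator

Because the package must be testable without laboratory data, the
generator in `simulate_monoculture_curve()`, `generate_cfsm_panel()`
and `simulate_coculture_trace()` emulates the assays under known truth:
logistic monocultures with a hard lag (density held at $S_0$ until
$T_L$), 10-min sampling, 48 h for growth assays and 24 h for cocultures,
4 replicate wells per condition — the standard plate-reader layout of
these experiments. The observation model is multiplicative lognormal
noise (default sd 0.02) for pipetting/well variation, additive Gaussian
read noise (default sd 0.003 OD600), an optional constant blank offset
(default 0), and clamping at a 0.001 OD600 detection floor. The noise
magnitudes are free parameters of the generator, chosen as typical of
benchtop plate readers; no published variance estimates exist for the
assays being emulated, so recovery rates measured here quantify
performance *under this noise model*, not under any specific
instrument.

Panels come in three regimes: `none` (exactly LV-consistent by
construction, $r_{ij}/K_{ij} = r_i/K_i$ to machine precision),
`rate_yield_tradeoff` ($r_{ij} = r_i(1 + \beta(1 - K_{ij}/K_i))$, a
parameterized anticorrelation), and `shuffled_K` (capacities permuted
across contexts within each focal isolate, destroying the pairing while
keeping the margins). Conditioned capacities driven non-positive are
generated as growth-suppressed wells at the floor and flagged, not
raised as errors. `example_panel_spec()` draws a reproducible community
(rates 0.8-2 h$^{-1}$, capacities 0.2-0.6 OD600, lags 1.5-2.5 h,
inoculum 0.005 OD600, mostly inhibitory interactions clipped so every
conditioned capacity stays measurable at 0.02 OD600).

What the generator does *not* emulate — pH drift, diauxic shifts,
nonlinear OD-to-cell-density response above 0.5 OD, well-position
effects, contact-dependent interactions — bounds what passing tests
mean: they demonstrate correctness and statistical performance of the
estimators on data satisfying the stated model, not robustness to every
real-world artifact. The non-LV coculture regime
(`dynamics = "saturating"`, logistic growth inhibited by a Monod-like
factor $1/(1 + S_j/h)$, $h$ = 0.05 OD600) exists precisely to show the
method's failure-detection behaviour: LV coefficients fitted to such
data drift with the inoculation ratio, whereas fits to true LV data do
not — the mechanism by which an unreliable LV fit betrays itself.

## Numerical choices

* ODE integration: `deSolve::ode` (lsoda), rtol $10^{-8}$ / atol
  $10^{-10}$, integrated piecewise between lag breakpoints so the
  discontinuous growth switch never sits inside a solver step; densities
  clamped at zero on output. Lags zero the whole growth term (bracket
  included) before $T_{iL}$, so mixed lags in coculture are
  well-defined; for a monoculture this reproduces the time-shifted
  closed form exactly.
* The logistic closed form is evaluated as
  $K/(1 + (K/S_0 - 1)e^{-r(t - T_L)})$, stable for large $rt$.
* Self-interaction $c_{ii}$ is stored (it is the self-spent-medium
  record) but excluded from the dynamics; self-limitation lives in
  $K_i$.
* Degenerate inputs are flagged rather than fatal wherever a flag is
  scientifically meaningful: suppressed CFSM records, no-growth wells,
  clamped or branch-boundary deconvolution points, failed rate fits.

## Validation scale

The shipped test suite exercises every stage at desk scale: closed-form
checks and an independent fixed-step RK4 integrator for the dynamics;
200 seeded replicates for monoculture parameter recovery (median errors
required below 5% in $r$ and 3% in $K$ at 2% multiplicative noise); 100
seeded panels of 6 isolates per regime for the consistency criterion's
operating characteristics (LV panels must pass at $\ge$ 95%,
rate-yield-tradeoff panels at $\le$ 5%); and 50 seeded coculture
experiments (6 replicates at each of two inoculation ratios) for
coefficient recovery (medians within 15% of truth, full sign
agreement). These sizes were chosen so the whole suite runs in a few
minutes on a laptop while leaving the statistical margins comfortable.

## Known limitations

The criterion is one-directional: linear $r$-$K$ consistency is
necessary for LV, not sufficient. The CFSM assay itself misses
contact-dependent and induced interactions. The deconvolution trusts a
single-strain calibration into cocultures. N-species dynamics are
implemented but validated only against two-species fixtures. And all
stochastic performance figures are relative to the generator's noise
model, as discussed above.
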