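---
title: "Methods: epidemic modelling and optimal refueling control of hurricane fuel shortages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epidemic modelling and optimal refueling control of hurricane fuel shortages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuelsir)
```

## The model and its assumptions

`fuelsir` treats the percentage of fuel stations that are out of gasoline in
a metro area during a hurricane evacuation as the infected compartment of an
SIR contagion. Stations with fuel that are at risk of being drained are
susceptible, $S$; empty stations are infected, $I$; stations resupplied
after running dry are recovered and — because the episode is a short, acute
outbreak — are assumed not to run dry again. All compartments are
percentages on the 0–100 scale, which makes the transmission rate $\beta$
carry units of 1/(percent·day) and the recovery rate $\gamma$ 1/day. This
scale convention matters: the packaged per-city fits ($\beta \approx
0.006$–$0.014$, $\gamma \approx 0.1$–$0.27$) only produce sensible basic
reproduction numbers $R_0 = \beta S(0)/\gamma$ of 1.6–11.6 when $S$ is
measured in percent.

The controlled dynamics add a "vaccination analogue": a per-capita
preemptive refueling rate $u_v$ (1/day) that removes susceptibles from the
at-risk pool before they drain,

$$\dot S = -\beta S I - u_v S,\quad
  \dot I = \beta S I - \gamma I,\quad
  \dot R_{rec} = \gamma I,\quad
  \dot R_{vac} = u_v S .$$

The fourth compartment doubles as the resource ledger: its terminal value
equals $\int u_v S\,dt$, the total preemptive refueling delivered, which is
the quantity a resource cap $r_{\max}$ constrains.

Key modelling assumptions, all inherited from the aggregate nature of the
data: mass-action mixing within a metro area (no spatial structure),
time-invariant rates over the 12–18-day window, no re-infection, and a
closed population of stations ($S + I + R_{rec} + R_{vac}$ conserved).
Demographic stochasticity is ignored — the unit is a percentage of dozens to
thousands of stations, not an individual count.

## Integration: forward Euler, deliberately

The discrete process equations used everywhere are forward Euler at the
reporting cadence of the source data: $dt = 0.25$ day for the Hurricane
Irma windows (12 days) and $dt = 1$ hour for the Hurricane Florence windows
(18 days). Euler at the native cadence is the canonical scheme here because
the estimation stage *defines* its process model that way; using the same
scheme for simulation and control keeps every stage on one grid. A
classical Runge–Kutta integrator (`sir_simulate(..., method = "rk4")`) is
included solely to let the test suite demonstrate convergence; no headline
quantity uses it.

Two numerical consequences are documented rather than hidden:

* **Peak overshoot.** Euler at $dt = 0.25$ overshoots the continuous-time
  infected peak. For the Fort Myers–Naples reconstruction the closed form
  $I_{\max} = I_0 + S_0 - \rho + \rho\ln(\rho/S_0)$, $\rho = \gamma/\beta$,
  gives 55.90 %, while the $dt = 0.25$ Euler series peaks at 57.22 %; at
  $dt = 0.025$ the gap shrinks to about 0.13 points. The test suite pins
  the overshoot with this closed form as an independent oracle.
* **Negative overshoot clipping.** On coarse grids a step can push a
  compartment below zero. The step clips it to zero and deposits the
  clipped mass into $R_{rec}$, so conservation survives exactly; a warning
  and a counter record every clip. In all packaged scenarios no clipping
  occurs — the rule exists for user-supplied extreme parameters.

The uncontrolled system's first integral $V = S + I - \rho \ln S$ is used
as a convergence diagnostic: its drift along an Euler trajectory is $O(dt)$
and the suite checks that halving the step at least halves the drift.

## Joint state–parameter estimation

The filter state is $X_k = [S_k, I_k, \beta_k, \gamma_k]^\top$ with the
rates propagated as constants ($\beta_k = \beta_{k-1}$, $\gamma_k =
\gamma_{k-1}$) and the observation operator the projection onto $(S, I)$.
The sigma-point (unscented) recursion is the standard one: scaling
$\lambda = \alpha^2(L + \kappa) - L$ with $L = 4$; $2L + 1$ points at the
mean and $\pm\sqrt{L + \lambda}$ times the Cholesky columns of the
covariance; weighted means and spreads for the time and measurement
updates; gain $K = P^{xy}(P^{yy})^{-1}$.

Defaults follow the working tuning for this problem: $\alpha = 1$,
$\beta_w = 2$ (the Gaussian-optimal covariance weighting, renamed to avoid
clashing with the transmission rate), $\kappa = 0$, $Q =
\mathrm{diag}(10, 10, 100, 100)$, $R = \mathrm{diag}(10, 10)$, $P_0 = I_4$,
with the state initialized from the first observation and $\beta = \gamma
= 0$ (to be learned). The $R$ scale implies percent-unit observations with
a few percent of measurement scatter. The very loose parameter process
noise deserves comment: variance 100 on rates of magnitude 0.01–0.3 lets
the per-step $\beta_k, \gamma_k$ roam widely, so the raw trajectories are
not themselves the estimate. They are raw material for the next stage.
Users who want tight per-step tracking (e.g. to watch a demand surge) pass
a small parameter process noise instead; one of the tracking tests does
exactly that.

Numerical safeguards, each chosen once: covariances are symmetrized every
step; a Cholesky failure triggers a diagonal jitter of
$10^{-8}\,(\mathrm{tr}/4)$, escalated twice before aborting with a
diagnostic; posterior $S, I$ are clipped to $[0, 100]$ and $\beta, \gamma$
to $\ge 0$ (the process model is meaningless outside these ranges), with a
logged count.

**Constant-pair selection.** The time-invariant model that the control
stage needs is chosen by brute force: every combination of the per-step
$\beta_k$ values with the per-step $\gamma_k$ values (negative rates
excluded) is simulated from the series' initial $(S, I)$ and scored by the
mean square error of $I(t)$ against the observations; the minimizer wins,
ties broken toward smaller $\beta$, then smaller $\gamma$. The error is
scored on $I$ only because the infected channel is the directly reported
quantity, while the susceptible channel of real feeds is partially derived;
scoring on both is available behind `on = "both"`. The candidate
simulations are vectorized across pairs, so even the hourly Florence
windows (433 steps, roughly $10^5$ candidate pairs) select in under a
second.

When an input file supplies only `i_pct`, the susceptible channel is
synthesized as $100 - I - \hat R(t)$ with $\hat R$ the trapezoidal
accumulation of $\gamma_{prov} I$ at a provisional recovery rate
($\gamma_{prov} = 0.2$/day by default, configurable); the synthesis is
flagged on the returned object. This is a documented reconstruction rule,
not an estimate — real two-channel data should be preferred.

## The refueling policy

With constant rates, the resource-constrained optimal refueling problem —
minimize the outbreak size $J = \int \beta S I\,dt$ subject to the control
bound $u_v \in [0, u_{v,\max}]$ and the resource constraint $\int u_v
S\,dt \le r_{\max}$ — has a bang-bang solution with a single switch: apply
$u_{v,\max}$ from $t = 0$ and switch off at the time $t_s$ when the
controlled susceptible level crosses the epidemic threshold $S = \gamma /
\beta$, i.e. when the effective reproduction number reaches 1 and $I(t)$
peaks. The package implements that conclusion directly rather than solving
the costate boundary-value problem: `switching_time()` marches the
controlled system and returns the *first grid node* with $\beta S/\gamma
\le 1$ (no interpolation — the published schedules are quantized near grid
multiples, and the grid convention keeps every stage consistent), 0 if the
start is already subcritical, and the horizon with a warning if the
threshold is never crossed.

The variational argument is still checked, by exhaustive search instead of
calculus: `brute_force_switch_oracle()` simulates every candidate switch
time and minimizes $J$ among candidates meeting the feasibility filters.
Because $J$ decreases monotonically in the switch time while resource use
increases, the unconstrained minimizer is always "control forever"; the
problem only has an interior answer because the resource budget binds. The
oracle therefore accepts the cap $r_{\max}$ as a filter, and the test suite
budgets it at the threshold policy's own resource use — under which the
$J$-minimizing switch coincides with the threshold rule within one grid
step on all five quarter-day parameter sets.

Policy bookkeeping defaults: the episode-end threshold $I_{\min}$ defaults
to 1 %, horizons default to the event windows (12 d / 18 d), and the
objective and resource integrals use the trapezoidal rule on the Euler grid
(matching orders of accuracy).

**Initial conditions.** The registry pins $S(0) = R_0\gamma/\beta$ by
inverting the reproduction number, but no day-0 infected level is part of
the registry. Two documented modes exist: `complement`
($I(0) = 100 - S(0)$), the default, which reproduces the reported
Fort Myers–Naples baseline peak of about 55 % to within a point; and
`peak-calibrated`, which bisects $I(0)$ until the closed-form uncontrolled
peak matches a supplied target. The initial recovered compartments are 0 —
nothing in the source analysis suggests otherwise, and the choice is
flagged here rather than inferred from figures.

This reconstruction is also the package's main known limitation. The
acceptance script's recomputation lands the uncontrolled Fort Myers–Naples
Euler peak at 57.2 % (reported: 55 %; the 2.2-point gap decomposes into
0.9 points of reconstruction and 1.3 points of Euler overshoot), the
controlled peaks at 53.5 % and 44.9 % (reported: 48 % and 37 %), and the
Wilmington switching time at 4.54 days (reported: 3 days), while the four
Fort Myers–Naples switching times match the reported schedule within one
grid step. The controlled-peak and Wilmington gaps are not discretization
artifacts — they persist at $dt \to 0$ — and trace to the unrecoverable
day-0 conditions behind the original figures; the within-city orderings
(peaks falling and switch times shrinking as $u_{v,\max}$ grows) hold
throughout and are what the test suite enforces.

**Breakpoint readout.** Sweeping $u_{v,\max}$ and fitting two connected
line segments (hinge basis, exhaustive search over interior sample points
as the knot, least squares per knot) summarizes the diminishing returns;
the kink is read as the most effective rate under a resource constraint.
Exactly linear sweeps leave the knot unidentified: the fit then returns the
smallest interior candidate with a `degenerate` flag rather than
manufacturing a breakpoint.

## The synthetic generator

`generate_series()` emulates what a crowd-sourced aggregate feed looks
like: a constant-parameter SIR trajectory at the event cadence with
additive Gaussian observation noise on the percent scale, truncated to
$[0, 100]$, deterministic in the scenario seed. The default noise scale
(sd 2 percent) is a scenario choice consistent with the filter's default
measurement variance of 10; the true reporting error of real feeds is
unknown. `city_fixture()` wires the registry rows to the right cadence
(quarter-day/12-day for the Irma cities, hourly/18-day for Florence) with
the complement initial state.

What the generator deliberately does **not** emulate: reporting gaps and
irregular cadence, spatially correlated outages, demand feedback from
traffic, non-Gaussian or heteroscedastic reporting error, and time-varying
transmission. A single non-canonical variant — a transmission rate ramped
down from `surge_factor` $\times\,\beta$ to $\beta$ over the first two
days — exists purely to give the filter's tracking tests a moving target,
and is labelled as such. Consequently, passing tests demonstrate that the
pipeline recovers the truth *under its own model class with well-behaved
noise*; they do not certify performance on real feeds, where model error
dominates.

Identifiability degrades as noise grows: with the default tuning the
end-to-end check (filter + selection recovering each registry city's $R_0$
within 20 %) is exercised at noise sd 1, where it holds on essentially
every seed for all seven cities; toward sd 2 the high-$R_0$ hourly fixtures
(Wilmington-like shapes that saturate early) develop a flat error surface
in the $(\beta, \gamma)$ direction and individual seeds can miss by more
than 20 % even though the median error for the quarter-day fixtures stays
near 10 %.

## Problem sizes and test design

The suite runs entirely on generated data: quarter-day 12-day windows (49
points) for most checks, hourly 18-day windows (433 points) for the
Florence-cadence paths, 20 seeds for the median-recovery property, 5 seeds
× 7 cities for the end-to-end recovery invariant, and exhaustive oracles
(dense moment recomputation, double-loop MSE search, candidate-grid switch
search, normal-equations segment fits) kept deliberately independent of the
implementation code paths. Trajectory and series writers round-trip at
better than $10^{-9}$, and the command-line layer is smoke-tested
synth → estimate → control → sweep with byte-identical reruns under a fixed
seed.
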