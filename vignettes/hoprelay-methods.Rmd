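---
title: "The hopping-and-relay model of ParABS positioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hopping-and-relay model of ParABS positioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoprelay)
```

## The model

ParABS partitioning systems position low-copy plasmids at regular fractions
of the nucleoid — mid-nucleoid for one plasmid, the quarter positions for
two.  `hoprelay` implements a minimal agent-based model of this process
together with the trajectory-analysis toolkit used to characterise plasmid
dynamics.

The nucleoid is a 2D rectangle of length `L` by width `W`.  Cytosolic
ParA-ATP dimers (a well-mixed pool; their slow reconversion to the
DNA-binding-competent state justifies ignoring cytosolic space) bind the
nucleoid at rate `ka` at a uniformly random site, which becomes the dimer's
*home position*.  A bound dimer

* fluctuates elastically about its home with the exact over-damped-spring
  (Ornstein–Uhlenbeck) propagator — spring constant `1/sigma_x^2`
  (`1/sigma_y^2` across the width) and diffusion coefficient `DA`,
  representing chromosomal locus fluctuations;
* *hops*: both its position and its home receive a common Gaussian offset of
  variance `2*Dh*dt` per step, an effective description of transient
  unbinding and rebinding between DNA strands; and
* dissociates by basal ATP hydrolysis at rate `kd`.

The plasmid is a ParB-coated disk of radius `Rp`.  Whenever a bound dimer
(radius `RA`) comes within `Rp + RA` of the disk centre it tethers
instantly.  Tethered dimers are carried with the plasmid while their home
positions stay put, so each tether is a spring between the plasmid and a
fixed chromosomal anchor.  The plasmid moves by the same over-damped-spring
propagator with spring constant `n/sigma^2` for `n` tethers, equilibrium
point displaced by the mean tether extension, and intrinsic diffusion `Dp`
(pure diffusion when untethered).  ParB-stimulated hydrolysis breaks each
tether at rate `kh`, returning the dimer to the cytosol.  All positions
reflect at the nucleoid boundary.

Three dimensionless quantities organise the behaviour
(`dimensionless_params()`):

* `lambda = sqrt(2*Dh/kd) / (L/2)` — how far a dimer diffuses on the
  nucleoid, per axis, before basal hydrolysis, relative to half the
  nucleoid.  Only for `lambda >~ 1` can the diffusive flux of ParA into the
  plasmid carry information about the nucleoid geometry, enabling true
  regular positioning; with `n` plasmids the threshold variable is
  `lambda_n = n*lambda`.
* `epsilon = kh/kd` — stimulated relative to basal hydrolysis.  Large
  `epsilon` depletes ParA around the plasmid (a moving depletion zone drives
  oscillations when `lambda` is small); small `epsilon` lets ParA accumulate
  at the plasmid.
* `theta = nA*ka/(ka+kd)` — the steady-state number of nucleoid-bound dimers
  absent a plasmid.  It sets the noise scale but not the type of dynamics.

## Parameters

Defaults (`par_params()`) are the study's reference values, in um and s:
`ka = 0.19/s`, `kd = 0.01/s`, `Dp = 3e-3 um^2/s`, `DA = 0.01 um^2/s`,
`sigma_x = 0.1 um`, `sigma_y = 0.05 um`, `Rp = 0.05 um`, `RA = 0.002 um`,
`nA = 500`, `W = 0.95 um`, `dt = 1e-3 s`.  `kh` and `Dh` are the two swept
axes of the phase diagram and have no default; `par_preset()` provides the
published per-figure combinations (e.g. `"fig4"`, the parameter point fitted
to F-plasmid data: `kh = 0.5642/s`, `Dh = 0.056760 um^2/s`, `L = 2.53 um`,
giving `lambda = 2.66`, `epsilon = 56.42`).

Validation enforces `dt * max(ka, kd, kh) < 0.1`: event probabilities are
the linearised `rate*dt`, which is accurate in that regime and matches the
reference time step of 1 ms.

## Numerical design

* Elastic moves use the exact OU transition density, not an Euler step, so
  the time step only enters through event probabilities and the
  tether-formation / force-update coupling.
* The sub-step order within `dt` is fixed: association, basal dissociation,
  tether breakage, bound-dimer motion, tether formation, plasmid motion,
  boundary reflection.  No order is canonical on physical grounds; any
  reordering changes results at `O(dt^2)`.
* The plasmid's equilibrium point and tether count are held fixed within one
  step (quasi-static force) and recomputed every step.
* Boundaries reflect dimer positions, home positions and plasmid centres;
  reflection conserves dimer number.
* The stepper carries its own random stream (xoshiro256++ with a ziggurat
  normal sampler) inside the simulation state, making every run
  bit-reproducible from its seed, resumable mid-run (used for replication
  events), and independent of R's global RNG.  The sampler is validated in
  the test suite against distributional moments and the closed-form
  stationary variance of a single bound dimer.
* Burn-in defaults to 600 s (about six basal-hydrolysis lifetimes); event
  counters reset when it ends, so ATP-consumption rates refer to the
  production window only.

## Behaviour of tethered dimers: a deliberately examined choice

The one genuinely under-determined ingredient is how a tethered dimer moves.
Three schemes are implemented (`tether_mode` in `par_run()`):

* **fixed** (default): the dimer is pinned to the plasmid and translates
  rigidly with it; its home stays put.  Each tether spring then relaxes
  through plasmid motion — the relay mechanism, and the scheme consistent
  with the model's DNA-relay ancestry.
* **hopping**: as above, but the home keeps hopping while tethered.  The
  anchors then perform a random walk that feeds directly into plasmid
  mobility: at the fitted parameter point this inflates the apparent
  diffusion coefficient roughly tenfold and destroys the quantitative
  agreement.
* **relay**: the tethered dimer keeps fluctuating about a frozen home and
  only transmits force.  Tether extensions then average to zero over the
  ~1 s locus-fluctuation time and the plasmid receives almost no positional
  information: regular positioning disappears entirely.

Only **fixed** produces spring-like regular positioning at the fitted point,
which is why it is the default; the alternatives remain available for
exploration.

## Trajectory analysis

`spring_fit()` is the package's model-fitting interface.  Step-wise
velocities `v_i = (x_{i+1} - x_i)/dt` are paired with positions relative to
the trajectory mean; a line is fitted by ordinary least squares on the raw
pairs inside the smallest symmetric central region holding at least 68.27%
of points (OLS on raw pairs rather than binned means maximises data use and
matches the closed-form slope; binned statistics are computed separately for
display).  The slope `m` and residual variance invert to

* `tau = -dt/log(dt*m + 1)` — the relaxation time;
* `D = Var[v] * log(dt*m + 1) / (dt*m^2 + 2*m)` — the diffusion
  coefficient;
* `k/kBT = 1/(D*tau)` — the effective spring constant, and the
  characteristic force `kBT*sqrt(k/kBT)` at one standard deviation of the
  equilibrium distribution.

Closed-form position and velocity autocorrelations (`autocorr_models()`),
the transition density, and time-averaged MSD complete the over-damped
spring toolkit.  Note one estimator property relevant when comparing fits
across trajectory lengths: centring each finite trajectory on its own mean
biases the fitted slope towards faster relaxation (the finite-sample AR(1)
bias), for simulated and experimental tracks alike; fits should therefore be
compared between data sets of similar length, as is done here (35-min
windows throughout).

## Regime descriptors and classifiers

For a trajectory with `n` plasmids on a nucleoid of length `L`
(`regime_descriptors()`):

* `phi = 1 - 2*|frac(n*x/L) - 0.5|` of the mean position `x` — 1 at the
  regular positions, 0 at the poles and midway between them.  (The
  published formula omits the absolute value, but its stated endpoint
  values force this form.)
* `psi` = position sd divided by `L/(n*sqrt(12))`, the sd of a uniform
  distribution of width `L/n` — near 1 for a trajectory sweeping its share
  of the nucleoid, small when confined.  (The typeset denominator "L/12n"
  contradicts its own parenthetical definition and is rejected.)  `psi` is
  clamped at 1 when forming scores so that `1 - psi` stays non-negative.
* `chi` — from the normalised position autocorrelation over lags up to half
  the series length: the highest positive local maximum after the first
  negative local minimum, 0 if either is absent.  Extrema are detected by
  sign changes of first differences.

Scores: regular `(1-psi)*phi`, static `(1-psi)*(1-phi)`, oscillation `chi`;
the dominant regime is the argmax, or "diffusive" when all scores are below
0.1.  Display colours blend light brown / blue / pink by score, black when
all are ~0.

Because `phi` evaluates the *mean* position, a plasmid that simply never
moves from a mid-nucleoid start would score as regularly positioned.  Where
the static regime is a live possibility (`phase_grid()` over low epsilon,
and the static/oscillatory/regular preset checks), probes therefore start
plasmids off-target at `L/6`, where an immobile trajectory scores static
and only genuine repositioning scores regular.  The lambda-threshold probe,
which works at the fitted epsilon where no static regime exists, instead
starts plasmids at their regular positions and asks whether the
configuration is *held* (low psi with high phi); this avoids conflating the
threshold question with the time needed for initially coincident plasmids
to separate.  Single-track classifications at reduced dimer counts carry
two known artifacts, both damped by classifying on seed-ensembles: the
sampling noise of chi (a positive floor of roughly 0.1-0.3 on 35-sample
tracks, which blurs the diffusive/oscillatory distinction), and inflated
mobility (fewer tethers make the plasmid faster, so the static point
creeps towards mid-nucleoid within 35 min below a few hundred dimers —
static calls therefore keep the full dimer count).

`phase_grid()` realises `lambda` through `Dh = (lambda*L/2)^2*kd/2` and
`epsilon` through `kh = epsilon*kd`, runs seeded simulations per cell and
averages descriptors over seeds.  Optional display smoothing (morphological
opening, 3x3 box, then a Gaussian of one cell) uses EBImage and is never
applied before numeric analysis.

The sliding-window classifier (`classify_segments()`) labels the centre of
each 12-sample window oscillatory when the window's lag-1 velocity
autocorrelation is positive (processive motion) and regularly positioned
otherwise (elastic motion has negative lag-1 velocity autocorrelation at
every relaxation time); runs of at least 6 equal labels form segments.
Window autocorrelations are mean-subtracted within the window, matching the
global estimator; whether the original procedure subtracted the window mean
is not documented, and with 11 velocities per window the difference is
small.  The centre of the even window is taken as index `window/2` (0-based
6).  Both defaults follow the published choice; small windows are known to
produce occasional false-positive oscillatory points.

## Synthetic data

`synthetic_spec()` + `gen_ou()` / `gen_diffusion()` / `gen_triangle()`
generate ground-truth tracks for every analysis stage: exact-discretisation
OU (no Euler error, so estimator tests carry no discretisation confound),
reflected pure diffusion, and noisy triangle waves emulating the
oscillatory regime's constant-speed shuttling.  Defaults mirror the
experimental scales: 60 s sampling, D of order 2e-4 um^2/s, tau of order
2 min, 35–100 samples per track.  What these generators do *not* emulate:
cell growth and division, replication-driven plasmid number changes,
segmentation/tracking noise beyond additive Gaussian error, and any
coupling between position and cell length.  Passing classifier tests on
them therefore demonstrates correctness of the estimators on their
idealised generating models, not performance on microscopy data.

## Problem sizes used in checks

The test suite and the acceptance script keep the full 500-dimer count for
the quantitative fitted-point ensemble and the no-plasmid binding check,
and use 50–200 dimers with 35-min productions for regime-classification
probes — the dynamical regimes are robust from a few tens of dimers, while
quantities like positioning precision are compared only at the full count.
Phase probes use 3–5 seeds per parameter point and majority vote; the
oscillatory-regime preset is probed with 70-min runs sampled at 30 s so the
position autocorrelation spans several oscillation periods.

## Known limitations

* 2D geometry with a static nucleoid: no growth within a run, no explicit
  ParB molecules or CTP mechanics, no ParA-ADP intermediate, no
  force-dependent bond breakage or tether-length limit, torque ignored.
* The simulator reproduces the *type* of dynamics robustly, but emergent
  quantitative timescales (the effective spring constant and relaxation
  time at the fitted point) depend at the factor-of-~2 level on
  under-documented scheme details such as the tethered-dimer rule above;
  see the acceptance outputs for the values this implementation actually
  produces.
* Descriptor conventions for `chi` (extremum detection, maximum lag) are
  the package's own documented choices where the original ones are
  unpublished.
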