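---
title: "Measuring cortex coupling and predicting advective segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cortex coupling and predicting advective segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corflow)
```

This vignette is the package's account of its science: the measurement
model behind the coupling-coefficient estimator, the transport model behind
the segregation predictions, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## The measurement problem

Cortical actomyosin in the *C. elegans* zygote flows from the posterior
toward the anterior pole during polarity establishment, and membrane
proteins that couple to this motion are carried with it. Whether a given
molecule is transported depends on three things that are easy to conflate
in images: how strongly its motion is entrained by the cortex, how fast it
diffuses in the membrane, and how long it stays membrane-bound at all.
The package separates them.

A step of a tracked particle over lag $\tau$ is decomposed in the frame of
the local flow vector (from PIV of the cortical channel, sampled at the
step's start position and time): $\Delta x$ parallel to the flow,
$\Delta y$ perpendicular. Under lateral diffusion with drift both are
Gaussian; perpendicular motion is purely diffusive, so

$$\upsilon_x = \langle\Delta x\rangle/\tau, \qquad
  \upsilon_y = \langle\Delta y\rangle/\tau \approx 0, \qquad
  cc = \upsilon_x/\bar\nu,$$

where $\bar\nu$ is the mean local flow speed over the fitted steps. The
estimator needs pooled steps because advective displacement per step
($\sim \nu\tau \approx 0.05\,\mu m$ at $\tau = 0.5$ s) is much smaller than
the diffusive spread ($\sqrt{2D\tau} \approx 0.3\,\mu m$ at
$D = 0.1\,\mu m^2/s$); the signal lives in the mean of many steps, not in
any single trajectory.

Parameters that matter, with defaults:

* advection lag `tau_frames = 5` — larger lags raise the advection:diffusion
  ratio linearly but cost steps (tracks end by dissociation and
  photobleaching); 5 frames balances the two for 0.1 s frame intervals.
* diffusion lag `tau_frames = 2` for $D_{ss}$ from step sizes; while flow is
  active only the perpendicular component is used
  ($\langle\Delta y^2\rangle = 2D\tau$), which removes the advective
  contribution exactly rather than approximately.
* `speed_floor = 0.01` µm/s — below this the flow direction is numerically
  meaningless and steps are flagged out of the cc fit.
* `min_samples = 200` for a fit; the Gaussian mean/SD are estimated
  unbinned (maximum likelihood), with a binned least-squares Gaussian fit
  computed as a cross-check. The two estimate the same parameter; the tests
  require agreement, and the unbinned estimate is the reported one because
  it has no binning tuning at all.

Statistical power: with $n$ pooled displacement pairs, drift is detectable
when $v\tau/\sqrt{2D\tau/n}$ clears the t-threshold. `detection_power()`
simulates this directly; at $v = 0.1$ µm/s and $\tau = 0.5$ s, single sets
of 1,000 steps lose reliable detection around
$D \approx 0.2\text{–}0.3\,\mu m^2/s$, and pooling ten such sets (the
realistic multi-embryo scenario) extends it well past $1\,\mu m^2/s$. PAR
protein diffusivities sit below $0.2\,\mu m^2/s$, safely inside the
detectable regime.

## The transport model

Segregation is predicted by a single-species model on a 1D membrane of
length $L = 60$ µm (position $x$ from the anterior pole) exchanging with a
well-mixed cytoplasm:

$$\partial_t A = D\,\partial_x^2 A + \partial_x(vA) + k_{on}A_{cyt}
  - k_{off}A, \qquad A_{cyt} = \rho_A - \psi\bar A,$$

with $\rho_A = 1.56\,\mu m^{-3}$, $\psi = 0.174\,\mu m^{-1}$ and
$k_{on} = k_{off}$ by default, so the uniform equilibrium is
$A^\* = \rho_A/(1+\psi) = 1.3288$. The flow profile

$$v(x) = \frac{60-x}{74}e^{-(60-x)^2/391} - \frac{x}{1000}e^{-x^2/100}$$

is an empirical fit to measured cortical flow (peak $\approx 0.115$ µm/s
near $x = 46$ µm, vanishing at both poles); with the $+\partial_x(vA)$ sign
convention positive $v$ transports mass toward the anterior. Flow is
active for `t_flow = 500` s — the duration of the establishment phase —
then set to zero everywhere and the system relaxes for `t_post` seconds.
There is deliberately no feedback in the model: it isolates what advection
plus membrane kinetics alone can do.

Metrics use the anterior- and posterior-most 30% of the membrane:
$ASI = (A-P)/(2(A+P))$ (maximum 0.5 at complete posterior clearance) and
posterior depletion $1 - P/\langle I\rangle$ (maximum 1). Both conventions
with and without these normalisations circulate; the package defaults to
the forms whose stated maxima (0.5, 1.0) are self-consistent with the
reference predictions, and `convention = "methods"` switches to the raw
$(A-P)/(A+P)$ and $P/\langle I\rangle$ forms. Decay half-times are first
crossings of half the end-of-flow value, linearly interpolated between
output samples, with an exponential-decay fit reported as a cross-check;
first-crossing is robust to the decay being non-exponential early on.

At the PAR-2-like reference point ($D = 0.1$, $k_{off} = 0.005$) the model
gives end-of-flow ASI ≈ 0.256, posterior depletion ≈ 0.635 and an ASI decay
half-time ≈ 108 s; segregation efficiency changes by about 1% when $D$
drops from 0.08 to 0.005 $\mu m^2/s$ but collapses for
$k_{off} \gtrsim 0.1\,s^{-1}$ — membrane residence time, not diffusivity,
is the controlling variable in this regime.

The two-state variant (`solve_two_state()`) splits binding events
`fraction_fast : 1 - fraction_fast` between fast- and slow-dissociating
membrane states sharing one cytoplasmic pool, keeping the total binding
rate at the single-species reference. At steady state membrane occupancy
weights each class by $f/k_{off}$, so slow exchangers dominate the
membrane even as a small minority of binding events (99% fast binding at
$k_{off,slow} = 10^{-3}$, $k_{off,fast} = 1$ still leaves 91% of membrane
molecules slow), and the mixture segregates like its slow component.

## Numerics

Space: conservative finite volumes, `n_grid = 400` cells
($\Delta x = 0.15$ µm), diffusive and advective fluxes both zero at the
poles (the flow profile itself vanishes there, so zero-flux is the natural
mass-conserving choice for the unstated boundary condition). Advective
face values are second-order central averages; a first-order upwind
fallback engages automatically if central interpolation ever produces
negative concentrations beyond tolerance (it does not at the parameter
ranges swept here, but the guard keeps extreme corners of phase diagrams
safe). Mass closure $\psi\bar A + A_{cyt} = \rho_A$ holds algebraically;
grid convergence is < 1% on peak ASI between 200 and 400 cells.

Time: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`, integration
split at the flow-off discontinuity. lsoda is the default because the
explicit adaptive Runge–Kutta pair (`method = "ode45"`, also supported and
agreeing to five decimals at the reference set) becomes impractically slow
when large $D$ makes the semi-discrete system stiff, as in phase-diagram
sweeps up to $D = 10\,\mu m^2/s$.

The half-time reported for a metric that never falls to half its
end-of-flow value within `t_post` is `Inf`, not an extrapolation.

## The synthetic data, and what passing tests mean

`simulate_trajectories()` emulates the particle side of a near-TIRF
experiment: a constant number of particles (replacement on dissociation
models binding from an effectively infinite cytoplasmic pool), Gaussian
diffusive steps with per-particle diffusivity, deterministic advective
offset $v\Delta t$, exponential lifetimes. Per-particle diffusivities are
log-normal with the requested mean and CV — the distribution family is a
package choice (it guarantees positivity; `cv_D = 0` recovers a common
$D$). Replacement positions are uniform over the field of view. No spatial
boundary is enforced on motion; the renderer instead pads its canvas 6 px
beyond the largest excursion so nothing is clipped.

`render_images()` draws each particle as a Gaussian of width
`psf_sigma = 1.3` px with amplitude `spot_amplitude` on Gaussian camera
background. `render_cortex_texture()` warps a fixed smoothed-noise speckle
(correlation length 1 px) by the flow field with bilinear subpixel
sampling, giving the PIV stage a channel with exactly known motion.
Background SNR and spot amplitude are repository defaults validated only
through estimator-recovery tests, since realistic values vary per
microscope.

What this does not emulate: Poisson shot noise and EMCCD gain cascades,
photobleaching of individual spots, out-of-focus and autofluorescent
background structure, embryo curvature, or flow fields with strong shear
at the interrogation-window scale. Passing the round-trip tests therefore
demonstrates that the estimators are correct and unbiased on data obeying
their own assumptions — it does not certify accuracy on any particular
microscope's noise, where detection thresholds (deliberately left as a
required user parameter) must be set empirically.

## PIV simplifications

The flow field is estimated by two-pass FFT cross-correlation (windows 64
then 32 px, the second pass offset by the rounded first-pass estimate),
3-point Gaussian subpixel fits per axis (parabolic fallback when a
neighbour correlation is non-positive, and the correlation pedestal is
removed by median subtraction first), vectors every 16 px, bicubic
(Catmull–Rom) spatial interpolation for lookups and nearest-frame temporal
lookup (fields are already 2-frame rolling-averaged, so temporal
interpolation beyond nearest adds nothing). Post-filters run in a fixed
order — manual velocity limit first, then the per-frame 5-SD filter — and
removed vectors are refilled iteratively from valid neighbours; the
replaced fraction is reported as a diagnostic. Linear window deformation
and 2D Gaussian peak fits found in full PIV packages are intentionally
omitted: they matter for strongly sheared flows, while the validation
flows here are mild, and the simplified scheme is testable against exact
translations (recovery within 0.05 px/frame at slow speeds, 0.2 px/frame
in stress tests). Bleach correction divides each frame by its mean — the
simplest correction consistent with "bleach corrected" pipelines whose
exact method is rarely reported.

One caveat discovered in validation: cross-correlating rolling-averaged
frames of a *fast* translation (≥ 1 px/frame) creates a zero-lag
correlation sidelobe that biases the subpixel fit; at the slow cortical
speeds the defaults target (≤ 0.3 px/frame, the manual velocity limit)
the sidelobes merge symmetrically and no bias occurs. Validation at
stress-test speeds uses `time_average = 1`.

## Tracking choices

Detection is Crocker–Grier style: boxcar background subtraction at the
feature scale plus 1 px Gaussian smoothing, local maxima above the user
threshold, iterative intensity-weighted centroiding (≤ 10 iterations,
$10^{-3}$ px convergence), merging of detections closer than
`min_separation` toward the brighter one. Linking minimises total squared
displacement among candidate pairs within `max_displacement`; conflict
components are solved exactly when small and greedily otherwise, with
exact distance ties broken toward the lower particle id so runs are
reproducible. `memory = 0` (no gap closing) is the only implemented
linking memory — a vanished particle ends its track — matching how
single-molecule data with fast exchange are usually processed; the
parameter exists so configs carry it explicitly.

## Image-side quantification

Straightened-membrane cross-sections are fit to a Gaussian (membrane) plus
error-function step (cytoplasm) sharing one centre and width,
$a\,e^{-(d-c)^2/2w^2} + b\,[1-\mathrm{erf}((d-c)/\sqrt{2}w)]/2 + o$; the
shared centre/width linkage is a stabilising choice where the exact
parameterisation is unspecified, and is recorded in the fit's metadata.
Membrane concentration is the Gaussian amplitude $a$, cytoplasm the
plateau $b$; non-convergent positions are flagged and interpolated from
neighbours. FRAP curves are normalised bleached/control then to pre-bleach,
and fit to $I(t) = P(1-e^{-t/\tau})$ with $k_{off} = 1/\tau$; the 95% CI
comes from the fit covariance, and coverage is verified on noisy synthetic
repeats. Flat (unbleached) and non-recovering curves are rejected as
degenerate rather than fit.

## Problem sizes used in the test-suite and acceptance runs

Simulations in the shipped tests use 100–300 particles for 5–10 s at 0.1 s
frame intervals (10⁴–4×10⁴ displacement steps per fit), PIV validation
uses 192×192 px frames, the reference PDE runs use 400 grid cells over
2,000 s, and stochastic recovery checks average 20 replicates of 1,000
displacements per diffusivity. These sizes put Monte-Carlo error well
below the tolerances being asserted while keeping the whole suite quick to
run; all of them scale up by changing the corresponding arguments.

## Known limitations

* No feedback, mutual antagonism, or 2D/3D geometry in the PDE — it
  quantifies pure advection + exchange, by design.
* The estimator assumes the PIV field is the particles' advective frame;
  systematic PIV bias propagates into cc one-to-one.
* Gap closing (`memory > 0`), anomalous-diffusion MSD models, and
  autofluorescence correction of raw embryo images are out of scope;
  straightened-membrane matrices are expected as input for profile
  quantification.
* Rendering omits shot noise; detection thresholds must be tuned per
  imaging condition.
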