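---
title: "Models and numerical methods in scafmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in scafmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafmech)
```

scafmech analyses scaffold-coupled electrical-stimulation experiments on
conductive foam scaffolds along four axes: unconfined-compression dynamic
mechanical analysis (DMA), hysteresis energy dissipation, microCT-style
binary-volume morphometry, and image-based transport (tortuosity) feeding
an effective electric-field estimate.  Because raw bioreactor traces and
CT reconstructions from such studies are rarely deposited, the package
ships seeded synthetic generators whose ground truth is known in closed
form; every analysis operation is validated against those closed forms or
against independent brute-force oracles.

## The viscoelastic material model

The simulator represents a specimen as a generalized Maxwell (Prony
series) solid with relaxation modulus

$$E(t) = E_\infty + \sum_i E_i\, e^{-t/\tau_i},$$

an equilibrium spring $E_\infty$ in parallel with Maxwell arms
$(E_i, \tau_i)$.  Stress under an arbitrary strain history is the
Boltzmann hereditary integral, discretized by the exact exponential
recursive update per arm (piecewise-linear strain between samples):

$$q_i^{k} = e^{-\Delta t/\tau_i}\, q_i^{k-1}
  + E_i \frac{\tau_i}{\Delta t}\bigl(1 - e^{-\Delta t/\tau_i}\bigr)
    \Delta\varepsilon_k .$$

This update is unconditionally stable and exact for linear ramps, unlike a
naive convolution quadrature.  The frequency-domain closed forms
($E'$, $E''$, $|E^*| = \sqrt{E'^2+E''^2}$,
$\delta = \operatorname{atan2}(E'', E')$) are implemented independently in
`prony_dynamic_modulus()` and serve as the oracle for the time-domain
path: the test suite requires steady-state amplitude and phase agreement
within 1% and endpoint recovery within 3% / 0.02 rad on a 20-material
seeded grid.

### The loading protocol

`dma_protocol()` encodes the testing schedule with these defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| preconditioning peak strain | 0.14 | - | standard cyclic preconditioning amplitude for these constructs |
| preconditioning frequency | 0.5 | Hz | quasi-physiological slow cycling |
| preconditioning cycles | 8 | - | the first/eighth cycle comparison needs eight |
| rest | 5 | s | recovery pause between preconditioning and the ramp |
| ramp target strain | 0.12 | - | held strain for stress relaxation |
| ramp duration | 1.2 | s | ramps at the same 10%/s used dynamically |
| relaxation hold | 120 | s | long enough for arms with tau up to ~20 s to decay |
| dynamic amplitude | 0.01 | - | small-strain linear regime |
| dynamic strain velocity | 0.10 | 1/s | peak velocity of the sinusoid |
| dynamic cycles | 10 | - | leaves >= 3 steady-state cycles to fit |
| sample rate | 500 | Hz | >= 50 samples per preconditioning cycle |

The dynamic frequency is derived, not set: for
$\varepsilon = \varepsilon_{hold} + a \sin\omega t$ the peak strain
velocity is $a\omega$, so $f_{dyn} = v/(2\pi a) \approx 1.59$ Hz.  The
preconditioning waveform is the offset sinusoid
$\tfrac12\varepsilon_{peak}(1-\cos 2\pi f t)$ starting from zero strain -
the natural zero-mean-rate choice when only the peak strain and frequency
are specified.  The small preload used to detect contact defines the
thickness datum; the preload strain itself is excluded from reported
strains (strain is measured from the contact datum).

Stress noise is additive Gaussian; the cohort generators default to an sd
of 0.5% of the peak preconditioning stress, the order of a good load
cell's noise floor relative to signal.

## DMA endpoint extraction

* **Compressive linear modulus** - the maximum of the numerical stress-strain
  derivative over the loading arc of the final preconditioning cycle,
  reported as the ordinary-least-squares slope of the 12 samples around
  the peak (6 before, 6 after, window shifted inward - never shrunk - at
  arc boundaries; first occurrence wins ties).  Because a sinusoidal arc
  has vanishing strain rate at its turning points, raw difference
  quotients there divide by near-zero increments and explode under noise;
  samples below 20% of the arc's peak strain rate are excluded and the
  peak is located on an 11-sample running mean of the derivative.  The
  least-squares fit itself uses raw samples.  This endpoint remains the
  most noise-sensitive of the five - a property of derivative estimation,
  not of the implementation - and its per-fit $R^2$ is carried in the
  diagnostics.
* **Equilibrium modulus** - mean stress over the final 10 s of the hold
  divided by the held strain (read from the trace, never hard-coded).
  With $\tau \le 20$ s the residual transient after 120 s is below
  $e^{-6}$.
* **Stress relaxation %** - $100(\sigma_{peak}-\sigma_{eq})/\sigma_{peak}$
  with $\sigma_{peak}$ searched over the ramp plus the first second of the
  hold (to catch the overshoot directly after compression).  Validation
  against the step-response closed form
  $100\sum E_i/(E_\infty+\sum E_i)$ is run on ramp-and-hold inputs:
  cyclic preconditioning leaves genuine arm memory (a few percent of peak
  stress survives the 5 s rest) that the step formula does not model, so
  including it would test the material, not the extraction.
* **Dynamic modulus and phase** - stress and strain over the last three
  dynamic cycles are each fit by $y = c + a\sin\omega t + b\cos\omega t$
  via linear least squares at the known protocol frequency (deterministic,
  no nonlinear search); $|E^*| = \sigma_0/\varepsilon_0$ and
  $\delta = \phi_\sigma - \phi_\varepsilon$ wrapped into $[0,\pi)$ so
  passive materials report a positive lag.  Phase is always reported in
  radians, named explicitly in the output.

## Hysteresis energetics

Each preconditioning cycle is split at its strain maximum into loading and
unloading arcs.  The dissipated energy density is the closed cycle
integral $\oint\sigma\,d\varepsilon$ by the trapezoid rule (the loop is
closed back to its first sample), reported positive in kJ/m^3; a signed
value below $-10^{-9}$ raises an error rather than being silently
flipped, so orientation bugs surface.  The strain energy is the trapezoid
area under the loading arc.  On a constructed stress-strain ellipse the
trapezoid area matches $\pi\sigma_0\varepsilon_0\sin\delta$ within 0.5%
at 200 samples per cycle with observed convergence order about 2.

The per-cycle energies over time are fit with

$$y_{fit} = A e^{-t/\tau} + y_0,$$

by bounded Levenberg-Marquardt least squares (`minpack.lm`), with
$A \ge 0$, $\tau > 0$, a fixed initializer
($y_0^0 = \min y$, $A^0 = y(t_1)-y_0^0$, $\tau^0 = \mathrm{span}/3$) and
three deterministic restarts ($\tau^0 \times \{0.3, 1, 3\}$) - no
randomness.  Diagnostics follow the conventions of the source analyses:
$\mathrm{RMSE} = \sqrt{SSE/n}$, $R^2$, and the regression F statistic
against the intercept-only model with $df = (2, n-3)$.  The normalized
($y_{fit}/A$) and adjusted ($(y_{fit}-y_0)/A = e^{-t/\tau}$) series are
attached; their defining algebra is asserted to $10^{-12}$ in the tests.
A flat series returns $A = 0$ with $\tau$ flagged unidentifiable instead
of a spurious fit.  Energies are computed in J/m^3 (Pa times strain) and
reported in kJ/m^3; when the series is normalized by the cycle-1 peak
stress (in kPa) both the raw and normalized fits are available, since the
two conventions coexist in practice.  The decay time axis is the cycle
end time (t = 2 s after the first 0.5 Hz compression).

## Synthetic volumes: what they emulate and what they do not

`generate_foam_volume()` emulates an open-cell conductive foam as a
random strut network: seeded nodes (two pinned to every grid face so the
network reaches the boundaries), a 3-nearest-neighbour graph augmented
with its minimum spanning tree for guaranteed connectivity, edges
rasterized as cylinders, and the strut radius set by order-statistic
thresholding of the distance-to-network field so realized porosity matches
the target to well under 0.5 percentage points.  A thresholded smooth
random field - the other common stand-in - cannot percolate at 97%
porosity (the solid fraction is far below the continuum percolation
threshold), which would make the percolation and tortuosity operations
degenerate; a connected strut network is also the better geometric analogue
of CVD graphene foam.  At desk-scale grids (up to 128^3) the network is
finer-grained than real foam at matching porosity - struts come out
around 3-4 um rather than 10 um at 2.43 um voxels - so passing tests
demonstrate correct morphometry and transport on known geometry, not
CT realism.  No CT noise, beam hardening or reconstruction artifacts are
modelled, and the generator is not a physical growth model.

Cells are seeded as spherical blobs in the void phase, mutually disjoint,
optionally required to touch the foam (gold-labelled adherent cells);
analytic phantoms (sphere, torus, slab, cylinder, straight and serpentine
channels, disjoint blobs) carry closed-form truth records and are the
oracle fixtures throughout.

## Morphometry conventions

* Foreground connectivity is 26, background 6 (the standard complementary
  pairing), for both component counting and topology.
* The Euler characteristic is computed exactly by vertex/edge/face/cell
  counting on the cubical complex of the foreground (diagonal contacts
  share vertices, matching 26-connectivity).  Connectivity is $1-\chi$
  and $\mathrm{Conn.Dn} = (1-\chi)/TV$ - the Euler-based convention of CT
  bone morphometry, stated prominently because commercial tools do not
  document theirs; absolute agreement with any particular commercial
  pipeline is therefore not claimed.
* Surface area uses a marching-tetrahedra triangulated isosurface at
  level 0.5 after Gaussian pre-smoothing with sigma = 1.0 voxel.  Meshing
  the raw binary staircase overestimates a sphere's area by about 27%;
  the smoothing bandwidth was calibrated once on sphere/cube/torus
  phantoms (sphere error falls from -2% at r = 10 voxels to +0.2% at
  r = 30; cube about -3%).  Voxel-face counting (about 1.5x bias on curved
  phases) is available behind a flag for cross-checks.
* Local thickness is the largest-inscribed-sphere definition: exact
  Euclidean distance transform, then largest-first sphere painting.  A
  sphere whose centre sits at distance $r$ from the nearest background
  voxel centre paints diameter $2r-1$ voxels, which makes an $n$-voxel
  slab report exactly $n$ - the calibration that matters for plate-like
  structures; the grid boundary counts as background.
* Threshold windows are inclusive on both ends.  With the conventional
  scaffold window 25-115 and cell window 115-255 the shared level 115 is
  assigned to the cell window (use 25-114 for the scaffold when
  segmenting both phases).
* TV is the full grid volume; irregular regions of interest are out of
  scope for this version.

## Transport and the effective field

The tortuosity solver discretizes the steady-state Laplace equation with
voxel-centred finite volumes on the conducting phase only: unit links
between adjacent phase voxels, Dirichlet values imposed through half-voxel
links on the inlet (c = 1) and outlet (c = 0) faces, and periodic (default)
or insulating lateral boundaries.  Components touching neither face carry
no flux and are excluded (they would make the system singular).  The
symmetric positive-definite system is solved by diagonally preconditioned
conjugate gradients with deterministic iteration order (a sparse direct
solve is retained as the cross-check oracle; the two agree to 1e-8 on
16^3 grids in the tests).  Convergence is reported as the relative
inlet/outlet flux mismatch against a 1e-6 tolerance.  The tortuosity
factor follows the effective-diffusivity convention

$$D_{eff} = D\,\varepsilon/\tau \quad\Longleftrightarrow\quad
  \tau = \varepsilon\,/\,(D_{eff}/D),$$

a transport reduction factor.  It is often paraphrased as paths being
"$\tau$ times longer", which conflates it with the geometric path-length
ratio ($\tau \approx (L_e/L)^2$ for a single thin channel); the package
documents the transport definition and does not replicate the conflation.

The effective stimulation field divides the nominal field by the
tortuosity factor:

$$E_{eff} = \frac{V_{RMS}}{(d/10)\,\tau}\ \ [\mathrm{mV/cm}],$$

with the electrode distance $d$ in mm (3.17 mm default).  This is a
deliberately simple, swappable policy: published per-condition field
values in this literature are not always mutually consistent with a
single $(V, d, \tau)$ formula (they typically involve per-replicate
averaging), so the package exposes the formula explicitly rather than
guessing a hidden one.  The biphasic square stimulus is generated with a
50/50 duty cycle and no interphase gap; its RMS equals $v_{pp}/2$
exactly, which the tests assert.

## Cohort statistics

One-way ANOVA (`stats::aov`) with Tukey HSD post-hoc comparisons and
post-hoc power from the observed effect size (Cohen's
$f^2 = \eta^2/(1-\eta^2)$, noncentrality $f^2 N$) at alpha = 0.05; paired
two-sided t-tests for the cycle-1 versus cycle-8 energy comparison.  No
additional multiplicity layer is added beyond Tukey.  Group sizes are
configurable per group in the pipeline config rather than assumed equal.
Null calibration is part of the test suite: over 1000 seeded null
replicates the ANOVA type-I error must land in [0.03, 0.07] and the
paired-t null p-values must be near-uniform (Kolmogorov distance < 0.05).

## Determinism and problem sizes

Every stochastic generator takes an integer seed and restores the RNG
state afterwards (`withr::with_seed`).  The pipeline derives per-specimen
sub-seeds as `seed * 1000 + counter` in listing order, so appending a
specimen never perturbs existing ones; manifests record the derived seeds
and MD5 hashes of all outputs, and identical configs reproduce
byte-identical output.  The shipped validation suite runs at desk scale:
20-material oracle grids at 500 Hz sampling (about 74k samples per
trace), foam volumes up to 128^3, transport phantoms up to 40^3 with a
16^3 direct-solve cross-check, and 1000-replicate null calibrations -
sizes chosen so the whole suite completes in a few minutes on one core
while still exercising every code path at meaningful resolution.

## Known limitations

* Linear viscoelasticity only: no poroelastic/biphasic constitutive
  fitting, no finite-strain corrections, no load-frame compliance model.
* The foam generator is geometric, not physical; structure thickness at
  matching porosity is finer than real CVD foam (see above).
* Voxels are isotropic; anisotropic spacing is unsupported.
* The compressive (maximum-derivative) modulus is intrinsically
  noise-sensitive; treat its cohort variance as expected behaviour.
* No electrical double-layer, electrode-kinetics or media-conductivity
  modelling behind the effective-field policy.
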