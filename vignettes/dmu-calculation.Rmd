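---
title: "Monitor-unit calculation for a double-scattering proton beamline: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitor-unit calculation for a double-scattering proton beamline: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind protonDMU, the assumptions it
makes, the parameters that matter, and the numerical and design choices a
maintainer would want to know about. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The factorized monitor-unit model

The dose per monitor unit (DMU) in a patient-specific double-scattering
field is written as a measured anchor times three factors:

$$\mathrm{DMU}_{clinical} = \mathrm{DMU}_{STD}\times F_{BSD}\times
F_{PSD}\times F_{FS}(A).$$

The decomposition matches how a passive beamline is actually commissioned:

* $F_{BSD}$ covers everything the *common* beam-spreading devices (scatterers,
  ridge filter, range shifter) do to the output. Those combinations are few,
  so the factor is measured once per (energy, SOBP width, RS thickness) node
  and looked up. Energy and SOBP width are categorical — discrete hardware —
  so `lookup_fbsd()` interpolates linearly in RS thickness only and refuses
  to extrapolate beyond the measured RS range (a safety-critical quantity).
* $F_{PSD}$ covers the patient-specific devices (aperture, compensator, air
  gap). There are infinitely many of them, so it is *calculated*: the ratio
  of two simplified-Monte-Carlo (SMC) outputs, the fully patient-specific
  condition over the matching beam-spreading-only condition. Taking a ratio
  of two simulations of the same beam cancels most engine model error.
* $F_{FS}(A)$ is an empirical correction for what the transport model misses
  at small field sizes (mainly collimator edge scatter, which the engine
  deliberately does not model — protons outside the opening are simply
  terminated). It is the ratio of the measured to the calculated
  field-size curve, both normalized at the 185 mm standard square, indexed
  by the **mean aperture radius** so that irregular clinical apertures map
  onto the measured square series.

Only $F_{PSD}$ (and the calculated field-size curve) carry Monte Carlo
uncertainty; $F_{BSD}$ and the measured field-size curve are treated as
exact measured inputs, so the composed result's statistical error is
$F_{PSD}$'s relative error.

## 2. The simplified Monte Carlo engine

Each proton is sampled from a single-Gaussian **effective source**: the
aggregate of everything upstream of the patient devices is reduced to a
virtual source at `source_to_axis_distance` (default 2000 mm) with lateral
blur `lateral_sigma` (10 mm) and angular spread `angular_sigma` (3 mrad).
These are *declared fixture values* — at a real facility they are fitted to
measurements and are not published. Aim points are drawn uniformly over a
square fluence window (Section 4), giving the flat incident fluence a
double-scattering system is designed to produce.

The SOBP is realized by **mixture sampling**: each proton is assigned one
constituent pristine peak with probability proportional to the ridge-filter
weight, and carries the residual range of that constituent. This keeps the
deposition kernel well-defined after compensator-induced range loss, which a
single pre-summed SOBP curve would not.

Transport applies, in order: range shifter (thin device: water-equivalent
range loss plus one scattering kick at the plane), range compensator
(bilinear thickness lookup at the crossing point, same treatment), aperture
(even-odd polygon containment; outside means terminated; boundary points
count as inside — a measure-zero convention fixed for determinism), then a
vacuum drift to the phantom (air contributes negligible scatter and energy
loss at these distances). Inside the uniform phantom the proton advances in
2 mm steps along its current direction; each step deposits
`curve(R0 - residual + dw/2) * dw` — the pristine depth-dose value at the
track's water-equivalent depth — and receives one Highland kick.

Two deposition details matter:

* **The curve outlives the nominal range.** The pristine curve carries the
  range-straggling tail beyond the nominal (Bragg-Kleeman) range; a track
  therefore continues depositing, on a straight line and without further
  kicks, until the curve's support ends. Stopping at the nominal range would
  chop the distal half of every constituent peak and depress the SOBP
  plateau by several percent (the broad-beam self-consistency test pins
  this at under 1%).
* **Cloud-in-cell scoring.** Each step's deposit is shared bilinearly over
  the four nearest voxel columns of its depth slice, i.e. the proton is
  scored as a voxel-width pencil. This is variance reduction, not physics:
  it leaves the expected dose field unchanged up to sub-voxel smoothing
  (well inside the 2 mm resolution) and cuts the particle count needed for
  a given voxel-level statistical error by roughly 2.3x.

### Scattering

Multiple Coulomb scattering uses Highland's parameterization
$\theta_0 = (14.1\,\mathrm{MeV}/pv)\sqrt{L/X_0}\,[1 + \tfrac19\log_{10}(L/X_0)]$
with $pv$ recovered from the proton's current residual range by inverting
the range-energy law, and $X_0 = 360.8$ mm (water) on the water-equivalent
path — the water-equivalent model treats every material as scaled water.
Applied naively per step, the formula's logarithmic term makes variances
non-additive (two slabs of $L$ each disagree with one $2L$ slab by 7-8%).
The engine therefore applies it in **cumulative form**: the kick variance
over a path increment is $\theta_0^2(l+\Delta l) - \theta_0^2(l)$ with $l$
the cumulative radiative path. Consecutive slabs then add exactly (at fixed
energy), and a single slab from $l = 0$ reproduces the closed form exactly —
both are tested. The bracket is clamped at zero for pathologically thin
paths. Kicks are small-angle: independent Gaussian deflections are added to
the two transverse direction components and the vector is renormalized.

Whether the range shifter scatters explicitly or is folded into the
effective source is a facility calibration choice; the engine scatters in
the shifter by default with a `scatter_in_rs` switch.

### Statistical errors

A run is split into `n_batches` (default 20) equal batches with independent
sub-seeds; the relative standard error of any scored quantity is
`sd(batch values) / (sqrt(n_batches) * mean)`. The engine's RNG is a
seeded counter-style generator (xoshiro256++ with a splitmix64-scrambled
per-batch seed) for the scattering stream, and R's RNG (seeded per batch)
for source sampling — a fixed seed makes the whole run bit-identical
regardless of execution history. The default particle count,
`n_protons = 2.4e7`, is chosen so the relative standard error of the dose in
the 2 mm voxel at the measurement point stays below 1% in the commissioning
geometries (the calculation's stated statistical-quality criterion), with
margin for the estimator's own sampling noise; that run takes a few minutes
on one CPU. Factor ratios at reduced counts inherit honest (larger) error
bars rather than biased values.

## 3. The synthetic commissioning data

No facility beam data are published, so `synthesize_commissioning()` builds
a plausible stand-in. What it emulates — and what it does not — bounds what
green tests say about real data.

* **Pristine curves**: Bragg-Kleeman stopping power
  $dE/dz \propto (R-z)^{1/p-1}$ (defaults $\alpha = 0.022$ mm/MeV$^p$,
  $p = 1.77$, the widely used water values), bin-integrated analytically
  across the singularity, then smeared by a Gaussian combining range
  straggling ($0.012\,R_{cm}^{0.935}$ cm) and a 0.8% beam energy spread.
  The curve is registered so its peak sits exactly at the nominal range —
  the smearing alone would pull it ~0.9 sigma upstream — making the
  range-energy law, the SOBP-center depth formula
  `(range - SOBP/2 - RS)/WELR` and the curve mutually consistent. Not
  emulated: nuclear buildup (the entrance-to-peak ratio is lower than
  measured curves show) and the low-dose nuclear halo.
* **SOBPs**: nonnegative least squares (`pracma::lsqnonneg`) of pristine
  peaks pulled back in 2.5 mm steps against a flat target from
  `R - width` to the deepest peak's maximum. Flatness tolerance 2%
  (achieved: well under 1%); the curve is normalized to 1.0 at the SOBP
  center `R - width/2`. Fitting past the deepest peak's maximum would force
  a distal horn — the flat region physically ends there.
* **F_BSD table**: separable exponential decay,
  $F = \mathrm{base}_E\,e^{-a_E\,\mathrm{RS} - b_E(w-80)}$, tuned only to
  reproduce the commissioned monotonicities (decreasing in RS thickness and
  SOBP width) and the exact STD normalization. The seed jitters the decay
  rates by up to 5%, so different seeds give different — but always valid —
  facilities. Absolute values are fixture conventions, not physics claims.
* **Measured field-size curves**: smooth exponential approach to 1 with a
  5% depth at 235 MeV and 0.8% at 150/190 MeV, matching the commissioned
  aperture effects. These are *deterministic* parametric fixtures.

Because the measured field-size fixture and the engine's calculated curve
are independent constructions, $F_{FS}$ here is a genuine
measured-over-calculated ratio, exercised end to end; but its magnitude
reflects the fixture, not any real beamline.

## 4. Numerical choices

* **Voxels and steps.** 2 mm isotropic scoring voxels; step length equals
  the voxel (one Highland kick per step). Halving the step must not move
  the isocenter dose beyond its statistical error (tested). Depth-dose
  curves are tabulated at 0.5 mm — sub-voxel — and linearly interpolated.
* **Fluence window.** Point-output runs (`simulate_dmu()`) restrict the
  sampled aim points to a square of half-width 40 mm around the measurement
  point and normalize per unit fluence (dose per proton times window area).
  The window edge lies more than four lateral-scattering sigmas beyond the
  detector edge, so the excluded fluence cannot reach the scored volume;
  this is an importance window, exact for the scored quantity, and it is
  what makes sub-1% voxel errors affordable on one CPU. Full-field maps
  (`run_simulation()` default) cover the whole projected aperture plus
  margin.
* **Geometry conventions.** Origin at the isocenter, beam along +z, devices
  at negative z. The phantom entrance is placed so the measurement point
  sits at the isocenter at the requested depth. The mean aperture radius is
  computed from the machined collimator-plane edge points (not their
  isocenter projection), resampled to uniform 1 mm arc length — the
  planning-CT resolution — before averaging; the choice between
  CT-resolution points and arc-uniform points is not fixed by practice, and
  arc-uniform resampling makes the quantity robust to how densely a
  segment happens to be digitized.
* **Detector averaging.** `detector_average()` integrates the trilinear
  interpolant of the voxel doses over the cell rectangle by midpoint
  quadrature (0.5 mm sub-grid). This is exact for linear dose gradients and
  agrees with dense quadrature to well under 0.5% for smooth fields. The
  alternative — area-weighted piecewise-constant voxel overlap — is exact
  for the degenerate one-voxel cell but biases cell averages toward voxel
  centers in gradients; the interpolation view was chosen because volume
  averaging of smooth dose is the quantity of clinical interest. The Farmer
  chamber is its 6.1 x 23.4 mm rectangular projection; the 2-D array cell
  is 5 x 5 mm with its sensitive center 8 mm WEL below the surface.
* **Degenerate inputs.** Compensator queries outside the thickness map
  clamp to the nearest edge value — the natural bilinear extension, which
  fails safe by keeping edge-region range loss rather than dropping to
  zero; apertures must be simple polygons and warn if the beam axis
  is outside the opening; the standard-condition label is validated against
  the exact standard beam; RS thickness is confined to the commissioned 0-120
  mm WEL; `field_size_correction()` clamps to 1 above the largest tabulated
  square and refuses below the smallest (outside the validated domain).
  `positional_uncertainty()` — the peak-to-peak dose variation over a 2 mm
  cube used as the setup-error bar — is exact for trilinear fields sampled
  at lattice corners; on simulated grids it also carries the per-voxel
  Monte Carlo noise floor, which its tests account for explicitly.

## 5. Problem sizes used by the tests

The suite runs the engine at reduced particle counts chosen for the
tolerance each check needs: geometric and identity checks at $10^5$ to
$4\times10^6$ protons, the broad-beam self-consistency at $4\times10^5$
(the laterally integrated curve converges much faster than any single
voxel), field-size sweeps at $2\times10^6$ per aperture, and exactly one
run at the full default $2.4\times10^7$ to verify the sub-1% voxel
criterion. The acceptance script mirrors these sizes.

## 6. Known limitations

* The phantom is uniform (water-equivalent scalar); no CT-based
  heterogeneous transport.
* Collimator edge scatter and the nuclear halo are not modelled; the
  field-size correction absorbs their net effect by construction, which is
  exactly the role it plays in the factorization.
* All synthetic commissioning magnitudes (F_BSD values, effective-source
  parameters, field-size depths) are fixtures; only their structure and
  trends are meaningful. Conclusions about a real beamline require
  replacing the bundle with measured tables via `read_commissioning()`.
* The small-angle kick update biases direction norms at large accumulated
  angles; at therapeutic energies and depths the accumulated RMS angle
  stays far below where this matters.
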