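---
title: "Methods: simulating and imaging boron neutron capture prompt gamma rays with a Si/CdTe Compton camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prompt-gamma Compton imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcam)
```

## The problem

Boron neutron capture therapy (BNCT) delivers dose through the
^10^B(n,&alpha;)^7^Li reaction. In about 94% of captures the ^7^Li product
is left in an excited state and emits a 478 keV prompt gamma ray (PG), so
imaging the PG emission maps the capture reaction — and hence the dose —
directly. The difficulty is the environment: annihilation gammas (AG) at
511 keV sit only 33 keV (about 7%) above the PG line, and hydrogen capture
produces 2.2 MeV gammas that no practical mechanical collimator stops. A
Compton camera needs no collimator and, with semiconductor detectors
(stacked Si scatterers and CdTe absorbers), resolves the PG/AG pair
spectroscopically.

`pgcam` implements the complete analysis chain for such an experiment —
event-level simulation of the bench scenes, event selection, 478 keV peak
spectroscopy, cone back-projection with list-mode MLEM refinement, and
background-subtracted contrast metrics — as a tested, reusable pipeline.
The measured list-mode data of the original bench study are not publicly
deposited, so the package ships a synthetic-data generator that emulates
the study conditions and carries ground-truth labels; every downstream
module consumes the same list-mode format the generator writes.

## Compton kinematics and cones

A photon of energy $E_0$ scatters in a Si layer (depositing $E_1$) and is
photo-absorbed in a CdTe layer (depositing $E_2$). Assuming full absorption,
$$\cos\theta = 1 - m_ec^2\!\left(\frac{1}{E_2} - \frac{1}{E_1+E_2}\right),
\qquad m_ec^2 = 511\ \mathrm{keV},$$
so each event constrains the source to a cone with apex at the scatter
position, axis from the absorber hit toward the scatter hit, and half-angle
$\theta$. Energies inconsistent with $|\cos\theta|\le 1$ are flagged
invalid (`NA`), never clamped: unselected event streams legitimately
contain such events, and the reconstructor skips them with a count.

The simulator inverts the same relation: scattering angles are drawn from
the Klein–Nishina differential cross-section by rejection sampling
(uniform directions on the sphere, accepted with the Klein–Nishina weight,
which is bounded by its forward-peak value of 1), and the energy split
follows from the sampled angle. The sampler and the reconstructor are
tested against each other through the inverse identity and against a
quadrature oracle of the same cross-section.

## Detector response and its calibration

The instrument is characterised by two published figures: 2.2% energy
resolution and a 5.4° angular resolution measure (ARM), both FWHM at
662 keV. The response model realises them with three components:

* **Energy blur** — Gaussian with
  $\mathrm{FWHM}(E) = \mathrm{FWHM}(662)\sqrt{E/662}$ (statistical-limit
  scaling; a single calibration point is published, so a one-parameter
  scaling law is the defensible choice).
* **Position blur** — isotropic lateral Gaussian on each hit,
  $\sigma_{pos} = 1$ mm by default. Layer spacings and strip pitch of the
  real instrument are unpublished; the stack geometry (eight Si layers at
  4 mm pitch, a 30 mm gap, four CdTe layers at 4 mm pitch, all 50 mm
  square) is a plausible compact default and is configurable. We chose
  1 mm rather than a larger blur because, under this default geometry, the
  intrinsic ARM floor from energy plus position blur alone must stay below
  the 5.4° instrument figure for the angular calibration to be feasible;
  at 1.5 mm the floor is ≈5.9° and no residual tilt can reach the target,
  while at 1 mm the floor is ≈4.1°.
* **Residual axis tilt** — a per-axis Gaussian tilt of the measured
  scatter axis, the one free parameter. `calibrate_angular_blur()` sets it
  by bisection so that the simulated ARM FWHM at 662 keV matches the
  instrument figure within 0.05°. Every candidate tilt is evaluated on the
  same seeded event sample (common random numbers), making the objective a
  deterministic monotone function of the tilt. The ARM distribution width
  is estimated by a Gaussian fit to the histogram core, the conventional
  estimator for resolution distributions with non-Gaussian tails.

ARM follows the standard sign convention, geometric minus kinematic angle.
For reconstruction, the per-event angular uncertainty at the assumed
incident energy scales the reference ARM as $\sqrt{662/E}$, mirroring the
relative energy-resolution scaling.

## The synthetic scenes

`preset_scene()` encodes the six bench acquisitions (2 h each): a
cylindrical B~4~C target (radius 25 mm, height 60 mm, 100 g, hence 14.5 g
of ^10^B at natural abundance) at X = −120, −20 or +80 mm on the plane
Z = 130 mm; a same-size graphite block; no target; and a 20 g B~4~C slab
(7 × 96 × 22 mm) inside a 100 mm water cube, which adds the 2.2 MeV
hydrogen-capture line. All scenes share four backgrounds: the 511 keV AG
line, a 558 keV line from neutron-activated Cd in the absorbers, a 478 keV
line emitted from inside the camera (boron in its printed circuit boards —
the reason a 478 keV peak persists with no target), and a smooth 300–600
keV scattered-gamma continuum with uncorrelated fake hit geometry (which
produces the flat sidebands the net/gross fit assumes). Target scenes also
carry a weak continuum component with *real* cone geometry from the target
volume: gammas scattered by the block itself, which is what distinguishes
a graphite run from an empty run.

Transport is phenomenological — no attenuation or neutron transport. Each
component's `intensity` is the expected number of *recorded two-hit
events* per second; per-run counts are Poisson. The absolute fluxes of the
bench study are simulation-derived and unpublished, so intensities are
free emulation parameters fixed once so that (a) the number of events
surviving selection in a 2 h scene lands in the measured 5000–7000 band
with the background scenes slightly below the target scenes, and (b) the
X = +80 mm target sits near the background level in the reconstructed
image, as observed. The PG intensity scales with the relative
thermal-neutron flux at the target position (1.0 / 0.8 / 0.4 at
X = −120 / −20 / +80 mm: the flux decreases along +X) multiplied by a
solid-angle factor $(r_{-20}/r_X)^2$ with $r_X = \sqrt{X^2 + 130^2}$,
because a recorded-event rate folds in the target–camera distance; both
factors are stated defaults, and only the decreasing ordering is treated
as load-bearing. The intrinsic Doppler broadening of the 478 keV line
defaults to 0 (configurable), matching its neglect in the reconstruction.

Each component draws from its own RNG stream derived deterministically
from the global seed and the component label, so removing one component
leaves every other component's events bit-identical; events are
interleaved by per-event ordering keys drawn inside the component streams.

What the generator deliberately does *not* emulate: interaction-depth
efficiency profiles (layers are chosen uniformly), three-or-more-hit
topologies (excluded upstream in the real data processing), dead time,
attenuation in the target or water, and neutron transport. Tests passing
on these synthetic scenes therefore validate the analysis chain and its
statistical behaviour, not detector physics beyond the calibrated
response figures.

## Event selection

Three rules, applied with fixed precedence (window, then scatterer energy,
then X-ray band) so per-rule rejection counts are reproducible:

1. $468 \le E_1+E_2 \le 488$ keV (inclusive bounds; the window excludes
   the 511 keV AG peak),
2. $E_1 < 200$ keV, strict (removes backward-scattered events and noise),
3. events in the deepest Si layer paired with the first CdTe layer are
   rejected when $E_1 \in [20, 35]$ keV inclusive (coincidences with CdTe
   fluorescence X-rays).

The published description does not state whether the window bounds are
inclusive; at 2.2% resolution the choice moves a negligible fraction of
events, and the conventions above are frozen in a boundary truth table
(`selection_truth_table()`) as a regression fixture.

## Spectroscopy

Analysis spectra histogram $E_1+E_2$ in half-open 2 keV bins over 300–700
keV (the source binning is unstated; 2 keV resolves the 12 keV-FWHM peak
comfortably). The pipeline forms its spectra from events passing rules 2–3
only — the energy window would cut the very peak under study. The 478 keV
peak is quantified as a net/gross ratio: gross is the raw count sum in the
468–488 keV window; the background under the peak is an unweighted
least-squares line through the 450–463 and 493–499 keV sidebands (counts
there are of similar magnitude, so weighting would change little);
net = gross − background. The ratio's standard deviation combines Poisson
error on the gross sum with the line-fit covariance by the delta method —
the published figure quotes only "standard deviations", so the propagation
is our documented choice. Photopeak centroids and widths come from a
Gaussian-plus-linear-baseline Levenberg–Marquardt fit.

## Reconstruction

Images live on the target plane Z = 130 mm (the bench images are planar;
3-D reconstruction is out of scope), default ±200 mm at 5 mm pixels. Each
selected event contributes a Gaussian-weighted cone:
$t_{ij} = \exp(-\Delta_{ij}^2 / 2\sigma_i^2)$, where $\Delta_{ij}$ is the
angle between the cone surface and the apex-to-pixel direction and
$\sigma_i$ the calibrated ARM at the assumed energy — the ARM is the only
published resolution statement, so a Gaussian profile rather than a
thin-shell cone is the natural smoothing. Back-projection sums $t_{ij}$
over events.

The half-angle convention is worth spelling out. The source description
says both that the initial PG energy was *assumed* to be 478 keV and that
the initial energy and the scatterer energy were used in back-projection.
Within the 468–488 keV window the two readings differ negligibly, so the
default computes $\theta$ from the measured pair $(E_1, E_2)$
(`"measured-total"`), with the assumed 478 keV entering only through the
angular-uncertainty scaling; the alternative
(`"assumed-initial"`, $\cos\theta = 1 - 511(1/(478-E_1) - 1/478)$) is a
configuration switch.

List-mode MLEM refines the back-projection with uniform sensitivity
($s_j = 1$: the field of view is small relative to the camera and no
sensitivity map is published):
$$\lambda_j^{(k+1)} = \lambda_j^{(k)} \sum_i
  \frac{t_{ij}}{\sum_m t_{im}\lambda_m^{(k)}}.$$
Ten iterations by default (no iteration count or stopping rule is
published); the log-likelihood term $\sum_i \log\sum_m t_{im}\lambda_m$ is
logged every iteration and asserted non-decreasing. One subtlety: with
unit sensitivity the EM-monotone Poisson objective also carries a
$-\sum_j \lambda_j$ term, and since the update preserves
$\sum_j \lambda_j = n$ only from the first iteration onward, the default
uniform start is scaled to $n/n_{pixels}$ so that the logged term is
monotone from the very first step. Events with zero forward projection
are skipped with a count; an all-zero initial image is an error.

## Background subtraction and contrast

`subtract_images()` subtracts equal-exposure background images pixel by
pixel, preserving negatives (a `scale` option covers unequal exposures).
The pixel-value ratio (PVR) first clips negatives to zero, then divides
the mean over the target ROI (the projected target footprint; pixels
belong to the ROI if their centre falls inside, half-open on the high
edges) by the mean over all other pixels of the grid — no annulus or
margin, since none is defined in the source.

Two background references are supported: the no-target run (SIwoT) and a
graphite run (SIwG). For SIwG the package uses a graphite reference with
the block at the *same position* as the B~4~C target being imaged
(`preset_scene("graphite", graphite_x = ...)`). The bench study's
supplementary material shows graphite was also imaged away from −20 mm
(at +80 mm), and a matched-position reference is what makes SIwG
scientifically meaningful: it cancels the target-scattered continuum at
the target location, leaving the prompt-gamma excess. It is also what
reproduces the measured contrast progression
PVR(original) ≤ PVR(SIwG) ≤ PVR(SIwoT): the no-target subtraction leaves
both the PG signal *and* the target-scatter excess in the ROI, while the
matched graphite subtraction removes the scatter excess — so SIwoT sits
above SIwG, and both sit far above the unsubtracted image, whose diffuse
background dominates the denominator. With a fixed-position graphite
reference the progression inverts for targets away from the reference
position, because subtracting the reference's focal spot only ever
deepens (and then clips) a dip *outside* the ROI.

The operational visibility criterion for "the target is distinguishable"
is: ROI mean above the mean plus two standard deviations of the non-ROI
pixel distribution, evaluated on the back-projection image. Back-projection
rather than MLEM is deliberate: MLEM concentrates an extended oblique blob
(the X = −120 mm target seen at an angle) into scattered bright pixels, so
an ROI-mean criterion under-reads exactly the targets a human reader of
the MLEM image would still call visible, while on the smooth
back-projection the criterion tracks the reader's judgement across all
four scenes.

## Numerical choices and scales

* FWHM/σ conversions use $2\sqrt{2\ln 2}$; $m_ec^2$ is exactly 511 keV
  (annihilation-line energy; sub-keV precision is irrelevant at 2.2%
  resolution).
* Energy blur resamples draws at or below zero; forward-scattered events
  keep a 0.1 keV floor on $E_1$ so deposited energies stay positive.
* The geometric-acceptance rejection loop (scattered ray must cross the
  chosen absorber inside its lateral extent) emulates the finite absorber
  acceptance and biases sampled angles exactly as the geometry does.
* Blurred hit positions may leave the nominal layer footprint; truth
  positions always lie inside. Invariant checks on hit containment use
  unblurred generation.
* Test and example runs use scaled-down problem sizes chosen once —
  reduced exposures (60–1800 s against the 7200 s study exposure), a 5 mm
  pixel grid, and 10^4^–10^5^-event calibration samples — sizes at which
  every qualitative conclusion of the full-scale runs is already stable.
  The contrast-ordering checks use 20 seeded replicates at 900 s exposure
  on a ±150 mm grid and compare medians.

## Known limitations

Uniform layer choice ignores depth-dependent efficiency; the continuum's
fake cone geometry is isotropic rather than physical; absolute detection
efficiency is not modelled (component intensities absorb it); the
energy-resolution scaling law is an assumption beyond its single
calibration point; and the PVR progression depends on the matched-position
graphite reference as described above. None of these affect the
closed-form quantities (boron inventory, clinical-equivalence time,
angular displacement) or the calibration-recovery properties, which are
the package's quantitative anchors.
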