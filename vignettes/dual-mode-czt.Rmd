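---
title: "Dual-mode PET and Compton-camera imaging with a dual-panel CZT scanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode PET and Compton-camera imaging with a dual-panel CZT scanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcc)
```

## The problem

Non-pure positron emitters such as arsenic-72 couple a large mean positron
range (5.19 mm in water) with high-yield prompt gammas (834 keV at 81%).
In PET, the positron range blurs the reconstructed activity away from the
radionuclide position; the prompt gamma, however, is emitted at the nuclide
itself, so a detector able to record its Compton kinematics can image the
source *free of positron-range blur*. A dual-panel scanner built from
edge-on CZT crystals (two 20 x 15 cm^2 panels, 4 cm thick, 20 cm apart,
each tiled by 150 crystals of 40 x 40 x 5 mm) has both the stopping power
and the energy resolution to act simultaneously as a PET camera (511 keV
coincidences) and as a single-layer Compton camera (834 keV
scatter-then-photoabsorption sequences).

`petcc` implements that study end to end at desk scale: a synthetic
photon-transport simulator for the scanner, truth-labelled coincidence
sorting into two list-mode text formats, list-mode MLEM reconstruction with
a line projector (PET) and a cone projector (Compton camera), and the
profile/FWHM analysis that summarizes both. The `analysis/` scripts in the
source repository run the four stages in order.

## Physics model

**Photon interactions.** Compton kinematics use the standard free-electron
relation `cos(theta) = 1 - mec2 (1/(E0-Et) - 1/E0)` with `mec2` fixed at
exactly 511 keV; scattering angles are drawn from the Klein-Nishina
differential cross-section by exact rejection sampling. Material
attenuation uses packaged per-process coefficient tables (photoelectric,
Compton, Rayleigh on a 40-point log grid over 10-1700 keV) for CZT
(density 5.78 g/cm^3, effective Z 48.2) and water, interpolated log-log.
The tables are generated by `data-raw/make_material_tables.R` from
analytic Klein-Nishina theory plus a semi-empirical photoelectric
(`A E^-3 (1 + E/511)`) and Rayleigh (`B E^-2`) parametrization anchored to
well-established attenuation values (water total ~0.096 /cm at 511 keV;
CZT photofraction ~17% at 511 keV; CZT total ~3 /cm at 140 keV). This
reproduces the features the study turns on: the photoelectric coefficient
at 340 keV far exceeds its 511 keV value, which in turn exceeds 834 keV,
so the deposited-energy spectrum shows a strong 511 keV photopeak, a
smaller 834 keV photopeak, and a Compton continuum ending at the 341 keV
edge. Rayleigh scatters are counted in the attenuation but treated as
direction-preserving, zero-deposit events. Electron transport,
fluorescence escape and pair production are out of scope (all tracked
lines are below 1.022 MeV).

**Positron range.** Only the mean annihilation distance (5.19 mm for
72As) is specified, so the radial law is a modeling choice. The package
default draws the annihilation distance from a Gamma(shape = 3,
scale = mean/3) density, i.e. an isotropic 3D exponential (Laplace)
annihilation kernel `exp(-r/theta)` — a standard positron-range blurring
kernel whose 3D density stays bounded at the origin. A two-exponential
mixture of the radial distance (fast fraction 0.6, scale ratio 4, jointly
calibrated to the mean) is available as `model = "twoexp"`, but for an
emitter as energetic as 72As (beta+ endpoints of 2.5 and 3.3 MeV) it
concentrates ~16% of annihilations within one voxel of the source; the
resulting 1/r^2 cusp makes the reconstructed point profile voxel-limited
at any iteration count, which contradicts the measured behaviour of this
isotope (point profiles several mm wide that barely sharpen with
iterations). The Gamma(3) kernel is therefore the default. Both models
recover the configured mean exactly and are isotropic; neither reproduces
the true aPSF's detailed shape, so sub-millimetre agreement of absolute
PET widths should not be expected from these simulations.

**Acquisition.** Decay counts are Poisson (activity x duration); nuclide
positions are uniform in the 0.1 mm source sphere centred in a 2 cm water
phantom. A positron is emitted with probability 0.88; annihilation photons
are collinear back-to-back 511 keV pairs from the displaced annihilation
point (acollinearity is not simulated, matching a collinear simulation
configuration); each prompt line (693 keV at 8.07%, 834 keV at 81%) is
emitted isotropically and independently from the nuclide position. Phantom
transport samples interactions along the chord; any phantom interaction
flags the photon so that it is excluded from coincidence records
downstream (scatter rejection by ground truth) while still contributing to
the detector spectrum. Detector tracking alternates free-path sampling
from the CZT total coefficient with process selection by coefficient
ratios, up to 5 recorded interactions; Compton deposits are angle-derived,
so fully absorbed tracks conserve energy to numerical precision.

## Coincidence records and list-mode formats

A PET line of response requires both annihilation photons of one decay to
be completely absorbed, neither phantom-scattered, with first interactions
in opposite panels. A Compton-camera record requires a prompt photon whose
track is exactly one Compton scatter followed by one photoelectric
absorption, fully contained, not phantom-scattered; the unblurred energies
then sum to the line energy exactly. Because the on-disk CC format carries
no line label, the 834 keV selection used for reconstruction happens at
sorting time, before the optional Gaussian energy blur (FWHM convention,
sigma = FWHM/2.355, applied independently to both deposits and clamped
positive).

Record coordinates default to the **true interaction positions**: the
study reconstructs from ground truth without spatial blurring, and this
choice matters — the cross-strip readout's 5 mm depth pitch, applied over
the short scatter-to-absorption baselines inside a panel, would tilt cone
axes by tenths of a radian and dominate every other uncertainty. The
readout quantization model (1 mm anode strips along x, 5 mm depth bins
along y, 1 mm along z, each snapping to bin centres inside the crystal) is
retained in the hit table and available via `positions = "quantized"` for
sensitivity studies.

Both list-mode formats are header-less single-space-delimited text with
fixed 6-decimal formatting: 6 columns for PET (`x1 y1 z1 x2 y2 z2`, mm), 8
for CC (`xs ys zs E1 xa ya za E2`, mm and keV). Volumes are raw
little-endian float32 blocks (x fastest) with a JSON sidecar.

## Reconstruction

Both modalities share one list-mode MLEM driver,

    f_j <- (f_j / s_j) * sum_i a_ij / (sum_j' a_ij' f_j'),

started from a uniform image, with unit projection weights, uniform
sensitivity `s_j = 1`, no regularization, and a fixed iteration count
(20/800/3500 in the study layout). The list-mode log-likelihood
`sum_i log q_i - sum_j s_j f_j` is recorded every iteration and is
non-decreasing by construction; forward projections below `1e-12` are
floored and counted.

**PET projector (OD-RT).** Voxel weights are
`exp(-d^2 / (2 tor_sigma^2))` of the orthogonal distance `d` from the
voxel centre to the infinite line through the two detection points,
truncated at 3 sigma and at the endpoints. The tube width is a kernel
choice of the projector (records carry true positions), defaulting to
half a voxel (0.5 mm); it is exposed in the configuration and recorded in
every run report.

A caveat that matters at desk scale: deep MLEM iteration on a point-like
source drives the estimate toward its spiky maximum-likelihood support.
With ~1e4 events on a 64k-voxel grid the image at hundreds-to-thousands
of iterations fragments into isolated voxel spikes, so a through-peak
profile there measures the spike granularity, not the positron range;
widening the tube (tested up to 2 mm) or doubling the event count does
not restore the plateau, which at full study statistics comes from
spike densities far below the voxel scale. Desk-scale PET widths are
therefore meaningful at early iteration counts (tens), and projection
(`mode = "sum"`) profiles — which are stable across iteration counts —
are the scale-robust alternative at deep counts.

**Compton projector (cone surface with angular Gaussian kernels).** Each
record defines a cone: apex at the scatter position, axis from the
absorption point back through the scatter point, half-angle from the
Compton relation at the assumed line energy (834 keV by default; an
`E1+E2` mode exists for realism studies). Blurred scatter energies past
the Compton edge are clamped just inside it. The angular kernel width
combines, in quadrature, energy resolution propagated through
`dtheta/dE1 = mec2 / ((E0-E1)^2 sin theta)`, a Doppler-broadening term
(0.01 rad at 511 keV, scaling as 1/E0), and a per-voxel subtense floor
`voxel/distance` that keeps zero-width cones resolvable; it is capped at
0.3 rad where the derivative diverges near the edge. Rows are evaluated
per voxel as the Gaussian of the deviation of the voxel's apex angle from
the half-angle, truncated at 3 sigma — the exact dense-sampling limit of
the line-sampled cone surface, which `cone_surface_row()` implements
explicitly (256 azimuthal lines swept across the band) and which agrees
with the per-voxel evaluation to within a few percent. Working in angular
deviation selects the correct nappe automatically.

**Event and voxel screening.** Two guards matter at reduced statistics
under the `s_j = 1` convention. First, events whose kernel only grazes the
grid with its Gaussian skirt (peak in-grid weight below 0.5 — the surface
itself misses the volume) are dropped and counted: such low-mass rows
otherwise equilibrate at large compensating intensities wherever they
land. Second, weights are restricted to the grid's inscribed sphere
(radius 20 mm by default): the cube corners between two flat panels are
crossed by too few response surfaces for the uniform-sensitivity
assumption to hold there, and spurious intensity accumulates. Both guards
are configurable (`min_peak = 0`, `fov_radius_mm = Inf` recover the raw
projector).

**Storage and cost.** Rows are built once and cached behind an external
pointer. At 51 keV energy resolution the propagated angular sigmas reach
0.05-0.3 rad and a cone's 3-sigma band can cover most of the 40^3 grid, so
rows denser than 1/8 of the grid are stored as full 8-bit-quantized
vectors (the quantized weights *are* the system matrix, so EM monotonicity
is unaffected) and swept with vectorized kernels; sparse rows use float
CSR. This keeps a 5e3-cone, 3500-iteration reconstruction within minutes
on one CPU core.

## Width analysis

Profiles are taken along each axis through the global-maximum voxel and
normalized to peak 1 (`mode = "sum"` provides projection profiles for
sensitivity checks). Gaussian fits report
`FWHM = 2 sigma sqrt(2 ln 2) = 2.3548 sigma` and
`FWTM = 2 sigma sqrt(2 ln 10) = 4.2919 sigma`; Lorentzian fits
(`A Gamma / ((x-x0)^2 + Gamma^2)`) report `FWHM = 2 Gamma` and
`FWTM = 6 Gamma`, so FWTM is exactly three times FWHM. The summary table
uses Lorentzian fits for PET (heavy positron-range tails) and Gaussian
fits for the Compton camera, while retaining both fits per cell. Fits are
Levenberg-Marquardt with deterministic initialization (peak position,
width from the interpolated half-maximum crossing); failures are recorded
per cell without aborting the table.

## Study conditions and desk-scale operating point

The full study condition is 2 MBq acquired for 1 s (~2e6 decays). The
packaged analysis scripts and the acceptance checks keep the activity,
geometry, phantom and isotope but shorten the acquisition to ~0.13 s
(~2.6e5 decays), from which the downstream stages use the first 1e4 lines
of response and the first 5e3 834-keV Compton records — enough for stable
photopeak spectra and width tables while a full reconstruction series
(rows + 3500 MLEM iterations, both modalities) completes in minutes on a
single core. Simulation-based tests use yet smaller draws where only a
rate or a mean is being checked. What passing at this scale demonstrates
is distributional and structural agreement (spectrum features, record
validity, convergence behaviour, anisotropy, width ordering); it does not
demonstrate event-level agreement with a full Monte Carlo transport code,
per-crystal charge transport, or the exact widths attainable at 200x the
statistics.

## Numerical choices

* Tracking floor 10 keV (coefficient tables start there); sub-threshold
  Compton remainders deposit locally as a photoelectric-like hit, keeping
  track energy conservation exact.
* Kernel truncation at 3 sigma for both projectors (sub-2% mass loss);
  weights below the 8-bit quantum vanish in dense rows.
* MLEM epsilon floor 1e-12 on forward projections; iteration counts are
  fixed (no convergence criterion), and a series at 20/800/3500 reuses the
  iterate, which equals independent runs because the update is
  deterministic.
* Half-open crystal boxes and bin-centre quantization make readout
  assignment unique; boundary points belong to the box toward increasing
  coordinate.
* Seeding: all randomness flows through R's global RNG, so
  `set.seed()` makes simulation, blur and pipeline byte-reproducible.

## Known limitations

* The positron-range law is calibrated to one number (the mean); absolute
  PET widths inherit that model choice.
* The coefficient tables are a smooth parametrization anchored at a few
  published values, not a library tabulation; fine structure (absorption
  edges) is absent, which is immaterial above 100 keV.
* Doppler broadening enters only as a fixed angular term on the
  reconstruction side, not in the simulated scattering kinematics.
* The uniform-sensitivity MLEM convention is kept (with the FOV and
  event-screening guards above) rather than computing a true sensitivity
  image; intensity scales are therefore relative, as in the study layout.
* Randoms, pile-up, timing and charge sharing are not modeled; coincidence
  sorting uses ground truth.
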