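# petcc — dual-mode PET + Compton-camera imaging with a dual-panel CZT scanner

Non-pure positron emitters used in radiotheranostics, such as arsenic-72,
pair a large mean positron range (5.19 mm in water) with high-yield prompt
gammas (834 keV at 81%). The positron range blurs PET images of such
tracers; the prompt gamma, emitted at the radionuclide itself, does not.
A dual-panel scanner of edge-on CZT crystals (two 20 × 15 cm² panels,
4 cm thick, 20 cm apart, 150 crystals of 40 × 40 × 5 mm each) can operate
simultaneously as a PET camera (511 keV coincidence pairs → lines of
response) and as a single-layer Compton camera (Compton scatter followed
by photoelectric absorption of the 834 keV gamma → cones of response),
so the Compton image localizes the source free of positron-range blur.

`petcc` implements that study as a desk-scale, fully synthetic pipeline:

* **Simulator** — Poisson decays of a ⁷²As point source in a 2 cm water
  phantom; positron-range displacement sampling; Klein–Nishina Compton
  kinematics; photoelectric/Compton/Rayleigh transport in water and CZT
  from packaged coefficient tables; truth-labelled coincidence sorting
  into the two list-mode text formats.
* **Reconstruction** — one list-mode MLEM driver
  (`f_j ← f_j/s_j · Σᵢ a_ij / Σ_j' a_ij' f_j'`, uniform start, `s_j = 1`,
  `p_i = 1`, no regularization) with two projectors: an
  orthogonal-distance ray tracer with a fixed Gaussian tube of response
  for PET, and a cone-surface projector with energy-based Gaussian angular
  kernels (energy resolution propagated through the Compton relation,
  plus Doppler broadening) for the Compton camera.
* **Analysis** — normalized activity profiles through the image maximum,
  Gaussian fits (FWHM = 2.355 σ, FWTM = 4.292 σ) for Compton-camera
  volumes and Lorentzian fits (FWHM = 2Γ, FWTM = 6Γ) for PET volumes,
  tabulated per modality/iteration-count/axis; slice maps; a one-call
  reproducible pipeline (`run_pipeline()`).

The repository is organised as an analysis workflow: every computation
lives in the package (`R/`, `src/`), and the numbered scripts under
`analysis/` are thin drivers that run the study stages in order
(simulate → PET MLEM → CC MLEM → width tables), writing their outputs
under `results/`.

## Worked example

```r
library(petcc)

set.seed(7)
sim <- simulate_acquisition(activity_bq = 2e6, duration_s = 0.02)
sim$counts
#>                 n_decays                n_photons                   n_hits
#>                    40457                   107184                    51176
#>                    n_lor                     n_cc n_lor_same_panel_dropped
#>                     3191                     1194                        0

# Compton-camera reconstruction of the 834 keV records at 1 keV blur
cc <- sim$cc[sim$cc$line_keV == 834, ]
rec <- reconstruct_cc(apply_energy_blur(cc, 1), iterations = 20,
                      model = angular_model(energy_fwhm_keV = 1))
fit_gaussian(extract_profile(rec$volumes[["20"]], "x"))
#> gaussian fit: fwhm = 1.223 mm, fwtm = 2.229 mm (residual 0.0001475)
fit_gaussian(extract_profile(rec$volumes[["20"]], "y"))
#> gaussian fit: fwhm = 2.362 mm, fwtm = 4.305 mm (residual 0.01221)
```

About 2.6% of decays yield a clean Compton record of the 834 keV line
(Compton scatter then photoelectric absorption, fully contained, no
phantom scatter). Twenty MLEM iterations already localize the point
source to ~1.2 mm FWHM in x — despite the 5.19 mm mean positron range,
which the prompt-gamma channel never sees — while the panel-normal axis y
is ~2× worse, the usual limited-angle behaviour of a dual-panel system.

The full study layout (PET at 20/800/3500 iterations from 10⁴ LORs, CC
at 1 keV and 51 keV energy blur from 5 × 10³ records, width tables for
both) is what `analysis/01_simulate.R` … `analysis/04_widths.R` run; see
the methods vignette (`vignettes/dual-mode-czt.Rmd`) for the model,
its parameters and its limitations.

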