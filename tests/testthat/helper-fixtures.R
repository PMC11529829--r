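# Shared fixtures: small geometries, synthetic records, and a memoised
# medium-scale acquisition reused by the acceptance-level tests.

paper_geometry <- function() build_geometry()

one_crystal_geometry <- function() {
  build_geometry(list(panel_width_mm = 40, panel_height_mm = 5,
                      panel_depth_mm = 40, crystal_dims_mm = c(40, 40, 5)))
}

# noiseless CC record from a known source position: choose a scatter point
# in a panel, a true scattering angle, and place the absorption point so
# that the cone through (apex, axis, angle from energies) contains the source
make_cc_record <- function(source, apex, theta, E0 = 834, azimuth = 0) {
  d_in <- (apex - source) / sqrt(sum((apex - source)^2))
  ref <- if (abs(d_in[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- c(d_in[2] * ref[3] - d_in[3] * ref[2],
          d_in[3] * ref[1] - d_in[1] * ref[3],
          d_in[1] * ref[2] - d_in[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d_in[2] * e1[3] - d_in[3] * e1[2],
          d_in[3] * e1[1] - d_in[1] * e1[3],
          d_in[1] * e1[2] - d_in[2] * e1[1])
  d_out <- d_in * cos(theta) + (e1 * cos(azimuth) + e2 * sin(azimuth)) * sin(theta)
  absp <- apex + 20 * d_out
  E1 <- angle_to_transfer(E0, theta)
  data.frame(xs = apex[1], ys = apex[2], zs = apex[3], E1 = E1,
             xa = absp[1], ya = absp[2], za = absp[3], E2 = E0 - E1)
}

# separable Gaussian test volume
gaussian_volume <- function(sigma = c(3, 4, 5), dims = c(40, 40, 40)) {
  g <- function(n, s) exp(-0.5 * ((seq_len(n) - 0.5 - n / 2) / s)^2)
  v <- outer(outer(g(dims[1], sigma[1]), g(dims[2], sigma[2])), g(dims[3], sigma[3]))
  image_volume(array(v, dims), dims = dims)
}

# memoised medium-scale 72As acquisition shared across acceptance tests:
# a fixed-seed run large enough for ~1e5 decays of spectrum statistics,
# ~1e4 LORs and ~5e3 usable 834 keV CC records
.acq_cache <- new.env(parent = emptyenv())
shared_acquisition <- function() {
  if (is.null(.acq_cache$sim)) {
    set.seed(20240614)
    .acq_cache$sim <- simulate_acquisition(activity_bq = 2e6, duration_s = 0.13,
                                           keep_hits = TRUE)
  }
  .acq_cache$sim
}

# memoised reconstruction series over the shared acquisition
shared_reconstructions <- function() {
  if (is.null(.acq_cache$recon)) {
    sim <- shared_acquisition()
    lor <- utils::head(sim$lor, 10000)
    cc <- utils::head(sim$cc[sim$cc$line_keV == 834, ], 5000)
    vol <- image_volume()
    pet <- reconstruct_pet(lor, iterations = c(20, 800, 3500), volume = vol)
    set.seed(11)
    cc1 <- apply_energy_blur(cc, 1)
    cc_lo <- reconstruct_cc(cc1, iterations = 20, volume = vol,
                            model = angular_model(1))
    set.seed(12)
    cc51 <- apply_energy_blur(cc, 51)
    cc_hi <- reconstruct_cc(cc51, iterations = c(20, 3500), volume = vol,
                            model = angular_model(51))
    .acq_cache$recon <- list(pet = pet, cc_lo = cc_lo, cc_hi = cc_hi,
                             n_lor = nrow(lor), n_cc = nrow(cc))
  }
  .acq_cache$recon
}

fwhm_of <- function(volume, axis, model = c("gaussian", "lorentzian")) {
  model <- match.arg(model)
  prof <- extract_profile(volume, axis)
  fit <- if (model == "gaussian") fit_gaussian(prof) else fit_lorentzian(prof)
  fit$fwhm
}
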