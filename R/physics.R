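# Photon-interaction physics: Compton kinematics, Klein-Nishina sampling,
# material coefficient tables, positron-range displacement sampling.

#' Electron rest energy in keV
#'
#' Fixed at exactly 511.0 keV throughout the package, consistent with the
#' labelling of the annihilation photopeak.
#' @export
MEC2 <- 511.0

#' Compton edge
#'
#' Maximum energy a photon of energy `E0` can transfer to an electron in a
#' single Compton scatter (the backscatter, theta = pi, case):
#' `2 E0^2 / (mec2 + 2 E0)`. For 511 keV photons this is 340.67 keV, the
#' cutoff of the annihilation-photon Compton continuum.
#'
#' @param E0 incident photon energy, keV (vectorized).
#' @return maximum transferable energy, keV.
#' @export
compton_edge <- function(E0) {
  if (any(!is.finite(E0)) || any(E0 <= 0)) {
    stop("compton_edge: E0 must be positive and finite")
  }
  2 * E0^2 / (MEC2 + 2 * E0)
}

#' Scattering angle from transferred energy
#'
#' Inverts the Compton energy-transfer relation at fixed incident energy:
#' `cos(theta) = 1 - mec2 * (1/(E0 - Et) - 1/E0)`. The admissible transfer
#' interval is `(0, compton_edge(E0)]`; the edge maps to exact backscatter
#' (theta = pi) and vanishing transfer to theta -> 0.
#'
#' @param E0 incident photon energy, keV.
#' @param E_transfer energy transferred to the electron, keV (vectorized).
#' @return scattering angle in radians, in (0, pi].
#' @seealso [angle_to_transfer()] for the forward relation.
#' @export
compton_transfer_to_angle <- function(E0, E_transfer) {
  if (any(E0 <= 0)) stop("compton_transfer_to_angle: E0 must be positive")
  edge <- compton_edge(E0)
  bad <- E_transfer <= 0 | E_transfer > edge * (1 + 1e-12)
  if (any(bad)) {
    stop(sprintf(
      "compton_transfer_to_angle: E_transfer must lie in (0, %.6f] keV for E0 = %.3f keV",
      edge[which(bad)[1]][1], if (length(E0) > 1) E0[which(bad)[1]] else E0
    ))
  }
  ct <- 1 - MEC2 * (1 / (E0 - E_transfer) - 1 / E0)
  acos(pmin(1, pmax(-1, ct)))
}

#' Transferred energy from scattering angle
#'
#' Forward Compton relation: a photon of energy `E0` scattered by `theta`
#' retains `E0 / (1 + k (1 - cos theta))` with `k = E0/mec2`, and transfers
#' the difference to the electron.
#'
#' @param E0 incident photon energy, keV.
#' @param theta scattering angle, radians (vectorized).
#' @return transferred energy, keV.
#' @export
angle_to_transfer <- function(E0, theta) {
  k <- E0 / MEC2
  E0 - E0 / (1 + k * (1 - cos(theta)))
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Draws polar scattering angles distributed per the Klein-Nishina
#' differential cross-section at incident energy `E0`, by exact rejection
#' sampling in cos(theta) (the unnormalized density is bounded by its
#' forward-scatter value). Uses R's global RNG, so results are reproducible
#' under [set.seed()].
#'
#' @param E0 incident photon energy, keV; scalar or vector of length `n`.
#' @param n number of draws (default `length(E0)` when `E0` is a vector).
#' @return vector of angles in radians.
#' @export
sample_klein_nishina_angle <- function(E0, n = length(E0)) {
  if (any(E0 <= 0)) stop("sample_klein_nishina_angle: E0 must be positive")
  k <- rep_len(E0 / MEC2, n)
  ct <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    c_prop <- stats::runif(length(todo), -1, 1)
    r <- 1 / (1 + k[todo] * (1 - c_prop))
    g <- r^2 * (r + 1 / r - (1 - c_prop^2))  # <= 2 (value at theta = 0)
    acc <- stats::runif(length(todo)) < g / 2
    ct[todo[acc]] <- c_prop[acc]
    todo <- todo[!acc]
  }
  acos(ct)
}

#' Klein-Nishina probability density over the scattering angle
#'
#' Unnormalized density f(theta) proportional to dsigma/dOmega * sin(theta);
#' used as the analytic reference for the sampler.
#'
#' @param theta angle, radians.
#' @param E0 incident photon energy, keV.
#' @param normalize if `TRUE`, numerically normalize to integrate to 1.
#' @return density values.
#' @export
klein_nishina_pdf <- function(theta, E0, normalize = TRUE) {
  k <- E0 / MEC2
  f <- function(th) {
    ct <- cos(th)
    r <- 1 / (1 + k * (1 - ct))
    r^2 * (r + 1 / r - (1 - ct^2)) * sin(th)
  }
  v <- f(theta)
  if (normalize) {
    Z <- stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
    v <- v / Z
  }
  v
}

# ---------------------------------------------------------------------------
# isotopes

#' Isotope specification for a non-pure positron emitter
#'
#' @param name label.
#' @param beta_plus_yield fraction of decays emitting a positron, in \[0, 1\].
#' @param mean_positron_range_mm mean annihilation distance in water, mm.
#' @param prompt_lines two-column matrix or data.frame (`energy_keV`, `yield`)
#'   of prompt-gamma lines emitted in coincidence with the decay.
#' @return an object of class `isotope_spec`.
#' @export
isotope_spec <- function(name, beta_plus_yield, mean_positron_range_mm,
                         prompt_lines = data.frame(energy_keV = numeric(),
                                                   yield = numeric())) {
  prompt_lines <- as.data.frame(prompt_lines)
  stopifnot(
    beta_plus_yield >= 0, beta_plus_yield <= 1,
    mean_positron_range_mm >= 0,
    all(prompt_lines$energy_keV > 0),
    all(prompt_lines$yield >= 0 & prompt_lines$yield <= 1)
  )
  structure(list(name = name,
                 beta_plus_yield = beta_plus_yield,
                 mean_positron_range_mm = mean_positron_range_mm,
                 prompt_lines = prompt_lines),
            class = "isotope_spec")
}

#' Packaged arsenic-72 specification
#'
#' 72As: beta+ yield 88%, mean positron range 5.19 mm in water, prompt-gamma
#' lines at 693 keV (8.07%) and 834 keV (81%).
#' @return an `isotope_spec`.
#' @export
isotope_as72 <- function() {
  isotope_spec("As-72", beta_plus_yield = 0.88, mean_positron_range_mm = 5.19,
               prompt_lines = data.frame(energy_keV = c(693, 834),
                                         yield = c(0.0807, 0.81)))
}

#' Sample positron annihilation displacements
#'
#' Draws isotropic 3D displacements from emission point to annihilation point
#' whose radial magnitude has mean equal to the isotope's mean positron range.
#' Two radial models are provided:
#'
#' * `"gamma3"` (default): radial distance ~ Gamma(shape = 3,
#'   scale = mean/3), equivalent to an isotropic 3D exponential (Laplace)
#'   annihilation kernel `exp(-r/theta)` — a standard positron-range blurring
#'   kernel whose 3D density is bounded at the origin, appropriate for
#'   energetic beta+ spectra.
#' * `"twoexp"`: radial distance from a two-exponential mixture (fast + slow
#'   component, fixed fraction 0.6 and scale ratio 4, scales jointly
#'   calibrated to the mean). Its 3D density carries a 1/r^2 cusp at the
#'   origin; provided for sensitivity studies.
#'
#' A zero mean range yields the zero vector.
#'
#' @param isotope an [isotope_spec()].
#' @param n number of displacement vectors.
#' @param model radial model, `"gamma3"` or `"twoexp"`.
#' @return `n x 3` matrix of displacements, mm.
#' @export
sample_positron_displacement <- function(isotope, n = 1L,
                                         model = c("gamma3", "twoexp")) {
  model <- match.arg(model)
  mu <- isotope$mean_positron_range_mm
  if (mu == 0) return(matrix(0, n, 3))
  r <- switch(model,
    gamma3 = stats::rgamma(n, shape = 3, scale = mu / 3),
    twoexp = {
      w <- 0.6; ratio <- 4
      l1 <- mu / (w + (1 - w) * ratio)
      l2 <- ratio * l1
      fast <- stats::runif(n) < w
      stats::rexp(n, rate = 1) * ifelse(fast, l1, l2)
    }
  )
  u <- random_unit_vectors(n)
  u * r
}

#' Uniform random directions on the unit sphere
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
random_unit_vectors <- function(n) {
  ct <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  cbind(st * cos(phi), st * sin(phi), ct)
}

# ---------------------------------------------------------------------------
# materials

.material_meta <- list(
  czt = list(density = 5.78, effective_Z = 48.2),
  water = list(density = 1.0, effective_Z = 7.42)
)

#' Load a material specification
#'
#' Reads a packaged (or user-supplied) per-energy linear attenuation
#' coefficient table split by process. Packaged materials: `"czt"`
#' (Cd0.9Zn0.1Te, density 5.78 g/cm^3, effective Z 48.2) and `"water"`.
#' Table files are whitespace-delimited text with columns
#' `energy_keV mu_photo mu_compton mu_rayleigh` (cm^-1); `#` starts a comment.
#'
#' @param name `"czt"`, `"water"`, or a label for a custom table.
#' @param file optional path to a coefficient table (defaults to the packaged
#'   table for `name`).
#' @param density,effective_Z metadata for custom tables.
#' @return an object of class `material_spec` with elements `name`, `density`,
#'   `effective_Z` and `coefficient_table`.
#' @export
material_spec <- function(name, file = NULL, density = NULL, effective_Z = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", sprintf("coeff_%s.txt", name),
                        package = "petcc")
    if (file == "") stop("material_spec: no packaged table for ", name)
  }
  tab <- utils::read.table(file, comment.char = "#",
                           col.names = c("energy_keV", "mu_photo",
                                         "mu_compton", "mu_rayleigh"))
  if (any(as.matrix(tab) < 0)) stop("material_spec: negative coefficients")
  if (is.unsorted(tab$energy_keV, strictly = TRUE)) {
    stop("material_spec: energy grid must be strictly increasing")
  }
  meta <- .material_meta[[name]]
  structure(list(
    name = name,
    density = density %||% meta$density,
    effective_Z = effective_Z %||% meta$effective_Z,
    coefficient_table = tab
  ), class = "material_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate interaction coefficients
#'
#' Log-log interpolation of a material's per-process linear attenuation
#' coefficients; the total is the sum of the three processes.
#'
#' @param material a [material_spec()].
#' @param E energies, keV (vectorized); must lie within the table's grid.
#' @return matrix with columns `photoelectric`, `compton`, `rayleigh`, `total`
#'   (cm^-1), one row per energy.
#' @export
interaction_coefficients <- function(material, E) {
  tab <- material$coefficient_table
  rng <- range(tab$energy_keV)
  if (any(E < rng[1] | E > rng[2])) {
    stop(sprintf("interaction_coefficients: energy outside table grid [%g, %g] keV",
                 rng[1], rng[2]))
  }
  lE <- log(E)
  lx <- log(tab$energy_keV)
  interp <- function(col) {
    exp(stats::approx(lx, log(pmax(tab[[col]], 1e-300)), xout = lE)$y)
  }
  ph <- interp("mu_photo"); co <- interp("mu_compton"); ra <- interp("mu_rayleigh")
  cbind(photoelectric = ph, compton = co, rayleigh = ra, total = ph + co + ra)
}

# ---------------------------------------------------------------------------
# cones

#' Cone-of-response parameters
#'
#' Apex at the Compton scatter position; axis pointing from the absorption
#' site through the scatter site (back along the incoming photon direction,
#' toward the source side); half-angle from the Compton energy transfer;
#' angular standard deviation of the Gaussian volume-of-response kernel.
#'
#' @param apex 3-vector, mm.
#' @param axis unit 3-vector.
#' @param half_angle radians, in (0, pi).
#' @param angular_sigma radians, >= 0.
#' @return an object of class `cone_params`.
#' @export
cone_params <- function(apex, axis, half_angle, angular_sigma) {
  stopifnot(length(apex) == 3, length(axis) == 3,
            abs(sqrt(sum(axis^2)) - 1) < 1e-12,
            half_angle > 0, half_angle < pi, angular_sigma >= 0)
  structure(list(apex = as.numeric(apex), axis = as.numeric(axis),
                 half_angle = half_angle, angular_sigma = angular_sigma),
            class = "cone_params")
}
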