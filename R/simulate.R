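# Synthetic acquisition stage: decay generation, phantom transport, detector
# interaction sampling, and truth-labelled coincidence sorting into PET and
# CC list-mode records.
#
# All photon tracking is vectorized in lockstep: every transport round acts
# on the full vector of still-active photons, so a 1e5-decay acquisition
# runs in seconds without compiled tracking code.

E_MIN_KEV <- 10  # tracking floor: below the coefficient tables a photon is
                 # absorbed on the spot

#' Generate radioactive decays and emitted photons
#'
#' Draws a Poisson number of decays (mean `activity_bq * duration_s`),
#' uniformly positioned in the spherical source. Each decay emits a positron
#' with probability `beta_plus_yield`; the annihilation point is displaced
#' from the nuclide position by [sample_positron_displacement()] and emits a
#' collinear back-to-back 511 keV photon pair in a uniform random
#' orientation. Each prompt-gamma line is emitted independently with its
#' yield, isotropically from the nuclide position.
#'
#' @param isotope an [isotope_spec()].
#' @param activity_bq source activity, Bq.
#' @param duration_s acquisition time, s.
#' @param source_radius_mm radius of the spherical source (default 0.1 mm).
#' @param source_center source center, mm.
#' @param range_model radial model passed to [sample_positron_displacement()].
#' @param n_decays optional: fix the decay count instead of drawing it.
#' @return list with `decays` (data.frame: id, x, y, z, has_positron, ax, ay,
#'   az) and `photons` (data.frame: decay_id, kind, line_keV, energy, ox, oy,
#'   oz, dx, dy, dz).
#' @export
generate_decays <- function(isotope, activity_bq, duration_s,
                            source_radius_mm = 0.1,
                            source_center = c(0, 0, 0),
                            range_model = "gamma3",
                            n_decays = NULL) {
  stopifnot(activity_bq > 0, duration_s > 0)
  n <- if (is.null(n_decays)) stats::rpois(1, activity_bq * duration_s) else n_decays
  r <- source_radius_mm * stats::runif(n)^(1 / 3)
  pos <- random_unit_vectors(n) * r
  pos <- sweep(pos, 2, source_center, "+")
  has_pos <- stats::runif(n) < isotope$beta_plus_yield
  ann <- matrix(NA_real_, n, 3)
  if (any(has_pos)) {
    disp <- sample_positron_displacement(isotope, sum(has_pos), model = range_model)
    ann[has_pos, ] <- pos[has_pos, , drop = FALSE] + disp
  }
  decays <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       has_positron = has_pos,
                       ax = ann[, 1], ay = ann[, 2], az = ann[, 3])

  # annihilation photon pairs
  np <- sum(has_pos)
  dirs <- random_unit_vectors(np)
  idx <- which(has_pos)
  ann_ph <- data.frame(
    decay_id = rep(idx, each = 2),
    kind = "annih",
    line_keV = MEC2,
    energy = MEC2,
    ox = rep(ann[idx, 1], each = 2),
    oy = rep(ann[idx, 2], each = 2),
    oz = rep(ann[idx, 3], each = 2),
    dx = as.vector(rbind(dirs[, 1], -dirs[, 1])),
    dy = as.vector(rbind(dirs[, 2], -dirs[, 2])),
    dz = as.vector(rbind(dirs[, 3], -dirs[, 3]))
  )

  prompt_list <- lapply(seq_len(nrow(isotope$prompt_lines)), function(li) {
    E <- isotope$prompt_lines$energy_keV[li]
    y <- isotope$prompt_lines$yield[li]
    emit <- which(stats::runif(n) < y)
    d <- random_unit_vectors(length(emit))
    data.frame(decay_id = emit, kind = "prompt", line_keV = E, energy = E,
               ox = pos[emit, 1], oy = pos[emit, 2], oz = pos[emit, 3],
               dx = d[, 1], dy = d[, 2], dz = d[, 3])
  })
  photons <- do.call(rbind, c(list(ann_ph), prompt_list))
  if (is.null(photons)) {
    photons <- data.frame(decay_id = integer(), kind = character(),
                          line_keV = numeric(), energy = numeric(),
                          ox = numeric(), oy = numeric(), oz = numeric(),
                          dx = numeric(), dy = numeric(), dz = numeric())
  }
  rownames(photons) <- NULL
  list(decays = decays, photons = photons)
}

# rotate unit vectors d by polar angle theta (about d) with uniform azimuth
rotate_directions <- function(d, theta) {
  n <- nrow(d)
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal basis (e1, e2) perpendicular to d
  ref <- cbind(rep(1, n), 0, 0)
  swap <- abs(d[, 1]) > 0.9
  if (any(swap)) ref[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3, byrow = TRUE)
  e1 <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
              d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
              d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(d[, 2] * e1[, 3] - d[, 3] * e1[, 2],
              d[, 3] * e1[, 1] - d[, 1] * e1[, 3],
              d[, 1] * e1[, 2] - d[, 2] * e1[, 1])
  st <- sin(theta)
  d * cos(theta) + (e1 * cos(phi) + e2 * sin(phi)) * st
}

#' Transport photons through the water phantom
#'
#' Samples interactions along each photon's chord through the spherical
#' phantom using the water coefficients. Photoelectric absorption terminates
#' the photon; Compton scattering updates direction (Klein-Nishina) and
#' energy and flags the photon as phantom-scattered; Rayleigh scattering is
#' direction-preserving with no energy deposit but also sets the flag.
#' Photons starting outside the phantom (e.g. annihilation points beyond the
#' phantom surface) exit unchanged.
#'
#' @param photons photon data.frame as from [generate_decays()].
#' @param phantom list with `center` (mm), `radius_mm`, `material` (a
#'   [material_spec()]; defaults to packaged water).
#' @return the photon data.frame with updated position/direction/energy and
#'   logical columns `phantom_scattered` and `alive`.
#' @export
transport_phantom <- function(photons, phantom = list()) {
  phantom <- utils::modifyList(
    list(center = c(0, 0, 0), radius_mm = 10, material = NULL), phantom)
  mat <- phantom$material %||% material_spec("water")
  ph <- photons
  ph$phantom_scattered <- FALSE
  ph$alive <- TRUE
  if (phantom$radius_mm <= 0 || nrow(ph) == 0) return(ph)

  pos <- as.matrix(ph[, c("ox", "oy", "oz")])
  dir <- as.matrix(ph[, c("dx", "dy", "dz")])
  E <- ph$energy
  active <- rowSums(sweep(pos, 2, phantom$center, "-")^2) < phantom$radius_mm^2 &
    ph$alive
  for (round in 1:10) {
    ia <- which(active)
    if (!length(ia)) break
    p <- sweep(pos[ia, , drop = FALSE], 2, phantom$center, "-")
    d <- dir[ia, , drop = FALSE]
    b <- rowSums(p * d)
    cc <- rowSums(p^2) - phantom$radius_mm^2
    t_exit <- -b + sqrt(pmax(b^2 - cc, 0))
    mu <- interaction_coefficients(mat, E[ia])
    s <- stats::rexp(length(ia)) / mu[, "total"] * 10  # cm -> mm
    hit <- s < t_exit
    # photons that exit: advance to the surface
    out <- ia[!hit]
    pos[out, ] <- pos[out, , drop = FALSE] + dir[out, , drop = FALSE] * t_exit[!hit]
    active[out] <- FALSE
    ih <- ia[hit]
    if (!length(ih)) break
    pos[ih, ] <- pos[ih, , drop = FALSE] + dir[ih, , drop = FALSE] * s[hit]
    u <- stats::runif(length(ih)) * mu[hit, "total"]
    is_pe <- u < mu[hit, "photoelectric"]
    is_co <- !is_pe & u < mu[hit, "photoelectric"] + mu[hit, "compton"]
    # photoelectric: absorbed in the phantom
    ph$alive[ih[is_pe]] <- FALSE
    active[ih[is_pe]] <- FALSE
    # Compton: redirect, degrade energy, flag
    ico <- ih[is_co]
    if (length(ico)) {
      th <- sample_klein_nishina_angle(E[ico], length(ico))
      k <- E[ico] / MEC2
      Enew <- E[ico] / (1 + k * (1 - cos(th)))
      dir[ico, ] <- rotate_directions(dir[ico, , drop = FALSE], th)
      E[ico] <- Enew
      ph$phantom_scattered[ico] <- TRUE
      dead <- ico[Enew < E_MIN_KEV]
      ph$alive[dead] <- FALSE
      active[dead] <- FALSE
    }
    # Rayleigh: flag only
    ira <- ih[!is_pe & !is_co]
    ph$phantom_scattered[ira] <- TRUE
  }
  ph$ox <- pos[, 1]; ph$oy <- pos[, 2]; ph$oz <- pos[, 3]
  ph$dx <- dir[, 1]; ph$dy <- dir[, 2]; ph$dz <- dir[, 3]
  ph$energy <- E
  ph
}

# vectorized ray/axis-aligned-box intersection; returns (tmin, tmax)
ray_box <- function(pos, dir, lo, hi) {
  big <- 1e30
  tmin <- rep(-big, nrow(pos)); tmax <- rep(big, nrow(pos))
  for (ax in 1:3) {
    d <- dir[, ax]
    par <- abs(d) < 1e-12
    t1 <- (lo[ax] - pos[, ax]) / ifelse(par, 1, d)
    t2 <- (hi[ax] - pos[, ax]) / ifelse(par, 1, d)
    ta <- pmin(t1, t2); tb <- pmax(t1, t2)
    inside_slab <- pos[, ax] > lo[ax] & pos[, ax] < hi[ax]
    ta[par] <- ifelse(inside_slab[par], -big, big)
    tb[par] <- ifelse(inside_slab[par], big, -big)
    tmin <- pmax(tmin, ta); tmax <- pmin(tmax, tb)
  }
  cbind(tmin, tmax)
}

#' Track photons through the CZT panels
#'
#' Ray-traces each photon into the panel boxes and repeatedly samples the
#' free path from the CZT total attenuation coefficient and the interaction
#' type from the per-process coefficient ratios. Compton scatters deposit the
#' angle-derived transfer energy and redirect the photon via
#' [sample_klein_nishina_angle()]; photoelectric absorption deposits the
#' remaining energy and terminates the track; Rayleigh scatters are recorded
#' with zero deposit and preserve the direction. Tracking stops on panel
#' exit (with re-entry into the other panel allowed), termination, or
#' `max_interactions` recorded hits. Hit positions are quantized to the
#' readout pitch via [quantize_position()].
#'
#' @param photons photon data.frame (with positions outside the panels).
#' @param geometry a [build_geometry()] result.
#' @param material CZT [material_spec()] (default packaged).
#' @param max_interactions maximum recorded interactions per photon.
#' @return data.frame of hits: `photon` (row index into `photons`), `order`,
#'   `process`, `x, y, z` (quantized to the readout pitch, mm), `xt, yt, zt`
#'   (true interaction position, mm), `crystal`, `deposited_keV`.
#' @export
interact_detector <- function(photons, geometry, material = NULL,
                              max_interactions = 5L) {
  mat <- material %||% material_spec("czt")
  n <- nrow(photons)
  if (n == 0) {
    return(data.frame(photon = integer(), order = integer(),
                      process = character(), x = numeric(), y = numeric(),
                      z = numeric(), xt = numeric(), yt = numeric(),
                      zt = numeric(), crystal = integer(),
                      deposited_keV = numeric()))
  }
  cfg <- geometry$config
  y0 <- cfg$panel_separation_mm / 2
  boxes <- list(
    list(lo = c(-cfg$panel_width_mm / 2, y0, -cfg$panel_height_mm / 2),
         hi = c(cfg$panel_width_mm / 2, y0 + cfg$panel_depth_mm,
                cfg$panel_height_mm / 2)),
    list(lo = c(-cfg$panel_width_mm / 2, -y0 - cfg$panel_depth_mm,
                -cfg$panel_height_mm / 2),
         hi = c(cfg$panel_width_mm / 2, -y0, cfg$panel_height_mm / 2))
  )

  pos <- as.matrix(photons[, c("ox", "oy", "oz")])
  dir <- as.matrix(photons[, c("dx", "dy", "dz")])
  E <- photons$energy
  alive <- if ("alive" %in% names(photons)) photons$alive else rep(TRUE, n)
  norder <- integer(n)
  hits <- vector("list", 0)

  for (round in seq_len(2L * max_interactions + 4L)) {
    ia <- which(alive & norder < max_interactions)
    if (!length(ia)) break
    p <- pos[ia, , drop = FALSE]; d <- dir[ia, , drop = FALSE]
    iv1 <- ray_box(p, d, boxes[[1]]$lo, boxes[[1]]$hi)
    iv2 <- ray_box(p, d, boxes[[2]]$lo, boxes[[2]]$hi)
    eps <- 1e-9
    v1 <- iv1[, 2] > pmax(iv1[, 1], 0) + eps
    v2 <- iv2[, 2] > pmax(iv2[, 1], 0) + eps
    # nearest panel interval ahead of the photon
    t0 <- ifelse(v1 & (!v2 | pmax(iv1[, 1], 0) <= pmax(iv2[, 1], 0)),
                 pmax(iv1[, 1], 0), pmax(iv2[, 1], 0))
    t1 <- ifelse(v1 & (!v2 | pmax(iv1[, 1], 0) <= pmax(iv2[, 1], 0)),
                 iv1[, 2], iv2[, 2])
    none <- !v1 & !v2
    alive[ia[none]] <- FALSE
    ii <- which(!none)
    if (!length(ii)) break
    idx <- ia[ii]
    mu <- interaction_coefficients(mat, E[idx])
    s <- stats::rexp(length(idx)) / mu[, "total"] * 10  # cm -> mm
    through <- s > (t1[ii] - t0[ii])
    # no interaction in this panel: hop past its far face and retry
    ithr <- idx[through]
    pos[ithr, ] <- pos[ithr, , drop = FALSE] +
      dir[ithr, , drop = FALSE] * (t1[ii][through] + 1e-6)
    iint <- idx[!through]
    if (length(iint)) {
      tint <- t0[ii][!through] + s[!through]
      pint <- pos[iint, , drop = FALSE] + dir[iint, , drop = FALSE] * tint
      mui <- mu[!through, , drop = FALSE]
      u <- stats::runif(length(iint)) * mui[, "total"]
      is_pe <- u < mui[, "photoelectric"]
      is_co <- !is_pe & u < mui[, "photoelectric"] + mui[, "compton"]
      proc <- ifelse(is_pe, "photoelectric", ifelse(is_co, "compton", "rayleigh"))
      dep <- numeric(length(iint))
      dep[is_pe] <- E[iint[is_pe]]
      if (any(is_co)) {
        ico <- iint[is_co]
        th <- sample_klein_nishina_angle(E[ico], length(ico))
        k <- E[ico] / MEC2
        Enew <- E[ico] / (1 + k * (1 - cos(th)))
        dep[is_co] <- E[ico] - Enew
        dir[ico, ] <- rotate_directions(dir[ico, , drop = FALSE], th)
        E[ico] <- Enew
      }
      pos[iint, ] <- pint
      cry <- locate_point(geometry, pint)
      # numerical edge: clamp just inside the crystal before quantizing
      ok <- !is.na(cry)
      qp <- pint
      if (any(ok)) {
        qp[ok, ] <- quantize_position(geometry, pint[ok, , drop = FALSE], cry[ok])
      }
      norder[iint] <- norder[iint] + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        photon = iint, order = norder[iint], process = proc,
        x = qp[, 1], y = qp[, 2], z = qp[, 3],
        xt = pint[, 1], yt = pint[, 2], zt = pint[, 3], crystal = cry,
        deposited_keV = dep
      )
      alive[iint[is_pe]] <- FALSE
      # sub-threshold residual energy: deposit locally as photoelectric
      low <- iint[is_co][E[iint[is_co]] < E_MIN_KEV & norder[iint[is_co]] < max_interactions]
      if (length(low)) {
        norder[low] <- norder[low] + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          photon = low, order = norder[low], process = "photoelectric",
          x = qp[match(low, iint), 1], y = qp[match(low, iint), 2],
          z = qp[match(low, iint), 3],
          xt = pint[match(low, iint), 1], yt = pint[match(low, iint), 2],
          zt = pint[match(low, iint), 3], crystal = cry[match(low, iint)],
          deposited_keV = E[low]
        )
        alive[low] <- FALSE
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(photon = integer(), order = integer(), process = character(),
               x = numeric(), y = numeric(), z = numeric(), xt = numeric(),
               yt = numeric(), zt = numeric(), crystal = integer(),
               deposited_keV = numeric())
  out <- out[order(out$photon, out$order), ]
  rownames(out) <- NULL
  out
}

#' Sort truth-labelled hits into coincidence records and the energy spectrum
#'
#' A PET line of response is kept when both annihilation photons of one decay
#' are fully absorbed in the detectors (summed deposits equal to 511 keV),
#' neither is phantom-scattered, and the two first-interaction positions lie
#' in opposite panels. A Compton-camera record is kept when a prompt photon's
#' track is exactly one Compton scatter followed by one photoelectric
#' absorption with full energy containment and no phantom scatter. The energy
#' spectrum accumulates every positive hit deposit in 1 keV bins keyed by
#' process.
#'
#' Record positions default to the true interaction points: the study design
#' reconstructs from ground-truth coordinates without spatial blurring, and
#' the cross-strip readout quantization (coarsest along the 5 mm depth
#' pitch) would otherwise tilt cone axes over the short scatter-absorption
#' baselines. Set `positions = "quantized"` to emulate the readout instead.
#'
#' @param sim list with `decays` and `photons` (from [generate_decays()],
#'   with transport columns) and `hits` (from [interact_detector()]).
#' @param geometry a [build_geometry()] result.
#' @param positions `"true"` (default) or `"quantized"`: which interaction
#'   coordinates enter the LOR and CC records.
#' @return list with `lor` (data.frame x1..z2), `cc` (data.frame
#'   xs..E2 + `line_keV`), `spectrum` (data.frame energy_keV, count_total,
#'   count_phot, count_compt) and `counts` (named vector of diagnostics).
#' @export
sort_coincidences <- function(sim, geometry,
                              positions = c("true", "quantized")) {
  positions <- match.arg(positions)
  poscols <- if (positions == "true") c("xt", "yt", "zt") else c("x", "y", "z")
  photons <- sim$photons
  hits <- sim$hits
  dep <- hits$deposited_keV
  # spectrum: 1 keV bins centered on integers
  bin <- as.integer(round(dep[dep > 0]))
  procp <- hits$process[dep > 0]
  emax <- max(c(bin, 1L))
  cnt <- function(sel) tabulate(bin[sel], nbins = emax)
  spectrum <- data.frame(
    energy_keV = seq_len(emax),
    count_total = cnt(rep(TRUE, length(bin))),
    count_phot = cnt(procp == "photoelectric"),
    count_compt = cnt(procp == "compton")
  )

  nph <- nrow(photons)
  absorbed <- rep(FALSE, nph)
  nhits <- integer(nph)
  if (nrow(hits)) {
    ds <- rowsum(dep, hits$photon)
    ph_idx <- as.integer(rownames(ds))
    absorbed[ph_idx] <- abs(ds[, 1] - photons$line_keV[ph_idx]) < 1e-6
    nhits <- tabulate(hits$photon, nbins = nph)
  }

  first <- hits[hits$order == 1L, ]
  fpos <- matrix(NA_real_, nrow(photons), 3)
  fcry <- rep(NA_integer_, nrow(photons))
  fproc <- rep(NA_character_, nrow(photons))
  fpos[first$photon, ] <- as.matrix(first[, poscols])
  fcry[first$photon] <- first$crystal
  fproc[first$photon] <- first$process

  # --- PET LORs
  is_ann <- photons$kind == "annih"
  good_ann <- is_ann & absorbed & !photons$phantom_scattered & !is.na(fcry)
  panel_of <- rep(NA_integer_, nrow(photons))
  panel_of[!is.na(fcry)] <- geometry$crystals$panel[fcry[!is.na(fcry)]]
  # pair the two annihilation photons of each decay (each positron decay
  # emits exactly two; sort by decay id and take consecutive rows)
  ann_idx <- which(is_ann)
  ord <- ann_idx[order(photons$decay_id[ann_idx])]
  a1 <- ord[c(TRUE, FALSE)]
  a2 <- ord[c(FALSE, TRUE)]
  both_good <- good_ann[a1] & good_ann[a2]
  opposite <- both_good & panel_of[a1] != panel_of[a2]
  same_panel <- sum(both_good & !opposite, na.rm = TRUE)
  keep <- which(opposite)
  lor <- data.frame(x1 = fpos[a1[keep], 1], y1 = fpos[a1[keep], 2],
                    z1 = fpos[a1[keep], 3],
                    x2 = fpos[a2[keep], 1], y2 = fpos[a2[keep], 2],
                    z2 = fpos[a2[keep], 3])

  # --- CC records: prompt, exactly compton(1) then photoelectric(2)
  cc_ph <- which(photons$kind == "prompt" & !photons$phantom_scattered &
                   absorbed & nhits == 2L & fproc == "compton")
  if (length(cc_ph)) {
    second <- hits[hits$order == 2L & hits$process == "photoelectric", ]
    m <- match(cc_ph, second$photon)
    keep <- !is.na(m)
    cc_ph <- cc_ph[keep]; m <- m[keep]
    e1 <- numeric(length(cc_ph))
    f1 <- match(cc_ph, first$photon)
    e1 <- first$deposited_keV[f1]
    cc <- data.frame(
      xs = fpos[cc_ph, 1], ys = fpos[cc_ph, 2], zs = fpos[cc_ph, 3],
      E1 = e1,
      xa = second[[poscols[1]]][m], ya = second[[poscols[2]]][m],
      za = second[[poscols[3]]][m],
      E2 = second$deposited_keV[m],
      line_keV = photons$line_keV[cc_ph]
    )
    # degenerate: scatter and absorption quantized to the same point
    cc <- cc[(cc$xs - cc$xa)^2 + (cc$ys - cc$ya)^2 + (cc$zs - cc$za)^2 > 1e-12, ]
  } else {
    cc <- data.frame(xs = numeric(), ys = numeric(), zs = numeric(),
                     E1 = numeric(), xa = numeric(), ya = numeric(),
                     za = numeric(), E2 = numeric(), line_keV = numeric())
  }
  rownames(cc) <- NULL

  counts <- c(n_decays = nrow(sim$decays), n_photons = nrow(photons),
              n_hits = nrow(hits), n_lor = nrow(lor), n_cc = nrow(cc),
              n_lor_same_panel_dropped = same_panel)
  list(lor = lor, cc = cc, spectrum = spectrum, counts = counts)
}

#' Apply Gaussian energy blur to CC records
#'
#' Adds independent zero-mean Gaussian noise of the stated FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2))) to both deposited energies of each
#' record, clamping at a small positive floor.
#'
#' @param cc_records CC record data.frame.
#' @param fwhm_keV energy resolution as FWHM, keV (>= 0).
#' @param floor_keV positive clamp floor.
#' @return the blurred records.
#' @export
apply_energy_blur <- function(cc_records, fwhm_keV, floor_keV = 0.1) {
  if (fwhm_keV < 0) stop("apply_energy_blur: fwhm_keV must be >= 0")
  if (fwhm_keV == 0 || nrow(cc_records) == 0) return(cc_records)
  sd <- fwhm_keV / (2 * sqrt(2 * log(2)))
  cc_records$E1 <- pmax(cc_records$E1 + stats::rnorm(nrow(cc_records), 0, sd),
                        floor_keV)
  cc_records$E2 <- pmax(cc_records$E2 + stats::rnorm(nrow(cc_records), 0, sd),
                        floor_keV)
  cc_records
}

#' Run a full synthetic acquisition
#'
#' Convenience driver: [generate_decays()], [transport_phantom()],
#' [interact_detector()], [sort_coincidences()].
#'
#' @param isotope an [isotope_spec()] (default packaged 72As).
#' @param geometry a [build_geometry()] result (default paper configuration).
#' @param activity_bq,duration_s source activity and acquisition time.
#' @param phantom phantom list passed to [transport_phantom()].
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param keep_hits if `TRUE`, the returned list includes the hit and photon
#'   tables (needed for truth-based spectrum studies).
#' @param ... further arguments to [generate_decays()].
#' @return list with `lor`, `cc`, `spectrum`, `counts` and (optionally)
#'   `hits`, `photons`, `decays`.
#' @export
simulate_acquisition <- function(isotope = isotope_as72(),
                                 geometry = build_geometry(),
                                 activity_bq = 2e6, duration_s = 1,
                                 phantom = list(), seed = NULL,
                                 keep_hits = FALSE, positions = "true", ...) {
  if (!is.null(seed)) set.seed(seed)
  gen <- generate_decays(isotope, activity_bq, duration_s, ...)
  ph <- transport_phantom(gen$photons, phantom)
  hits <- interact_detector(ph[ph$alive, , drop = FALSE], geometry)
  # re-index hit photon ids to the full photon table
  hits$photon <- which(ph$alive)[hits$photon]
  sim <- list(decays = gen$decays, photons = ph, hits = hits)
  out <- sort_coincidences(sim, geometry, positions = positions)
  if (keep_hits) {
    out$hits <- hits; out$photons <- ph; out$decays <- gen$decays
  }
  out
}
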