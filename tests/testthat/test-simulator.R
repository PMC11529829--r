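# Decay generation, phantom transport, detector interaction sampling,
# coincidence sorting, energy blur.

test_that("decay generation reproduces the configured yields", {
  set.seed(21)
  iso <- isotope_as72()
  gen <- generate_decays(iso, activity_bq = 2e6, duration_s = 0.02)
  n <- nrow(gen$decays)
  expect_lt(abs(n - 4e4), 3 * sqrt(4e4))           # Poisson decay count
  f_pos <- mean(gen$decays$has_positron)
  expect_lt(abs(f_pos - 0.88), 3 * sqrt(0.88 * 0.12 / n))
  f_834 <- sum(gen$photons$kind == "prompt" & gen$photons$line_keV == 834) / n
  expect_lt(abs(f_834 - 0.81), 3 * sqrt(0.81 * 0.19 / n))
  # nuclide positions inside the 0.1 mm source sphere
  expect_lt(max(sqrt(rowSums(gen$decays[, c("x", "y", "z")]^2))), 0.1 + 1e-12)
  # annihilation photons come in collinear pairs
  ann <- gen$photons[gen$photons$kind == "annih", ]
  expect_equal(nrow(ann), 2 * sum(gen$decays$has_positron))
  d1 <- as.matrix(ann[c(TRUE, FALSE), c("dx", "dy", "dz")])
  d2 <- as.matrix(ann[c(FALSE, TRUE), c("dx", "dy", "dz")])
  expect_equal(d1, -d2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("phantom transport matches the closed-form attenuation and flags scatters", {
  set.seed(22)
  n <- 4e4
  ph <- data.frame(decay_id = seq_len(n), kind = "annih", line_keV = 511,
                   energy = 511, ox = 0, oy = 0, oz = 0)
  d <- random_unit_vectors(n)
  ph$dx <- d[, 1]; ph$dy <- d[, 2]; ph$dz <- d[, 3]
  out <- transport_phantom(ph, phantom = list(radius_mm = 10))
  # survival over the 1 cm chord = exp(-mu_total(511) * 1 cm)
  mu <- interaction_coefficients(material_spec("water"), 511)[, "total"]
  p_exp <- exp(-mu * 1)
  p_obs <- mean(!out$phantom_scattered & out$alive)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  # unscattered photons keep direction and energy and sit on the surface
  keep <- !out$phantom_scattered & out$alive
  expect_equal(out$energy[keep], rep(511, sum(keep)))
  expect_equal(sqrt(out$ox[keep]^2 + out$oy[keep]^2 + out$oz[keep]^2),
               rep(10, sum(keep)), tolerance = 1e-9)
  # zero-diameter phantom: photons exit unchanged
  out0 <- transport_phantom(ph, phantom = list(radius_mm = 0))
  expect_false(any(out0$phantom_scattered))
  expect_true(all(out0$alive))
})

test_that("detector tracking matches the attenuation oracle and conserves energy", {
  set.seed(23)
  g <- paper_geometry()
  n <- 2e4
  ph <- data.frame(decay_id = seq_len(n), kind = "annih", line_keV = 511,
                   energy = 511, ox = stats::runif(n, -90, 90), oy = 0,
                   oz = stats::runif(n, -65, 65),
                   dx = 0, dy = 1, dz = 0, phantom_scattered = FALSE,
                   alive = TRUE)
  hits <- interact_detector(ph, g)
  # interaction probability over the 4 cm depth (normal incidence)
  mu <- interaction_coefficients(material_spec("czt"), 511)[, "total"]
  p_exp <- 1 - exp(-mu * 4)
  p_obs <- length(unique(hits$photon)) / n
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  # photon aimed to miss both panels (parallel to the panel faces)
  miss <- ph[1, ]; miss$dy <- 0; miss$dx <- 1
  expect_equal(nrow(interact_detector(miss, g)), 0)
  # energy conservation on fully absorbed tracks
  dep <- rowsum(hits$deposited_keV, hits$photon)
  ends_pe <- tapply(hits$process, hits$photon, function(p) p[length(p)] == "photoelectric")
  full <- dep[ends_pe, 1]
  expect_true(all(abs(full - 511) < 1e-6))
  # compton deposits never exceed the incident-energy Compton edge
  first_co <- hits[hits$order == 1 & hits$process == "compton", ]
  expect_true(all(first_co$deposited_keV <= compton_edge(511) + 1e-9))
  # all hit positions resolve to crystals
  expect_false(anyNA(hits$crystal))
})

test_that("coincidence sorting applies the truth-based selection rules", {
  set.seed(24)
  g <- paper_geometry()
  sim <- simulate_acquisition(activity_bq = 2e6, duration_s = 0.005,
                              keep_hits = TRUE)
  # every CC record: pre-blur energies sum exactly to a prompt line
  expect_true(all(abs(sim$cc$E1 + sim$cc$E2 - sim$cc$line_keV) < 1e-6))
  expect_true(all(sim$cc$line_keV %in% c(693, 834)))
  # LOR endpoints lie in crystals, in opposite panels
  p1 <- locate_point(g, as.matrix(sim$lor[, c("x1", "y1", "z1")]))
  p2 <- locate_point(g, as.matrix(sim$lor[, c("x2", "y2", "z2")]))
  expect_false(anyNA(p1) || anyNA(p2))
  expect_true(all(g$crystals$panel[p1] != g$crystals$panel[p2]))
  # no decay without a positron contributes an LOR
  expect_lte(nrow(sim$lor), sum(sim$decays$has_positron))
  # a prompt photon absorbed photoelectrically in one step yields no CC
  # record but a full-energy spectrum entry
  one_step <- with(sim, {
    nh <- tabulate(hits$photon, nbins = nrow(photons))
    which(photons$kind == "prompt" & photons$line_keV == 834 &
            !photons$phantom_scattered & nh == 1)
  })
  h1 <- sim$hits[sim$hits$photon %in% one_step & sim$hits$process == "photoelectric", ]
  if (nrow(h1)) expect_true(all(abs(h1$deposited_keV - 834) < 1e-6))
  expect_gt(sim$spectrum$count_phot[sim$spectrum$energy_keV == 834], 0)
  # phantom-scattered photons are excluded from records
  sc <- which(sim$photons$phantom_scattered)
  cc_ph <- which(sim$photons$kind == "prompt" & !sim$photons$phantom_scattered)
  expect_true(nrow(sim$cc) <= length(cc_ph))
})

test_that("energy blur follows the FWHM convention and clamps positive", {
  set.seed(25)
  cc <- data.frame(xs = 0, ys = 100, zs = 0, E1 = rep(300, 1e4),
                   xa = 0, ya = 110, za = 0, E2 = rep(534, 1e4))
  expect_identical(apply_energy_blur(cc, 0), cc)
  b <- apply_energy_blur(cc, 51)
  sd_obs <- stats::sd(b$E1 - cc$E1)
  sd_exp <- 51 / (2 * sqrt(2 * log(2)))
  se <- sd_exp / sqrt(2 * (nrow(cc) - 1))
  expect_lt(abs(sd_obs - sd_exp), 3 * se)
  expect_true(all(b$E1 > 0 & b$E2 > 0))
  # heavy blur on small energies still clamps positive
  low <- data.frame(xs = 0, ys = 100, zs = 0, E1 = rep(1, 1000),
                    xa = 0, ya = 110, za = 0, E2 = rep(833, 1000))
  bl <- apply_energy_blur(low, 51)
  expect_true(all(bl$E1 > 0))
  expect_error(apply_energy_blur(cc, -1), ">= 0")
})

test_that("identical config and seed give byte-identical list-mode files", {
  run <- function() {
    sim <- simulate_acquisition(activity_bq = 2e6, duration_s = 0.002,
                                seed = 77)
    f1 <- tempfile(); f2 <- tempfile()
    write_pet_lm(sim$lor, f1)
    write_cc_lm(sim$cc[sim$cc$line_keV == 834, ], f2)
    list(pet = readBin(f1, "raw", file.info(f1)$size),
         cc = readBin(f2, "raw", file.info(f2)$size))
  }
  a <- run(); b <- run()
  expect_identical(a$pet, b$pet)
  expect_identical(a$cc, b$cc)
})
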