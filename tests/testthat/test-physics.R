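# Compton kinematics, Klein-Nishina sampling, coefficient tables, positron
# range sampling.

test_that("Compton edge matches the closed form and its brute-force scan", {
  expect_equal(compton_edge(511), 2 * 511^2 / (511 + 2 * 511), tolerance = 1e-12)
  expect_equal(round(compton_edge(511), 2), 340.67)
  # brute-force: maximize the transfer over theta for 834 keV
  th <- seq(1e-4, pi, length.out = 20000)
  expect_equal(compton_edge(834), max(angle_to_transfer(834, th)),
               tolerance = 1e-6)
  expect_lt(compton_edge(1e-6), 1e-6)      # edge -> 0 with E0 -> 0
  E <- c(100, 300, 511, 834, 1500)
  expect_true(all(compton_edge(E) < E))
  expect_true(all(diff(compton_edge(seq(10, 1700, by = 5))) > 0))
  expect_error(compton_edge(-1), "positive")
})

test_that("angle/transfer relation round-trips and honors its domain", {
  expect_equal(compton_transfer_to_angle(511, compton_edge(511)), pi,
               tolerance = 1e-9)
  expect_lt(compton_transfer_to_angle(511, 1e-9), 1e-3)  # no transfer, no deflection
  for (E0 in c(170, 511, 834, 1200)) {
    th <- seq(0.05, pi - 0.05, length.out = 25)
    back <- compton_transfer_to_angle(E0, angle_to_transfer(E0, th))
    expect_equal(back, th, tolerance = 1e-10)
  }
  expect_equal(compton_transfer_to_angle(834, angle_to_transfer(834, pi / 3)),
               pi / 3, tolerance = 1e-10)
  expect_error(compton_transfer_to_angle(511, 400), "keV")
  expect_error(compton_transfer_to_angle(511, -3), "keV")
})

test_that("Klein-Nishina sampler matches the analytic density", {
  set.seed(7)
  # chi-square GOF against the normalized KN pdf at three energies
  for (E0 in c(170, 511, 834)) {
    th <- sample_klein_nishina_angle(E0, n = 1e5)
    breaks <- seq(0, pi, length.out = 41)
    obs <- table(cut(th, breaks))
    p <- vapply(seq_len(40), function(i) {
      stats::integrate(function(x) klein_nishina_pdf(x, E0), breaks[i],
                       breaks[i + 1], rel.tol = 1e-8)$value
    }, numeric(1))
    gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p / sum(p)))
    expect_gt(gof$p.value, 0.01)
  }
  # mean cos(theta) against quadrature at 511 keV
  th <- sample_klein_nishina_angle(511, n = 1e5)
  m_exp <- stats::integrate(function(x) cos(x) * klein_nishina_pdf(x, 511),
                            0, pi, rel.tol = 1e-10)$value
  v_exp <- stats::integrate(function(x) cos(x)^2 * klein_nishina_pdf(x, 511),
                            0, pi, rel.tol = 1e-10)$value - m_exp^2
  expect_lt(abs(mean(cos(th)) - m_exp), 3 * sqrt(v_exp / 1e5))
})

test_that("Klein-Nishina sampler reaches the Thomson limit and is seed-deterministic", {
  set.seed(8)
  th <- sample_klein_nishina_angle(0.01, n = 1e5)
  breaks <- seq(0, pi, length.out = 31)
  obs <- table(cut(th, breaks))
  thomson <- function(x) (1 + cos(x)^2) * sin(x)
  Z <- stats::integrate(thomson, 0, pi)$value
  p <- vapply(seq_len(30), function(i) {
    stats::integrate(thomson, breaks[i], breaks[i + 1])$value / Z
  }, numeric(1))
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)

  set.seed(99); a <- sample_klein_nishina_angle(511, n = 1000)
  set.seed(99); b <- sample_klein_nishina_angle(511, n = 1000)
  expect_identical(a, b)
})

test_that("positron displacement recovers the configured mean range", {
  set.seed(9)
  for (mu in c(1.27, 3.56, 5.19)) {
    iso <- isotope_spec("test", 0.9, mu)
    for (model in c("gamma3", "twoexp")) {
      d <- sample_positron_displacement(iso, 2e4, model = model)
      r <- sqrt(rowSums(d^2))
      expect_lt(abs(mean(r) - mu), 3 * stats::sd(r) / sqrt(length(r)))
    }
  }
  # isotropy: each Cartesian component has mean 0
  iso <- isotope_as72()
  d <- sample_positron_displacement(iso, 1e5)
  r <- sqrt(rowSums(d^2))
  for (ax in 1:3) {
    expect_lt(abs(mean(d[, ax])), 3 * stats::sd(d[, ax]) / sqrt(nrow(d)))
  }
  # zero mean range -> zero vector
  iso0 <- isotope_spec("zero", 0.9, 0)
  expect_true(all(sample_positron_displacement(iso0, 10) == 0))
})

test_that("packaged 72As spec carries the tabulated decay properties", {
  iso <- isotope_as72()
  expect_equal(iso$beta_plus_yield, 0.88)
  expect_equal(iso$mean_positron_range_mm, 5.19)
  expect_equal(iso$prompt_lines$energy_keV, c(693, 834))
  expect_equal(iso$prompt_lines$yield, c(0.0807, 0.81))
  expect_error(isotope_spec("bad", 1.2, 1), "beta_plus_yield")
})

test_that("material tables interpolate correctly and order the photoelectric cross-section", {
  czt <- material_spec("czt")
  expect_equal(czt$density, 5.78)
  expect_equal(czt$effective_Z, 48.2)
  tab <- czt$coefficient_table
  expect_gte(nrow(tab), 30)
  expect_lte(min(tab$energy_keV), 10)
  expect_gte(max(tab$energy_keV), 1700)
  # interpolation reproduces the knots
  k <- c(3, 17, 40)
  mu <- interaction_coefficients(czt, tab$energy_keV[k])
  expect_equal(unname(mu[, "photoelectric"]), tab$mu_photo[k], tolerance = 1e-12)
  expect_equal(unname(mu[, "total"]),
               tab$mu_photo[k] + tab$mu_compton[k] + tab$mu_rayleigh[k],
               tolerance = 1e-9)
  # photoelectric falls with energy: 340 > 511 > 834 keV
  pe <- interaction_coefficients(czt, c(340, 511, 834))[, "photoelectric"]
  expect_true(all(diff(pe) < 0))
  expect_error(interaction_coefficients(czt, 5000), "grid")
})

test_that("cone parameter container enforces its invariants", {
  expect_s3_class(cone_params(c(0, 100, 0), c(0, -1, 0), pi / 4, 0.01),
                  "cone_params")
  expect_error(cone_params(c(0, 100, 0), c(0, -2, 0), pi / 4, 0.01))
  expect_error(cone_params(c(0, 100, 0), c(0, -1, 0), 0, 0.01))
  expect_error(cone_params(c(0, 100, 0), c(0, -1, 0), pi / 4, -1))
})
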