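# Cone parameterization, angular-sigma propagation, cone projector, CC MLEM.

test_that("noiseless cones contain the true source direction", {
  set.seed(51)
  src <- c(2, -3, 5)
  for (i in 1:10) {
    apex <- c(stats::runif(1, -80, 80), sample(c(-1, 1), 1) * stats::runif(1, 100, 135),
              stats::runif(1, -60, 60))
    theta <- stats::runif(1, 0.2, 1.3)
    rec <- make_cc_record(src, apex, theta, azimuth = stats::runif(1, 0, 2 * pi))
    cone <- cone_from_record(rec, assumed_E0 = 834, model = angular_model(0, 0))
    u <- src - cone$apex; u <- u / sqrt(sum(u^2))
    dev <- abs(acos(sum(u * cone$axis)) - cone$half_angle)
    expect_lt(dev, 1e-9)
  }
})

test_that("cone construction handles degenerate and clamped kinematics", {
  rec <- make_cc_record(c(0, 0, 0), c(10, 110, 5), 0.8)
  # E1 -> 0: half-angle -> 0
  rec0 <- rec; rec0$E1 <- 1e-9
  cone0 <- cone_from_record(rec0, 834, angular_model(0, 0))
  expect_lt(cone0$half_angle, 1e-3)
  # E1 above the edge (blur): clamped to just inside, still well-formed
  recb <- rec; recb$E1 <- compton_edge(834) + 5
  coneb <- cone_from_record(recb, 834, angular_model(51))
  expect_true(coneb$half_angle > 0 && coneb$half_angle < pi)
  # invalid kinematics
  rece <- rec; rece$E1 <- 900
  expect_error(cone_from_record(rece, 834), "kinematics")
  recd <- rec; recd$xa <- rec$xs; recd$ya <- rec$ys; recd$za <- rec$zs
  expect_error(cone_from_record(recd, 834), "coincide")
})

test_that("angular sigma propagation matches a finite-difference oracle", {
  model0 <- angular_model(energy_fwhm_keV = 10, doppler_sigma0 = 0)
  for (E1 in c(100, 250, 400, 600)) {
    sig <- as.numeric(propagate_angular_sigma(834, E1, model0))
    h <- 1e-4
    dth <- (compton_transfer_to_angle(834, E1 + h) -
              compton_transfer_to_angle(834, E1 - h)) / (2 * h)
    expect_equal(sig, abs(dth) * 10 / (2 * sqrt(2 * log(2))), tolerance = 1e-6)
  }
  # zero resolution and zero Doppler -> zero sigma
  expect_equal(as.numeric(propagate_angular_sigma(834, 300, angular_model(0, 0))), 0)
  # 51 keV blur always wider than 1 keV
  s51 <- propagate_angular_sigma(834, 300, angular_model(51, 0.01))
  s1 <- propagate_angular_sigma(834, 300, angular_model(1, 0.01))
  expect_gt(as.numeric(s51), as.numeric(s1))
  # the cap engages near the Compton edge and is counted
  se <- propagate_angular_sigma(834, compton_edge(834) - 0.01, angular_model(51))
  expect_equal(as.numeric(se), angular_model()$sigma_max)
  expect_equal(attr(se, "n_capped"), 1L)
})

test_that("line-sampled cone rows agree with the exact per-voxel kernel", {
  vol <- image_volume()
  set.seed(52)
  for (i in 1:3) {
    apex <- c(stats::runif(1, -40, 40), 105, stats::runif(1, -30, 30))
    rec <- make_cc_record(c(0, 0, 0), apex, stats::runif(1, 0.4, 1.0),
                          azimuth = stats::runif(1, 0, 2 * pi))
    model <- angular_model(energy_fwhm_keV = 10)
    cone <- cone_from_record(rec, 834, model)
    ls <- cone_surface_row(cone, vol, n_lines = 256)
    rows <- build_cone_rows(rec, vol, 834, model, min_peak = 0,
                            fov_radius_mm = Inf)
    ex <- get_row(rows, 1)
    # same support and, on it, weights within 5% (8-bit storage + sampling)
    common <- intersect(ls$voxel, ex$voxel)
    expect_gt(length(common) / length(ex$voxel), 0.95)
    wl <- ls$weight[match(common, ls$voxel)]
    we <- ex$weight[match(common, ex$voxel)]
    expect_lt(max(abs(wl - we)), 0.05)
    # voxels on the cone surface carry the row's maximal weight
    expect_gt(max(we), 0.98)
    # truncation: nothing beyond the band, so far-off voxels get nothing
    u <- sweep(as.matrix(expand.grid(x = voxel_centers(vol, 1),
                                     y = voxel_centers(vol, 2),
                                     z = voxel_centers(vol, 3))), 2, cone$apex)
    dist <- sqrt(rowSums(u^2))
    dev <- abs(acos(pmin(1, pmax(-1, (u %*% cone$axis) / dist))) - cone$half_angle)
    s_v <- sqrt(cone$angular_sigma^2 + (vol$voxel_mm / dist)^2)
    far <- which(dev > 4 * s_v)
    expect_equal(intersect(ex$voxel, far), integer(0))
  }
})

test_that("cones far outside the grid give empty rows that are dropped", {
  vol <- image_volume(dims = c(10L, 10L, 10L))
  rec <- make_cc_record(c(200, 0, 0), c(300, 110, 0), 0.3)  # aims far off-grid
  rows <- build_cone_rows(rec, vol, 834, angular_model(1), min_peak = 0.5)
  expect_equal(rows$n_empty, 1)
})

test_that("noiseless-cone MLEM localizes the source", {
  set.seed(53)
  src <- c(0, 0, 0)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    apex <- c(stats::runif(1, -70, 70),
              sample(c(-1, 1), 1) * stats::runif(1, 100, 135),
              stats::runif(1, -50, 50))
    make_cc_record(src, apex, stats::runif(1, 0.3, 1.2),
                   azimuth = stats::runif(1, 0, 2 * pi))
  }))
  res <- reconstruct_cc(recs, iterations = 20, model = angular_model(0, 0))
  v <- res$volumes[["20"]]$values
  am <- which(v == max(v), arr.ind = TRUE)
  expect_true(all(abs(unname(am[1, ]) - 20.5) <= 1))
  expect_true(all(diff(res$loglik) >= -1e-8 * abs(res$loglik[-1])))
  # >= 3 generic cones localize the source centroid within half a voxel
  res3 <- reconstruct_cc(recs[1:3, ], iterations = 60, model = angular_model(0, 0))
  v3 <- res3$volumes[["60"]]$values
  w <- v3 / sum(v3)
  vol <- res3$volumes[["60"]]
  ctr <- c(sum(voxel_centers(vol, 1) * apply(w, 1, sum)),
           sum(voxel_centers(vol, 2) * apply(w, 2, sum)),
           sum(voxel_centers(vol, 3) * apply(w, 3, sum)))
  expect_true(all(abs(ctr - src) < 0.5))
})

test_that("reconstruct_cc validates input and honors the E0 assumption", {
  empty <- data.frame(xs = numeric(), ys = numeric(), zs = numeric(),
                      E1 = numeric(), xa = numeric(), ya = numeric(),
                      za = numeric(), E2 = numeric())
  expect_error(reconstruct_cc(empty, iterations = 5), "empty")
  # "sum" mode on unblurred records equals fixed-E0 mode
  rec <- make_cc_record(c(0, 0, 0), c(20, 110, -10), 0.7)
  a <- build_cone_rows(rec, image_volume(), assumed_E0 = 834,
                       model = angular_model(0, 0))
  b <- build_cone_rows(rec, image_volume(), assumed_E0 = "sum",
                       model = angular_model(0, 0))
  expect_equal(get_row(a, 1), get_row(b, 1))
})
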