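# OD-RT projector and the shared list-mode MLEM driver.

test_that("compiled OD-RT rows match the plain-R exhaustive oracle", {
  vol <- image_volume(dims = c(20L, 20L, 20L), voxel_mm = 1)
  set.seed(41)
  for (i in 1:8) {
    lor <- c(stats::runif(1, -8, 8), 30, stats::runif(1, -8, 8),
             stats::runif(1, -8, 8), -30, stats::runif(1, -8, 8))
    ref <- od_rt_row(lor, vol, tor_sigma = 0.7)
    rows <- build_lor_rows(as.data.frame(as.list(stats::setNames(
      lor, c("x1", "y1", "z1", "x2", "y2", "z2")))), vol,
      tor_sigma = 0.7, min_peak = 0, fov_radius_mm = Inf)
    got <- get_row(rows, 1)
    expect_equal(got$voxel, ref$voxel)
    expect_equal(got$weight, ref$weight, tolerance = 1e-6)  # float storage
  }
})

test_that("axis-aligned LOR weights follow the closed form", {
  vol <- image_volume(dims = c(11L, 11L, 11L), voxel_mm = 1)
  sigma <- 0.8
  row <- od_rt_row(c(0, 30, 0, 0, -30, 0), vol, tor_sigma = sigma)
  w <- numeric(prod(vol$dims)); w[row$voxel] <- row$weight
  a <- array(w, dim = vol$dims)
  # voxels on the line get weight 1, one voxel off-axis exp(-1/(2 sigma^2))
  expect_equal(a[6, 6, 6], 1)
  expect_equal(a[6, 1, 6], 1)
  expect_equal(a[7, 6, 6], exp(-1 / (2 * sigma^2)))
  expect_equal(a[6, 6, 5], exp(-1 / (2 * sigma^2)))
  expect_equal(a[7, 6, 7], exp(-2 / (2 * sigma^2)))
})

test_that("degenerate and out-of-grid LORs are rejected or dropped", {
  vol <- image_volume(dims = c(10L, 10L, 10L))
  expect_error(od_rt_row(c(1, 2, 3, 1, 2, 3), vol), "degenerate")
  expect_error(build_lor_rows(data.frame(x1 = 1, y1 = 2, z1 = 3, x2 = 1,
                                         y2 = 2, z2 = 3), vol), "degenerate")
  far <- data.frame(x1 = 100, y1 = 30, z1 = 100, x2 = 100, y2 = -30, z2 = 100)
  rows <- build_lor_rows(far, vol)
  expect_equal(rows$n_empty, 1)
})

test_that("MLEM satisfies its fixed-point, monotonicity and conservation contracts", {
  # single event, single-voxel grid: fixed point after one iteration
  vol1 <- image_volume(dims = c(1L, 1L, 1L), voxel_mm = 1)
  rows1 <- build_lor_rows(data.frame(x1 = 0, y1 = 5, z1 = 0,
                                     x2 = 0, y2 = -5, z2 = 0), vol1)
  r1 <- mlem(rows1, 3)
  expect_equal(as.numeric(r1$volume$values), 1)
  expect_equal(r1$loglik[2], r1$loglik[3])

  # noiseless LORs through the origin voxel: argmax at the center
  set.seed(42)
  n <- 400
  d <- random_unit_vectors(n)
  keep <- abs(d[, 2]) > 0.6
  d <- d[keep, ]
  lors <- data.frame(x1 = 105 * d[, 1], y1 = 105 * d[, 2], z1 = 105 * d[, 3],
                     x2 = -105 * d[, 1], y2 = -105 * d[, 2], z2 = -105 * d[, 3])
  vol <- image_volume(dims = c(21L, 21L, 21L))
  rows <- build_lor_rows(lors, vol)
  res <- mlem(rows, 20)
  am <- which(res$volume$values == max(res$volume$values), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(11, 11, 11))
  # nonnegativity and likelihood monotonicity
  expect_true(all(res$volume$values >= 0))
  expect_true(all(diff(res$loglik) >= -1e-8 * abs(res$loglik[-1])))

  # matched sensitivity conserves sum_j s_j f_j = event count
  resm <- mlem(rows, 7, sensitivity = "matched")
  s <- petcc:::cpp_colsums(rows$ptr)
  expect_equal(sum(s * as.numeric(resm$volume$values)), nrow(lors),
               tolerance = 1e-8)
})

test_that("off-center point source centroid is recovered within half a voxel", {
  set.seed(43)
  src <- c(3.2, -2.1, 4.4)
  n <- 500
  d <- random_unit_vectors(n)
  d <- d[abs(d[, 2]) > 0.6, ]
  t1 <- (120 - src[2]) / d[, 2]  # reach |y| = 120 on both sides
  t2 <- (-120 - src[2]) / d[, 2]
  lors <- data.frame(x1 = src[1] + t1 * d[, 1], y1 = src[2] + t1 * d[, 2],
                     z1 = src[3] + t1 * d[, 3],
                     x2 = src[1] + t2 * d[, 1], y2 = src[2] + t2 * d[, 2],
                     z2 = src[3] + t2 * d[, 3])
  vol <- image_volume()
  res <- mlem(build_lor_rows(lors, vol), 100)
  v <- res$volume$values
  w <- v / sum(v)
  ctr <- c(sum(voxel_centers(vol, 1) * apply(w, 1, sum)),
           sum(voxel_centers(vol, 2) * apply(w, 2, sum)),
           sum(voxel_centers(vol, 3) * apply(w, 3, sum)))
  expect_true(all(abs(ctr - src) < 0.5))
})

test_that("reconstruction scale-equivariance: doubled coordinates, doubled grid", {
  set.seed(44)
  n <- 200
  d <- random_unit_vectors(n)
  d <- d[abs(d[, 2]) > 0.6, ]
  lors <- data.frame(x1 = 110 * d[, 1], y1 = 110 * d[, 2], z1 = 110 * d[, 3],
                     x2 = -110 * d[, 1], y2 = -110 * d[, 2], z2 = -110 * d[, 3])
  vol <- image_volume(dims = c(16L, 16L, 16L), voxel_mm = 1)
  vol2 <- image_volume(dims = c(16L, 16L, 16L), voxel_mm = 2)
  r <- mlem(build_lor_rows(lors, vol, tor_sigma = 0.5), 10)
  lors2 <- lors * 2
  r2 <- mlem(build_lor_rows(lors2, vol2, tor_sigma = 1.0), 10)
  expect_equal(r2$volume$values, r$volume$values, tolerance = 1e-4)
})

test_that("reconstruct_pet runs a series, writes volumes, rejects empty input", {
  set.seed(45)
  d <- random_unit_vectors(300)
  d <- d[abs(d[, 2]) > 0.6, ]
  lors <- data.frame(x1 = 115 * d[, 1], y1 = 115 * d[, 2], z1 = 115 * d[, 3],
                     x2 = -115 * d[, 1], y2 = -115 * d[, 2], z2 = -115 * d[, 3])
  out <- tempfile()
  res <- reconstruct_pet(lors, iterations = c(5, 12), out_dir = out)
  expect_named(res$volumes, c("5", "12"))
  expect_true(file.exists(file.path(out, "pet_iter12.f32")))
  expect_length(res$loglik, 12)
  # series continuation equals a fresh run at the same count
  fresh <- reconstruct_pet(lors, iterations = 12)
  expect_equal(res$volumes[["12"]]$values, fresh$volumes[["12"]]$values,
               tolerance = 1e-12)
  empty <- data.frame(x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      x2 = numeric(), y2 = numeric(), z2 = numeric())
  expect_error(reconstruct_pet(empty, iterations = 5), "empty")
})
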