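test_that("forward projection: zeros, linearity, slice separability", {
  grid <- voxel_grid(c(32, 32, 3), c(2, 2, 6))
  geom <- geometry_for_grid(grid, n_angles = 24)
  zero <- image_volume(grid, array(0, grid$shape), "activity")
  expect_true(all(forward_project(zero, geom)$values == 0))
  set.seed(5)
  f <- array(runif(prod(grid$shape)), grid$shape)
  g <- array(runif(prod(grid$shape)), grid$shape)
  pf <- forward_project(image_volume(grid, f, "activity"), geom)$values
  pg <- forward_project(image_volume(grid, g, "activity"), geom)$values
  pfg <- forward_project(image_volume(grid, f + g, "activity"), geom)$values
  expect_lt(max(abs(pfg - (pf + pg))) / max(pfg), 1e-10)
  # slice separability: perturbing slice 2 only changes sinogram slice 2
  f2 <- f; f2[, , 2] <- f2[, , 2] + 1
  pf2 <- forward_project(image_volume(grid, f2, "activity"), geom)$values
  expect_identical(pf2[, , c(1, 3)], pf[, , c(1, 3)])
  expect_false(identical(pf2[, , 2], pf[, , 2]))
})

test_that("central rays through a uniform disk integrate to the diameter", {
  grid <- voxel_grid(c(64, 64, 1), c(2, 2, 6))
  geom <- sinogram_geometry(96, 8, 1, 2)
  R <- 40
  disk <- disk_volume(grid, R)
  p <- forward_project(disk, geom)$values
  rc <- petlesionsim:::radial_centers(geom)
  cb <- which.min(abs(rc))
  chord <- 2 * sqrt(R^2 - rc[cb]^2)
  for (a in 1:8)
    expect_lt(abs(p[cb, a, 1] - chord), 2)   # one voxel-size tolerance
})

test_that("voxel-aligned rectangles project to width / cos(theta) integrals", {
  grid <- voxel_grid(c(32, 32, 1), c(2, 2, 6))
  vals <- array(0, grid$shape)
  vals[9:24, 13:20, 1] <- 1          # 32 mm in x, 16 mm in y
  img <- image_volume(grid, vals, "activity")
  geom <- sinogram_geometry(48, 2, 1, 2)        # angles 0 and pi/2
  p <- forward_project(img, geom)$values
  rc <- petlesionsim:::radial_centers(geom)
  # theta = 0: rays along y, integral = y-extent (16 mm) for rays inside x-range
  xr <- range(axis_coords(grid, 1)[9:24])
  inside_x <- rc > xr[1] + 1 & rc < xr[2] - 1
  expect_true(all(abs(p[inside_x, 1, 1] - 16) < 2))
  # theta = pi/2: rays along x, integral = x-extent (32 mm)
  yr <- range(axis_coords(grid, 2)[13:20])
  inside_y <- rc > yr[1] + 1 & rc < yr[2] - 1
  expect_true(all(abs(p[inside_y, 2, 1] - 32) < 2))
})

test_that("back projection is the exact adjoint of forward projection", {
  grid <- voxel_grid(c(64, 64, 2), c(2, 2, 6))
  geom <- geometry_for_grid(grid, n_angles = 48)
  worst <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    x <- array(runif(prod(grid$shape)), grid$shape)
    y <- array(runif(geom$n_radial * geom$n_angles * geom$n_slices),
               c(geom$n_radial, geom$n_angles, geom$n_slices))
    Px <- forward_project(image_volume(grid, x, "activity"), geom)$values
    Pty <- back_project(sinogram(geom, y, "line-integral"), grid)$values
    lhs <- sum(Px * y); rhs <- sum(x * Pty)
    worst <- max(worst, abs(lhs - rhs) / abs(lhs))
  }
  expect_lt(worst, 1e-6)
  zero <- sinogram(geom, array(0, dim(Px)), "line-integral")
  expect_true(all(back_project(zero, grid)$values == 0))
})

test_that("a single-bin impulse backprojects onto exactly its traced ray", {
  grid <- voxel_grid(c(32, 32, 1), c(2, 2, 6))
  geom <- sinogram_geometry(48, 12, 1, 2)
  a <- 5; r <- 30
  y <- array(0, c(48, 12, 1)); y[r, a, 1] <- 1
  bp <- back_project(sinogram(geom, y, "line-integral"), grid)$values[, , 1]
  # independent dense march along the same ray
  th <- geom$angles[a]; s <- petlesionsim:::radial_centers(geom)[r]
  u <- c(-sin(th), cos(th)); p0 <- s * c(cos(th), sin(th))
  hit <- matrix(FALSE, 32, 32)
  for (t in seq(-100, 100, by = 0.05)) {
    w <- p0 + t * u
    idx <- round((w - grid$origin_mm[1:2]) / grid$voxel_size_mm[1:2]) + 1
    if (all(idx >= 1 & idx <= 32)) hit[idx[1], idx[2]] <- TRUE
  }
  got <- bp > 1e-9
  # support agreement up to corner grazings shorter than ~0.2 mm
  expect_true(all(got[!hit] * bp[!hit] < 0.2))
  expect_true(all(bp[hit] >= 0))
  expect_gt(sum(got & hit), 0.9 * sum(got))
})

test_that("attenuation factors follow the Beer-Lambert closed form", {
  grid <- voxel_grid(c(128, 128, 1), c(2, 2, 6))
  geom <- geometry_for_grid(grid, n_angles = 8)
  mu0 <- mu_map(disk_volume(grid, 100, 0, "lac"), "ctac")
  expect_true(all(attenuation_factors(mu0, geom)$values == 1))
  mu <- mu_map(disk_volume(grid, 100, 0.096, "lac"), "ctac")
  af <- attenuation_factors(mu, geom)$values
  rc <- petlesionsim:::radial_centers(geom)
  cb <- which.min(abs(rc))
  expect_equal(af[cb, 1, 1], exp(-1.92), tolerance = 0.01)
  expect_true(all(af > 0 & af <= 1))
  # monotone: raising any voxel's mu cannot raise any factor
  v <- mu$image$values; v[64, 64, 1] <- v[64, 64, 1] + 0.05
  af2 <- attenuation_factors(mu_map(image_volume(grid, v, "lac"), "ctac"),
                             geom)$values
  expect_true(all(af2 <= af + 1e-15))
})

test_that("PSF smoothing conserves counts and has the requested width", {
  grid <- voxel_grid(c(64, 64, 5), c(2, 2, 2))
  vals <- array(0, grid$shape); vals[33, 33, 3] <- 1
  img <- image_volume(grid, vals, "activity")
  sm <- apply_psf(img, psf_model(6))
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  prof <- sm$values[, 33, 3]
  half <- max(prof) / 2
  # linear-interpolated width at half maximum
  xs <- axis_coords(grid, 1)
  above <- which(prof >= half)
  fwhm <- xs[max(above)] - xs[min(above)] + 2
  expect_lt(abs(fwhm - 6), 1)   # half a voxel
  # below half a voxel the filter is the identity
  expect_identical(apply_psf(img, psf_model(0.5))$values, vals)
  # smoothing a random field conserves its sum too
  set.seed(2)
  rnd <- image_volume(grid, array(runif(prod(grid$shape)), grid$shape),
                      "activity")
  expect_equal(sum(apply_psf(rnd, psf_model(5))$values), sum(rnd$values),
               tolerance = 1e-6)
})

test_that("sinogram and geometry contracts are enforced", {
  geom <- sinogram_geometry(16, 8, 2, 2)
  vals <- array(1, c(16, 8, 2))
  expect_error(sinogram(geom, -vals, "counts"), ">= 0")
  expect_error(sinogram(geom, vals * 2, "factors"), "<= 1")
  expect_error(sinogram(geom, array(1, c(16, 8, 3)), "counts"), "shape")
  grid <- voxel_grid(c(32, 32, 3), c(2, 2, 6))
  expect_error(forward_project(disk_volume(grid, 10), geom),
               "geometry error")  # slice mismatch
  tiny <- sinogram_geometry(4, 8, 3, 2)
  expect_error(forward_project(disk_volume(grid, 10), tiny),
               "geometry error")  # radial extent too small
})
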