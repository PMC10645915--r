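test_that("sphere rasterization matches brute-force voxel-center membership", {
  grid <- voxel_grid(c(32, 32, 16), c(2, 2, 2))
  spec <- lesion_spec("sphere", center_mm = c(1, -3, 2), radius_mm = 4,
                      activity_mode = "absolute", value = 10)
  mask <- rasterize_roi(spec, grid)
  brute <- 0
  for (i in 1:32) for (j in 1:32) for (k in 1:16) {
    w <- c(axis_coords(grid, 1)[i], axis_coords(grid, 2)[j],
           axis_coords(grid, 3)[k])
    if (sum((w - spec$center_mm)^2) <= 16) brute <- brute + 1
  }
  expect_equal(sum(mask$values), brute)
  # count is near the analytic sphere volume, within the surface-voxel band
  vol_vox <- (4 / 3) * pi * 4^3 / prod(grid$voxel_size_mm)
  surface_vox <- 4 * pi * 4^2 * max(grid$voxel_size_mm) /
    prod(grid$voxel_size_mm)
  expect_lt(abs(sum(mask$values) - vol_vox), surface_vox)
  out <- lesion_spec("sphere", center_mm = c(500, 0, 0), radius_mm = 4,
                     activity_mode = "absolute", value = 1)
  expect_error(rasterize_roi(out, grid), "empty-ROI")
})

test_that("atlas-region rasterization is exact label equality", {
  b <- generate_phantom(smoke_phantom_config(), 1)
  lab <- region_label(b$atlas, "fusiform")
  spec <- lesion_spec("atlas_region", region_label = lab,
                      activity_mode = "absolute", value = 5)
  mask <- rasterize_roi(spec, b$atlas$grid, b$atlas)
  expect_identical(mask$values > 0, b$atlas$labels == lab)
  bad <- lesion_spec("atlas_region", region_label = 999L,
                     activity_mode = "absolute", value = 5)
  expect_error(rasterize_roi(bad, b$atlas$grid, b$atlas), "lookup error")
})

test_that("activity assignment: absolute, LBR, and degenerate background", {
  grid <- voxel_grid(c(16, 16, 4), c(2, 2, 2))
  spec_abs <- lesion_spec("sphere", center_mm = c(0, 0, 1), radius_mm = 5,
                          activity_mode = "absolute", value = 10)
  mask <- rasterize_roi(spec_abs, grid)
  act <- assign_activity(mask, spec_abs)
  expect_true(all(act$values[mask$values > 0] == 10))
  expect_true(all(act$values[mask$values == 0] == 0))
  spec_lbr <- lesion_spec("sphere", center_mm = c(0, 0, 1), radius_mm = 5,
                          activity_mode = "lbr", value = 2)
  bg <- image_volume(grid, array(5, grid$shape), "activity")
  act <- assign_activity(mask, spec_lbr, bg)
  expect_true(all(act$values[mask$values > 0] == 10))
  expect_error(assign_activity(mask, spec_lbr), "config error")
  zero_bg <- image_volume(grid, array(0, grid$shape), "activity")
  expect_error(assign_activity(mask, spec_lbr, zero_bg),
               "degenerate-background")
})

test_that("expected lesion counts collapse to calibrated line integrals", {
  sc <- cylinder_scene(nx = 32, nz = 2, radius_mm = 25)
  acq <- acquisition_model(duration_s = 100, sensitivity = 1e-3,
                           scatter_fraction = 0)
  mu0 <- mu_map(disk_volume(sc$grid, 25, 0, "lac"), "ctac")
  zero <- image_volume(sc$grid, array(0, sc$grid$shape), "activity")
  expect_true(all(lesion_to_expected_counts(zero, mu0, acq, NULL,
                                            sc$geom)$values == 0))
  li <- forward_project(sc$emission, sc$geom)$values
  exp1 <- lesion_to_expected_counts(sc$emission, mu0, acq, NULL, sc$geom)
  expect_equal(exp1$values, li * 100 * 1e-3, tolerance = 1e-12)
  acq2 <- acquisition_model(duration_s = 200, sensitivity = 1e-3,
                            scatter_fraction = 0)
  exp2 <- lesion_to_expected_counts(sc$emission, mu0, acq2, NULL, sc$geom)
  expect_equal(exp2$values, 2 * exp1$values, tolerance = 1e-12)
})

test_that("scatter estimate honours the scatter fraction and is smooth", {
  sc <- cylinder_scene(nx = 32, nz = 2, radius_mm = 25)
  acq0 <- acquisition_model(scatter_fraction = 0)
  trues <- lesion_to_expected_counts(sc$emission, sc$mu, acq0, NULL, sc$geom)
  expect_true(all(estimate_scatter(trues, acq0)$values == 0))
  acq3 <- acquisition_model(scatter_fraction = 0.3)
  s <- estimate_scatter(trues, acq3)
  frac <- sum(s$values) / (sum(trues$values) + sum(s$values))
  expect_equal(frac, 0.3, tolerance = 1e-9)
  # point-source trues: the scatter radial profile is smoother
  pt <- array(0, dim(trues$values)); pt[24, 3, 1] <- 1000
  pt_s <- estimate_scatter(sinogram(sc$geom, pt, "expected-counts"), acq3)
  d_t <- max(abs(diff(pt[, 3, 1])))
  d_s <- max(abs(diff(pt_s$values[, 3, 1])))
  expect_lt(d_s, d_t)
})

test_that("Poisson sampling is seeded and has Poisson moments", {
  geom <- sinogram_geometry(100, 100, 1, 2)
  lam <- sinogram(geom, array(100, c(100, 100, 1)), "expected-counts")
  c1 <- sample_poisson(lam, 42)
  c2 <- sample_poisson(lam, 42)
  expect_identical(c1$values, c2$values)
  expect_true(all(c1$values == round(c1$values) & c1$values >= 0))
  m <- mean(c1$values)
  expect_lt(abs(m - 100), 3 * sqrt(100 / 1e4))
  expect_gt(var(as.vector(c1$values)) / m, 0.9)
  expect_lt(var(as.vector(c1$values)) / m, 1.1)
  zero <- sinogram(geom, array(0, c(100, 100, 1)), "expected-counts")
  expect_true(all(sample_poisson(zero, 1)$values == 0))
})

test_that("merge modes: additivity, footprint replacement, integer counts", {
  sc <- cylinder_scene(nx = 32, nz = 2, radius_mm = 25)
  acq <- acquisition_model(scatter_fraction = 0.2)
  bg_counts <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 9)
  les <- array(0, sc$grid$shape)
  les[16, 16, 1] <- 50
  lesion <- image_volume(sc$grid, les, "activity")
  lexp <- lesion_to_expected_counts(lesion, sc$mu, acq, NULL, sc$geom)
  lsc <- estimate_scatter(lexp, acq)
  wb <- merge_into_patient(bg_counts, lexp, lsc, "with_background", 5)
  lo <- merge_into_patient(NULL, lexp, lsc, "lesion_only", 5)
  expect_equal(sum(wb$merged_counts$values),
               sum(bg_counts$values) + sum(lo$merged_counts$values))
  expect_true(all(wb$merged_counts$values >= bg_counts$values))
  rp <- merge_into_patient(bg_counts, lexp, lsc, "replace", 5)
  foot <- lexp$values > 1e-3 * max(lexp$values)
  expect_identical(rp$merged_counts$values[!foot], bg_counts$values[!foot])
  for (r in list(wb, lo, rp)) {
    v <- r$merged_counts$values
    expect_true(all(v >= 0 & v == round(v)))
  }
  expect_error(merge_into_patient(NULL, lexp, lsc, "with_background", 1),
               "config error")
  # lesion_only totals sit within 3 sigma of the total expectation
  lam_tot <- sum(lexp$values) + sum(lsc$values)
  expect_lt(abs(sum(lo$merged_counts$values) - lam_tot), 3 * sqrt(lam_tot))
})

test_that("expected counts are linear: background + lesion = sum of parts", {
  sc <- cylinder_scene(nx = 32, nz = 2, radius_mm = 25)
  acq <- acquisition_model(scatter_fraction = 0)
  les <- array(0, sc$grid$shape); les[14, 18, 2] <- 20
  lesion <- image_volume(sc$grid, les, "activity")
  combined <- image_volume(sc$grid, sc$emission$values + les, "activity")
  e_bg <- lesion_to_expected_counts(sc$emission, sc$mu, acq, NULL, sc$geom)
  e_les <- lesion_to_expected_counts(lesion, sc$mu, acq, NULL, sc$geom)
  e_all <- lesion_to_expected_counts(combined, sc$mu, acq, NULL, sc$geom)
  expect_lt(max(abs(e_all$values - (e_bg$values + e_les$values))) /
              max(e_all$values), 1e-9)
})

test_that("simulated acquisitions are seeded and vanish without emission", {
  sc <- cylinder_scene(nx = 32, nz = 2, radius_mm = 25)
  acq <- acquisition_model(scatter_fraction = 0.3)
  zero <- image_volume(sc$grid, array(0, sc$grid$shape), "activity")
  expect_true(all(simulate_acquisition(zero, sc$mu, acq, NULL, sc$geom,
                                       1)$values == 0))
  a <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 33)
  b <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 33)
  expect_identical(a$values, b$values)
})
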