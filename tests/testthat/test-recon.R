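test_that("OSEM with matched attenuation recovers a uniform cylinder", {
  sc <- cylinder_scene()
  acq <- acquisition_model(scatter_fraction = 0)
  trues <- lesion_to_expected_counts(sc$emission, sc$mu, acq, NULL, sc$geom)
  noisefree <- sinogram(sc$geom, trues$values, "counts")
  cfg <- recon_config(n_iterations = 10, n_subsets = 8,
                      post_filter_fwhm_mm = 0)
  rr <- osem_reconstruct(noisefree, sc$mu, acq, NULL, sc$geom, cfg)
  interior <- disk_volume(sc$grid, 25)$values > 0
  expect_equal(mean(rr$image$values[interior]), 5, tolerance = 0.02)
  expect_true(all(rr$image$values >= 0))
})

test_that("zero counts give a zero image after the first update", {
  sc <- cylinder_scene(nx = 32, nz = 2)
  acq <- acquisition_model(scatter_fraction = 0)
  zero <- sinogram(sc$geom, array(0, c(sc$geom$n_radial, sc$geom$n_angles,
                                       sc$geom$n_slices)), "counts")
  rr <- osem_reconstruct(zero, sc$mu, acq, NULL, sc$geom,
                         recon_config(n_iterations = 1, n_subsets = 4,
                                      post_filter_fwhm_mm = 0))
  expect_true(all(rr$image$values == 0))
})

test_that("MLEM increases the Poisson log-likelihood monotonically", {
  sc <- cylinder_scene(nx = 32, nz = 2)
  acq <- acquisition_model(scatter_fraction = 0.2)
  counts <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 17)
  trues <- lesion_to_expected_counts(sc$emission, sc$mu, acq, NULL, sc$geom)
  scat <- estimate_scatter(trues, acq)
  cfg <- recon_config(n_iterations = 10, n_subsets = 1,
                      post_filter_fwhm_mm = 0, track_loglik = TRUE)
  rr <- osem_reconstruct(counts, sc$mu, acq, scat, sc$geom, cfg)
  expect_length(rr$loglik, 10)
  expect_true(all(diff(rr$loglik) > -1e-6 * abs(rr$loglik[1])))
})

test_that("MLEM on noise-free matched data reproduces the data totals", {
  sc <- cylinder_scene(nx = 32, nz = 2)
  acq <- acquisition_model(scatter_fraction = 0)
  trues <- lesion_to_expected_counts(sc$emission, sc$mu, acq, NULL, sc$geom)
  noisefree <- sinogram(sc$geom, trues$values, "counts")
  cfg <- recon_config(n_iterations = 20, n_subsets = 1,
                      post_filter_fwhm_mm = 0)
  rr <- osem_reconstruct(noisefree, sc$mu, acq, NULL, sc$geom, cfg)
  # forward-project the estimate through the same system model
  cal <- acq$sensitivity * acq$duration_s
  fp <- forward_project(rr$image, sc$geom)$values *
    attenuation_factors(sc$mu, sc$geom)$values * cal
  expect_equal(sum(fp), sum(noisefree$values), tolerance = 0.01)
})

test_that("a bone-free attenuation map biases skull-adjacent uptake down", {
  b <- generate_phantom(smoke_phantom_config(), 1)
  fam <- derive_mrac_family(b, degrade_config(), 1)
  geom <- geometry_for_grid(b$emission$grid, n_angles = 48)
  acq <- acquisition_model(scatter_fraction = 0)
  psf <- psf_model(4)
  trues <- lesion_to_expected_counts(b$emission, fam$reference, acq, psf, geom)
  noisefree <- sinogram(geom, trues$values, "counts")
  cfg <- smoke_recon_config()
  r_ctac <- osem_reconstruct(noisefree, fam$reference, acq, NULL, geom, cfg)
  r_dixon <- osem_reconstruct(noisefree, fam$candidates$dixon, acq, NULL,
                              geom, cfg)
  specs <- default_lesion_specs(b$config)
  m_sf <- rasterize_roi(specs$superior_frontal_sphere, b$emission$grid)
  m_deep <- rasterize_roi(specs$fusiform_sphere, b$emission$grid)
  bias_sf <- relative_bias(roi_mean(r_dixon$image, roi = m_sf),
                           roi_mean(r_ctac$image, roi = m_sf))
  bias_deep <- relative_bias(roi_mean(r_dixon$image, roi = m_deep),
                             roi_mean(r_ctac$image, roi = m_deep))
  expect_lt(bias_sf, 0)
  expect_lt(bias_deep, 0)
  expect_gt(abs(bias_sf), abs(bias_deep))
})

test_that("reconstruct_all: five maps, identity family gives identical images", {
  sc <- cylinder_scene(nx = 32, nz = 2)
  acq <- acquisition_model(scatter_fraction = 0)
  counts <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 3)
  fam <- structure(list(reference = sc$mu,
                        candidates = list(
                          dixon = mu_map(sc$mu$image, "dixon"),
                          dixonbone = mu_map(sc$mu$image, "dixonbone"),
                          ute = mu_map(sc$mu$image, "ute"),
                          dl_dixon = mu_map(sc$mu$image, "dl_dixon"))),
                   class = "mrac_family")
  rr <- reconstruct_all(counts, fam, acq, NULL, sc$geom, smoke_recon_config())
  expect_length(rr, 5)
  expect_named(rr, c("ctac", "dixon", "dixonbone", "ute", "dl_dixon"))
  for (m in names(rr)[-1])
    expect_equal(rr[[m]]$image$values, rr$ctac$image$values)
})

test_that("the near-truth pseudo-CT reconstruction is closest to reference", {
  b <- generate_phantom(smoke_phantom_config(), 1)
  fam <- derive_mrac_family(b, degrade_config(), 1)
  geom <- geometry_for_grid(b$emission$grid, n_angles = 48)
  acq <- acquisition_model(scatter_fraction = 0)
  counts <- simulate_acquisition(b$emission, fam$reference, acq,
                                 psf_model(4), geom, 21)
  rr <- reconstruct_all(counts, fam, acq, NULL, geom, smoke_recon_config())
  brain <- !(b$atlas$labels %in% c(0L, 1L, region_label(b$atlas, "skull")))
  rmse <- function(m) sqrt(mean((rr[[m]]$image$values[brain] -
                                   rr$ctac$image$values[brain])^2))
  expect_lt(rmse("dl_dixon"), rmse("dixon"))
})

test_that("recon configuration errors are caught", {
  sc <- cylinder_scene(nx = 32, nz = 2, n_angles = 8)
  acq <- acquisition_model(scatter_fraction = 0)
  counts <- simulate_acquisition(sc$emission, sc$mu, acq, NULL, sc$geom, 1)
  expect_error(osem_reconstruct(counts, sc$mu, acq, NULL, sc$geom,
                                recon_config(n_subsets = 16)),
               "config error")
  expect_error(recon_config(n_iterations = 0), "n_iterations")
})
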