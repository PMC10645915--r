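#' Lesion / ROI specification
#'
#' Declarative description of one inserted lesion: either a sphere (center
#' and radius in world mm) or an atlas region (integer label). Activity is
#' either absolute (Bq/mL) or a lesion-to-background ratio (LBR) applied to
#' the mean background activity inside the ROI.
#'
#' @param shape `"sphere"` or `"atlas_region"`.
#' @param center_mm sphere center in world mm (sphere only).
#' @param radius_mm sphere radius in mm (sphere only), e.g. 4.
#' @param region_label integer atlas label (atlas_region only).
#' @param activity_mode `"absolute"` or `"lbr"`.
#' @param value activity in Bq/mL (absolute) or unitless ratio (lbr); > 0.
#' @param name optional ROI name used in reports.
#' @return a `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("sphere", "atlas_region"),
                        center_mm = NULL, radius_mm = NULL,
                        region_label = NULL,
                        activity_mode = c("absolute", "lbr"),
                        value, name = NULL) {
  shape <- match.arg(shape)
  activity_mode <- match.arg(activity_mode)
  if (value <= 0) stop("lesion value must be > 0")
  if (shape == "sphere") {
    if (is.null(center_mm) || is.null(radius_mm) || radius_mm <= 0)
      stop("sphere lesions need center_mm and a positive radius_mm")
    if (!is.null(region_label)) stop("sphere lesions must not set region_label")
  } else {
    if (is.null(region_label)) stop("atlas_region lesions need region_label")
    if (!is.null(center_mm) || !is.null(radius_mm))
      stop("atlas_region lesions must not set center_mm/radius_mm")
  }
  structure(list(shape = shape, center_mm = center_mm, radius_mm = radius_mm,
                 region_label = region_label, activity_mode = activity_mode,
                 value = value,
                 name = if (is.null(name)) shape else name),
            class = "lesion_spec")
}

#' Acquisition model
#'
#' Calibration and correction factors of the synthetic acquisition. The
#' calibration constant mapping projected activity (Bq/mL x mm) to expected
#' counts per bin is `duration_s * sensitivity`.
#'
#' @param duration_s frame duration (s), default 300.
#' @param sensitivity expected counts per (Bq/mL x mm) of projected
#'   activity per bin per second, default 2e-4.
#' @param scatter_fraction scattered fraction of total counts, in `[0, 1)`,
#'   default 0.3.
#' @param norm optional normalization factor [sinogram()] (content
#'   `"factors"`); `NULL` means uniform (all ones).
#' @return an `acquisition_model`.
#' @export
acquisition_model <- function(duration_s = 300, sensitivity = 2e-4,
                              scatter_fraction = 0.3, norm = NULL) {
  if (duration_s <= 0 || sensitivity <= 0)
    stop("duration_s and sensitivity must be > 0")
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)")
  structure(list(duration_s = duration_s, sensitivity = sensitivity,
                 scatter_fraction = scatter_fraction, norm = norm),
            class = "acquisition_model")
}

norm_values <- function(acq, geom) {
  if (is.null(acq$norm)) {
    array(1, dim = c(geom$n_radial, geom$n_angles, geom$n_slices))
  } else {
    if (!identical(acq$norm$geometry$n_radial, geom$n_radial) ||
        !identical(acq$norm$geometry$n_angles, geom$n_angles) ||
        !identical(acq$norm$geometry$n_slices, geom$n_slices))
      stop("normalization sinogram geometry mismatch")
    acq$norm$values
  }
}

#' Rasterize a lesion specification to a binary mask
#'
#' Sphere membership is decided by voxel-center distance <= radius; atlas
#' mode is exact label equality.
#'
#' @param spec a [lesion_spec()].
#' @param grid target [voxel_grid()].
#' @param atlas a [label_volume()] (required for atlas-region specs).
#' @return an [image_volume()] with quantity `"label-probability"` (0/1).
#' @export
rasterize_roi <- function(spec, grid, atlas = NULL) {
  if (spec$shape == "sphere") {
    dx2 <- (axis_coords(grid, 1) - spec$center_mm[1])^2
    dy2 <- (axis_coords(grid, 2) - spec$center_mm[2])^2
    dz2 <- (axis_coords(grid, 3) - spec$center_mm[3])^2
    r2 <- spec$radius_mm^2
    mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
  } else {
    if (is.null(atlas)) stop("atlas required for atlas_region specs")
    stop_if_grid_mismatch(atlas$grid, grid, "atlas and target grid")
    if (!spec$region_label %in% atlas$labels)
      stop("lookup error: atlas label not present: ", spec$region_label)
    mask <- atlas$labels == spec$region_label
  }
  if (!any(mask))
    stop("empty-ROI error: lesion specification produced an empty mask")
  image_volume(grid, array(as.numeric(mask), dim = grid$shape),
               "label-probability")
}

#' Assign activity to a rasterized ROI
#'
#' Absolute mode sets every mask voxel to `value` Bq/mL; LBR mode sets them
#' to `value` times the mean background activity inside the mask.
#'
#' @param mask binary [image_volume()] from [rasterize_roi()].
#' @param spec the [lesion_spec()].
#' @param background background activity [image_volume()] (required for
#'   LBR mode).
#' @return an [image_volume()] with quantity `"activity"`.
#' @export
assign_activity <- function(mask, spec, background = NULL) {
  if (spec$activity_mode == "absolute") {
    level <- spec$value
  } else {
    if (is.null(background))
      stop("config error: lbr mode requires a background image")
    stop_if_grid_mismatch(mask$grid, background$grid)
    mb <- mean(background$values[mask$values > 0])
    if (mb <= 0)
      stop("degenerate-background error: zero mean background under lbr")
    level <- spec$value * mb
  }
  image_volume(mask$grid, mask$values * level, "activity")
}

#' Expected lesion counts in projection space
#'
#' The projection-space insertion chain: PSF smoothing in image space,
#' forward projection, multiplication by attenuation and normalization
#' factor sinograms, and calibration by `sensitivity * duration`.
#'
#' @param lesion activity [image_volume()].
#' @param mu a [mu_map()] used for the attenuation factors.
#' @param acq an [acquisition_model()].
#' @param psf a [psf_model()] (or `NULL` to skip smoothing).
#' @param geom a [sinogram_geometry()].
#' @return a [sinogram()] with content `"expected-counts"`.
#' @export
lesion_to_expected_counts <- function(lesion, mu, acq, psf, geom) {
  stop_if_grid_mismatch(lesion$grid, mu$image$grid, "lesion and mu map")
  sm <- if (is.null(psf)) lesion else apply_psf(lesion, psf)
  li <- forward_project(sm, geom)
  af <- attenuation_factors(mu, geom)
  vals <- li$values * af$values * norm_values(acq, geom) *
    acq$sensitivity * acq$duration_s
  sinogram(geom, vals, "expected-counts")
}

#' Convolution scatter estimate
#'
#' Broad radial Gaussian convolution of the expected trues per angle and
#' slice, rescaled so that `total scatter / (total trues + total scatter)`
#' equals the acquisition's scatter fraction.
#'
#' @param trues expected-counts [sinogram()].
#' @param acq an [acquisition_model()] (its `scatter_fraction` is used).
#' @param kernel_fwhm_mm radial kernel FWHM (mm), default 80.
#' @return a [sinogram()] with content `"expected-counts"`.
#' @export
estimate_scatter <- function(trues, acq, kernel_fwhm_mm = 80) {
  geom <- trues$geometry
  f <- acq$scatter_fraction
  if (f == 0 || sum(trues$values) == 0)
    return(sinogram(geom, array(0, dim = dim(trues$values)), "expected-counts"))
  sigma_bins <- fwhm_to_sigma(kernel_fwhm_mm) / geom$radial_bin_mm
  sm <- conv_along_axis(trues$values, gaussian_kernel(sigma_bins), 1L)
  sm <- pmax(sm, 0)
  target_total <- sum(trues$values) * f / (1 - f)
  sm <- sm * (target_total / sum(sm))
  sinogram(geom, array(sm, dim = dim(trues$values)), "expected-counts")
}

#' Poisson count sampling
#'
#' Independent Poisson draw per bin, reproducible under the seed.
#'
#' @param expected expected-counts [sinogram()].
#' @param seed integer seed.
#' @return a [sinogram()] with content `"counts"` (integer-valued).
#' @export
sample_poisson <- function(expected, seed) {
  lam <- expected$values
  if (any(lam < 0)) stop("validation error: negative expectations")
  counts <- withr::with_seed(seed, stats::rpois(length(lam), lam))
  sinogram(expected$geometry, array(as.numeric(counts), dim = dim(lam)),
           "counts")
}

#' Merge lesion counts into (or substitute for) patient projection data
#'
#' * `with_background`: background counts plus one Poisson draw of
#'   `lesion_expected + scatter`.
#' * `lesion_only`: the Poisson draw alone.
#' * `replace`: background counts zeroed on the lesion footprint (bins with
#'   `lesion_expected` above 1e-3 of its maximum), then the draw added
#'   there; all other bins are bit-identical to the background.
#'
#' @param background counts [sinogram()] or `NULL` (lesion_only).
#' @param lesion_expected expected-counts [sinogram()].
#' @param scatter expected-counts [sinogram()].
#' @param mode `"with_background"`, `"lesion_only"` or `"replace"`.
#' @param seed integer seed for the lesion Poisson draw.
#' @return an `insertion_result`: list with `lesion_expected`, `scatter`,
#'   `merged_counts`, `mode`, `seed`.
#' @export
merge_into_patient <- function(background, lesion_expected, scatter,
                               mode = c("with_background", "lesion_only",
                                        "replace"),
                               seed = 1L) {
  mode <- match.arg(mode)
  geom <- lesion_expected$geometry
  total_expected <- sinogram(geom, lesion_expected$values + scatter$values,
                             "expected-counts")
  draw <- sample_poisson(total_expected, seed)
  if (mode == "lesion_only") {
    merged <- draw$values
  } else {
    if (is.null(background))
      stop("config error: mode '", mode, "' requires a background sinogram")
    if (mode == "with_background") {
      merged <- background$values + draw$values
    } else {
      thr <- 1e-3 * max(lesion_expected$values)
      foot <- lesion_expected$values > thr
      merged <- background$values
      merged[foot] <- draw$values[foot]
    }
  }
  structure(list(lesion_expected = lesion_expected, scatter = scatter,
                 merged_counts = sinogram(geom, merged, "counts"),
                 mode = mode, seed = as.integer(seed)),
            class = "insertion_result")
}

#' Simulate a full synthetic acquisition
#'
#' Stand-in for measured patient projection data: expected trues of the
#' emission volume plus a convolution scatter estimate, Poisson sampled.
#'
#' @param emission activity [image_volume()].
#' @param mu [mu_map()] used to attenuate the data (normally ground truth).
#' @param acq an [acquisition_model()].
#' @param psf a [psf_model()] or `NULL`.
#' @param geom a [sinogram_geometry()].
#' @param seed integer seed.
#' @return a counts [sinogram()].
#' @export
simulate_acquisition <- function(emission, mu, acq, psf, geom, seed) {
  trues <- lesion_to_expected_counts(emission, mu, acq, psf, geom)
  sc <- estimate_scatter(trues, acq)
  expected <- sinogram(geom, trues$values + sc$values, "expected-counts")
  sample_poisson(expected, seed)
}
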