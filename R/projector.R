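#' Multi-slice parallel-beam sinogram geometry
#'
#' Rays lie in the axial plane (one sinogram slice per image slice). Angles
#' span `[0, pi)` uniformly; `theta = 0` rays run parallel to the y axis.
#' The signed radial coordinate is measured from the world in-plane origin,
#' with bin centers symmetric about 0.
#'
#' @param n_radial number of radial bins.
#' @param n_angles number of projection angles.
#' @param n_slices number of axial slices.
#' @param radial_bin_mm radial bin width (mm).
#' @return a `sinogram_geometry`.
#' @export
sinogram_geometry <- function(n_radial, n_angles, n_slices, radial_bin_mm) {
  if (n_radial < 1 || n_angles < 1 || n_slices < 1 || radial_bin_mm <= 0)
    stop("invalid sinogram geometry")
  structure(list(n_radial = as.integer(n_radial),
                 n_angles = as.integer(n_angles),
                 n_slices = as.integer(n_slices),
                 radial_bin_mm = radial_bin_mm,
                 angles = seq(0, pi, length.out = n_angles + 1L)[1:n_angles]),
            class = "sinogram_geometry")
}

#' Default sinogram geometry for an image grid
#'
#' `n_radial = ceil(1.5 nx)`, `n_angles = max(nx, 96)` (configurable),
#' radial bin = in-plane voxel size: the radial extent then covers the
#' in-plane grid diagonal.
#'
#' @param grid a [voxel_grid()].
#' @param n_angles number of angles; default `max(nx, 96)`.
#' @param n_radial number of radial bins; default `ceiling(1.5 * nx)`.
#' @return a `sinogram_geometry`.
#' @export
geometry_for_grid <- function(grid, n_angles = NULL, n_radial = NULL) {
  nx <- grid$shape[1]
  if (is.null(n_angles)) n_angles <- max(nx, 96L)
  if (is.null(n_radial)) n_radial <- as.integer(ceiling(1.5 * nx))
  sinogram_geometry(n_radial, n_angles, grid$shape[3], grid$voxel_size_mm[1])
}

radial_centers <- function(geom) {
  (seq_len(geom$n_radial) - (geom$n_radial + 1) / 2) * geom$radial_bin_mm
}

SINO_CONTENT <- c("line-integral", "expected-counts", "counts", "factors")

#' Sinogram container
#'
#' @param geometry a [sinogram_geometry()].
#' @param values array `(n_radial, n_angles, n_slices)`, all >= 0;
#'   `"factors"` content must additionally be <= 1.
#' @param content one of `"line-integral"`, `"expected-counts"`,
#'   `"counts"`, `"factors"`.
#' @return a `sinogram`.
#' @export
sinogram <- function(geometry, values, content) {
  content <- match.arg(content, SINO_CONTENT)
  values <- as.array(values)
  expect <- c(geometry$n_radial, geometry$n_angles, geometry$n_slices)
  if (!identical(as.integer(dim(values)), as.integer(expect)))
    stop("sinogram values shape does not match geometry")
  if (any(values < 0)) stop("sinogram values must be >= 0")
  if (content == "factors" && any(values > 1 + 1e-12))
    stop("factor sinograms must be <= 1")
  structure(list(geometry = geometry, values = values, content = content),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("sinogram [%s]: %d radial x %d angles x %d slices, total %.4g\n",
              x$content, g$n_radial, g$n_angles, g$n_slices, sum(x$values)))
  invisible(x)
}

check_projection_geom <- function(grid, geom) {
  if (grid$shape[3] != geom$n_slices)
    stop("geometry error: image slices and sinogram slices differ")
  half_span <- (geom$n_radial / 2) * geom$radial_bin_mm
  if (half_span + 1e-9 < grid_inplane_halfdiag(grid))
    stop("geometry error: radial extent does not cover the image grid diagonal")
  invisible(TRUE)
}

#' Forward projection (exact ray tracing)
#'
#' Line integral of the image along each bin's ray (value x mm), by exact
#' voxel-intersection-length (Siddon-style) traversal, one ray per bin
#' center. Linear in the image; slice-separable.
#'
#' @param img an [image_volume()].
#' @param geom a [sinogram_geometry()] with `n_slices == nz`.
#' @param angle_subset optional integer vector of angle indices (1-based)
#'   to project; the result's angle dimension then has that length.
#' @return a [sinogram()] with content `"line-integral"`.
#' @export
forward_project <- function(img, geom, angle_subset = NULL) {
  check_projection_geom(img$grid, geom)
  ai <- if (is.null(angle_subset)) seq_len(geom$n_angles) else as.integer(angle_subset)
  vals <- .cpp_project(as.numeric(img$values), img$grid$shape,
                       img$grid$voxel_size_mm, img$grid$origin_mm,
                       geom$angles, ai - 1L, radial_centers(geom),
                       geom$n_radial, numeric(0), TRUE)
  vals <- array(vals, dim = c(geom$n_radial, length(ai), geom$n_slices))
  if (is.null(angle_subset)) sinogram(geom, vals, "line-integral") else vals
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param sino a [sinogram()] (or, with `angle_subset`, a raw array whose
#'   angle dimension matches the subset).
#' @param grid target [voxel_grid()].
#' @param geom geometry (defaults to `sino$geometry`).
#' @param angle_subset optional 1-based angle indices.
#' @return an [image_volume()] with quantity `"activity"`.
#' @export
back_project <- function(sino, grid, geom = NULL, angle_subset = NULL) {
  if (inherits(sino, "sinogram")) {
    geom <- sino$geometry
    vals_in <- sino$values
  } else {
    if (is.null(geom)) stop("geom required when sino is a raw array")
    vals_in <- sino
  }
  check_projection_geom(grid, geom)
  ai <- if (is.null(angle_subset)) seq_len(geom$n_angles) else as.integer(angle_subset)
  vals <- .cpp_project(numeric(0), grid$shape,
                       grid$voxel_size_mm, grid$origin_mm,
                       geom$angles, ai - 1L, radial_centers(geom),
                       geom$n_radial, as.numeric(vals_in), FALSE)
  img <- array(vals, dim = grid$shape)
  image_volume(grid, pmax(img, 0), "activity")
}

#' Attenuation factor sinogram
#'
#' Per bin, the photon-pair survival probability `exp(-sum mu * l)` along
#' the ray, with path lengths converted mm to cm (`mu` in cm^-1). Values
#' lie in `(0, 1]`.
#'
#' @param mu a [mu_map()].
#' @param geom a [sinogram_geometry()].
#' @return a [sinogram()] with content `"factors"`.
#' @export
attenuation_factors <- function(mu, geom) {
  if (any(mu$image$values < 0))
    stop("validation error: negative attenuation coefficients")
  li <- forward_project(mu$image, geom)
  sinogram(geom, exp(-0.1 * li$values), "factors")
}

#' Isotropic Gaussian point-spread-function model
#'
#' @param fwhm_mm full width at half maximum (mm), default 4.
#' @return a `psf_model`.
#' @export
psf_model <- function(fwhm_mm = 4.0) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  structure(list(fwhm_mm = fwhm_mm), class = "psf_model")
}

#' Apply the scanner point-spread function
#'
#' Separable 3D Gaussian convolution with `sigma = fwhm / 2.3548` per axis
#' (mm converted to voxels). Axes where the FWHM is below half a voxel are
#' left untouched (identity limit). The total image sum is conserved
#' (edge-renormalized).
#'
#' @param img an [image_volume()].
#' @param psf a [psf_model()].
#' @return an [image_volume()] with the same quantity.
#' @export
apply_psf <- function(img, psf) {
  vals <- img$values
  s_before <- sum(vals)
  for (axis in 1:3) {
    vox <- img$grid$voxel_size_mm[axis]
    if (psf$fwhm_mm < 0.5 * vox) next
    sigma_vox <- fwhm_to_sigma(psf$fwhm_mm) / vox
    vals <- conv_along_axis(vals, gaussian_kernel(sigma_vox), axis)
  }
  s_after <- sum(vals)
  if (s_after > 0) vals <- vals * (s_before / s_after)
  image_volume(img$grid, array(vals, dim = img$grid$shape), img$quantity)
}
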