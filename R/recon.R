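#' OSEM reconstruction configuration
#'
#' Defaults follow common brain-PET practice: 3 iterations, 21 angular
#' subsets, 4 mm post-reconstruction Gaussian filter.
#'
#' @param n_iterations full iterations (>= 1), default 3.
#' @param n_subsets angular subsets (angle-interleaved: angle `i` goes to
#'   subset `i mod n_subsets`), default 21.
#' @param post_filter_fwhm_mm post-reconstruction Gaussian FWHM (mm, >= 0;
#'   0 disables), default 4.
#' @param epsilon division guard, default 1e-12.
#' @param track_loglik if `TRUE`, record the Poisson log-likelihood after
#'   each full iteration.
#' @return a `recon_config`.
#' @export
recon_config <- function(n_iterations = 3L, n_subsets = 21L,
                         post_filter_fwhm_mm = 4.0, epsilon = 1e-12,
                         track_loglik = FALSE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 post_filter_fwhm_mm = post_filter_fwhm_mm,
                 epsilon = epsilon, track_loglik = track_loglik),
            class = "recon_config")
}

#' Attenuation-corrected OSEM reconstruction
#'
#' Classic multiplicative OSEM with the attenuation and normalization
#' factors inside the system model and scatter as a known additive term:
#' for subset S,
#' `x <- x * [ Pt_S( f * y_S / (f * P_S x + s_S + eps) ) ] / [ Pt_S f_S ]`
#' with `f = attenuation * normalization`, `P` the ray-tracing projector
#' and `y` the measured counts. The result is divided by
#' `sensitivity * duration` to return activity units, then post-filtered.
#' Voxels with zero subset sensitivity are frozen at 0.
#'
#' @param counts counts [sinogram()].
#' @param mu [mu_map()] used for the attenuation factors.
#' @param acq an [acquisition_model()].
#' @param scatter expected scatter [sinogram()] or `NULL` for none.
#' @param geom a [sinogram_geometry()].
#' @param cfg a [recon_config()].
#' @param grid output [voxel_grid()].
#' @return a `recon_result`: list with `image` (activity
#'   [image_volume()]), `config`, `mu_method`, and `loglik` (numeric vector,
#'   only when tracked).
#' @export
osem_reconstruct <- function(counts, mu, acq, scatter = NULL, geom, cfg,
                             grid = mu$image$grid) {
  check_projection_geom(grid, geom)
  if (geom$n_angles < cfg$n_subsets)
    stop("config error: more subsets than angles")
  y <- counts$values
  f <- attenuation_factors(mu, geom)$values * norm_values(acq, geom)
  s <- if (is.null(scatter)) array(0, dim = dim(y)) else scatter$values
  eps <- cfg$epsilon

  subsets <- lapply(seq_len(cfg$n_subsets), function(k)
    which((seq_len(geom$n_angles) - 1L) %% cfg$n_subsets == (k - 1L)))
  sens <- lapply(subsets, function(ai)
    back_project(f[, ai, , drop = FALSE], grid, geom, ai)$values)

  x <- array(1, dim = grid$shape)
  support <- Reduce(`+`, sens) > 0
  x[!support] <- 0
  loglik <- if (cfg$track_loglik) numeric(cfg$n_iterations) else NULL

  for (it in seq_len(cfg$n_iterations)) {
    for (k in seq_len(cfg$n_subsets)) {
      ai <- subsets[[k]]
      fp <- forward_project(image_volume(grid, x, "activity"), geom, ai)
      lam <- f[, ai, , drop = FALSE] * fp + s[, ai, , drop = FALSE]
      ratio <- f[, ai, , drop = FALSE] * y[, ai, , drop = FALSE] / (lam + eps)
      bp <- back_project(ratio, grid, geom, ai)$values
      upd <- ifelse(sens[[k]] > 0, bp / pmax(sens[[k]], eps), 0)
      x <- x * upd
    }
    if (cfg$track_loglik) {
      fp_full <- forward_project(image_volume(grid, x, "activity"), geom)
      lam <- f * fp_full$values + s
      loglik[it] <- sum(y * log(lam + eps) - lam)
    }
  }

  act <- x / (acq$sensitivity * acq$duration_s)
  img <- image_volume(grid, act, "activity")
  if (cfg$post_filter_fwhm_mm > 0)
    img <- apply_psf(img, psf_model(cfg$post_filter_fwhm_mm))
  structure(list(image = img, config = cfg, mu_method = mu$method,
                 loglik = loglik),
            class = "recon_result")
}

#' Reconstruct one counts sinogram with every map of a family
#'
#' Five reconstructions from the same counts, differing only in the
#' attenuation map inside the system model.
#'
#' @param counts counts [sinogram()].
#' @param family an `mrac_family` from [derive_mrac_family()].
#' @param acq an [acquisition_model()].
#' @param scatter expected scatter [sinogram()] or `NULL`.
#' @param geom a [sinogram_geometry()].
#' @param cfg a [recon_config()].
#' @return named list of `recon_result`s: `ctac`, `dixon`, `dixonbone`,
#'   `ute`, `dl_dixon`.
#' @export
reconstruct_all <- function(counts, family, acq, scatter = NULL, geom, cfg) {
  maps <- c(list(ctac = family$reference), family$candidates)
  lapply(maps, function(m)
    osem_reconstruct(counts, m, acq, scatter, geom, cfg))
}
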