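#' Digital head phantom configuration
#'
#' Parameters of the analytic head phantom: nested ellipsoids (scalp, skull,
#' cortical gray-matter ribbon, deep gray band, white-matter core) whose
#' cortical ribbon is partitioned into named angular sectors. HU assignments
#' span both segments of the bilinear HU to LAC model (air -1000, soft
#' tissue 0-60 HU, skull 700-1200 HU).
#'
#' @param shape grid shape, default `c(128, 128, 16)`.
#' @param voxel_size_mm voxel size in mm, default `c(2, 2, 6)`.
#' @param head_radius_mm lateral (x) semi-axis of the outer skin ellipsoid.
#' @param head_aspect semi-axis multipliers `(x, y, z)` applied to
#'   `head_radius_mm`; the default gives a head elongated front-back and
#'   flattened axially so it fits a 16-slice field of view.
#' @param scalp_thickness_mm,skull_thickness_mm,ribbon_thickness_mm,deep_band_mm
#'   layer thicknesses (mm): scalp, skull shell, cortical ribbon, and the
#'   deep gray band (the "fusiform" analogue) respectively.
#' @param n_sectors number of cortical ribbon sectors (>= 16).
#' @param gray_activity gray-matter activity (Bq/mL).
#' @param gray_white_ratio gray:white activity ratio.
#' @param scalp_activity scalp activity (Bq/mL).
#' @param scalp_hu,gray_hu,white_hu,skull_hu tissue HU values.
#' @param region_activity_scale optional named numeric vector of per-region
#'   activity multipliers (names from the atlas name table); used by
#'   [cohort()] to create inter-subject variability.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(128L, 128L, 16L),
                           voxel_size_mm = c(2, 2, 6),
                           head_radius_mm = 70,
                           head_aspect = c(1, 1.15, 0.55),
                           scalp_thickness_mm = 5,
                           skull_thickness_mm = 6,
                           ribbon_thickness_mm = 10,
                           deep_band_mm = 12,
                           n_sectors = 16L,
                           gray_activity = 10,
                           gray_white_ratio = 4,
                           scalp_activity = 1,
                           scalp_hu = 50, gray_hu = 40, white_hu = 30,
                           skull_hu = 1000,
                           region_activity_scale = NULL) {
  cfg <- list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
              head_radius_mm = head_radius_mm, head_aspect = head_aspect,
              scalp_thickness_mm = scalp_thickness_mm,
              skull_thickness_mm = skull_thickness_mm,
              ribbon_thickness_mm = ribbon_thickness_mm,
              deep_band_mm = deep_band_mm,
              n_sectors = as.integer(n_sectors),
              gray_activity = gray_activity,
              gray_white_ratio = gray_white_ratio,
              scalp_activity = scalp_activity,
              scalp_hu = scalp_hu, gray_hu = gray_hu, white_hu = white_hu,
              skull_hu = skull_hu,
              region_activity_scale = region_activity_scale)
  class(cfg) <- "phantom_config"
  cfg
}

# FreeSurfer-style names for the cortical ribbon sectors; the sector
# containing the +y (anterior) direction is "superior_frontal" so that a
# skull-adjacent lesion can be placed there by name.
sector_names <- function(n) {
  base <- c("superior_frontal", "rostral_middle_frontal",
            "caudal_middle_frontal", "pars_opercularis", "pars_triangularis",
            "precentral", "postcentral", "supramarginal", "superior_parietal",
            "inferior_parietal", "lateral_occipital", "lingual",
            "inferior_temporal", "middle_temporal", "superior_temporal",
            "insula")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("cortical_sector_%02d", seq(length(base) + 1L, n)))
}

# ellipsoid membership: semi-axes in mm, centered on world origin
inside_ellipsoid <- function(X, Y, Z, semi) {
  (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
}

#' Generate one digital head phantom
#'
#' Builds the emission volume, CT-like HU volume, region atlas and the
#' ground-truth 511 keV attenuation map for one synthetic subject. The
#' construction is a pure function of `(config, seed)`; emission is
#' piecewise constant per atlas region (gray > white), attenuation is air
#' outside the scalp surface, and the skull shell separates brain labels
#' from background on every axial slice through the brain.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed recorded in the bundle (per-subject variability
#'   is drawn in [cohort()], not here).
#' @return a `phantom_bundle`: list with elements `emission`, `ct_hu`,
#'   `atlas` ([label_volume()]), `mu_true`, `seed`, `config`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  cfg <- config
  if (cfg$n_sectors < 16L)
    stop("config error: number of cortical sectors must be >= 16")

  grid <- voxel_grid(cfg$shape, cfg$voxel_size_mm)
  semi_skin <- cfg$head_radius_mm * cfg$head_aspect
  half_extent <- cfg$shape * cfg$voxel_size_mm / 2
  if (any(semi_skin + cfg$voxel_size_mm / 2 > half_extent))
    stop("sizing error: grid too small to contain the head at the requested radii")

  # Layers are nested in-plane only (shared z semi-axis): the projector's
  # rays are axial, so in-plane shell geometry carries all the attenuation
  # physics, and the skull stays a closed annulus on every axial slice.
  shrink <- function(semi, t) c(semi[1] - t, semi[2] - t, semi[3])
  semi_skull_out <- shrink(semi_skin, cfg$scalp_thickness_mm)
  semi_skull_in  <- shrink(semi_skull_out, cfg$skull_thickness_mm)
  semi_ribbon_in <- shrink(semi_skull_in, cfg$ribbon_thickness_mm)
  semi_deep_in   <- shrink(semi_ribbon_in, cfg$deep_band_mm)
  if (any(semi_deep_in[1:2] <= 2))
    stop("sizing error: layer thicknesses leave no white-matter core")

  nx <- cfg$shape[1]; ny <- cfg$shape[2]; nz <- cfg$shape[3]
  X <- array(axis_coords(grid, 1), dim = cfg$shape)
  Y <- array(rep(axis_coords(grid, 2), each = nx), dim = cfg$shape)
  Z <- array(rep(axis_coords(grid, 3), each = nx * ny), dim = cfg$shape)

  in_skin   <- inside_ellipsoid(X, Y, Z, semi_skin)
  in_sk_out <- inside_ellipsoid(X, Y, Z, semi_skull_out)
  in_sk_in  <- inside_ellipsoid(X, Y, Z, semi_skull_in)
  in_rib_in <- inside_ellipsoid(X, Y, Z, semi_ribbon_in)
  in_deep   <- inside_ellipsoid(X, Y, Z, semi_deep_in)
  in_thal   <- inside_ellipsoid(X, Y, Z, c(14, 10, 8))

  ns <- cfg$n_sectors
  # sector 0 centered on the +y (anterior) direction
  ang <- (atan2(Y, X) - pi / 2) %% (2 * pi)
  sec <- floor(ang / (2 * pi / ns) + 0.5) %% ns

  labels <- array(0L, dim = cfg$shape)
  labels[in_skin & !in_sk_out] <- 1L                       # scalp
  labels[in_sk_out & !in_sk_in] <- 2L                      # skull
  ribbon <- in_sk_in & !in_rib_in
  labels[ribbon] <- 3L + as.integer(sec[ribbon])           # cortical sectors
  fus_lab  <- 3L + ns
  thal_lab <- 4L + ns
  wm_lab   <- 5L + ns
  labels[in_rib_in & !in_deep] <- fus_lab                  # deep gray band
  labels[in_deep] <- wm_lab
  labels[in_deep & in_thal] <- thal_lab

  region_names <- c("scalp", "skull", sector_names(ns),
                    "fusiform", "thalamus", "white_matter")
  name_table <- stats::setNames(region_names, as.character(seq_along(region_names)))
  atlas <- label_volume(grid, labels, name_table)

  hu <- array(-1000, dim = cfg$shape)
  hu[labels == 1L] <- cfg$scalp_hu
  hu[labels == 2L] <- cfg$skull_hu
  gray_labs <- c(3:(2L + ns), fus_lab, thal_lab)
  hu[labels %in% gray_labs] <- cfg$gray_hu
  hu[labels == wm_lab] <- cfg$white_hu

  act <- array(0, dim = cfg$shape)
  act[labels == 1L] <- cfg$scalp_activity
  act[labels %in% gray_labs] <- cfg$gray_activity
  act[labels == wm_lab] <- cfg$gray_activity / cfg$gray_white_ratio
  if (!is.null(cfg$region_activity_scale)) {
    for (nm in names(cfg$region_activity_scale)) {
      lab <- region_label(atlas, nm)
      act[labels == lab] <- act[labels == lab] * cfg$region_activity_scale[[nm]]
    }
  }

  ct_hu <- image_volume(grid, hu, "hounsfield")
  bundle <- list(emission = image_volume(grid, act, "activity"),
                 ct_hu = ct_hu,
                 atlas = atlas,
                 mu_true = hu_to_lac(ct_hu),
                 seed = as.integer(seed),
                 config = cfg)
  class(bundle) <- "phantom_bundle"
  bundle
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle (seed %d): ", x$seed))
  print(x$atlas)
  invisible(x)
}

#' Per-subject randomized configuration
#'
#' Draws the inter-subject variability of one cohort member from seeds
#' derived from the master seed: head size +/-5%, skull thickness +/-20%,
#' skull HU uniform in 700-1200, scalp HU in 30-60, and per-region activity
#' multipliers +/-10%.
#'
#' @param config base [phantom_config()].
#' @param master_seed cohort master seed.
#' @param i subject index (1-based).
#' @return list with elements `config` (jittered) and `seed` (the subject's
#'   derived phantom seed).
#' @export
subject_config <- function(config, master_seed, i) {
  cfg_seed <- derive_seed(master_seed, "subject-config", i)
  cfg <- config
  withr::with_seed(cfg_seed, {
    cfg$head_radius_mm <- cfg$head_radius_mm * stats::runif(1, 0.95, 1.05)
    cfg$skull_thickness_mm <- cfg$skull_thickness_mm * stats::runif(1, 0.8, 1.2)
    cfg$skull_hu <- stats::runif(1, 700, 1200)
    cfg$scalp_hu <- stats::runif(1, 30, 60)
    regions <- c(sector_names(cfg$n_sectors), "fusiform", "thalamus",
                 "white_matter")
    cfg$region_activity_scale <-
      stats::setNames(stats::runif(length(regions), 0.9, 1.1), regions)
  })
  list(config = cfg, seed = derive_seed(master_seed, "subject-phantom", i))
}

#' Generate a cohort of phantoms
#'
#' Stand-in for a multi-patient dataset: `n` phantoms with seeded
#' per-subject jitter (see [subject_config()]), all reproducible from one
#' master seed.
#'
#' @param config base [phantom_config()].
#' @param n cohort size (>= 1), default 11.
#' @param master_seed integer master seed.
#' @return list of `n` `phantom_bundle`s.
#' @export
cohort <- function(config = phantom_config(), n = 11L, master_seed = 1L) {
  if (n < 1) stop("config error: cohort size must be >= 1")
  lapply(seq_len(n), function(i) {
    sc <- subject_config(config, master_seed, i)
    generate_phantom(sc$config, sc$seed)
  })
}
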