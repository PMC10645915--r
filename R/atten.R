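#' Bilinear HU to 511 keV LAC parameters
#'
#' Standard two-segment model: below the break the LAC is the line through
#' the air anchor (-1000 HU, 0) and the water anchor (0 HU, `mu_water`);
#' above the break it continues with the bone slope. Values are clipped to
#' `[0, max_lac]`. Vendor slopes are not standardized, so everything is
#' configurable.
#'
#' @param break_hu segment break point (HU), default 0.
#' @param mu_water water LAC at 511 keV (cm^-1), default 0.096.
#' @param bone_slope supra-break slope (cm^-1 per HU), default 5.1e-5
#'   (about 0.147 cm^-1 at 1000 HU, conventional cortical bone).
#' @param max_lac upper clip (cm^-1), default 0.3.
#' @return a `bilinear_params` list.
#' @export
bilinear_params <- function(break_hu = 0, mu_water = 0.096,
                            bone_slope = 5.1e-5, max_lac = 0.3) {
  structure(list(break_hu = break_hu, mu_water = mu_water,
                 bone_slope = bone_slope, max_lac = max_lac),
            class = "bilinear_params")
}

#' Convert a CT HU volume to 511 keV linear attenuation coefficients
#'
#' Voxelwise continuous piecewise-linear scaling (see [bilinear_params()]).
#' The map is monotone non-decreasing in HU and continuous at the break.
#'
#' @param ct an [image_volume()] with quantity `"hounsfield"`.
#' @param params a [bilinear_params()].
#' @return an [image_volume()] with quantity `"lac"` (cm^-1).
#' @export
hu_to_lac <- function(ct, params = bilinear_params()) {
  if (!inherits(ct, "image_volume") || ct$quantity != "hounsfield")
    stop("type error: hu_to_lac expects an image_volume with quantity 'hounsfield'")
  hu <- ct$values
  # soft segment through (-1000, 0) and (0, mu_water); its value at the break
  mu_at_break <- params$mu_water * (params$break_hu + 1000) / 1000
  mu <- ifelse(hu <= params$break_hu,
               params$mu_water * (hu + 1000) / 1000,
               mu_at_break + params$bone_slope * (hu - params$break_hu))
  mu <- pmin(pmax(mu, 0), params$max_lac)
  image_volume(ct$grid, array(mu, dim = dim(hu)), "lac")
}

#' Tissue-class LAC lookup table
#'
#' @param entries named numeric vector of 511 keV LACs (cm^-1); must contain
#'   at least `air`, `fat` and `soft`.
#' @return a `tissue_lut`.
#' @export
tissue_lut <- function(entries = c(air = 0.0, fat = 0.0864, soft = 0.096,
                                   spongeous_bone = 0.11,
                                   cortical_bone = 0.147)) {
  if (any(entries < 0)) stop("all LAC entries must be >= 0")
  if (!all(c("air", "fat", "soft") %in% names(entries)))
    stop("tissue LUT must contain at least air, fat and soft")
  structure(entries, class = "tissue_lut")
}

#' Segmented-tissue attenuation map from a class label volume
#'
#' Voxelwise lookup of fixed 511 keV LACs per tissue class, as in
#' segmentation-based MR attenuation correction. Background (label 0) maps
#' to air.
#'
#' @param classmap a [label_volume()] whose name table gives tissue-class
#'   names.
#' @param lut a [tissue_lut()].
#' @param method method tag for the resulting map.
#' @return a [mu_map()].
#' @export
classes_to_mu <- function(classmap, lut = tissue_lut(), method = "dixon") {
  present <- setdiff(sort(unique(as.vector(classmap$labels))), 0L)
  classes <- classmap$name_table[as.character(present)]
  missing <- classes[!classes %in% names(lut)]
  if (length(missing))
    stop("lookup error: no LUT entry for tissue class(es): ",
         paste(unique(missing), collapse = ", "))
  mu <- array(lut[["air"]], dim = classmap$grid$shape)
  for (lab in present)
    mu[classmap$labels == lab] <- lut[[classmap$name_table[[as.character(lab)]]]]
  mu_map(image_volume(classmap$grid, mu, "lac"), method)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target voxel takes the value of the source voxel whose center is
#' nearest in world coordinates; target voxels outside the source extent
#' take the fill value (0 for activity/LAC/masks, -1000 for HU).
#'
#' @param src an [image_volume()].
#' @param target a [voxel_grid()].
#' @return an [image_volume()] on `target` with the same quantity.
#' @export
resample_nearest <- function(src, target) {
  sg <- src$grid
  # world extents (voxel-edge to voxel-edge) must overlap on every axis
  for (a in 1:3) {
    s_lo <- sg$origin_mm[a] - sg$voxel_size_mm[a] / 2
    s_hi <- s_lo + sg$shape[a] * sg$voxel_size_mm[a]
    t_lo <- target$origin_mm[a] - target$voxel_size_mm[a] / 2
    t_hi <- t_lo + target$shape[a] * target$voxel_size_mm[a]
    if (t_lo >= s_hi || t_hi <= s_lo)
      stop("geometry error: source and target grids are disjoint in world space")
  }
  fill <- if (src$quantity == "hounsfield") -1000 else 0
  idx <- vector("list", 3)
  inside <- vector("list", 3)
  for (a in 1:3) {
    tw <- axis_coords(target, a)
    i <- round((tw - sg$origin_mm[a]) / sg$voxel_size_mm[a]) + 1
    inside[[a]] <- i >= 1 & i <= sg$shape[a]
    idx[[a]] <- pmin(pmax(i, 1), sg$shape[a])
  }
  vals <- src$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out_mask <- !(outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&"))
  vals[out_mask] <- fill
  image_volume(target, array(vals, dim = target$shape), src$quantity)
}

#' Attenuation map with a method tag
#'
#' @param image an [image_volume()] with quantity `"lac"`, values in
#'   `[0, 0.3]` cm^-1.
#' @param method one of `"ctac"`, `"dixon"`, `"dixonbone"`, `"ute"`,
#'   `"dl_dixon"`.
#' @return a `mu_map`.
#' @export
mu_map <- function(image, method) {
  method <- match.arg(method, MRAC_METHODS_ALL)
  if (image$quantity != "lac") stop("mu_map requires a lac image")
  if (any(image$values < 0) || any(image$values > 0.3))
    stop("LAC values must lie in [0, 0.3] cm^-1")
  structure(list(image = image, method = method), class = "mu_map")
}

MRAC_METHODS <- c("dixon", "dixonbone", "ute", "dl_dixon")
MRAC_METHODS_ALL <- c("ctac", MRAC_METHODS)

#' Degradation parameters for the MR-style attenuation map family
#'
#' @param bone_scale multiplicative bias of continuous bone LAC in the
#'   model-based bone map (default 0.9).
#' @param bone_erosion_mm boundary erosion of the model-based bone shell
#'   (mm, default 2).
#' @param ute_bone_lac fixed LAC of the single binary bone compartment
#'   (cm^-1, default 0.11).
#' @param misclass_frac fraction of skull-boundary voxels misclassified in
#'   the two-compartment map (default 0.05).
#' @param dl_noise_sd voxelwise LAC noise of the pseudo-CT map (cm^-1,
#'   default 0.002).
#' @return a `degrade_config` list.
#' @export
degrade_config <- function(bone_scale = 0.9, bone_erosion_mm = 2,
                           ute_bone_lac = 0.11, misclass_frac = 0.05,
                           dl_noise_sd = 0.002) {
  if (misclass_frac < 0 || misclass_frac > 1 || bone_scale < 0 || bone_scale > 1)
    stop("config error: fractional degrade parameters must lie in [0, 1]")
  structure(list(bone_scale = bone_scale, bone_erosion_mm = bone_erosion_mm,
                 ute_bone_lac = ute_bone_lac, misclass_frac = misclass_frac,
                 dl_noise_sd = dl_noise_sd),
            class = "degrade_config")
}

# 6-neighbourhood binary erosion, n iterations
erode_mask <- function(mask, n_iter) {
  d <- dim(mask)
  for (it in seq_len(n_iter)) {
    m <- mask
    shift_and <- function(m, axis, by) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      n <- d[axis]
      if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
      else        { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    keep <- mask
    for (axis in 1:2)   # erode in-plane only; slices are thick
      for (by in c(1L, -1L))
        keep <- keep & shift_and(m, axis, by)
    mask <- keep
  }
  mask
}

#' Derive the candidate attenuation-map family from a phantom
#'
#' Builds the reference CT-based map and four MR-style candidates as
#' controlled degradations of the ground truth, ordered by bone fidelity:
#'
#' * `dixon`: soft-tissue-only; every skull voxel is set to the soft-tissue
#'   LAC (bone ignored entirely).
#' * `dixonbone`: continuous bone, biased by `bone_scale` and eroded at the
#'   shell boundary by `bone_erosion_mm`.
#' * `ute`: a single binary bone compartment at one fixed LAC, with a
#'   seeded fraction of shell-boundary voxels misclassified.
#' * `dl_dixon`: pseudo-CT; ground truth plus small seeded voxelwise noise,
#'   closest to truth by construction.
#'
#' All candidates except `dl_dixon` equal the ground truth exactly on
#' brain-interior voxels.
#'
#' @param bundle a `phantom_bundle` from [generate_phantom()].
#' @param degrade a [degrade_config()].
#' @param seed integer seed for the stochastic degradations.
#' @return an `mrac_family`: list with `reference` ([mu_map()], method
#'   `ctac`) and `candidates` (named list of the four candidate maps).
#' @export
derive_mrac_family <- function(bundle, degrade = degrade_config(), seed = 1L) {
  grid <- bundle$mu_true$grid
  mu0 <- bundle$mu_true$values
  skull <- bundle$atlas$labels == region_label(bundle$atlas, "skull")
  scalp <- bundle$atlas$labels == region_label(bundle$atlas, "scalp")
  soft_lac <- 0.096

  # dixon: bone ignored, skull becomes uniform soft tissue
  v <- mu0; v[skull] <- soft_lac
  dixon <- mu_map(image_volume(grid, v, "lac"), "dixon")

  # dixonbone: continuous but biased bone, boundary-eroded shell
  n_it <- round(degrade$bone_erosion_mm / min(grid$voxel_size_mm[1:2]))
  core <- if (n_it > 0) erode_mask(skull, n_it) else skull
  v <- mu0
  v[skull & !core] <- soft_lac
  v[core] <- pmin(mu0[core] * degrade$bone_scale, 0.3)
  dixonbone <- mu_map(image_volume(grid, v, "lac"), "dixonbone")

  # ute: binary bone compartment at one fixed LAC + seeded boundary
  # misclassification (skull boundary -> soft; adjacent scalp -> bone);
  # brain-label voxels are never touched
  inner <- erode_mask(skull, 1L)
  bone_boundary <- which(skull & !inner)
  # scalp voxels whose in-plane 4-neighbourhood touches skull
  dil_once <- function(m) {
    d <- dim(m); out <- m
    for (axis in 1:2) for (by in c(1L, -1L)) {
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      n <- d[axis]
      if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
      else        { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
      tmp <- array(FALSE, d)
      tmp[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out <- out | tmp
    }
    out
  }
  scalp_boundary <- which(scalp & dil_once(skull))
  boundary <- c(bone_boundary, scalp_boundary)
  v <- mu0
  v[skull] <- degrade$ute_bone_lac
  if (degrade$misclass_frac > 0 && length(boundary) > 0) {
    n_flip <- round(degrade$misclass_frac * length(boundary))
    flip <- withr::with_seed(derive_seed(seed, "ute-misclass"),
                             sample(boundary, n_flip))
    flip_bone <- flip[flip %in% bone_boundary]
    flip_scalp <- flip[flip %in% scalp_boundary]
    v[flip_bone] <- soft_lac
    v[flip_scalp] <- degrade$ute_bone_lac
  }
  ute <- mu_map(image_volume(grid, v, "lac"), "ute")

  # dl_dixon: near-truth pseudo-CT with small voxelwise noise
  noise <- withr::with_seed(derive_seed(seed, "dl-noise"),
                            stats::rnorm(length(mu0), 0, degrade$dl_noise_sd))
  v <- pmin(pmax(mu0 + array(noise, dim = dim(mu0)), 0), 0.3)
  dl_dixon <- mu_map(image_volume(grid, v, "lac"), "dl_dixon")

  structure(list(reference = mu_map(bundle$mu_true, "ctac"),
                 candidates = list(dixon = dixon, dixonbone = dixonbone,
                                   ute = ute, dl_dixon = dl_dixon)),
            class = "mrac_family")
}
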