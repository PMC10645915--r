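#' Read an image volume from a NIfTI-1 file
#'
#' The voxel size and origin are taken from the header (sform); values are
#' unchanged. Only axis-aligned affines are supported.
#'
#' @param path NIfTI-1 file path.
#' @param quantity quantity tag for the resulting [image_volume()].
#' @return an [image_volume()].
#' @export
read_volume <- function(path, quantity = "activity") {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  nii <- RNifti::readNifti(path)
  aff <- RNifti::xform(nii)
  vox <- abs(diag(aff)[1:3])
  orig <- aff[1:3, 4]
  grid <- voxel_grid(dim(nii)[1:3], vox, orig)
  image_volume(grid, array(as.numeric(nii), dim = grid$shape), quantity)
}

#' Write an image volume as NIfTI-1
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  vals <- if (inherits(vol, "label_volume")) vol$labels else vol$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  aff <- diag(c(vol$grid$voxel_size_mm, 1))
  aff[1:3, 4] <- vol$grid$origin_mm
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Write a phantom bundle to a directory
#'
#' Emission, HU, ground-truth attenuation and atlas volumes as NIfTI-1,
#' plus the atlas name table as a JSON sidecar.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$emission, file.path(dir, "emission.nii.gz"))
  write_volume(bundle$ct_hu, file.path(dir, "ct_hu.nii.gz"))
  write_volume(bundle$mu_true, file.path(dir, "mu_true.nii.gz"))
  write_volume(bundle$atlas, file.path(dir, "atlas.nii.gz"))
  jsonlite::write_json(as.list(bundle$atlas$name_table),
                       file.path(dir, "atlas_labels.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Write a sinogram as NIfTI-1 plus a JSON geometry sidecar
#'
#' @param sino a [sinogram()].
#' @param path output `.nii`/`.nii.gz` path; the sidecar gets the same
#'   name with extension `.json`.
#' @return invisibly, `path`.
#' @export
write_sinogram <- function(sino, path) {
  g <- sino$geometry
  img <- RNifti::asNifti(sino$values)
  RNifti::pixdim(img) <- c(g$radial_bin_mm, 1, 1)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(n_radial = g$n_radial, n_angles = g$n_angles,
                            n_slices = g$n_slices,
                            radial_bin_mm = g$radial_bin_mm,
                            content = sino$content),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path `.nii`/`.nii.gz` path with its `.json` sidecar alongside.
#' @return a [sinogram()].
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("I/O error: missing geometry sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  geom <- sinogram_geometry(meta$n_radial, meta$n_angles, meta$n_slices,
                            meta$radial_bin_mm)
  nii <- RNifti::readNifti(path)
  sinogram(geom, array(as.numeric(nii), dim = dim(nii)[1:3]), meta$content)
}

#' Read a phantom bundle written by [write_phantom()]
#'
#' Reconstructs the bundle from its NIfTI volumes and the atlas name-table
#' sidecar; the ground-truth attenuation map is re-derived from the HU
#' volume so the bundle invariant `mu_true == hu_to_lac(ct_hu)` holds
#' exactly.
#'
#' @param dir directory produced by [write_phantom()].
#' @return a `phantom_bundle` (with `seed = NA` and `config = NULL`).
#' @export
read_phantom <- function(dir) {
  emission <- read_volume(file.path(dir, "emission.nii.gz"), "activity")
  ct_hu <- read_volume(file.path(dir, "ct_hu.nii.gz"), "hounsfield")
  atlas_img <- read_volume(file.path(dir, "atlas.nii.gz"),
                           "label-probability")
  tab <- unlist(jsonlite::read_json(file.path(dir, "atlas_labels.json"),
                                    simplifyVector = TRUE))
  atlas <- label_volume(atlas_img$grid,
                        array(as.integer(round(atlas_img$values)),
                              dim = atlas_img$grid$shape), tab)
  structure(list(emission = emission, ct_hu = ct_hu, atlas = atlas,
                 mu_true = hu_to_lac(ct_hu), seed = NA_integer_,
                 config = NULL),
            class = "phantom_bundle")
}
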