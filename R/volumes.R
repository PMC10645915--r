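#' Voxel grid
#'
#' Axis-aligned 3D voxel grid. `origin_mm` is the world coordinate of the
#' *center* of the first voxel (index `(1,1,1)`). When `origin_mm` is `NULL`
#' the grid is centered on the world origin, which is where the phantom and
#' the projector's rotation axis live.
#'
#' @param shape integer triple `(nx, ny, nz)`, all >= 1.
#' @param voxel_size_mm positive real triple, mm per voxel along each axis.
#' @param origin_mm world coordinate (mm) of the center of voxel `(1,1,1)`,
#'   or `NULL` to center the grid on the world origin.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three integers >= 1")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel sizes must be three positive reals")
  if (is.null(origin_mm)) origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("origin_mm must have length 3")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}

# world coordinates of voxel centers along one axis (1-based index)
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}

# half-extent of the in-plane bounding box diagonal, from world origin,
# used to check radial coverage of a sinogram geometry
grid_inplane_halfdiag <- function(grid) {
  xs <- range(axis_coords(grid, 1)) + c(-0.5, 0.5) * grid$voxel_size_mm[1]
  ys <- range(axis_coords(grid, 2)) + c(-0.5, 0.5) * grid$voxel_size_mm[2]
  sqrt(max(abs(xs))^2 + max(abs(ys))^2)
}

VOLUME_QUANTITIES <- c("activity", "hounsfield", "lac", "label-probability")

#' Image volume
#'
#' A scalar field on a [voxel_grid()]. `quantity` records the physical
#' meaning and units: `"activity"` (Bq/mL), `"hounsfield"` (HU),
#' `"lac"` (cm^-1 at 511 keV) or `"label-probability"` (unitless mask).
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array with `dim == grid$shape`.
#' @param quantity one of `"activity"`, `"hounsfield"`, `"lac"`,
#'   `"label-probability"`.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(grid, values, quantity) {
  quantity <- match.arg(quantity, VOLUME_QUANTITIES)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values array shape does not match the grid")
  storage.mode(values) <- "double"
  if (quantity %in% c("activity", "lac") && any(values < 0))
    stop(sprintf("%s volumes must be >= 0 everywhere", quantity))
  if (quantity == "hounsfield" && any(values < -1024))
    stop("HU volumes must be >= -1024")
  structure(list(grid = grid, values = values, quantity = quantity),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s]: %d x %d x %d, range [%.4g, %.4g]\n",
              x$quantity, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Label volume
#'
#' Integer region atlas on a [voxel_grid()]. Label 0 is reserved for
#' background; every non-zero label present in the array must be named in
#' `name_table`.
#'
#' @param grid a [voxel_grid()].
#' @param labels integer array with `dim == grid$shape`, values >= 0.
#' @param name_table named character vector mapping label (as name) to
#'   region name, e.g. `c("1" = "scalp", "2" = "skull")`.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(grid, labels, name_table) {
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("labels array shape does not match the grid")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(present), names(name_table))
  if (length(missing))
    stop("labels present in the array but absent from name_table: ",
         paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels,
                 name_table = name_table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf("label_volume: %d x %d x %d, %d non-zero regions\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], n))
  invisible(x)
}

#' Look up the integer label of a named atlas region
#'
#' @param atlas a [label_volume()].
#' @param region_name region name as it appears in the atlas name table.
#' @return integer label.
#' @export
region_label <- function(atlas, region_name) {
  hit <- names(atlas$name_table)[atlas$name_table == region_name]
  if (length(hit) != 1L)
    stop("region name not found in atlas: ", region_name)
  as.integer(hit)
}
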