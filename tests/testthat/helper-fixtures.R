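# Shared in-code fixtures: small grids, disks and the smoke-scale phantom
# configuration used throughout the suite.

smoke_phantom_config <- function(...) {
  phantom_config(shape = c(64L, 64L, 8L), voxel_size_mm = c(4, 4, 12), ...)
}

smoke_recon_config <- function(...) {
  recon_config(n_iterations = 2L, n_subsets = 8L, ...)
}

# uniform axial disk of given radius/value replicated over slices
disk_volume <- function(grid, radius_mm, value = 1, quantity = "activity") {
  x <- axis_coords(grid, 1)
  y <- axis_coords(grid, 2)
  d2 <- outer(x^2, y^2, "+")
  slice <- (d2 <= radius_mm^2) * value
  image_volume(grid, array(rep(slice, grid$shape[3]), dim = grid$shape),
               quantity)
}

# grid coordinate helper re-exported for tests
axis_coords <- petlesionsim:::axis_coords

# uniform-cylinder matched-model scene: emission + true mu + geometry
cylinder_scene <- function(nx = 64L, nz = 4L, radius_mm = 40,
                           activity = 5, n_angles = 48L) {
  grid <- voxel_grid(c(nx, nx, nz), c(2, 2, 6))
  emission <- disk_volume(grid, radius_mm, activity)
  mu <- mu_map(disk_volume(grid, radius_mm, 0.096, "lac"), "ctac")
  geom <- geometry_for_grid(grid, n_angles = n_angles)
  list(grid = grid, emission = emission, mu = mu, geom = geom)
}

# brute-force Benjamini-Hochberg step-up: adj_i = min_{j >= i} m p_(j) / j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(adj_sorted, 1)[order(o)]
}
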