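# Shared fixtures: small phantoms and grids built in code at test time.

# uniform water box grid (no air), spacing 2 mm by default
water_grid <- function(half_xy = 30, half_z = 20, spacing = 2, rsp = 1.0) {
  nx <- as.integer(2 * half_xy / spacing)
  nz <- as.integer(2 * half_z / spacing)
  voxel_grid(origin = c(-half_xy, -half_xy, -half_z),
             spacing = rep(spacing, 3),
             values = array(rsp, dim = c(nx, nx, nz)))
}

# sphere mask centered at `center` on a grid
sphere_mask <- function(grid, center, radius) {
  ctr <- voxel_centers(grid)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  array(d2 <= radius^2, dim = grid$dims)
}

# z-axis cylinder mask
cylinder_mask <- function(grid, center_xy, radius, half_height) {
  ctr <- voxel_centers(grid)
  ok <- (ctr[, 1] - center_xy[1])^2 + (ctr[, 2] - center_xy[2])^2 <=
    radius^2 & abs(ctr[, 3]) <= half_height
  array(ok, dim = grid$dims)
}

# small water phantom with an embedded sphere target (fast unit fixture)
tiny_phantom <- function(target_radius = 10, body = 24, spacing = 2) {
  grid <- water_grid(half_xy = body, half_z = body * 0.7, spacing = spacing)
  tgt <- sphere_mask(grid, c(0, 0, 0), target_radius)
  list(grid = grid,
       structures = list(rt_structure("CTV", "target", tgt)))
}

# small BEV grid for mask-level tests
small_bev <- function(extent = 40, pixel = 1) {
  bev_grid(pixel_mm = pixel, u_extent = extent, v_extent = extent)
}

# analytic disk mask on a BEV grid
disk_mask <- function(bev, radius, center = c(0, 0)) {
  outer(bev$u, bev$v, function(u, v)
    (u - center[1])^2 + (v - center[2])^2 <= radius^2)
}
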