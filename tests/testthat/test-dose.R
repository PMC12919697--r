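# Aperture-aware analytic dose engine: fluence maps, depth transport,
# linearity, collimation effects and scenario perturbations.

machine <- default_machine()
mlc <- machine$mlc

test_that("layer fluence integrates to the total spot weight", {
  bev <- small_bev(40)
  sp <- data.frame(u = 0, v = 0, weight = 1)
  Fm <- layer_fluence(sp, sigma_iso_mm = 5, aperture = NULL, bev = bev)
  expect_lt(abs(sum(Fm) * bev$pixel_mm^2 - 1), 0.01)
  expect_true(all(Fm >= 0))
  # fully closed aperture yields an all-zero map
  closed <- matrix(NA_real_, mlc$n_pairs, 2)
  F0 <- layer_fluence(sp, 5, closed, bev, mlc)
  expect_true(all(F0 == 0))
})

test_that("half-plane clipping reproduces the Gaussian x Heaviside form", {
  bev <- small_bev(40)
  sp <- data.frame(u = 0, v = 0, weight = 1)
  # open only for u >= 0 across all pairs
  ap <- matrix(rep(c(0, 75), each = mlc$n_pairs), mlc$n_pairs, 2)
  Fm <- layer_fluence(sp, 5, ap, bev, mlc, edge_sigma_mm = 0)
  # integral equals 0.5 (erf closed form for a half-plane)
  expect_lt(abs(sum(Fm) * bev$pixel_mm^2 - 0.5), 0.02)
  # pointwise: Gaussian on the open side, zero on the closed side
  iu_open <- which(bev$u > 1); iu_closed <- which(bev$u < -1)
  iv0 <- which.min(abs(bev$v))
  g <- exp(-(bev$u^2 + bev$v[iv0]^2) / 50) / (2 * pi * 25)
  expect_equal(Fm[iu_open, iv0], g[iu_open], tolerance = 1e-12)
  expect_true(all(Fm[iu_closed, iv0] == 0))
})

# single-beam water fixture shared by the engine tests
water_state <- function(aperture_mode = c("none", "cover", "half"),
                        energy = 85, weight = 1) {  # R ~ 55 mm, inside the box
  aperture_mode <- match.arg(aperture_mode)
  grid <- water_grid(half_xy = 40, half_z = 24)
  beam <- beam_config(0, 0)
  bev <- bev_grid()
  geom <- beam_geometry(grid, beam, bev)
  lay <- energy_layer(energy, machine)  # R ~ 54 mm, no RS
  sp <- data.frame(u = 0, v = 0, weight = weight)
  ap <- switch(aperture_mode,
               none = NULL,
               cover = { a <- matrix(NA_real_, mlc$n_pairs, 2)
                         kv <- protonDMLC:::pair_of_v(mlc, c(-12, 12))
                         a[kv[1]:kv[2], ] <- rep(c(-12, 12),
                                                 each = kv[2] - kv[1] + 1)
                         a },
               half = { a <- matrix(NA_real_, mlc$n_pairs, 2)
                        a[, 1] <- -75; a[, 2] <- 0
                        a })
  st <- beam_state(geom, list(lay), list(sp),
                   if (is.null(ap)) NULL else list(ap), machine)
  protonDMLC:::refresh_fluence(st)
}

test_that("a single spot peaks on-axis near the layer range", {
  st <- water_state("none")
  dg <- compute_dose(list(st))
  lay <- st$layers[[1]]
  # profile along the beam axis (x = z = 0 -> central voxel column)
  grid <- st$geom$grid
  d <- grid$dims
  ix <- ceiling(d[1] / 2); iz <- ceiling(d[3] / 2)
  prof <- dg$values[ix, , iz]
  y <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing[2]
  depth <- 40 - y  # beam enters from +y at the box face y = 40
  zpk <- depth[which.max(prof)]
  expect_lt(abs(zpk - lay$range_mm), 3)
  # off-axis dose is lower than on-axis at the peak depth
  iy <- which.max(prof)
  expect_gt(dg$values[ix, iy, iz], dg$values[ix - 8, iy, iz])
})

test_that("dose is exactly linear in spot weights", {
  st1 <- water_state("cover", weight = 1)
  st2 <- water_state("cover", weight = 2)
  d1 <- compute_dose(list(st1))$values
  d2 <- compute_dose(list(st2))$values
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("integral dose never increases when the aperture shrinks", {
  d_open <- compute_dose(list(water_state("none")))$values
  d_cov <- compute_dose(list(water_state("cover")))$values
  d_half <- compute_dose(list(water_state("half")))$values
  expect_lte(sum(d_cov), sum(d_open))
  expect_lte(sum(d_half), sum(d_cov) + 1e-12)
  # voxel-wise: clipping only removes fluence
  expect_true(all(d_cov <= d_open + 1e-12))
})

test_that("a wide-open aperture is a no-op for the engine", {
  st_none <- water_state("none")
  a <- matrix(rep(c(-75, 75), each = mlc$n_pairs), mlc$n_pairs, 2)
  st_full <- water_state("none")
  st_full$apertures <- list(a)
  st_full <- protonDMLC:::refresh_fluence(st_full)
  d0 <- compute_dose(list(st_none))$values
  d1 <- compute_dose(list(st_full))$values
  expect_lt(max(abs(d1 - d0)) / max(d0), 0.001)
})

test_that("collimation sharpens the lateral penumbra", {
  st_open <- water_state("none")
  st_half <- water_state("half")
  lay <- st_open$layers[[1]]
  u <- seq(-20, 20, by = 0.5)
  mid <- -(lay$range_mm / 2 - 40)   # s of the mid-depth plane
  p_open <- dose_plane(st_open, u, 0, s_mm = mid)
  p_half <- dose_plane(st_half, u, 0, s_mm = mid)
  w_open <- penumbra_8020(u, p_open$values[, 1])
  w_half <- penumbra_8020(u, p_half$values[, 1])
  expect_lt(w_half, w_open)
})

test_that("scenario machinery: nominal identity, range scaling, translation", {
  st <- water_state("cover")
  d0 <- compute_dose(list(st))$values
  # nominal scenario reproduces compute_dose exactly
  dn <- scenario_dose(list(st), scenario(c(0, 0, 0), 0))$values
  expect_identical(dn, d0)
  # +3.5% range error on water scales every voxel's WEL depth by 1.035:
  # the Bragg peak moves distally by 3.5% of the range... check on axis
  dr <- scenario_dose(list(st), scenario(c(0, 0, 0), -0.035))$values
  grid <- st$geom$grid; d <- grid$dims
  ix <- ceiling(d[1] / 2); iz <- ceiling(d[3] / 2)
  y <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing[2]
  depth0 <- (40 - y)[which.max(d0[ix, , iz])]
  depth1 <- (40 - y)[which.max(dr[ix, , iz])]
  expect_lt(abs(depth1 - depth0 / (1 - 0.035)), 3)  # 2 mm voxel quantization
  # a 2 mm lateral shift translates the dose by 2 mm (translation oracle)
  ds <- scenario_dose(list(st), scenario(c(2, 0, 0), 0))$values
  prof0 <- d0[, which.max(d0[ix, , iz]), iz]
  profs <- ds[, which.max(d0[ix, , iz]), iz]
  x <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1]
  # compare shifted profile against interpolated original
  ref <- stats::approx(x + 2, prof0, xout = x)$y
  ok <- !is.na(ref) & ref > 0.05 * max(prof0)
  expect_lt(max(abs(profs[ok] - ref[ok])) / max(prof0), 0.02)
})

test_that("engine matches the brute-force sub-spot oracle (gamma 2%/2mm)", {
  st <- water_state("half")
  u <- seq(-24, 24, by = 2); v <- seq(-16, 16, by = 2)
  p_eng <- dose_plane(st, u, v, s_mm = 0)
  p_ref <- dose_plane_reference(st, u, v, s_mm = 0, sub_step_mm = 1.0)
  g <- gamma_2d(p_ref, p_eng)
  expect_gte(g$pass_rate, 95)
})
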