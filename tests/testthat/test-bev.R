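# Water-equivalent ray tracing and BEV projection.

test_that("WEPL equals physical depth in uniform water and is linear in RSP", {
  grid <- water_grid()
  beam <- beam_config(0, 0)  # beam travels along -y
  tr <- wepl_along_ray(grid, beam, c(0.5, 0.5))
  expect_true(all(diff(tr$wepl) >= 0))
  # at the isocenter plane (s = 0) the ray has crossed 30 mm of water
  expect_lt(abs(stats::approx(tr$s, tr$wepl, 0)$y - 30), 1.01)
  # scaling all RSP scales every WEPL value
  grid2 <- grid
  grid2$values <- grid2$values * 1.035
  tr2 <- wepl_along_ray(grid2, beam, c(0.5, 0.5))
  expect_equal(tr2$wepl, tr$wepl * 1.035, tolerance = 1e-10)
})

test_that("a high-density slab adds exactly its excess WEL", {
  grid <- water_grid()
  # 6 mm slab of RSP 2.0 spanning y in [10, 16]
  ctr <- voxel_centers(grid)
  slab <- ctr[, 2] > 10 & ctr[, 2] < 16
  grid$values[array(slab, dim = grid$dims)] <- 2.0
  beam <- beam_config(0, 0)
  tr <- wepl_along_ray(grid, beam, c(0.5, 0.5))
  w_iso <- stats::approx(tr$s, tr$wepl, 0)$y
  # two-medium hand oracle: 30 mm of water plus 6 mm excess from the slab
  expect_lt(abs(w_iso - 36), 1.01)
})

test_that("cached WEPL table agrees with the dense single-ray integrator", {
  ph <- make_phantom(phantom_spec(), seed = 1)
  beam <- beam_config(70, 30)
  geom <- beam_geometry(ph$grid, beam, bev_grid())
  for (uv in list(c(0.5, 0.5), c(-10.5, 4.5), c(7.5, -8.5))) {
    ray <- wepl_along_ray(ph$grid, beam, uv, step_mm = 0.1)
    for (s in c(-20, 0, 15)) {
      w_tab <- wepl_at(geom, uv[1], uv[2], s)
      w_ray <- stats::approx(ray$s, ray$wepl, s)$y
      expect_lt(abs(w_tab - w_ray), 0.5)
    }
  }
})

test_that("structure depth intervals match analytic chords", {
  grid <- water_grid(half_xy = 30, half_z = 24)
  sph <- rt_structure("S", "target", sphere_mask(grid, c(0, 0, 0), 12))
  beam <- beam_config(0, 0)
  # central ray: one interval of length 2 r
  iv <- structure_depth_intervals(sph, grid, beam, c(0.5, 0.5))
  expect_equal(nrow(iv), 1)
  expect_lt(abs((iv$wel_out - iv$wel_in) - 24), 2.1)
  # ray missing the structure
  miss <- structure_depth_intervals(sph, grid, beam, c(25.5, 0.5))
  expect_equal(nrow(miss), 0)
})

test_that("a ray through both arms of a C-shape yields two disjoint intervals", {
  # C opening rotated to face +x, beam along -y: a ray near the axis crosses
  # the front and rear arcs of the C on either side of the OAR
  ph <- make_phantom(phantom_spec(opening_dir_deg = 0), seed = 1)
  tgt <- ph$structures[[1]]
  iv <- structure_depth_intervals(tgt, ph$grid, beam_config(0, 0),
                                  c(0.5, 0.5))
  expect_equal(nrow(iv), 2)
  expect_true(all(diff(as.numeric(t(as.matrix(iv)))) > 0))  # sorted, disjoint
})

test_that("layer cross-sections recover analytic areas and silhouettes", {
  grid <- water_grid(half_xy = 30, half_z = 24)
  sph <- rt_structure("S", "target", sphere_mask(grid, c(0, 0, 0), 12))
  beam <- beam_config(0, 0)
  geom <- beam_geometry(grid, beam, bev_grid())
  machine <- default_machine()
  # the sphere center sits 30 mm deep: a layer with R = 30 cuts the equator
  xs <- layer_cross_section(sph, geom, 30)
  expect_lt(abs(sum(xs) - pi * 12^2) / (pi * 12^2), 0.06)
  # a layer distal to the whole structure has an empty cross-section
  expect_false(any(layer_cross_section(sph, geom, 55)))
  # union over a tiling set of layers contains the silhouette
  layers <- select_layers(c(18, 42), machine)
  un <- Reduce(`|`, lapply(layers, function(l)
    layer_cross_section(sph, geom, l, depth_band_mm =
                          machine$layer_spacing / 2)))
  sil <- structure_silhouette(sph, geom)
  expect_true(all(un[sil]))
})

test_that("BEV projection at gantry 0 equals the axis-aligned silhouette", {
  grid <- water_grid(half_xy = 30, half_z = 24)
  # asymmetric structure: off-center sphere
  sph <- rt_structure("S", "target", sphere_mask(grid, c(8, 2, -6), 9))
  geom <- beam_geometry(grid, beam_config(0, 0), bev_grid())
  sil <- structure_silhouette(sph, geom)
  bev <- geom$bev
  # oracle: direct projection of the voxel mask along y onto (x, z)
  proj <- apply(sph$mask, c(1, 3), any)
  d <- grid$dims
  xs <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1]
  zs <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing[3]
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) {
    iu <- which.min(abs(bev$u - xs[i]))
    iv <- which.min(abs(bev$v - zs[k]))
    if (proj[i, k]) expect_true(sil[iu, iv])
  }
})

test_that("collimator rotation by 90 degrees rotates BEV masks", {
  grid <- water_grid(half_xy = 30, half_z = 24)
  sph <- rt_structure("S", "target", sphere_mask(grid, c(6, 0, -8), 7))
  g0 <- beam_geometry(grid, beam_config(0, 0), small_bev(24))
  g90 <- beam_geometry(grid, beam_config(0, 90), small_bev(24))
  s0 <- structure_silhouette(sph, g0)
  s90 <- structure_silhouette(sph, g90)
  # rotating the collimator by +90 about the beam axis maps (u,v)->(v,-u)
  pred <- t(s0)[, rev(seq_len(nrow(s0)))]
  mismatch <- mean(pred != s90)
  expect_lt(mismatch, 0.01)
})

test_that("dilate_mask performs Euclidean disk dilation", {
  bev <- small_bev(20)
  m <- matrix(FALSE, bev$nu, bev$nv)
  expect_identical(dilate_mask(m, 5), m)  # empty stays empty
  m[20, 20] <- TRUE
  expect_identical(dilate_mask(m, 0), m)  # zero margin is the identity
  d5 <- dilate_mask(m, 5, bev$pixel_mm)
  expect_lt(abs(sum(d5) - pi * 25) / (pi * 25), 0.12)  # disk area
  # monotone under mask inclusion
  m2 <- m; m2[25, 25] <- TRUE
  d5b <- dilate_mask(m2, 5, bev$pixel_mm)
  expect_true(all(d5b[d5]))
  expect_error(dilate_mask(m, -1), ">= 0")
})

test_that("OAR block shadow thresholds on the proximal entry depth", {
  grid <- water_grid(half_xy = 30, half_z = 24)
  oar <- rt_structure("O", "oar", cylinder_mask(grid, c(0, 0), 5, 10))
  geom <- beam_geometry(grid, beam_config(0, 0), bev_grid())
  # OAR occupies y in [-5, 5] -> proximal entry at ~25 mm WEL
  expect_false(any(oar_block_shadow(oar, geom, 15)))  # layer shallower
  deep <- oar_block_shadow(oar, geom, 50)             # beyond the OAR
  sil <- structure_silhouette(oar, geom)
  expect_identical(deep, sil)                         # full silhouette
  # monotone non-decreasing in range
  sh1 <- oar_block_shadow(oar, geom, 27)
  sh2 <- oar_block_shadow(oar, geom, 33)
  expect_true(all(sh2[sh1]))
  expect_error(oar_block_shadow(rt_structure("T", "target", oar$mask),
                                geom, 30), "role")
})
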