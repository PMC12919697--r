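# Leaf fitting for cover and block modes, aperture exports and the
# multi-beam block feasibility check.

mlc <- mlc_model()
bev <- bev_grid()  # full-field BEV, 1 mm pixels

test_that("cover fit opens at field limits for a full-field mask and closes empty rows", {
  full <- matrix(TRUE, bev$nu, bev$nv)
  ap <- suppressWarnings(fit_leaves_cover(full, bev, mlc))
  open <- !is.na(ap[, 1])
  expect_true(all(ap[open, 1] == -75) && all(ap[open, 2] == 75))
  empty <- matrix(FALSE, bev$nu, bev$nv)
  ap0 <- fit_leaves_cover(empty, bev, mlc)
  expect_true(all(is.na(ap0)))
})

test_that("cover fit reproduces per-row disk chords against a rasterization oracle", {
  r <- 30
  mask <- disk_mask(bev, r)
  ap <- fit_leaves_cover(mask, bev, mlc)
  for (k in seq_len(mlc$n_pairs)) {
    band <- c(mlc$v0 + (k - 1) * mlc$leaf_width_mm,
              mlc$v0 + k * mlc$leaf_width_mm)
    cols <- which(bev$v >= band[1] & bev$v < band[2])
    # brute-force oracle: scan the mask pixels of this 3.75 mm band
    row_true <- rowSums(mask[, cols, drop = FALSE]) > 0
    if (!any(row_true)) {
      expect_true(is.na(ap[k, 1]))
    } else {
      expect_false(is.na(ap[k, 1]))
      expect_lte(abs(ap[k, 1] - (min(bev$u[row_true]) - 0.5)), 0.1)
      expect_lte(abs(ap[k, 2] - (max(bev$u[row_true]) + 0.5)), 0.1)
    }
  }
  # every true pixel lies inside the aperture (exact containment)
  idx <- which(mask, arr.ind = TRUE)
  expect_true(all(point_in_aperture(ap, mlc, bev$u[idx[, 1]],
                                           bev$v[idx[, 2]])))
})

test_that("block fit removes the shadow and keeps the largest run", {
  cover <- disk_mask(bev, 25)
  empty_shadow <- matrix(FALSE, bev$nu, bev$nv)
  expect_identical(fit_leaves_block(cover, empty_shadow, bev, mlc),
                   fit_leaves_cover(cover, bev, mlc))
  # shadow covering everything closes all pairs
  expect_true(all(is.na(fit_leaves_block(cover, cover |
                                           TRUE, bev, mlc))))
  # shadow bisecting rows into a 20 px and an 8 px run keeps the 20 px run
  cover2 <- matrix(FALSE, bev$nu, bev$nv)
  rows20 <- which(bev$u >= -14.5 & bev$u <= 4.5)   # 20 px
  rows8 <- which(bev$u >= 9.5 & bev$u <= 16.5)     # 8 px
  gap <- which(bev$u > 4.5 & bev$u < 9.5)
  cols <- which(abs(bev$v) < 2)
  cover2[c(rows20, gap, rows8), cols] <- TRUE
  shadow2 <- matrix(FALSE, bev$nu, bev$nv)
  shadow2[gap, cols] <- TRUE
  apb <- fit_leaves_block(cover2, shadow2, bev, mlc)
  k <- which(!is.na(apb[, 1]))
  expect_true(length(k) >= 1)
  for (kk in k) {
    expect_equal(unname(apb[kk, 1]), -15, tolerance = 1e-9)
    expect_equal(unname(apb[kk, 2]), 5, tolerance = 1e-9)
  }
})

test_that("block apertures expose no shadow pixels and stay within cover", {
  ph <- make_phantom(phantom_spec(), seed = 1)
  geom <- beam_geometry(ph$grid, beam_config(0, 0), bev)
  machine <- default_machine()
  tw <- geom$vox_wepl[which(ph$structures[[1]]$mask)]
  layers <- select_layers(range(tw), machine)
  for (l in c(1, ceiling(length(layers) / 2), length(layers))) {
    lay <- layers[[l]]
    xs <- layer_cross_section(ph$structures[[1]], geom, lay)
    if (!any(xs)) next
    xd <- dilate_mask(xs, 0.5 * lay$sigma_peak, bev$pixel_mm)
    sh <- oar_block_shadow(ph$structures[[2]], geom, lay)
    apc <- fit_leaves_cover(xd, bev, mlc)
    apb <- fit_leaves_block(xd, sh, bev, mlc)
    # cover containment of every dilated-mask pixel (exact assertion)
    idx <- which(xd, arr.ind = TRUE)
    expect_true(all(point_in_aperture(apc, mlc, bev$u[idx[, 1]],
                                             bev$v[idx[, 2]])))
    # no shadow pixel inside the block aperture (exact assertion)
    sidx <- which(sh, arr.ind = TRUE)
    if (nrow(sidx))
      expect_false(any(point_in_aperture(apb, mlc, bev$u[sidx[, 1]],
                                                bev$v[sidx[, 2]])))
    # block aperture contained in the cover aperture, pair by pair
    for (k in seq_len(mlc$n_pairs)) {
      if (is.na(apb[k, 1])) next
      expect_false(is.na(apc[k, 1]))
      expect_gte(apb[k, 1], apc[k, 1] - 1e-9)
      expect_lte(apb[k, 2], apc[k, 2] + 1e-9)
    }
  }
})

test_that("aperture areas are monotone under mask inclusion", {
  small <- disk_mask(bev, 15)
  large <- disk_mask(bev, 25)
  aps <- fit_leaves_cover(small, bev, mlc)
  apl <- fit_leaves_cover(large, bev, mlc)
  area <- function(ap, m) sum((ap[, 2] - ap[, 1]) * m$leaf_width_mm,
                              na.rm = TRUE)
  expect_lt(area(aps, mlc), area(apl, mlc))
  for (k in seq_len(mlc$n_pairs)) {
    if (is.na(aps[k, 1])) next
    expect_gte(aps[k, 1], apl[k, 1] - 1e-9)
    expect_lte(aps[k, 2], apl[k, 2] + 1e-9)
  }
})

test_that("aperture tables round-trip bit-exactly through the text format", {
  ap1 <- fit_leaves_cover(disk_mask(bev, 22), bev, mlc)
  ap2 <- fit_leaves_block(disk_mask(bev, 22),
                          outer(bev$u, bev$v, function(u, v) abs(u) < 4),
                          bev, mlc)
  path <- withr::local_tempfile(fileext = ".txt")
  write_apertures(list(ap1, ap2), c(120.5, 118.25), path)
  back <- read_apertures(path)
  expect_identical(back$apertures[[1]], ap1)
  expect_identical(back$apertures[[2]], ap2)
  expect_equal(back$energies, c(120.5, 118.25))
})

test_that("block feasibility distinguishes compensable and shielded targets", {
  ph <- make_phantom(phantom_spec(), seed = 1)
  machine <- default_machine()
  target <- ph$structures[[1]]
  build <- function(gantries) {
    beams <- lapply(gantries, function(g) beam_config(g, 0))
    geoms <- lapply(beams, function(b) beam_geometry(ph$grid, b, bev))
    aps <- list(); lays <- list()
    for (i in seq_along(beams)) {
      g <- geoms[[i]]
      tw <- g$vox_wepl[which(target$mask)]
      layers <- select_layers(range(tw), machine)
      entry <- protonDMLC:::structure_entry_wel(ph$structures[[2]], g)
      a <- lapply(layers, function(lay) {
        xs <- layer_cross_section(target, g, lay,
                                  machine$layer_spacing / 2)
        xd <- dilate_mask(xs, 0.5 * lay$sigma_peak, bev$pixel_mm)
        sh <- oar_block_shadow(ph$structures[[2]], g, lay, entry)
        fit_leaves_block(xd, sh, bev, mlc)
      })
      aps[[i]] <- a; lays[[i]] <- layers
    }
    list(geoms = geoms, aps = aps, lays = lays)
  }
  # one beam alone cannot compensate its own shadow
  one <- build(0)
  f1 <- check_block_feasibility(one$geoms, one$aps, one$lays, target, mlc,
                                machine$layer_spacing)
  expect_false(f1$feasible)
  expect_gt(f1$n_blocked, 0)
  expect_equal(nrow(f1$blocked_xyz), f1$n_blocked)
  # three well-separated beams compensate each other's shadows
  three <- build(c(0, 120, 240))
  f3 <- check_block_feasibility(three$geoms, three$aps, three$lays, target,
                                mlc, machine$layer_spacing)
  expect_true(f3$feasible)
  expect_equal(f3$n_blocked, 0)
  # with no OAR there is no shadow: cover apertures are trivially feasible
  g1 <- one$geoms[[1]]
  tw <- g1$vox_wepl[which(target$mask)]
  layers <- select_layers(range(tw), machine)
  cov <- lapply(layers, function(lay) {
    xs <- layer_cross_section(target, g1, lay, machine$layer_spacing / 2)
    fit_leaves_cover(dilate_mask(xs, 0.5 * lay$sigma_peak, bev$pixel_mm),
                     bev, mlc)
  })
  fc <- check_block_feasibility(list(g1), list(cov), list(layers), target,
                                mlc, machine$layer_spacing)
  expect_true(fc$feasible)
})
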