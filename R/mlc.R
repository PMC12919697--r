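# dMLC leaf sequencing: fit 54-pair apertures per energy layer for the
# target-enclosing "cover" mode and the OAR-shielding "block" mode, plus the
# multi-beam feasibility check for block mode.

#' MLC geometry model
#'
#' 54 opposing leaf pairs of 3.75 mm width stacked along the BEV v axis and
#' travelling along u. The maximum field is 150 mm (parallel to leaf
#' travel) x 200 mm (perpendicular). Each leaf can retract up to 75 mm from
#' the closed central position, so a pair's opening spans at most the
#' 150 mm field. The leaf bank is centered on the beam axis; the stack
#' (202.5 mm) slightly exceeds the 200 mm field, so the outermost pairs are
#' partially outside the field, which is enforced as the binding limit.
#'
#' @param n_pairs number of leaf pairs.
#' @param leaf_width_mm leaf width along v.
#' @param max_travel_mm maximum retraction of one leaf from the center.
#' @param field_u_mm,field_v_mm rectangular field limits.
#' @param step_mm leaf position quantization step.
#' @return An object of class `mlc_model`.
#' @export
mlc_model <- function(n_pairs = 54L, leaf_width_mm = 3.75,
                      max_travel_mm = 75, field_u_mm = 150,
                      field_v_mm = 200, step_mm = 0.1) {
  if (n_pairs * leaf_width_mm < field_v_mm)
    stop("leaf stack must cover the field perpendicular to travel")
  m <- list(n_pairs = as.integer(n_pairs), leaf_width_mm = leaf_width_mm,
            max_travel_mm = max_travel_mm, field_u_mm = field_u_mm,
            field_v_mm = field_v_mm, step_mm = step_mm,
            v0 = -n_pairs * leaf_width_mm / 2,
            u_lim = min(max_travel_mm, field_u_mm / 2))
  structure(m, class = "mlc_model")
}

# v interval [lo, hi) of leaf pair k
pair_band <- function(mlc, k) {
  lo <- mlc$v0 + (k - 1) * mlc$leaf_width_mm
  c(lo, lo + mlc$leaf_width_mm)
}

# pair index of v coordinates (NA outside the bank)
pair_of_v <- function(mlc, v) {
  k <- floor((v - mlc$v0) / mlc$leaf_width_mm) + 1
  k[k < 1 | k > mlc$n_pairs] <- NA_integer_
  as.integer(k)
}

empty_aperture <- function(mlc) {
  matrix(NA_real_, mlc$n_pairs, 2,
         dimnames = list(NULL, c("u_left", "u_right")))
}

#' Fit cover-mode leaf openings for one energy layer
#'
#' For each leaf pair the opening is the [min u, max u] span of TRUE pixels
#' of the (already margin-dilated) layer mask falling in that pair's v band,
#' widened to the pixel edges, quantized outward to the leaf step (so the
#' mask is never clipped) and clipped to the travel/field limits. Pairs with
#' no mask pixels stay closed.
#'
#' @param mask_dilated logical BEV mask, already dilated by the MLC margin.
#' @param bev a [bev_grid()] describing the mask raster.
#' @param mlc an [mlc_model()].
#' @return `n_pairs` x 2 matrix of openings (mm); NA rows are closed pairs.
#' @export
fit_leaves_cover <- function(mask_dilated, bev, mlc = mlc_model()) {
  ap <- empty_aperture(mlc)
  if (!any(mask_dilated)) return(ap)
  half <- bev$pixel_mm / 2
  kv <- pair_of_v(mlc, bev$v)
  clipped <- FALSE
  for (k in unique(kv[!is.na(kv)])) {
    cols <- which(kv == k)
    rowmask <- mask_dilated[, cols, drop = FALSE]
    if (!any(rowmask)) next
    uu <- bev$u[which(rowSums(rowmask) > 0)]
    ul <- floor((min(uu) - half) / mlc$step_mm) * mlc$step_mm
    ur <- ceiling((max(uu) + half) / mlc$step_mm) * mlc$step_mm
    if (ul < -mlc$u_lim || ur > mlc$u_lim) clipped <- TRUE
    ap[k, ] <- c(max(ul, -mlc$u_lim), min(ur, mlc$u_lim))
  }
  if (clipped) warning("mask exceeds field/travel limits; opening clipped")
  ap
}

#' Fit block-mode leaf openings for one energy layer
#'
#' Per leaf pair the admissible region is (cover mask minus OAR shadow). A
#' physical pair admits a single interval, so when the admissible pixels of
#' a row split into several runs the run with the largest pixel count is
#' kept (ties go to the run whose center is nearest the row's cover
#' centroid). Openings are quantized inward so no shadow pixel is exposed.
#'
#' @param cover_mask logical BEV mask (dilated target cross-section).
#' @param shadow_mask logical BEV mask of blocked pixels (congruent).
#' @param bev a [bev_grid()].
#' @param mlc an [mlc_model()].
#' @return `n_pairs` x 2 matrix of openings; NA rows are closed pairs.
#' @export
fit_leaves_block <- function(cover_mask, shadow_mask, bev,
                             mlc = mlc_model()) {
  stopifnot(all(dim(cover_mask) == dim(shadow_mask)))
  ap <- empty_aperture(mlc)
  half <- bev$pixel_mm / 2
  kv <- pair_of_v(mlc, bev$v)
  for (k in unique(kv[!is.na(kv)])) {
    cols <- which(kv == k)
    cov <- rowSums(cover_mask[, cols, drop = FALSE]) > 0
    shd <- rowSums(shadow_mask[, cols, drop = FALSE]) > 0
    if (!any(cov)) next
    open <- cov & !shd
    if (!any(open)) next
    # run-length scan of the open pixels along u
    d <- diff(c(FALSE, open, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1
    len <- ends - starts + 1
    best <- which(len == max(len))
    if (length(best) > 1) {
      centroid <- sum(bev$u * cov) / sum(cov)
      mid <- (bev$u[starts[best]] + bev$u[ends[best]]) / 2
      best <- best[which.min(abs(mid - centroid))]
    } else best <- best[1]
    ul <- ceiling((bev$u[starts[best]] - half) / mlc$step_mm) * mlc$step_mm
    ur <- floor((bev$u[ends[best]] + half) / mlc$step_mm) * mlc$step_mm
    ul <- max(ul, -mlc$u_lim); ur <- min(ur, mlc$u_lim)
    if (ur > ul) ap[k, ] <- c(ul, ur)
  }
  ap
}

# Open-region geometry helpers -------------------------------------------

#' Test whether BEV points lie inside an aperture's open region
#'
#' The open region is the union of per-pair rectangles
#' `[u_left, u_right] x leaf band`.
#'
#' @param aperture `n_pairs` x 2 opening matrix.
#' @param mlc an [mlc_model()].
#' @param u,v point coordinates (mm).
#' @return logical vector.
#' @export
point_in_aperture <- function(aperture, mlc, u, v) {
  k <- pair_of_v(mlc, v)
  ok <- !is.na(k)
  out <- logical(length(u))
  kk <- k[ok]
  ul <- aperture[kk, 1]; ur <- aperture[kk, 2]
  out[ok] <- !is.na(ul) & u[ok] >= ul & u[ok] <= ur
  out
}

# Exact open-area fraction of square cells (side `cell_mm`, centered on the
# points) within the aperture's open region; used for convergent quadrature
# over the aperture plane.
aperture_cell_fraction <- function(aperture, mlc, u, v, cell_mm) {
  frac <- numeric(length(u))
  h <- cell_mm / 2
  for (k in which(!is.na(aperture[, 1]))) {
    band <- pair_band(mlc, k)
    fu <- clamp((pmin(aperture[k, 2], u + h) -
                   pmax(aperture[k, 1], u - h)) / cell_mm, 0, 1)
    fv <- clamp((pmin(band[2], v + h) - pmax(band[1], v - h)) / cell_mm,
                0, 1)
    frac <- pmin(frac + fu * fv, 1)
  }
  frac
}

#' Penetration depth of points into the leaf-covered region
#'
#' Euclidean distance from each point to the nearest open point of the
#' aperture (0 inside the open region; Inf for a fully closed aperture).
#' Exact continuous geometry over the union of open rectangles; this is the
#' distance the spot-exclusion rule thresholds at 0.5 sigma.
#'
#' @inheritParams point_in_aperture
#' @return numeric vector of distances (mm).
#' @export
aperture_penetration <- function(aperture, mlc, u, v) {
  open_k <- which(!is.na(aperture[, 1]))
  n <- length(u)
  if (!length(open_k)) return(rep(Inf, n))
  d2 <- rep(Inf, n)
  for (k in open_k) {
    band <- pair_band(mlc, k)
    du <- pmax(aperture[k, 1] - u, u - aperture[k, 2], 0)
    dv <- pmax(band[1] - v, v - band[2], 0)
    d2 <- pmin(d2, du^2 + dv^2)
  }
  sqrt(d2)
}

# Transmission map of an aperture on the BEV grid: each pixel carries the
# exact area fraction of its footprint inside the open region (1 fully
# open, `transmission` fully covered), so sub-pixel leaf positions are
# represented without aliasing.
aperture_transmission <- function(aperture, bev, mlc = mlc_model(),
                                  transmission = 0) {
  px <- bev$pixel_mm
  open_frac <- matrix(0, bev$nu, bev$nv)
  cover1d <- function(x, lo, hi)
    clamp((pmin(hi, x + px / 2) - pmax(lo, x - px / 2)) / px, 0, 1)
  for (k in which(!is.na(aperture[, 1]))) {
    band <- pair_band(mlc, k)
    fu <- cover1d(bev$u, aperture[k, 1], aperture[k, 2])
    fv <- cover1d(bev$v, band[1], band[2])
    if (!any(fu > 0) || !any(fv > 0)) next
    open_frac <- pmin(open_frac + outer(fu, fv), 1)
  }
  transmission + (1 - transmission) * open_frac
}

#' Export / import aperture patterns as a plain-text table
#'
#' One row per (layer, pair): `layer energy_mev pair u_left u_right` with
#' closed pairs written as `CLOSED`. The round trip is bit exact because
#' leaf positions are quantized to the MLC step.
#'
#' @param apertures list of aperture matrices (one per layer).
#' @param energies energies (MeV) of the layers.
#' @param path output file.
#' @export
write_apertures <- function(apertures, energies, path) {
  lines <- c("# protonDMLC aperture table",
             "# layer energy_mev pair u_left_mm u_right_mm")
  for (l in seq_along(apertures)) {
    ap <- apertures[[l]]
    for (k in seq_len(nrow(ap))) {
      lines <- c(lines, if (is.na(ap[k, 1]))
        sprintf("%d %.4f %d CLOSED CLOSED", l, energies[l], k)
        else sprintf("%d %.4f %d %.1f %.1f", l, energies[l], k,
                     ap[k, 1], ap[k, 2]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_apertures
#' @return `read_apertures` returns list(apertures, energies).
#' @export
read_apertures <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("layer", "energy", "pair",
                                         "ul", "ur"),
                           colClasses = c("integer", "numeric", "integer",
                                          "character", "character"))
  layers <- sort(unique(tab$layer))
  energies <- numeric(length(layers))
  aps <- vector("list", length(layers))
  for (l in layers) {
    sub <- tab[tab$layer == l, ]
    energies[l] <- sub$energy[1]
    ap <- matrix(NA_real_, max(sub$pair), 2,
                 dimnames = list(NULL, c("u_left", "u_right")))
    opened <- sub$ul != "CLOSED"
    ap[sub$pair[opened], 1] <- as.numeric(sub$ul[opened])
    ap[sub$pair[opened], 2] <- as.numeric(sub$ur[opened])
    aps[[l]] <- ap
  }
  list(apertures = aps, energies = energies)
}

#' Check multi-beam feasibility of the block configuration
#'
#' A target voxel is shielded in one beam when its BEV position lies outside
#' every layer aperture whose residual range can reach the voxel's WEL depth
#' (range >= depth - half a layer spacing). The block configuration is
#' feasible iff no target voxel is shielded in every beam, i.e. blocked
#' regions do not overlap within the target volume.
#'
#' @param geoms list of [beam_geometry()] (one per beam).
#' @param apertures_by_beam list (per beam) of lists of aperture matrices.
#' @param layers_by_beam list (per beam) of lists of [energy_layer()].
#' @param target an `rt_structure` with role `"target"`.
#' @param mlc an [mlc_model()].
#' @param layer_spacing_mm half-spacing reach tolerance (mm).
#' @return list with `feasible`, `n_blocked`, `blocked_idx` (voxel indices)
#'   and `blocked_xyz` (coordinates of fully shielded voxels).
#' @export
check_block_feasibility <- function(geoms, apertures_by_beam, layers_by_beam,
                                    target, mlc = mlc_model(),
                                    layer_spacing_mm = 3.3) {
  idx <- which(target$mask)
  if (!length(idx)) stop("empty target")
  blocked_all <- rep(TRUE, length(idx))
  for (b in seq_along(geoms)) {
    g <- geoms[[b]]
    u <- g$vox_u[idx]; v <- g$vox_v[idx]; w <- g$vox_wepl[idx]
    aps <- apertures_by_beam[[b]]
    if (is.null(aps)) { blocked_all[] <- FALSE; break }  # uncollimated beam
    covered <- rep(FALSE, length(idx))
    for (l in seq_along(aps)) {
      R <- layers_by_beam[[b]][[l]]$range_mm
      reach <- R >= w - layer_spacing_mm / 2
      if (!any(reach)) next
      covered[reach] <- covered[reach] |
        point_in_aperture(aps[[l]], mlc, u[reach], v[reach])
    }
    blocked_all <- blocked_all & !covered
    if (!any(blocked_all)) break
  }
  bidx <- idx[blocked_all]
  ctr <- voxel_centers(geoms[[1]]$grid)
  list(feasible = !any(blocked_all), n_blocked = length(bidx),
       blocked_idx = bidx,
       blocked_xyz = ctr[bidx, , drop = FALSE])
}
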