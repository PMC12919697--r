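# Water-equivalent conversion and beam's-eye-view (BEV) geometry: parallel
# ray tracing of cumulative WEPL, per-layer structure cross-sections at the
# Bragg-peak depth, OAR distal shadows, and BEV mask morphology.
#
# Parallel-ray geometry: scanning beams have a large virtual SAD, so rays
# are parallel to the beam axis. The BEV frame is collimator-rotated with
# u = leaf-travel axis and v = leaf-stacking axis.

#' Beam configuration
#'
#' @param gantry_deg gantry angle in degrees, [0, 360). At gantry 0 the beam
#'   travels along -y (enters from the anterior, +y, side); the gantry
#'   rotates about +z.
#' @param collimator_deg collimator rotation in degrees, [0, 360).
#' @param isocenter mm 3-vector.
#' @param air_gap_mm minimum range-shifter-to-surface air gap (mm).
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(gantry_deg = 0, collimator_deg = 0,
                        isocenter = c(0, 0, 0), air_gap_mm = 30) {
  if (gantry_deg < 0 || gantry_deg >= 360 ||
      collimator_deg < 0 || collimator_deg >= 360)
    stop("angles must lie in [0, 360)")
  if (air_gap_mm < 0) stop("air gap must be >= 0")
  structure(list(gantry_deg = gantry_deg, collimator_deg = collimator_deg,
                 isocenter = as.numeric(isocenter), air_gap_mm = air_gap_mm),
            class = "beam_config")
}

#' Beam axes in the patient frame
#'
#' @param beam a [beam_config()].
#' @return list with unit vectors `d` (beam travel direction), `u` (leaf
#'   travel axis) and `v` (leaf stacking axis); (u, v, d) is right-handed.
#' @export
beam_axes <- function(beam) {
  g <- beam$gantry_deg * pi / 180
  c0 <- beam$collimator_deg * pi / 180
  d <- c(-sin(g), -cos(g), 0)
  u0 <- c(cos(g), -sin(g), 0)
  v0 <- c(0, 0, 1)
  list(d = d,
       u = cos(c0) * u0 + sin(c0) * v0,
       v = -sin(c0) * u0 + cos(c0) * v0)
}

#' BEV pixel grid
#'
#' @param pixel_mm pixel size (default 1 mm, finer than the dose grid so
#'   leaf-edge geometry is resolved).
#' @param u_extent,v_extent half-extents (mm) along the leaf-travel (u) and
#'   leaf-stacking (v) axes. Defaults are the physical field limits
#'   (150 x 200 mm).
#' @return An object of class `bev_grid` with pixel-center coordinate
#'   vectors `u`, `v`.
#' @export
bev_grid <- function(pixel_mm = 1, u_extent = 75, v_extent = 101.25) {
  if (pixel_mm <= 0) stop("pixel size must be positive")
  nu <- 2L * ceiling(u_extent / pixel_mm)
  nv <- 2L * ceiling(v_extent / pixel_mm)
  u <- (seq_len(nu) - (nu + 1) / 2) * pixel_mm
  v <- (seq_len(nv) - (nv + 1) / 2) * pixel_mm
  structure(list(pixel_mm = pixel_mm, u = u, v = v, nu = nu, nv = nv),
            class = "bev_grid")
}

# Sample grid RSP (nearest voxel) at an n x 3 matrix of points; outside -> 0.
sample_rsp <- function(grid, pts) {
  ijk <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$dims[3]
  out <- numeric(nrow(pts))
  out[ok] <- grid$values[ijk[ok, , drop = FALSE]]
  out
}

# Sample a logical mask (nearest voxel) at points; outside -> FALSE.
sample_mask <- function(mask, grid, pts) {
  ijk <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$dims[3]
  out <- logical(nrow(pts))
  out[ok] <- mask[ijk[ok, , drop = FALSE]]
  out
}

#' Precompute beam geometry (WEPL table and voxel beam coordinates)
#'
#' Traces cumulative water-equivalent path length along parallel rays on
#' the BEV raster through the RSP grid (midpoint sampling, step `ds_mm`),
#' and caches every voxel center's beam coordinates (u, v, s) and WEPL.
#' One `beam_geometry` is reusable across all planning techniques.
#'
#' @param grid a `voxel_grid`.
#' @param beam a [beam_config()].
#' @param bev a [bev_grid()].
#' @param ds_mm ray sampling step (mm).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(grid, beam, bev = bev_grid(), ds_mm = 0.5) {
  ax <- beam_axes(beam)
  # raster covering both the BEV field and the grid's projected footprint
  corners <- as.matrix(expand.grid(
    x = grid$origin[1] + c(0, grid$dims[1] * grid$spacing[1]),
    y = grid$origin[2] + c(0, grid$dims[2] * grid$spacing[2]),
    z = grid$origin[3] + c(0, grid$dims[3] * grid$spacing[3])))
  rel <- sweep(corners, 2, beam$isocenter)
  pu <- rel %*% ax$u; pv <- rel %*% ax$v; ps <- rel %*% ax$d
  px <- bev$pixel_mm
  # extend the BEV pixel raster outward (whole pixels, shared centers) until
  # it covers the grid's projected footprint
  ext <- function(b, pmin_, pmax_) {
    lo <- max(0, ceiling((b[1] - (pmin_ - 2)) / px))
    hi <- max(0, ceiling(((pmax_ + 2) - b[length(b)]) / px))
    seq(b[1] - lo * px, b[length(b)] + hi * px, by = px)
  }
  u <- ext(bev$u, min(pu), max(pu))
  v <- ext(bev$v, min(pv), max(pv))
  s <- seq(floor(min(ps) - 1), ceiling(max(ps) + 1), by = ds_mm)
  nu <- length(u); nv <- length(v); ns <- length(s)
  UV <- cbind(rep(u, times = nv), rep(v, each = nu))
  base <- matrix(beam$isocenter, nu * nv, 3, byrow = TRUE) +
    UV[, 1] %*% t(ax$u) + UV[, 2] %*% t(ax$v)
  W <- matrix(0, nu * nv, ns)
  acc <- numeric(nu * nv)
  for (k in seq_len(ns)) {
    pts <- base + matrix(ax$d * (s[k] + ds_mm / 2), nu * nv, 3, byrow = TRUE)
    acc <- acc + sample_rsp(grid, pts) * ds_mm
    W[, k] <- acc
  }
  g <- list(grid = grid, beam = beam, bev = bev, axes = ax,
            u = u, v = v, s = s, ds = ds_mm, W = W, nu = nu, nv = nv)
  # voxel beam coordinates and WEPL (trilinear in the (u, v, s) table)
  ctr <- voxel_centers(grid)
  rel <- sweep(ctr, 2, beam$isocenter)
  g$vox_u <- as.numeric(rel %*% ax$u)
  g$vox_v <- as.numeric(rel %*% ax$v)
  g$vox_s <- as.numeric(rel %*% ax$d)
  g$vox_wepl <- wepl_at(g, g$vox_u, g$vox_v, g$vox_s)
  structure(g, class = "beam_geometry")
}

# Trilinear interpolation of the WEPL table at beam coordinates. W[, k] is
# the WEPL at the END of step k, i.e. at s = s[k] + ds (cumulative through
# the step); interpolate accordingly.
wepl_at <- function(geom, uq, vq, sq) {
  nu <- geom$nu; nv <- geom$nv; ns <- length(geom$s)
  ti <- (uq - geom$u[1]) / geom$bev$pixel_mm
  tj <- (vq - geom$v[1]) / geom$bev$pixel_mm
  tk <- (sq - (geom$s[1] + geom$ds)) / geom$ds
  i <- clamp(floor(ti), 0, nu - 2); fi <- clamp(ti - i, 0, 1)
  j <- clamp(floor(tj), 0, nv - 2); fj <- clamp(tj - j, 0, 1)
  k <- clamp(floor(tk), 0, ns - 2); fk <- clamp(tk - k, 0, 1)
  idx <- function(ii, jj) ii + 1 + jj * nu
  val <- function(ii, jj, kk) geom$W[cbind(idx(ii, jj), kk + 1)]
  w <- (1 - fk) * ((1 - fi) * (1 - fj) * val(i, j, k) +
                   fi * (1 - fj) * val(i + 1, j, k) +
                   (1 - fi) * fj * val(i, j + 1, k) +
                   fi * fj * val(i + 1, j + 1, k)) +
    fk * ((1 - fi) * (1 - fj) * val(i, j, k + 1) +
          fi * (1 - fj) * val(i + 1, j, k + 1) +
          (1 - fi) * fj * val(i, j + 1, k + 1) +
          fi * fj * val(i + 1, j + 1, k + 1))
  # upstream of the first sample the accumulated WEPL is ~0
  w[sq <= geom$s[1]] <- 0
  w
}

#' Cumulative WEPL along a single ray
#'
#' Dense midpoint sampling (step contribution = RSP x step length) along the
#' parallel ray through BEV point (u, v).
#'
#' @param grid a `voxel_grid`.
#' @param beam a [beam_config()].
#' @param uv length-2 BEV coordinates (mm).
#' @param step_mm sampling step.
#' @return data.frame with columns `s` (depth along the beam axis, mm,
#'   relative to the isocenter plane) and `wepl` (cumulative mm WEL);
#'   `wepl` is non-decreasing. Empty if the ray misses the grid.
#' @export
wepl_along_ray <- function(grid, beam, uv, step_mm = 0.1) {
  ax <- beam_axes(beam)
  if (abs(sum(ax$d^2) - 1) > 1e-8) stop("degenerate beam direction")
  corners <- as.matrix(expand.grid(
    x = grid$origin[1] + c(0, grid$dims[1] * grid$spacing[1]),
    y = grid$origin[2] + c(0, grid$dims[2] * grid$spacing[2]),
    z = grid$origin[3] + c(0, grid$dims[3] * grid$spacing[3])))
  ps <- sweep(corners, 2, beam$isocenter) %*% ax$d
  s <- seq(min(ps), max(ps), by = step_mm)
  if (!length(s)) return(data.frame(s = numeric(), wepl = numeric()))
  pts <- matrix(beam$isocenter + uv[1] * ax$u + uv[2] * ax$v,
                length(s), 3, byrow = TRUE) +
    (s + step_mm / 2) %*% t(ax$d)
  rsp <- sample_rsp(grid, pts)
  data.frame(s = s + step_mm, wepl = cumsum(rsp * step_mm))
}

#' WEL depth intervals of a structure along a ray
#'
#' @inheritParams wepl_along_ray
#' @param structure an `rt_structure` congruent with the grid.
#' @return data.frame with columns `wel_in`, `wel_out`: disjoint, sorted
#'   intervals (mm WEL); zero rows when the ray misses the structure.
#' @export
structure_depth_intervals <- function(structure, grid, beam, uv,
                                      step_mm = 0.1) {
  ax <- beam_axes(beam)
  corners <- as.matrix(expand.grid(
    x = grid$origin[1] + c(0, grid$dims[1] * grid$spacing[1]),
    y = grid$origin[2] + c(0, grid$dims[2] * grid$spacing[2]),
    z = grid$origin[3] + c(0, grid$dims[3] * grid$spacing[3])))
  ps <- sweep(corners, 2, beam$isocenter) %*% ax$d
  s <- seq(min(ps), max(ps), by = step_mm)
  pts <- matrix(beam$isocenter + uv[1] * ax$u + uv[2] * ax$v,
                length(s), 3, byrow = TRUE) +
    (s + step_mm / 2) %*% t(ax$d)
  rsp <- sample_rsp(grid, pts)
  wepl <- cumsum(rsp * step_mm)
  inside <- sample_mask(structure$mask, grid, pts)
  dd <- diff(c(FALSE, inside, FALSE))
  starts <- which(dd == 1)
  ends <- which(dd == -1) - 1
  if (!length(starts)) return(data.frame(wel_in = numeric(), wel_out = numeric()))
  w_in <- ifelse(starts == 1, 0, wepl[starts - 1])
  w_out <- wepl[ends]
  data.frame(wel_in = w_in, wel_out = w_out)
}

# Depth s*(u, v) at which the cumulative WEPL first reaches `wel` along each
# raster ray; NA where never reached. Vectorized over the whole raster.
depth_of_wel <- function(geom, wel) {
  cnt <- rowSums(geom$W < wel)
  ns <- length(geom$s)
  sstar <- rep(NA_real_, length(cnt))
  hit <- cnt < ns
  k <- pmax(cnt[hit], 1L)
  w1 <- ifelse(cnt[hit] == 0, 0, geom$W[cbind(which(hit), k)])
  w2 <- geom$W[cbind(which(hit), pmin(cnt[hit] + 1L, ns))]
  s1 <- geom$s[1] + geom$ds * cnt[hit]  # end of step cnt (wepl = w1)
  frac <- ifelse(w2 > w1, (wel - w1) / (w2 - w1), 0.5)
  sstar[hit] <- s1 + frac * geom$ds
  sstar
}

# Restrict a raster-sized vector/matrix to the BEV field window.
raster_to_bev <- function(geom, m_raster) {
  iu <- match(round(geom$bev$u, 6), round(geom$u, 6))
  iv <- match(round(geom$bev$v, 6), round(geom$v, 6))
  M <- matrix(m_raster, geom$nu, geom$nv)
  M[iu, iv, drop = FALSE]
}

#' Structure cross-section at an energy layer's Bragg-peak depth
#'
#' A BEV pixel is TRUE iff the structure is present at the depth where the
#' cumulative WEPL along that pixel's ray equals the layer's residual range
#' (i.e. some WEL interval of the structure contains the layer range).
#'
#' @param structure an `rt_structure`.
#' @param geom a [beam_geometry()].
#' @param layer an [energy_layer()] (or a numeric range in mm WEL).
#' @param depth_band_mm half-width (mm WEL) of a depth tolerance band around
#'   the layer range: with the default 0 a pixel is TRUE iff the structure is
#'   present exactly at the Bragg-peak depth; with a positive band the
#'   structure may be present anywhere in [R - band, R + band], reflecting
#'   that one energy layer treats a slab of depths half a layer spacing each
#'   way.
#' @return logical matrix on the BEV grid (rows = u, cols = v).
#' @export
layer_cross_section <- function(structure, geom, layer, depth_band_mm = 0) {
  R <- if (inherits(layer, "energy_layer")) layer$range_mm else layer
  wels <- if (depth_band_mm > 0)
    unique(c(R, seq(R - depth_band_mm, R + depth_band_mm, length.out = 3)))
  else R
  UV <- cbind(rep(geom$u, times = geom$nv), rep(geom$v, each = geom$nu))
  ax <- geom$axes
  inside <- logical(nrow(UV))
  for (wel in wels) {
    sstar <- depth_of_wel(geom, wel)
    ok <- which(!is.na(sstar) & !inside)
    if (!length(ok)) next
    pts <- matrix(geom$beam$isocenter, length(ok), 3, byrow = TRUE) +
      UV[ok, 1] %*% t(ax$u) + UV[ok, 2] %*% t(ax$v) + sstar[ok] %*% t(ax$d)
    inside[ok] <- sample_mask(structure$mask, geom$grid, pts)
  }
  raster_to_bev(geom, inside)
}

# Proximal-entry WEL map of a structure: for each raster ray, the cumulative
# WEPL at the first sample inside the structure (Inf if the ray misses it).
structure_entry_wel <- function(structure, geom) {
  nuv <- geom$nu * geom$nv
  UV <- cbind(rep(geom$u, times = geom$nv), rep(geom$v, each = geom$nu))
  ax <- geom$axes
  base <- matrix(geom$beam$isocenter, nuv, 3, byrow = TRUE) +
    UV[, 1] %*% t(ax$u) + UV[, 2] %*% t(ax$v)
  entry <- rep(Inf, nuv)
  todo <- rep(TRUE, nuv)
  for (k in seq_along(geom$s)) {
    if (!any(todo)) break
    pts <- base[todo, , drop = FALSE] +
      matrix(ax$d * (geom$s[k] + geom$ds / 2), sum(todo), 3, byrow = TRUE)
    hit <- sample_mask(structure$mask, geom$grid, pts)
    if (any(hit)) {
      idx <- which(todo)[hit]
      w_prev <- if (k == 1) 0 else geom$W[idx, k - 1]
      entry[idx] <- w_prev
      todo[idx] <- FALSE
    }
  }
  entry
}

#' OAR blocking shadow for an energy layer
#'
#' BEV pixels whose ray enters the OAR at a WEL depth no deeper than the
#' layer's residual range, i.e. pixels where the Bragg peak would land in
#' the OAR or its distal region. Deeper layers have monotonically larger
#' shadows.
#'
#' @param oar an `rt_structure` with role `"oar"`.
#' @param geom a [beam_geometry()].
#' @param layer an [energy_layer()] (or numeric residual range, mm WEL).
#' @param entry_wel optional precomputed [structure_entry_wel()] raster.
#' @return logical matrix on the BEV grid.
#' @export
oar_block_shadow <- function(oar, geom, layer, entry_wel = NULL) {
  if (inherits(oar, "rt_structure") && oar$role != "oar")
    stop("structure role must be 'oar'")
  R <- if (inherits(layer, "energy_layer")) layer$range_mm else layer
  if (is.null(entry_wel)) entry_wel <- structure_entry_wel(oar, geom)
  raster_to_bev(geom, entry_wel <= R)
}

#' Euclidean dilation of a BEV mask
#'
#' Dilates by a disk of the given radius: an output pixel is TRUE iff some
#' TRUE input pixel center lies within `margin_mm` of its center.
#'
#' @param mask logical BEV matrix.
#' @param margin_mm dilation radius (mm), >= 0. 0 is the identity.
#' @param pixel_mm pixel size of the mask.
#' @return logical matrix of the same dimension.
#' @export
dilate_mask <- function(mask, margin_mm, pixel_mm = 1) {
  if (margin_mm < 0) stop("margin must be >= 0")
  r <- margin_mm / pixel_mm
  h <- floor(r)
  if (h < 1 && r < 1) {
    offs <- expand.grid(du = 0, dv = 0)
  } else {
    offs <- expand.grid(du = -h:h, dv = -h:h)
  }
  offs <- offs[offs$du^2 + offs$dv^2 <= r^2 + 1e-9, , drop = FALSE]
  nu <- nrow(mask); nv <- ncol(mask)
  out <- matrix(FALSE, nu, nv)
  for (q in seq_len(nrow(offs))) {
    du <- offs$du[q]; dv <- offs$dv[q]
    su <- seq_len(nu) - du; sv <- seq_len(nv) - dv
    oku <- su >= 1 & su <= nu; okv <- sv >= 1 & sv <= nv
    out[oku, okv] <- out[oku, okv] | mask[su[oku], sv[okv], drop = FALSE]
  }
  out
}

#' Axis-aligned silhouette of a structure in BEV
#'
#' Projects the structure mask along the beam axis onto the BEV grid
#' (a pixel is TRUE iff its ray intersects the structure anywhere).
#'
#' @param structure an `rt_structure`.
#' @param geom a [beam_geometry()].
#' @return logical matrix on the BEV grid.
#' @export
structure_silhouette <- function(structure, geom) {
  entry <- structure_entry_wel(structure, geom)
  raster_to_bev(geom, is.finite(entry))
}
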