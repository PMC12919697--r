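# Hexagonal per-layer spot lattices (0.75 sigma spacing, 1.0 sigma lateral
# margin) and the block-mode spot exclusion rule (spots overlapping the leaf
# projection by more than 0.5 sigma are removed).

#' Hexagonal spot lattice for one energy layer
#'
#' Spots sit on a hexagonal lattice with nearest-neighbor distance
#' `spacing_factor * sigma`, anchored at the centroid of the layer target
#' mask. A lattice point is kept iff its distance to the mask (0 inside) is
#' at most `margin_factor * sigma`, implementing the rule that spots are
#' placed up to one sigma beyond the lateral target boundary. Deterministic:
#' no randomness is involved.
#'
#' @param layer_mask logical BEV matrix of the (undilated) layer target
#'   cross-section.
#' @param sigma_mm spot sigma used for spacing and margin (in-medium sigma
#'   at the layer's Bragg depth by default upstream).
#' @param bev a [bev_grid()].
#' @param spacing_factor lattice nearest-neighbor distance in sigma units.
#' @param margin_factor lateral margin in sigma units.
#' @return data.frame with columns `u`, `v`, `weight` (initialized to 1).
#' @export
hex_grid_spots <- function(layer_mask, sigma_mm, bev,
                           spacing_factor = 0.75, margin_factor = 1.0) {
  stopifnot(sigma_mm > 0)
  empty <- data.frame(u = numeric(), v = numeric(), weight = numeric())
  if (!any(layer_mask)) return(empty)
  d <- spacing_factor * sigma_mm
  margin <- margin_factor * sigma_mm
  true_idx <- which(layer_mask, arr.ind = TRUE)
  mu <- bev$u[true_idx[, 1]]; mv <- bev$v[true_idx[, 2]]
  cu <- mean(mu); cv <- mean(mv)
  # lattice rows: v = cv + j * d * sqrt(3)/2, u offset d/2 on odd rows
  jmax <- ceiling((max(abs(mv - cv)) + margin) / (d * sqrt(3) / 2)) + 1
  imax <- ceiling((max(abs(mu - cu)) + margin) / d) + 1
  pts <- do.call(rbind, lapply(-jmax:jmax, function(j) {
    off <- if (j %% 2 == 0) 0 else d / 2
    cbind(u = cu + off + (-imax:imax) * d,
          v = cv + j * d * sqrt(3) / 2)
  }))
  # exact distance to the nearest TRUE pixel center
  keep <- vapply(seq_len(nrow(pts)), function(q) {
    min((pts[q, 1] - mu)^2 + (pts[q, 2] - mv)^2) <= margin^2 + 1e-9
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  # enforce field limits
  infield <- pts[, 1] >= min(bev$u) & pts[, 1] <= max(bev$u) &
    pts[, 2] >= min(bev$v) & pts[, 2] <= max(bev$v)
  pts <- pts[infield, , drop = FALSE]
  if (!nrow(pts)) return(empty)
  data.frame(u = pts[, 1], v = pts[, 2], weight = 1)
}

#' Exclude spots blocked by the MLC
#'
#' A spot is removed iff its center lies deeper than `0.5 * sigma` inside
#' the leaf-covered (closed) region, measured as the Euclidean distance from
#' the spot center to the nearest open point of the aperture. Spots whose
#' centers are open, or closed by exactly 0.5 sigma, are kept (the boundary
#' is inclusive). Enlarging the aperture never removes a kept spot.
#'
#' @param spots data.frame with columns `u`, `v` (mm).
#' @param aperture `n_pairs` x 2 opening matrix for the same layer.
#' @param sigma_mm spot sigma (mm).
#' @param mlc an [mlc_model()].
#' @return the filtered spots data.frame.
#' @export
exclude_blocked_spots <- function(spots, aperture, sigma_mm,
                                  mlc = mlc_model()) {
  if (!nrow(spots)) return(spots)
  pen <- aperture_penetration(aperture, mlc, spots$u, spots$v)
  spots[pen <= 0.5 * sigma_mm + 1e-9, , drop = FALSE]
}

#' Export / import spot lists as a plain-text table
#'
#' Interchange format between the sequencer, optimizer and dose engine:
#' one row per spot, columns `layer energy_mev u_mm v_mm weight`.
#'
#' @param spots data.frame with columns `layer`, `energy_mev`, `u`, `v`,
#'   `weight`.
#' @param path file path.
#' @export
write_spots <- function(spots, path) {
  lines <- c("# protonDMLC spot table",
             "# layer energy_mev u_mm v_mm weight",
             sprintf("%d %.4f %.6f %.6f %.10g", spots$layer,
                     spots$energy_mev, spots$u, spots$v, spots$weight))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  utils::read.table(path, comment.char = "#",
                    col.names = c("layer", "energy_mev", "u", "v", "weight"))
}
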