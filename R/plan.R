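# Plan orchestration: layer selection, sequencing per technique, spot
# placement, sparse per-scenario dose influence, robust optimization,
# normalization and the final dose.

# Per-spot sparse influence over the optimization voxel set, for every
# scenario. A spot's lateral footprint is its aperture-clipped in-air
# Gaussian patch convolved (full) with each sigma bin; the dose to a voxel
# is depth_dose(wepl') x the sigma-interpolated patch at the voxel's shifted
# beam coordinates (wepl' = wepl x (1 + range error)). Entries below
# `cutoff` x the spot's maximum are dropped (sparse storage).
build_influence <- function(states, opt_pts, scenarios,
                            sigma_bins = SIGMA_BINS, cutoff = 1e-4,
                            patch_sigma_factor = 3.5) {
  n_opt <- length(opt_pts$idx)
  n_sc <- length(scenarios)
  trip <- lapply(seq_len(n_sc), function(s) list(i = list(), j = list(),
                                                 x = list()))
  col0 <- 0L
  for (b in seq_along(states)) {
    st <- states[[b]]
    g <- st$geom
    bev <- st$bev
    px <- bev$pixel_mm
    u_all <- opt_pts$u[[b]]; v_all <- opt_pts$v[[b]]
    w_all <- opt_pts$wepl[[b]]
    # per (scenario, layer) caches of depth dose and sigma at the opt voxels
    dd_cache <- vector("list", n_sc)
    for (s in seq_len(n_sc)) {
      sc <- scenarios[[s]]
      wp <- w_all * (1 + sc$range_error)
      dd_cache[[s]] <- lapply(st$layers, function(lay) {
        dd <- depth_dose(lay, pmax(wp, 0))
        act <- which(dd > 1e-6)
        list(act = act, dd = dd[act],
             sig = sigma_mcs(wp[act], lay$range_mm, st$machine))
      })
    }
    shifts_uv <- t(vapply(scenarios, function(sc)
      c(sum(sc$shift_mm * g$axes$u), sum(sc$shift_mm * g$axes$v)),
      numeric(2)))
    max_shift <- if (nrow(shifts_uv)) max(abs(shifts_uv)) else 0
    for (l in seq_along(st$layers)) {
      lay <- st$layers[[l]]
      sp <- st$spots[[l]]
      if (!nrow(sp)) next
      sa <- lay$sigma_air_iso
      hw <- ceiling(patch_sigma_factor * sa / px)
      ap <- if (is.null(st$apertures)) NULL else st$apertures[[l]]
      Tm <- if (is.null(ap)) NULL else {
        tm <- aperture_transmission(ap, bev, st$machine$mlc)
        if (st$edge_sigma_mm > 0) conv_gauss_same(tm, st$edge_sigma_mm / px)
        else tm
      }
      for (j in seq_len(nrow(sp))) {
        # aperture-clipped in-air patch on the BEV pixel lattice
        iu0 <- round((sp$u[j] - bev$u[1]) / px) + 1
        iv0 <- round((sp$v[j] - bev$v[1]) / px) + 1
        iu <- max(1, iu0 - hw):min(bev$nu, iu0 + hw)
        iv <- max(1, iv0 - hw):min(bev$nv, iv0 + hw)
        if (!length(iu) || !length(iv)) next
        gu <- exp(-(bev$u[iu] - sp$u[j])^2 / (2 * sa^2))
        gv <- exp(-(bev$v[iv] - sp$v[j])^2 / (2 * sa^2))
        P0 <- outer(gu, gv) / (2 * pi * sa^2)
        if (!is.null(Tm)) P0 <- P0 * Tm[iu, iv, drop = FALSE]
        patches <- vector("list", length(sigma_bins))
        pads <- integer(length(sigma_bins))
        for (bq in seq_along(sigma_bins)) {
          cv <- conv_gauss_full(P0, sigma_bins[bq] / px)
          patches[[bq]] <- cv$M
          pads[bq] <- cv$pad
        }
        # candidate voxels: inside the widest patch under any scenario shift
        pad_max <- max(pads)
        uu0 <- bev$u[iu[1]]; vv0 <- bev$v[iv[1]]
        cand <- which(u_all >= uu0 - pad_max * px - max_shift &
                      u_all <= bev$u[iu[length(iu)]] + pad_max * px + max_shift &
                      v_all >= vv0 - pad_max * px - max_shift &
                      v_all <= bev$v[iv[length(iv)]] + pad_max * px + max_shift)
        if (!length(cand)) next
        col <- col0 + j_global(st, l, j)
        for (s in seq_len(n_sc)) {
          ca <- dd_cache[[s]][[l]]
          sub <- intersect(cand, ca$act)
          if (!length(sub)) next
          pos <- match(sub, ca$act)
          uq <- u_all[sub] - shifts_uv[s, 1]
          vq <- v_all[sub] - shifts_uv[s, 2]
          sig <- ca$sig[pos]
          sc_ <- clamp(sig, sigma_bins[1], sigma_bins[length(sigma_bins)])
          kb <- clamp(findInterval(sc_, sigma_bins, rightmost.closed = TRUE),
                      1L, length(sigma_bins) - 1L)
          fb <- (sc_ - sigma_bins[kb]) / (sigma_bins[kb + 1] - sigma_bins[kb])
          val <- numeric(length(sub))
          for (bq in unique(c(kb, kb + 1L))) {
            wq <- ifelse(kb == bq, 1 - fb, ifelse(kb + 1L == bq, fb, 0))
            pick <- which(wq > 0)
            if (!length(pick)) next
            val[pick] <- val[pick] + wq[pick] *
              bilinear_lookup(patches[[bq]],
                              uu0 - pads[bq] * px, px,
                              vv0 - pads[bq] * px, px,
                              uq[pick], vq[pick])
          }
          val <- val * ca$dd[pos]
          keep <- val > cutoff * max(val, 0)
          if (!any(keep)) next
          trip[[s]]$i[[length(trip[[s]]$i) + 1]] <- sub[keep]
          trip[[s]]$j[[length(trip[[s]]$j) + 1]] <-
            rep.int(col, sum(keep))
          trip[[s]]$x[[length(trip[[s]]$x) + 1]] <- val[keep]
        }
      }
    }
    col0 <- col0 + st$n_spots
  }
  lapply(trip, function(tr)
    Matrix::sparseMatrix(i = unlist(tr$i), j = unlist(tr$j),
                         x = unlist(tr$x), dims = c(n_opt, col0)))
}

# global spot column index within one beam state (layers stacked)
j_global <- function(state, layer, j) {
  before <- if (layer > 1)
    sum(vapply(state$spots[seq_len(layer - 1)], nrow, integer(1))) else 0L
  before + j
}

#' Build a robustly optimized plan
#'
#' End-to-end planning for one technique on a phantom: per-beam WEPL
#' geometry, energy-layer selection from the target WEL interval, leaf
#' sequencing (`cover` encloses the margin-dilated target cross-section per
#' layer; `block` additionally shields every OAR and its distal region;
#' `pbs` is uncollimated), hexagonal spot placement with block-mode spot
#' exclusion, worst-case robust spot-weight optimization over the scenario
#' set, and normalization of the CTV median to the prescription.
#'
#' @param phantom list with `grid` and `structures` (from [make_phantom()]
#'   or equivalent).
#' @param beams list of [beam_config()].
#' @param technique `"pbs"`, `"cover"` or `"block"`.
#' @param machine machine model.
#' @param objectives a [default_objectives()] list.
#' @param scenarios scenario list used for both optimization and reporting
#'   (all 21 by default).
#' @param bev a [bev_grid()].
#' @param mlc_margin_sigma MLC margin in units of the in-medium sigma at the
#'   layer's Bragg depth (default 0.5).
#' @param depth_band_mm depth tolerance band (mm WEL) used when taking the
#'   per-layer target cross-section; the default (half the machine's layer
#'   spacing) treats each layer as covering its full depth slab.
#' @param shadow_margin_mm extra margin on the OAR block shadow (default 0).
#' @param max_iter,tol optimizer settings.
#' @param robust_mode worst-case flavor (see [worst_case_objective()]);
#'   the default `"per_term"` is the objective-wise worst case.
#' @param geoms optional precomputed list of [beam_geometry()] (reused
#'   across techniques).
#' @param on_infeasible `"warn"` (default) or `"error"` when the block
#'   configuration fully shields part of the target in every beam.
#' @param seed integer; retained in the plan for provenance (the pipeline is
#'   deterministic, the seed only feeds optional stochastic components).
#' @return object of class `dmlc_plan`: beam states with optimized weights,
#'   the normalized nominal `dose`, the feasibility report (block mode), and
#'   all inputs needed to re-evaluate scenarios.
#' @export
make_plan <- function(phantom, beams, technique = c("pbs", "cover", "block"),
                      machine = default_machine(),
                      objectives = default_objectives(),
                      scenarios = generate_scenarios(),
                      bev = bev_grid(),
                      mlc_margin_sigma = 0.5, shadow_margin_mm = 0,
                      depth_band_mm = NULL,
                      max_iter = 600, tol = 1e-5,
                      robust_mode = c("per_term", "composite"),
                      geoms = NULL,
                      on_infeasible = c("warn", "error"), seed = 1L) {
  technique <- match.arg(technique)
  on_infeasible <- match.arg(on_infeasible)
  if (is.null(depth_band_mm)) depth_band_mm <- machine$layer_spacing / 2
  robust_mode <- match.arg(robust_mode)
  grid <- phantom$grid
  structures <- phantom$structures
  roles <- vapply(structures, function(s) s$role, character(1))
  targets <- structures[roles == "target"]
  oars <- structures[roles == "oar"]
  if (!length(targets)) stop("at least one target structure is required")
  tmask <- Reduce(`|`, lapply(targets, function(s) s$mask))
  if (is.null(geoms))
    geoms <- lapply(beams, function(b) beam_geometry(grid, b, bev))
  states <- vector("list", length(beams))
  apertures_by_beam <- vector("list", length(beams))
  layers_by_beam <- vector("list", length(beams))
  tidx <- which(tmask)
  for (b in seq_along(beams)) {
    g <- geoms[[b]]
    wt <- g$vox_wepl[tidx]
    layers <- select_layers(c(min(wt), max(wt)), machine,
                            air_gap_mm = beams[[b]]$air_gap_mm)
    # per-layer target cross-section, margins, shadows, apertures, spots
    oar_entry <- lapply(oars, function(o) structure_entry_wel(o, g))
    keep <- logical(length(layers))
    aps <- vector("list", length(layers))
    spots <- vector("list", length(layers))
    for (l in seq_along(layers)) {
      lay <- layers[[l]]
      xs <- Reduce(`|`, lapply(targets, function(s)
        layer_cross_section(s, g, lay, depth_band_mm)))
      if (!any(xs)) next
      keep[l] <- TRUE
      margin <- mlc_margin_sigma * lay$sigma_peak
      xs_dil <- dilate_mask(xs, margin, bev$pixel_mm)
      sp <- hex_grid_spots(xs, lay$sigma_peak, bev)
      if (technique == "pbs") {
        aps[l] <- list(NULL)
      } else if (technique == "cover") {
        aps[[l]] <- fit_leaves_cover(xs_dil, bev, machine$mlc)
      } else {
        shadow <- matrix(FALSE, bev$nu, bev$nv)
        for (q in seq_along(oars)) {
          sh <- oar_block_shadow(oars[[q]], g, lay, entry_wel = oar_entry[[q]])
          if (shadow_margin_mm > 0)
            sh <- dilate_mask(sh, shadow_margin_mm, bev$pixel_mm)
          shadow <- shadow | sh
        }
        aps[[l]] <- fit_leaves_block(xs_dil, shadow, bev, machine$mlc)
        sp <- exclude_blocked_spots(sp, aps[[l]], lay$sigma_peak,
                                    machine$mlc)
      }
      spots[[l]] <- sp
      keep[l] <- keep[l] && nrow(sp) > 0
    }
    layers <- layers[keep]
    aps <- aps[keep]
    spots <- spots[keep]
    if (!length(layers)) stop("beam ", b, " delivers no spots")
    layers_by_beam[[b]] <- layers
    apertures_by_beam[b] <- if (technique == "pbs") list(NULL) else list(aps)
    states[[b]] <- beam_state(geoms[[b]], layers, spots,
                              apertures_by_beam[[b]], machine)
  }
  feas <- NULL
  if (technique == "block" && length(oars)) {
    tstruct <- rt_structure("target_union", "target", tmask)
    feas <- check_block_feasibility(geoms, apertures_by_beam, layers_by_beam,
                                    tstruct, machine$mlc,
                                    machine$layer_spacing)
    if (!feas$feasible) {
      msg <- sprintf("block configuration shields %d target voxel(s) in every beam",
                     feas$n_blocked)
      if (on_infeasible == "error") stop(msg) else warning(msg)
    }
  }
  # optimization voxel set: union of target and OAR voxels
  opt_idx <- sort(unique(c(which(tmask),
                           unlist(lapply(oars, function(o) which(o$mask))))))
  opt_pts <- list(idx = opt_idx,
                  u = lapply(geoms, function(g) g$vox_u[opt_idx]),
                  v = lapply(geoms, function(g) g$vox_v[opt_idx]),
                  wepl = lapply(geoms, function(g) g$vox_wepl[opt_idx]))
  struct_idx <- list()
  for (s in structures) {
    if (s$role == "external") next
    struct_idx[[s$name]] <- match(which(s$mask), opt_idx)
    struct_idx[[s$name]] <- struct_idx[[s$name]][!is.na(struct_idx[[s$name]])]
  }
  roles_map <- as.list(stats::setNames(roles, vapply(structures, function(s)
    s$name, character(1))))
  terms <- build_objective_terms(objectives, struct_idx, roles_map)
  A_list <- build_influence(states, opt_pts, scenarios)
  # scale-aware uniform initialization: mean CTV dose at the prescription
  n_spots <- sum(vapply(states, function(st) st$n_spots, integer(1)))
  d1 <- as.numeric(A_list[[1]] %*% rep(1, n_spots))
  ct_rows <- struct_idx[[targets[[1]]$name]]
  m0 <- stats::median(d1[ct_rows])
  if (!is.finite(m0) || m0 <= 0) stop("no influence on the target")
  w0 <- rep(objectives$prescription_gy / m0, n_spots)
  opt <- optimize_weights(w0, A_list, terms, max_iter = max_iter,
                          tol = tol, mode = robust_mode)
  w <- opt$weights
  # distribute weights back to the beam states and compute the nominal dose
  states <- assign_weights(states, w)
  states <- lapply(states, refresh_fluence)
  dose <- compute_dose(states)
  ctv <- targets[[1]]
  sf <- normalize_to_median(dose, ctv, objectives$prescription_gy)
  w <- w * sf
  states <- assign_weights(states, w)
  states <- lapply(states, refresh_fluence)
  dose$values <- dose$values * sf
  structure(list(technique = technique, beams = beams, states = states,
                 weights = w, dose = dose, phantom = phantom,
                 machine = machine, objectives = objectives,
                 scenarios = scenarios, optimizer = opt[c("objective",
                                                          "iterations",
                                                          "converged")],
                 feasibility = feas, norm_factor = sf, seed = seed),
            class = "dmlc_plan")
}

# write a flat weight vector back into the per-layer spot data frames
assign_weights <- function(states, w) {
  k <- 0
  for (b in seq_along(states)) {
    for (l in seq_along(states[[b]]$spots)) {
      n <- nrow(states[[b]]$spots[[l]])
      if (n) {
        states[[b]]$spots[[l]]$weight <- w[k + seq_len(n)]
        k <- k + n
      }
    }
    states[[b]]$convs <- NULL
  }
  stopifnot(k == length(w))
  states
}

#' Nominal dose of a plan
#' @param plan a `dmlc_plan`.
#' @return the nominal `dose_grid`.
#' @export
plan_dose <- function(plan) plan$dose

#' Flat spot table of a plan (for export)
#' @param plan a `dmlc_plan`.
#' @return data.frame with beam, layer, energy, u, v, weight.
#' @export
plan_spot_table <- function(plan) {
  out <- list()
  for (b in seq_along(plan$states)) {
    st <- plan$states[[b]]
    for (l in seq_along(st$layers)) {
      sp <- st$spots[[l]]
      if (!nrow(sp)) next
      out[[length(out) + 1]] <- data.frame(
        beam = b, layer = l, energy_mev = st$layers[[l]]$energy_mev,
        u = sp$u, v = sp$v, weight = sp$weight)
    }
  }
  do.call(rbind, out)
}
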