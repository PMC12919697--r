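# Voxel-grid and structure primitives plus the synthetic-phantom generator.
#
# Coordinate convention (used throughout the package): right-handed patient
# frame, x = left-right, y = anterior-posterior, z = cranial-caudal, all in
# millimetres. The grid origin is the corner of voxel (1,1,1); voxel centers
# sit at origin + (i - 0.5) * spacing.

#' Create a voxel grid of relative stopping power
#'
#' @param origin mm 3-vector, corner of the first voxel.
#' @param spacing mm 3-vector of voxel sizes (all > 0).
#' @param values 3D numeric array of relative stopping power (water = 1.0,
#'   air about 0.001). All values must be >= 0.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, values) {
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(values < 0)) stop("RSP values must be non-negative")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dim(values), values = values),
            class = "voxel_grid")
}

#' Voxel center coordinates of a grid
#'
#' @param grid a `voxel_grid`.
#' @return An n x 3 matrix of voxel center positions (mm), in array order.
#' @export
voxel_centers <- function(grid) {
  d <- grid$dims
  cx <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing[3]
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Named structure on a voxel grid
#'
#' @param name structure name.
#' @param role one of `"target"`, `"oar"`, `"external"`.
#' @param mask logical 3D array congruent with the grid.
#' @return An object of class `rt_structure`.
#' @export
rt_structure <- function(name, role = c("target", "oar", "external"), mask) {
  role <- match.arg(role)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(name = name, role = role, mask = mask),
            class = "rt_structure")
}

#' Synthetic phantom specification
#'
#' Describes a water body in air with one target (sphere or a C-shaped
#' annular sector wrapping the OAR) and one OAR (cylinder or sphere). The
#' C-shape emulates the geometric challenge of a target abutting or partly
#' surrounding a critical organ. The body is a water cylinder with its axis
#' along z, centered at the frame origin.
#'
#' @param body_radius_mm radius of the water body cylinder.
#' @param body_height_mm height of the water body cylinder along z.
#' @param target_shape `"c_shape"` or `"sphere"`.
#' @param target_outer_mm outer radius of the C-shape (or sphere radius).
#' @param gap_mm radial gap between OAR surface and target inner surface
#'   (C-shape only); the inner radius is `oar_radius_mm + gap_mm`.
#' @param opening_deg full angular width of the C opening.
#' @param opening_dir_deg direction (degrees, counterclockwise from +x in
#'   the axial plane) the C opening faces. The default faces the anterior
#'   (+y) side so that with the reference three-beam arrangement (gantry
#'   0/120/240) two of the three OAR shadow sectors fall inside the opening
#'   and only one beam shields a target arc, which the other two beams can
#'   compensate -- the same feasibility consideration that drives manual
#'   beam/collimator-angle selection in block-mode planning.
#' @param target_height_mm height of the C-shape along z.
#' @param oar_shape `"cylinder"` or `"sphere"`.
#' @param oar_radius_mm OAR radius.
#' @param oar_height_mm OAR height along z (cylinder only).
#' @param spacing_mm isotropic voxel spacing (default 2 mm, matching the
#'   dose-calculation grid).
#' @param air_rsp relative stopping power of surrounding air.
#' @param rsp_noise_sd standard deviation of optional Gaussian RSP noise
#'   inside the body (default 0, i.e. exactly water).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_radius_mm = 45, body_height_mm = 60,
                         target_shape = c("c_shape", "sphere"),
                         target_outer_mm = 20, gap_mm = 7,
                         opening_deg = 160, opening_dir_deg = 90,
                         target_height_mm = 24,
                         oar_shape = c("cylinder", "sphere"),
                         oar_radius_mm = 4, oar_height_mm = 24,
                         spacing_mm = 2, air_rsp = 0.001,
                         rsp_noise_sd = 0) {
  target_shape <- match.arg(target_shape)
  oar_shape <- match.arg(oar_shape)
  sp <- list(body_radius_mm = body_radius_mm, body_height_mm = body_height_mm,
             target_shape = target_shape, target_outer_mm = target_outer_mm,
             gap_mm = gap_mm, opening_deg = opening_deg,
             opening_dir_deg = opening_dir_deg,
             target_height_mm = target_height_mm, oar_shape = oar_shape,
             oar_radius_mm = oar_radius_mm, oar_height_mm = oar_height_mm,
             spacing_mm = spacing_mm, air_rsp = air_rsp,
             rsp_noise_sd = rsp_noise_sd)
  num <- unlist(sp[c("body_radius_mm", "body_height_mm", "target_outer_mm",
                     "target_height_mm", "oar_radius_mm", "oar_height_mm",
                     "spacing_mm")])
  if (any(num <= 0)) stop("phantom dimensions must be positive")
  if (gap_mm < 0) stop("gap_mm must be >= 0 for the wrapped-OAR phantom")
  if (target_shape == "c_shape" &&
      target_outer_mm <= oar_radius_mm + gap_mm)
    stop("target outer radius must exceed inner radius (oar radius + gap)")
  if (target_outer_mm > body_radius_mm || oar_radius_mm > body_radius_mm ||
      target_height_mm > body_height_mm || oar_height_mm > body_height_mm)
    stop("target/OAR shapes must fit inside the body")
  if (target_shape == "sphere" &&
      oar_radius_mm + gap_mm + 2 * target_outer_mm > body_radius_mm)
    stop("offset sphere target does not fit inside the body")
  structure(sp, class = "phantom_spec")
}

#' Generate a synthetic phantom
#'
#' Builds the RSP voxel grid (water body, RSP exactly 1.0, surrounded by
#' air) and the target / OAR structure masks described by the spec. The
#' result is bitwise deterministic for a given (spec, seed); the seed only
#' matters when `rsp_noise_sd > 0`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the optional RSP noise.
#' @return list with elements `grid` (a `voxel_grid`) and `structures`
#'   (list of `rt_structure`: CTV then OAR).
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  # grid extent: body + 5 mm air margin, snapped to whole voxels
  rext <- ceiling((spec$body_radius_mm + 5) / sp) * sp
  zext <- ceiling((spec$body_height_mm / 2 + 2) / sp) * sp
  nx <- as.integer(2 * rext / sp); nz <- as.integer(2 * zext / sp)
  origin <- c(-rext, -rext, -zext)
  dims <- c(nx, nx, nz)
  cx <- origin[1] + (seq_len(nx) - 0.5) * sp
  cz <- origin[3] + (seq_len(nz) - 0.5) * sp
  X <- array(rep(cx, times = nx * nz), dim = dims)
  Y <- array(rep(rep(cx, each = nx), times = nz), dim = dims)
  Z <- array(rep(cz, each = nx * nx), dim = dims)
  R2 <- X^2 + Y^2
  body <- R2 <= spec$body_radius_mm^2 & abs(Z) <= spec$body_height_mm / 2
  values <- array(spec$air_rsp, dim = dims)
  values[body] <- 1.0
  if (spec$rsp_noise_sd > 0) {
    set.seed(as.integer(seed))
    noise <- stats::rnorm(sum(body), 0, spec$rsp_noise_sd)
    values[body] <- pmax(0.2, 1.0 + noise)
  }
  # OAR mask
  if (spec$oar_shape == "cylinder") {
    oar <- R2 <= spec$oar_radius_mm^2 & abs(Z) <= spec$oar_height_mm / 2
  } else {
    oar <- (R2 + Z^2) <= spec$oar_radius_mm^2
  }
  # target mask
  if (spec$target_shape == "sphere") {
    # sphere offset so it abuts the OAR with the requested gap
    cxo <- spec$oar_radius_mm + spec$gap_mm + spec$target_outer_mm
    tgt <- ((X - cxo)^2 + Y^2 + Z^2) <= spec$target_outer_mm^2
  } else {
    inner <- spec$oar_radius_mm + spec$gap_mm
    ang <- atan2(Y, X) * 180 / pi - spec$opening_dir_deg
    ang <- (ang + 180) %% 360 - 180  # wrapped angle from the opening axis
    tgt <- R2 >= inner^2 & R2 <= spec$target_outer_mm^2 &
      abs(Z) <= spec$target_height_mm / 2 &
      abs(ang) >= spec$opening_deg / 2
  }
  tgt <- tgt & !oar & body
  oar <- oar & body
  grid <- voxel_grid(origin, rep(sp, 3), values)
  list(grid = grid,
       structures = list(rt_structure("CTV", "target", tgt),
                         rt_structure("OAR", "oar", oar)))
}

#' Default HU-to-RSP calibration table
#'
#' A generic piecewise-linear calibration with air / lung / water / bone
#' nodes. Synthetic phantoms specify RSP directly and bypass calibration.
#'
#' @return data.frame with columns `hu` and `rsp`.
#' @export
default_hu_rsp_table <- function() {
  data.frame(hu = c(-1000, -800, -100, 0, 50, 1000, 2000, 3000),
             rsp = c(0.001, 0.190, 0.930, 1.000, 1.040, 1.560, 2.000, 2.400))
}

#' Convert Hounsfield units to relative stopping power
#'
#' Linear interpolation between calibration nodes, clamped at the table
#' ends. The table must be monotone non-decreasing in both columns.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param table calibration data.frame with columns `hu`, `rsp`.
#' @return numeric vector of RSP values.
#' @export
hu_to_rsp <- function(hu, table = default_hu_rsp_table()) {
  stopifnot(all(c("hu", "rsp") %in% names(table)))
  o <- order(table$hu)
  table <- table[o, ]
  if (any(diff(table$hu) <= 0)) stop("calibration table has duplicated HU nodes")
  if (any(diff(table$rsp) < 0)) stop("calibration table must be monotone non-decreasing")
  stats::approx(table$hu, table$rsp, xout = hu, rule = 2)$y
}

#' Write / read a phantom archive
#'
#' Single-file persistence of the grid metadata, RSP array and named masks.
#' The archive is an RDS file holding the list returned by [make_phantom()].
#'
#' @param phantom list with `grid` and `structures`.
#' @param path file path.
#' @return `read_phantom` returns the phantom list.
#' @export
write_phantom <- function(phantom, path) {
  saveRDS(phantom, path)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) readRDS(path)
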