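# Analytic 4D mitral-valve label phantoms. The annulus is a tube of radius
# tube_radius_mm around a saddle ring (radius R, height modulation
# h*cos(2*theta)); the two leaflets are thin half-annular sheets spanning from
# the annulus inward to a cardiac-cycle dependent orifice radius. Every
# quantity the downstream pipeline measures (valve plane, per-frame effective
# area, peak frame) has a closed form recorded in the returned truth object.

#' Specification of a synthetic valve phantom
#'
#' Defaults describe a mid-size adult mitral annulus: ring radius 14 mm with a
#' 2 mm saddle, a 1.5 mm annulus tube, an orifice opening from 2 mm to 10 mm
#' radius over a 16-frame cycle, on a 96^3 grid at 0.5 mm isotropic spacing.
#'
#' @param annulus_radius_mm annulus ring radius (mm).
#' @param saddle_height_mm peak-to-midplane height of the annulus saddle (mm);
#'   the ring height is modulated as `saddle_height_mm * cos(2*theta)`.
#' @param tube_radius_mm radius of the annulus tube (mm).
#' @param orifice_radius_min_mm,orifice_radius_max_mm orifice radius at full
#'   closure / full opening (mm).
#' @param n_frames number of frames in the cycle.
#' @param voxel_spacing_mm numeric length-3 voxel spacing (mm).
#' @param grid_shape integer length-3 grid dimensions.
#' @param tilt_deg rotation of the valve plane about the world x axis.
#' @param leaflet_thickness_mm thickness of the leaflet sheets (mm); defaults
#'   to two voxels at the default spacing.
#' @param seed integer stored with the spec; phantom generation itself is
#'   deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(annulus_radius_mm = 14, saddle_height_mm = 2,
                         tube_radius_mm = 1.5, orifice_radius_min_mm = 2,
                         orifice_radius_max_mm = 10, n_frames = 16,
                         voxel_spacing_mm = c(0.5, 0.5, 0.5),
                         grid_shape = c(96, 96, 96), tilt_deg = 0,
                         leaflet_thickness_mm = 1, seed = 1L) {
  if (length(voxel_spacing_mm) == 1L) voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3)
  spec <- structure(
    list(annulus_radius_mm = annulus_radius_mm,
         saddle_height_mm = saddle_height_mm,
         tube_radius_mm = tube_radius_mm,
         orifice_radius_min_mm = orifice_radius_min_mm,
         orifice_radius_max_mm = orifice_radius_max_mm,
         n_frames = as.integer(n_frames),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         grid_shape = as.integer(grid_shape),
         tilt_deg = tilt_deg,
         leaflet_thickness_mm = leaflet_thickness_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (annulus_radius_mm <= 0 || tube_radius_mm <= 0 ||
        orifice_radius_min_mm <= 0 || orifice_radius_max_mm <= 0)
      mv_error("mv_argument_error", "radii must be positive")
    if (saddle_height_mm < 0)
      mv_error("mv_argument_error", "saddle_height_mm must be non-negative")
    if (!(orifice_radius_min_mm < orifice_radius_max_mm &&
          orifice_radius_max_mm < annulus_radius_mm))
      mv_error("mv_argument_error",
               "need orifice_radius_min_mm < orifice_radius_max_mm < annulus_radius_mm")
    if (n_frames < 1L) mv_error("mv_argument_error", "n_frames must be positive")
    if (any(voxel_spacing_mm <= 0)) mv_error("mv_argument_error", "spacings must be > 0")
    if (any(grid_shape < 8L)) mv_error("mv_sizing_error", "grid_shape too small")
    # the tilted annulus torus must fit with >= 2 voxels of margin on each axis
    bound <- sqrt(annulus_radius_mm^2 + saddle_height_mm^2) + tube_radius_mm
    half <- (grid_shape - 1) / 2 * voxel_spacing_mm
    if (any(bound > half - 2 * voxel_spacing_mm))
      mv_error("mv_sizing_error", sprintf(
        "grid too small: phantom radius %.1f mm exceeds usable half-extent %.1f mm",
        bound, min(half - 2 * voxel_spacing_mm)))
  })
  invisible(spec)
}

#' Orifice radius schedule
#'
#' Cosine opening schedule
#' `r(t) = r_min + (r_max - r_min) * (1 - cos(2*pi*t/n_frames)) / 2`
#' for 0-based frame index t.
#'
#' @param spec a `phantom_spec`.
#' @param frame_index 0-based frame index (vectorized).
#' @return orifice radius in mm.
#' @export
orifice_radius <- function(spec, frame_index) {
  spec$orifice_radius_min_mm +
    (spec$orifice_radius_max_mm - spec$orifice_radius_min_mm) *
    (1 - cos(2 * pi * frame_index / spec$n_frames)) / 2
}

phantom_affine <- function(spec) {
  sp <- spec$voxel_spacing_mm
  A <- diag(c(sp, 1))
  A[1:3, 4] <- -sp * (spec$grid_shape - 1) / 2  # world origin at grid center
  A
}

phantom_tilt <- function(spec) rotation_matrix(c(1, 0, 0), spec$tilt_deg)

# Saddle annulus curve in world coordinates at the given angles.
phantom_annulus_curve <- function(spec, theta) {
  q <- cbind(spec$annulus_radius_mm * cos(theta),
             spec$annulus_radius_mm * sin(theta),
             spec$saddle_height_mm * cos(2 * theta))
  q %*% t(phantom_tilt(spec))
}

# Valve-frame cylindrical coordinates (rho, theta, height) of every voxel
# center, plus the world affine. Computed once and shared across frames.
phantom_geometry <- function(spec) {
  A <- phantom_affine(spec)
  d <- spec$grid_shape
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  P <- vox_to_world(idx, A)
  Q <- P %*% phantom_tilt(spec)  # rows are t(Rtilt) %*% p
  rho <- sqrt(Q[, 1]^2 + Q[, 2]^2)
  theta <- atan2(Q[, 2], Q[, 1])
  list(affine = A, dims = d, rho = rho, theta = theta, height = Q[, 3])
}

# Exact (densely sampled) annulus tube mask over the precomputed geometry.
phantom_annulus_mask <- function(spec, geom, n_curve = 720L) {
  R <- spec$annulus_radius_mm; h <- spec$saddle_height_mm; a <- spec$tube_radius_mm
  cand <- which(abs(geom$rho - R) <= a + 0.01 & abs(geom$height) <= h + a + 0.01)
  mask <- logical(length(geom$rho))
  if (length(cand)) {
    th <- geom$theta[cand]
    # candidate coordinates back in the (untilted) valve frame
    x <- geom$rho[cand] * cos(th); y <- geom$rho[cand] * sin(th); z <- geom$height[cand]
    phi <- seq(0, 2 * pi, length.out = n_curve + 1L)[-(n_curve + 1L)]
    d2 <- rep(Inf, length(cand))
    for (p in phi) {
      cx <- R * cos(p); cy <- R * sin(p); cz <- h * cos(2 * p)
      d2 <- pmin(d2, (x - cx)^2 + (y - cy)^2 + (z - cz)^2)
    }
    mask[cand] <- d2 <= a^2
  }
  dim(mask) <- geom$dims
  mask
}

# Leaflet sheet masks for a frame: sheets blend from the saddle at the annulus
# to the mid-plane at the orifice rim, with finite thickness.
phantom_leaflet_masks <- function(spec, geom, frame_index) {
  rt <- orifice_radius(spec, frame_index)
  R <- spec$annulus_radius_mm
  zs <- spec$saddle_height_mm * cos(2 * geom$theta) * (geom$rho / R)
  on_sheet <- geom$rho >= rt & geom$rho <= R &
    abs(geom$height - zs) <= spec$leaflet_thickness_mm / 2
  anterior <- on_sheet & geom$theta >= 0
  posterior <- on_sheet & geom$theta < 0
  dim(anterior) <- geom$dims; dim(posterior) <- geom$dims
  list(anterior = anterior, posterior = posterior)
}

assemble_phantom_frame <- function(spec, geom, annulus_mask, frame_index) {
  vox <- array(0L, geom$dims)
  lf <- phantom_leaflet_masks(spec, geom, frame_index)
  vox[lf$anterior] <- 1L
  vox[lf$posterior] <- 2L
  vox[annulus_mask] <- 3L  # annulus tube has precedence in the phantom
  label_volume(vox, spec$voxel_spacing_mm, geom$affine)
}

#' Generate one phantom frame
#'
#' @param spec a `phantom_spec`.
#' @param frame_index 0-based frame index in `[0, n_frames)`.
#' @return a `label_volume` with labels 0 (background), 1 (anterior leaflet),
#'   2 (posterior leaflet), 3 (annulus).
#' @export
make_phantom_frame <- function(spec, frame_index) {
  validate_phantom_spec(spec)
  if (frame_index < 0 || frame_index >= spec$n_frames)
    mv_error("mv_argument_error", "frame_index out of range")
  geom <- phantom_geometry(spec)
  assemble_phantom_frame(spec, geom, phantom_annulus_mask(spec, geom), frame_index)
}

#' Generate a full phantom cycle with analytic ground truth
#'
#' @param spec a `phantom_spec`.
#' @return list with `frames` (list of `label_volume`) and `truth`, a
#'   `phantom_truth` object recording the exact valve plane, the analytic
#'   per-frame effective areas `pi * r(t)^2`, the peak (maximum-opening) frame
#'   and the annulus centerline.
#' @export
make_phantom_sequence <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  ann <- phantom_annulus_mask(spec, geom)
  frames <- lapply(seq_len(spec$n_frames) - 1L, function(f)
    assemble_phantom_frame(spec, geom, ann, f))
  f <- seq_len(spec$n_frames) - 1L
  ea <- pi * orifice_radius(spec, f)^2
  truth <- structure(
    list(plane_normal = as.numeric(phantom_tilt(spec) %*% c(0, 0, 1)),
         plane_point = c(0, 0, 0),
         ea_per_frame_mm2 = ea,
         peak_frame = f[which.max(ea)],
         annulus_centerline = phantom_annulus_curve(
           spec, seq(0, 2 * pi, length.out = 361L)[-361L])),
    class = "phantom_truth"
  )
  list(frames = frames, truth = truth)
}

#' Sample annulus control points from the phantom
#'
#' Points lie exactly on the analytic saddle annulus curve at equally spaced
#' angles, ordered by angle, mimicking manual control-point placement.
#'
#' @param spec a `phantom_spec`.
#' @param n_points number of control points (>= 4).
#' @return a `control_point_set`.
#' @export
make_annulus_control_points <- function(spec, n_points = 12L) {
  validate_phantom_spec(spec)
  if (n_points < 4L)
    mv_error("mv_fit_error", "at least 4 control points are required for a spline fit")
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  control_point_set(phantom_annulus_curve(spec, theta))
}
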