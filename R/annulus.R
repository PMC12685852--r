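# Annulus reconstruction from sparse manual control points: periodic cubic
# spline fit through the points (zero smoothing by default, as used for the
# manual annotations this mirrors), dense sampling at equally spaced parameter
# values, voxelization of a cylindrical tube around the sampled curve, and
# connected-component post-processing.

#' Construct a control point set
#'
#' @param points n x 3 matrix of ordered world coordinates (mm).
#' @param frame_of_reference tag naming the world convention (e.g. "LPS").
#' @return object of class `control_point_set`.
#' @export
control_point_set <- function(points, frame_of_reference = "LPS") {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    mv_error("mv_format_error", "control points must be n x 3")
  if (nrow(points) < 4L)
    mv_error("mv_fit_error", "at least 4 control points are required")
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d < 1e-9))
    mv_error("mv_fit_error", "consecutive control points must be distinct")
  structure(list(points = points, frame_of_reference = frame_of_reference),
            class = "control_point_set")
}

#' Fit a smooth 3D spline through annulus control points
#'
#' Each world coordinate is fitted against a normalized chord-length parameter.
#' With `smoothing = 0` (the default, matching manual-annotation practice) the
#' curve interpolates every control point exactly; closed curves use a periodic
#' cubic spline basis, open curves a natural cubic spline. A positive
#' `smoothing` fits a cubic smoothing spline (penalty `lambda = smoothing`)
#' instead of interpolating.
#'
#' @param cps a `control_point_set` (or n x 3 matrix).
#' @param smoothing non-negative smoothing penalty; 0 interpolates.
#' @param closed treat the curve as closed/periodic (the mitral annulus is a
#'   ring, so this is the default).
#' @return object of class `mv_spline`, evaluable with [eval_spline()].
#' @export
fit_spline <- function(cps, smoothing = 0, closed = TRUE) {
  if (!inherits(cps, "control_point_set")) cps <- control_point_set(cps)
  pts <- cps$points
  n <- nrow(pts)
  ctr <- sweep(pts, 2, colMeans(pts))
  if (closed) {
    sv <- svd(ctr)$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-12))
      mv_error("mv_fit_error", "control points are collinear; cannot fit a closed curve")
  }
  # chord-length parameterization on [0, 1]
  if (closed) {
    seg <- sqrt(rowSums((rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts)^2))
    tt <- c(0, cumsum(seg))          # length n + 1; wraps to the start
    tt <- tt / tt[n + 1L]
    ptsw <- rbind(pts, pts[1, , drop = FALSE])
  } else {
    seg <- sqrt(rowSums(diff(pts)^2))
    tt <- c(0, cumsum(seg)) / sum(seg)
    ptsw <- pts
  }
  fit_coord <- function(y) {
    if (smoothing > 0) {
      if (closed) {
        # wrap one period on each side so the smoothed curve is near-periodic
        tw <- c(tt[-length(tt)] - 1, tt, tt[-1] + 1)
        yw <- c(y[-length(y)], y, y[-1])
        fit <- stats::smooth.spline(tw, yw, lambda = smoothing, all.knots = TRUE)
      } else {
        fit <- stats::smooth.spline(tt, y, lambda = smoothing, all.knots = TRUE)
      }
      function(t) stats::predict(fit, t)$y
    } else if (closed) {
      fit <- splines::periodicSpline(tt[-length(tt)], y[-length(y)], period = 1)
      function(t) stats::predict(fit, t)$y
    } else {
      fit <- splines::interpSpline(tt, y)
      function(t) stats::predict(fit, t)$y
    }
  }
  funs <- lapply(1:3, function(c) fit_coord(ptsw[, c]))
  structure(list(funs = funs, closed = closed, control_points = pts,
                 smoothing = smoothing),
            class = "mv_spline")
}

#' Evaluate a fitted spline
#'
#' @param spline an `mv_spline`.
#' @param t parameter values in `[0, 1]` (periodic curves wrap).
#' @return length(t) x 3 matrix of world coordinates.
#' @export
eval_spline <- function(spline, t) {
  if (spline$closed) t <- t %% 1
  cbind(spline$funs[[1]](t), spline$funs[[2]](t), spline$funs[[3]](t))
}

#' Sample a spline at equally spaced parameter values
#'
#' @param spline an `mv_spline` from [fit_spline()].
#' @param n_samples number of samples (default 100, the density used for
#'   annulus annotation enhancement).
#' @return object of class `spline_curve` with fields `points` (n x 3) and
#'   `closed`. For closed curves the first and last samples coincide.
#' @export
sample_spline <- function(spline, n_samples = 100L) {
  if (n_samples < 2L)
    mv_error("mv_argument_error", "n_samples must be at least 2")
  t <- seq(0, 1, length.out = n_samples)
  pts <- eval_spline(spline, t)
  if (spline$closed) pts[n_samples, ] <- pts[1, ]  # close exactly
  structure(list(points = pts, closed = spline$closed), class = "spline_curve")
}

#' Voxelize a cylindrical tube around a curve
#'
#' A voxel is set iff its world-space center lies within `radius_mm` of the
#' sampled polyline (exact point-to-segment distance).
#'
#' @param curve a `spline_curve` (or n x 3 matrix of world points).
#' @param radius_mm tube radius in mm (default 1.5, the standard annulus tube).
#' @param template a `label_volume` providing the target grid and affine.
#' @return logical 3D array on the template grid.
#' @export
voxelize_tube <- function(curve, radius_mm = 1.5, template) {
  pts <- if (inherits(curve, "spline_curve")) curve$points else as.matrix(curve)
  if (nrow(pts) < 2L) mv_error("mv_argument_error", "curve needs at least 2 points")
  bounds <- volume_world_bounds(template)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (any(lo < bounds["lo", ] - 1e-6) || any(hi > bounds["hi", ] + 1e-6))
    mv_error("mv_bounds_error", "curve lies outside the template volume bounds")
  if (radius_mm < max(template$spacing_mm) / 2)
    warning("tube radius is below half the voxel spacing; the tube may be disconnected",
            call. = FALSE)
  # candidate voxel box: world bbox of the curve grown by the radius
  corners <- as.matrix(expand.grid(c(lo[1] - radius_mm, hi[1] + radius_mm),
                                   c(lo[2] - radius_mm, hi[2] + radius_mm),
                                   c(lo[3] - radius_mm, hi[3] + radius_mm)))
  vc <- world_to_vox(corners, template$affine) - 1  # 0-based
  ilo <- pmax(floor(apply(vc, 2, min)) - 1L, 0L)
  ihi <- pmin(ceiling(apply(vc, 2, max)) + 1L, dim(template$voxels) - 1L)
  mask <- .tube_mask_cpp(pts, radius_mm, template$affine,
                         dim(template$voxels),
                         as.integer(ilo), as.integer(ihi))
  if (!any(mask)) mv_error("mv_empty_error", "tube voxelization produced an empty mask")
  mask
}

#' Keep the most significant connected component
#'
#' Among 26-connected components whose voxel count is at least `size_gate`
#' times the largest component, keeps the one with the highest mean world
#' z-coordinate; everything else is removed. This is the post-processing used
#' to clean spurious disconnected fragments from the voxelized annulus tube,
#' where the annulus is the atrial-most (highest) significant structure.
#'
#' @param mask logical 3D array.
#' @param affine 4x4 voxel-to-world affine; defaults to identity spacing.
#' @param size_gate fraction of the largest component size a component must
#'   reach to be considered significant (default 0.25).
#' @return logical 3D array containing exactly one connected component.
#' @export
postprocess_components <- function(mask, affine = NULL, size_gate = 0.25) {
  if (!any(mask)) mv_error("mv_empty_error", "mask is empty")
  if (is.null(affine)) affine <- diag(4)
  lab <- .label3d_cpp(mask, dim(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep_ids <- which(sizes >= size_gate * max(sizes))
  meanz <- vapply(keep_ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    mean(vox_to_world(idx, affine)[, 3])
  }, numeric(1))
  winner <- keep_ids[which.max(meanz)]
  if (length(keep_ids) > 1L)
    mv_log("component post-processing: candidates (size, mean z) = %s; kept #%d",
           paste(sprintf("(%d, %.2f)", sizes[keep_ids], meanz), collapse = " "), winner)
  out <- lab == winner
  attr(out, "candidates") <- data.frame(component = keep_ids,
                                        size = sizes[keep_ids], mean_z = meanz)
  out
}

#' Build a volumetric annulus label from control points
#'
#' Composition of the full reconstruction pipeline: spline fit (zero
#' smoothing), sampling at `n_samples` parameter values, tube voxelization at
#' `radius_mm`, and connected-component post-processing. The resulting mask is
#' written as label 3 into a copy of the template; existing leaflet labels
#' (1, 2) are never overwritten, since the leaflets are the thin structures of
#' interest and the tube radius is a modelling artifact.
#'
#' @param cps a `control_point_set`.
#' @param template a `label_volume` (may already contain leaflet labels).
#' @param radius_mm tube radius (mm).
#' @param n_samples number of spline samples.
#' @param smoothing spline smoothing penalty (0 interpolates).
#' @param closed fit a closed (periodic) curve.
#' @return a `label_volume` with the reconstructed annulus as label 3.
#' @export
build_annulus_label <- function(cps, template, radius_mm = 1.5,
                                n_samples = 100L, smoothing = 0, closed = TRUE) {
  spl <- fit_spline(cps, smoothing = smoothing, closed = closed)
  curve <- sample_spline(spl, n_samples)
  mask <- voxelize_tube(curve, radius_mm, template)
  mask <- postprocess_components(mask, template$affine)
  vox <- template$voxels
  vox[mask & !(vox %in% c(1L, 2L))] <- 3L
  label_volume(vox, template$spacing_mm, template$affine, template$legend)
}
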