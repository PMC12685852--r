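# Shared helpers: classed conditions, affine algebra, small geometry utilities.

mv_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mvquant_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

mv_log <- function(...) {
  if (isTRUE(getOption("mvquant.verbose", FALSE))) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(u)
}

# Map 1-based voxel indices (n x 3) to world mm through a 4x4 affine whose
# convention is world = A %*% c(i - 1, j - 1, k - 1, 1).
vox_to_world <- function(idx, affine) {
  idx <- rbind(idx)  # tolerate a single point as a vector
  h <- cbind(idx - 1, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

world_to_vox <- function(pts, affine) {
  pts <- rbind(pts)
  h <- cbind(pts, 1)
  t(solve(affine) %*% t(h))[, 1:3, drop = FALSE] + 1
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}
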