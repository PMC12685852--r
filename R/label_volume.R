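# The label_volume container: a 3D integer label grid with voxel spacing and a
# voxel-index -> world affine. All downstream measurements are performed in
# world millimetres through the affine; voxel indices never leak out.

#' Default label legend for mitral valve volumes
#'
#' Label 1 is the anterior leaflet, 2 the posterior leaflet and 3 the annulus;
#' 0 is background.
#' @return named integer vector.
#' @export
mv_label_legend <- function() {
  c(background = 0L, anterior = 1L, posterior = 2L, annulus = 3L)
}

#' Construct a label volume
#'
#' @param voxels 3D integer array with labels in `legend`.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm. Defaults
#'   to a diagonal affine with the given spacing and origin at voxel (1,1,1).
#' @param legend named integer vector naming the labels.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing_mm, affine = NULL,
                         legend = mv_label_legend()) {
  if (length(dim(voxels)) != 3L)
    mv_error("mv_format_error", "voxels must be a 3D array")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    mv_error("mv_metadata_error", "spacing_mm must be 3 positive lengths")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    mv_error("mv_metadata_error", "affine must be an invertible 4x4 matrix")
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
         affine = affine, legend = legend),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels,", paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  tab <- table(x$voxels)
  cat("labels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' World coordinates of voxels carrying a given label
#'
#' @param vol a `label_volume`.
#' @param label integer label value.
#' @return n x 3 matrix of world mm coordinates of voxel centers.
#' @export
label_world_coords <- function(vol, label) {
  idx <- which(vol$voxels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  vox_to_world(idx, vol$affine)
}

# World-space axis-aligned bounding box of the voxel-center lattice.
volume_world_bounds <- function(vol) {
  d <- dim(vol$voxels)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  w <- vox_to_world(corners, vol$affine)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}
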