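# Temporal analysis: assemble per-frame measurements into an effective-area
# curve, detect the maximum-opening (mid-diastolic) frame, summarize the
# cycle, and compare paired area measurements (Pearson correlation and
# Bland-Altman limits of agreement).

#' Compute the effective-area curve of a 4D sequence
#'
#' Runs [quantify_frame()] on every frame. Frames whose annulus fails (open
#' ring, missing annulus, degenerate geometry) are recorded as gaps rather
#' than aborting the whole sequence.
#'
#' @param frames list of `label_volume` objects (one cardiac cycle); frames
#'   are indexed 0-based in acquisition order.
#' @param pixel_size_mm,tube_radius_mm passed to [quantify_frame()].
#' @return object of class `ea_curve` with fields `frame_indices`, `ea_mm2`,
#'   `measurements`, `peak_frame`, `mean_mm2`, `min_mm2`, `max_mm2` and
#'   `gaps` (a data frame of failed frames and reasons).
#' @export
compute_ea_curve <- function(frames, pixel_size_mm = NULL, tube_radius_mm = 1.5) {
  if (length(frames) < 1L) mv_error("mv_argument_error", "need at least one frame")
  res <- vector("list", length(frames))
  gaps <- list()
  for (f in seq_along(frames)) {
    m <- tryCatch(
      quantify_frame(frames[[f]], frame_index = f - 1L,
                     pixel_size_mm = pixel_size_mm, tube_radius_mm = tube_radius_mm),
      mvquant_error = function(e) e
    )
    if (inherits(m, "area_measurement")) {
      res[[f]] <- m
    } else {
      gaps[[length(gaps) + 1L]] <- data.frame(frame = f - 1L,
                                              reason = conditionMessage(m))
      mv_log("frame %d skipped: %s", f - 1L, conditionMessage(m))
    }
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) mv_error("mv_empty_error", "no frame could be quantified")
  res <- res[ok]
  idx <- vapply(res, function(m) m$frame_index, integer(1))
  ea <- vapply(res, function(m) m$effective_area_mm2, numeric(1))
  structure(
    list(frame_indices = idx, ea_mm2 = ea, measurements = res,
         peak_frame = idx[which.max(ea)],
         mean_mm2 = mean(ea), min_mm2 = min(ea), max_mm2 = max(ea),
         gaps = if (length(gaps)) do.call(rbind, gaps)
                else data.frame(frame = integer(0), reason = character(0))),
    class = "ea_curve"
  )
}

#' Detect the maximum-opening frame
#'
#' The mid-diastolic (maximum-opening) frame is the frame with the largest
#' effective area; ties are broken by the earliest frame (and logged).
#'
#' @param curve an `ea_curve`, or a bare numeric vector of areas (then treated
#'   as frames 0, 1, ...).
#' @return the 0-based frame index of the peak.
#' @export
detect_peak_frame <- function(curve) {
  if (inherits(curve, "ea_curve")) {
    ea <- curve$ea_mm2; idx <- curve$frame_indices
  } else {
    ea <- as.numeric(curve); idx <- seq_along(ea) - 1L
  }
  if (length(ea) == 0L) mv_error("mv_empty_error", "empty curve")
  if (sum(ea == max(ea)) > 1L) mv_log("peak detection: tie broken by earliest frame")
  idx[which.max(ea)]
}

#' Summarize an effective-area curve
#'
#' @param curve an `ea_curve` or numeric vector of areas.
#' @return list with `mean_mm2`, `min_mm2`, `max_mm2`, `peak_frame`,
#'   `n_frames`.
#' @export
summarize_curve <- function(curve) {
  ea <- if (inherits(curve, "ea_curve")) curve$ea_mm2 else as.numeric(curve)
  if (length(ea) == 0L) mv_error("mv_empty_error", "empty curve")
  list(mean_mm2 = mean(ea), min_mm2 = min(ea), max_mm2 = max(ea),
       peak_frame = detect_peak_frame(curve), n_frames = length(ea))
}

#' Compare paired area measurements
#'
#' Agreement statistics between a reference series (e.g. clinical report
#' planimetry) and a predicted series (pipeline output): Pearson correlation,
#' Bland-Altman mean difference and 95% limits of agreement
#' (mean difference +/- 1.96 SD of the differences), optionally stratified by
#' the median of the pair means.
#'
#' @param reference,predicted equal-length numeric vectors (n >= 3).
#' @param stratify also report the two bias estimates obtained after splitting
#'   the pairs at the median pair mean.
#' @return object of class `paired_validation`.
#' @export
compare_measurements <- function(reference, predicted, stratify = FALSE) {
  if (length(reference) != length(predicted))
    mv_error("mv_argument_error", "reference and predicted must have equal length")
  if (length(reference) < 3L)
    mv_error("mv_argument_error", "need at least 3 pairs")
  if (anyNA(reference) || anyNA(predicted))
    mv_error("mv_argument_error", "missing values are not allowed")
  if (sd(reference) == 0 || sd(predicted) == 0)
    mv_error("mv_degenerate_error", "zero variance in a series; correlation undefined")
  r <- cor(reference, predicted)
  d <- predicted - reference
  bias <- mean(d)
  s <- sd(d)
  out <- list(n = length(d), pearson_r = r,
              bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
              loa_halfwidth = 1.96 * s)
  if (stratify) {
    pm <- (reference + predicted) / 2
    cut <- median(pm)
    lo <- pm <= cut
    out$strata <- data.frame(
      group = c("low", "high"),
      n = c(sum(lo), sum(!lo)),
      bias = c(mean(d[lo]), if (any(!lo)) mean(d[!lo]) else NA_real_),
      split_at = cut
    )
  }
  structure(out, class = "paired_validation")
}

#' @export
print.paired_validation <- function(x, ...) {
  cat(sprintf("paired validation (n = %d): r = %.3f, bias = %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$pearson_r, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}
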