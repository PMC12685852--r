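# Multi-class segmentation objectives and evaluation metrics, independent of
# any network: generalized Dice loss over the classes present in the image,
# focal loss over all classes, their unweighted mean, deep supervision with
# nearest-neighbour downsampled ground truth, and per-class Dice / precision /
# recall / false-positive-rate metrics.
#
# Probability maps and one-hot masks are 3D arrays [H, W, C]: per-pixel class
# probabilities along the third dimension.

#' Loss configuration
#'
#' @param epsilon small constant guarding the Dice denominator.
#' @param gamma focal-loss focusing parameter (2 by default).
#' @param clip probabilities are clipped to `[clip, 1 - clip]` before logs.
#' @param deep_supervision_scales downsampling factors of the intermediate
#'   outputs, finest first (128/64/32 from a 256 input gives `c(2, 4, 8)`).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-6, gamma = 2, clip = 1e-7,
                        deep_supervision_scales = c(2L, 4L, 8L)) {
  if (epsilon <= 0) mv_error("mv_argument_error", "epsilon must be > 0")
  if (gamma < 0) mv_error("mv_argument_error", "gamma must be >= 0")
  structure(list(epsilon = epsilon, gamma = gamma, clip = clip,
                 deep_supervision_scales = deep_supervision_scales),
            class = "loss_config")
}

check_prob_map <- function(p) {
  if (length(dim(p)) != 3L) mv_error("mv_format_error", "probability map must be [H, W, C]")
  if (any(p < -1e-8) || any(p > 1 + 1e-8))
    mv_error("mv_format_error", "probabilities must lie in [0, 1]")
  s <- apply(p, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-5))
    mv_error("mv_format_error", "per-pixel class probabilities must sum to 1")
  invisible(p)
}

check_one_hot <- function(g) {
  if (length(dim(g)) != 3L) mv_error("mv_format_error", "mask must be [H, W, C]")
  if (!all(g %in% c(0, 1)))
    mv_error("mv_format_error", "one-hot mask entries must be 0 or 1")
  if (any(apply(g, c(1, 2), sum) != 1))
    mv_error("mv_format_error", "exactly one class must be set per pixel")
  invisible(g)
}

check_shapes <- function(p, g) {
  if (!all(dim(p) == dim(g)))
    mv_error("mv_format_error", "prediction and ground truth shapes differ")
}

#' One-hot encode a label map
#'
#' @param labels H x W matrix of class indices.
#' @param classes vector of class values defining channel order.
#' @return [H, W, C] one-hot array.
#' @export
one_hot <- function(labels, classes) {
  g <- array(0, c(dim(labels), length(classes)))
  for (c in seq_along(classes)) g[, , c] <- (labels == classes[c]) * 1
  if (any(apply(g, c(1, 2), sum) != 1))
    mv_error("mv_format_error", "labels contain values outside `classes`")
  g
}

#' Generalized Dice loss
#'
#' `L = 1 - (1/|C'|) * sum_{c in C'} (2 sum_i p_ic g_ic + eps) /
#' (sum_i p_ic + sum_i g_ic + eps)`, where `C'` is the set of classes with at
#' least one ground-truth pixel. Absent classes do not contribute.
#'
#' @param p probability map `[H, W, C]`.
#' @param g one-hot ground truth of the same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(p, g, cfg = loss_config()) {
  check_prob_map(p); check_one_hot(g); check_shapes(p, g)
  eps <- cfg$epsilon
  gsum <- apply(g, 3, sum)
  present <- which(gsum > 0)
  if (length(present) == 0L)
    mv_error("mv_degenerate_error", "ground truth contains no class")
  dice_c <- vapply(present, function(c) {
    (2 * sum(p[, , c] * g[, , c]) + eps) / (sum(p[, , c]) + gsum[c] + eps)
  }, numeric(1))
  1 - mean(dice_c)
}

#' Focal loss
#'
#' `L = -(1/N) sum_i sum_{c in C} (1 - p_ic)^gamma g_ic log p_ic`, summed over
#' all classes (not just those present), averaged over the N pixels.
#' Probabilities are clipped before the log.
#'
#' @inheritParams generalized_dice_loss
#' @return non-negative scalar loss.
#' @export
focal_loss <- function(p, g, cfg = loss_config()) {
  check_prob_map(p); check_one_hot(g); check_shapes(p, g)
  pc <- pmin(pmax(p, cfg$clip), 1 - cfg$clip)
  n <- dim(p)[1] * dim(p)[2]
  sum((1 - pc)^cfg$gamma * g * (-log(pc))) / n
}

#' Combined segmentation loss
#'
#' The unweighted mean of the generalized Dice loss and the focal loss.
#'
#' @inheritParams generalized_dice_loss
#' @return scalar loss.
#' @export
combined_loss <- function(p, g, cfg = loss_config()) {
  (generalized_dice_loss(p, g, cfg) + focal_loss(p, g, cfg)) / 2
}

#' Downsample a one-hot ground truth by nearest neighbour
#'
#' Each output pixel takes the class of its nearest-neighbour source pixel
#' (source index = `floor(output index * scale)`, 0-based), so the result
#' stays one-hot and class labels remain discrete.
#'
#' @param g one-hot mask `[H, W, C]`.
#' @param factor integer downsampling factor (must divide H and W), or `NULL`
#'   if `out_shape` is given.
#' @param out_shape explicit output size `c(Hk, Wk)`.
#' @return one-hot mask `[Hk, Wk, C]`.
#' @export
downsample_gt <- function(g, factor = NULL, out_shape = NULL) {
  check_one_hot(g)
  d <- dim(g)
  if (is.null(out_shape)) {
    if (is.null(factor) || factor < 1 || factor != as.integer(factor))
      mv_error("mv_argument_error", "factor must be a positive integer")
    if (d[1] %% factor != 0 || d[2] %% factor != 0)
      mv_error("mv_argument_error", "factor must divide the mask height and width")
    out_shape <- d[1:2] %/% factor
  }
  ri <- floor((seq_len(out_shape[1]) - 1) * d[1] / out_shape[1]) + 1
  ci <- floor((seq_len(out_shape[2]) - 1) * d[2] / out_shape[2]) + 1
  g[ri, ci, , drop = FALSE]
}

#' Deep supervision loss
#'
#' Total loss = combined loss of the final output against the ground truth,
#' plus the unweighted sum of the combined losses of each intermediate output
#' against the ground truth downsampled (nearest neighbour) to its size.
#'
#' @param final probability map at full resolution `[H, W, C]`.
#' @param intermediates list of lower-resolution probability maps.
#' @param g one-hot ground truth at full resolution.
#' @param cfg a [loss_config()].
#' @return scalar total loss.
#' @export
deep_supervision_loss <- function(final, intermediates, g, cfg = loss_config()) {
  total <- combined_loss(final, g, cfg)
  for (psi in intermediates) {
    dk <- dim(psi)
    if (dk[3] != dim(g)[3])
      mv_error("mv_format_error", "intermediate output has wrong class count")
    gk <- downsample_gt(g, out_shape = dk[1:2])
    total <- total + combined_loss(psi, gk, cfg)
  }
  total
}

#' Dice score between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b logical/0-1 arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  if (!identical(as.integer(dim(a) %||% length(a)), as.integer(dim(b) %||% length(b))))
    mv_error("mv_format_error", "mask shapes differ")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Per-class segmentation metrics
#'
#' Binarizes prediction and ground truth at `class_id` and reports Dice,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and false positive rate
#' `FP/(FP+TN)`. Empty denominators yield 0 with an `undefined` attribute
#' naming the affected metrics.
#'
#' @param pred,gt label maps (equal shape).
#' @param class_id class value to evaluate.
#' @return named numeric vector `(dice, precision, recall, fpr)`.
#' @export
class_metrics <- function(pred, gt, class_id) {
  if (!identical(as.integer(dim(pred) %||% length(pred)),
                 as.integer(dim(gt) %||% length(gt))))
    mv_error("mv_format_error", "label map shapes differ")
  a <- pred == class_id; b <- gt == class_id
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b); tn <- sum(!a & !b)
  undef <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else { undef <- c(undef, "precision"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "recall"); 0 }
  fpr <- if (fp + tn > 0) fp / (fp + tn) else { undef <- c(undef, "fpr"); 0 }
  out <- c(dice = dice_score(a, b), precision = precision, recall = recall, fpr = fpr)
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Per-class metrics across a set of images
#'
#' Computes [class_metrics()] per image and class, then reports the per-image
#' mean and standard deviation for each class.
#'
#' @param preds,gts lists of label maps (paired by position).
#' @param classes integer class values to evaluate.
#' @param class_names optional names for the report rows.
#' @return data frame with one row per class: mean and SD of each metric.
#' @export
seg_metrics_table <- function(preds, gts, classes, class_names = NULL) {
  if (length(preds) != length(gts))
    mv_error("mv_argument_error", "preds and gts must have equal length")
  class_names <- class_names %||% as.character(classes)
  rows <- lapply(seq_along(classes), function(ci) {
    m <- t(vapply(seq_along(preds), function(i)
      class_metrics(preds[[i]], gts[[i]], classes[ci]), numeric(4)))
    data.frame(label = class_names[ci],
               dice_mean = mean(m[, 1]), dice_sd = sd(m[, 1]),
               precision_mean = mean(m[, 2]), precision_sd = sd(m[, 2]),
               recall_mean = mean(m[, 3]), recall_sd = sd(m[, 3]),
               fpr_mean = mean(m[, 4]), fpr_sd = sd(m[, 4]))
  })
  do.call(rbind, rows)
}
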