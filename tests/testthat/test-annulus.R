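# Annulus reconstruction: spline interpolation, sampling, tube voxelization,
# component post-processing, and the composed pipeline.

chord_param <- function(pts, closed) {
  if (closed) {
    seg <- sqrt(rowSums((rbind(pts[-1, ], pts[1, , drop = FALSE]) - pts)^2))
    tt <- c(0, cumsum(seg)); (tt / tt[length(tt)])[seq_len(nrow(pts))]
  } else {
    seg <- sqrt(rowSums(diff(pts)^2))
    c(0, cumsum(seg)) / sum(seg)
  }
}

test_that("zero-smoothing spline interpolates every control point", {
  for (n in c(4, 7, 12)) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    pts <- cbind(10 * cos(th), 10 * sin(th), 1.5 * cos(2 * th))
    s <- fit_spline(pts, smoothing = 0, closed = TRUE)
    got <- eval_spline(s, chord_param(pts, TRUE))
    expect_lt(max(abs(got - pts)), 1e-6)
  }
})

test_that("open spline through collinear points recovers the segment length", {
  pts <- cbind(seq(0, 9, length.out = 4), 0, 0)
  s <- fit_spline(pts, closed = FALSE)
  dense <- eval_spline(s, seq(0, 1, length.out = 4000))
  expect_lt(abs(sum(sqrt(rowSums(diff(dense)^2))) - 9), 1e-3)
})

test_that("degenerate control point sets are rejected", {
  pts <- cbind(seq(0, 9, length.out = 4), 0, 0)
  expect_error(fit_spline(pts, closed = TRUE), class = "mv_fit_error")        # collinear ring
  expect_error(control_point_set(pts[c(1, 2, 2, 3), ]), class = "mv_fit_error")  # duplicates
  expect_error(control_point_set(pts[1:3, ]), class = "mv_fit_error")         # too few
})

test_that("sample_spline returns the requested number of equally spaced samples", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- fit_spline(cbind(10 * cos(th), 10 * sin(th), 0), closed = TRUE)
  expect_equal(nrow(sample_spline(ring, 100L)$points), 100L)
  expect_error(sample_spline(ring, 1L), class = "mv_argument_error")
  # two samples on an open segment give its endpoints
  seg <- fit_spline(cbind(c(0, 1, 2, 3), 0, 0), closed = FALSE)
  expect_equal(sample_spline(seg, 2L)$points, cbind(c(0, 3), 0, 0), tolerance = 1e-9)
  # 100 samples around a circle recover the circumference to 0.5%
  len <- sum(sqrt(rowSums(diff(sample_spline(ring, 100L)$points)^2)))
  expect_lt(abs(len - 2 * pi * 10) / (2 * pi * 10), 0.005)
  # closed curves close exactly
  pts <- sample_spline(ring, 50L)$points
  expect_equal(pts[1, ], pts[50, ])
})

test_that("tube voxelization matches the analytic cylinder volume", {
  tmpl <- centered_template(80L, 0.4)
  seg <- cbind(seq(-10, 10, length.out = 50), 0, 0)
  mask <- voxelize_tube(seg, 1.5, tmpl)
  vol <- sum(mask) * 0.4^3
  expect_lt(abs(vol - pi * 1.5^2 * 20) / (pi * 1.5^2 * 20), 0.15)
})

test_that("tube voxelization is monotone in radius and respects bounds", {
  tmpl <- centered_template(48L, 0.5)
  th <- seq(0, 2 * pi, length.out = 33)
  ring <- cbind(8 * cos(th), 8 * sin(th), 0)
  m1 <- voxelize_tube(ring, 1.0, tmpl)
  m2 <- voxelize_tube(ring, 1.5, tmpl)
  expect_true(all(m2[m1]))
  # a closed tube is a single connected component
  expect_equal(sum(postprocess_components(m2, tmpl$affine)), sum(m2))
  # curve outside the grid
  far <- cbind(100 + 8 * cos(th), 8 * sin(th), 0)
  expect_error(voxelize_tube(far, 1.5, tmpl), class = "mv_bounds_error")
  # needle-thin tube warns about possible disconnection
  tmpl_odd <- centered_template(49L, 0.5)  # voxel centers on the world axes
  axis_seg <- cbind(c(-8, 8), 0, 0)
  expect_warning(m <- voxelize_tube(axis_seg, 0.2, tmpl_odd), "disconnected")
  expect_gt(sum(m), 0)
})

test_that("component post-processing keeps the significant highest-z component", {
  A <- diag(4)
  m <- array(FALSE, c(20, 20, 40))
  m[5:8, 5:8, 5:8] <- TRUE     # 64 voxels, mean z ~ 6.5
  one <- postprocess_components(m, A)
  expect_equal(sum(one), sum(m))  # single component: unchanged
  m[5:8, 5:8, 30:33] <- TRUE   # equal-size component at high z
  kept <- postprocess_components(m, A)
  expect_equal(sum(kept), 64L)
  expect_true(all(which(kept, arr.ind = TRUE)[, 3] >= 30))
  # a small speck at high z fails the 25% size gate
  m2 <- array(FALSE, c(20, 20, 40))
  m2[5:10, 5:10, 5:10] <- TRUE   # 216 voxels, low z
  m2[5, 5, 36:38] <- TRUE        # 3-voxel speck, high z
  kept2 <- postprocess_components(m2, A)
  expect_true(all(which(kept2, arr.ind = TRUE)[, 3] <= 10))
  expect_error(postprocess_components(array(FALSE, c(4, 4, 4)), A),
               class = "mv_empty_error")
})

test_that("reconstructed annulus overlaps the phantom annulus label (Dice >= 0.8)", {
  spec <- phantom_spec(voxel_spacing_mm = 0.4, grid_shape = 96)
  fr <- make_phantom_frame(spec, 0L)
  rec <- build_annulus_label(make_annulus_control_points(spec, 12L), fr)
  expect_gte(dice_score(rec$voxels == 3L, fr$voxels == 3L), 0.8)
  # leaflet labels are never overwritten
  expect_identical(rec$voxels %in% c(1L, 2L), fr$voxels %in% c(1L, 2L))
})

test_that("building on an empty template yields labels {0, 3} in one component", {
  spec <- tiny_spec()
  tmpl <- centered_template(56L, 0.5)
  out <- build_annulus_label(make_annulus_control_points(spec, 12L), tmpl)
  expect_setequal(unique(as.vector(out$voxels)), c(0L, 3L))
  m <- out$voxels == 3L
  expect_equal(sum(postprocess_components(m, tmpl$affine)), sum(m))
})
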