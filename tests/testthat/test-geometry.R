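# Per-frame geometry: skeletonization, centerline ordering, PCA plane,
# projection and effective orifice area.

test_that("skeleton of a circular tube hugs the analytic circle", {
  spec <- tiny_spec(saddle_height_mm = 0, tilt_deg = 0)
  fr <- make_phantom_frame(spec, 0L)
  skel <- skeletonize_annulus(fr)
  mask_n <- sum(fr$voxels == 3L)
  expect_lte(nrow(skel), 0.15 * mask_n)           # strong compression
  w <- t(fr$affine %*% t(cbind(skel - 1, 1)))[, 1:3]
  d <- sqrt((sqrt(w[, 1]^2 + w[, 2]^2) - spec$annulus_radius_mm)^2 + w[, 3]^2)
  expect_lt(max(d), 1.5 * max(spec$voxel_spacing_mm))
  # skeleton is contained in the mask
  expect_true(all(fr$voxels[skel] == 3L))
})

test_that("a single annulus voxel is its own skeleton; empty annulus errors", {
  vol <- centered_template(16L, 0.5)
  expect_error(skeletonize_annulus(vol), class = "mv_missing_annulus_error")
  vol$voxels[8, 8, 8] <- 3L
  expect_equal(skeletonize_annulus(vol)[, 1:3, drop = FALSE],
               matrix(c(8L, 8L, 8L), 1), ignore_attr = TRUE)
})

test_that("centerline ordering traverses a circle monotonically in angle", {
  set.seed(7)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- cbind(10 * cos(th), 10 * sin(th), 0)[sample(72), ]
  path <- order_centerline(pts)
  ang <- atan2(path$points[, 2], path$points[, 1])
  d <- diff(ang); d <- (d + pi) %% (2 * pi) - pi
  expect_true(all(d > 0) || all(d < 0))
  expect_true(path$closed)
  expect_equal(path$backtracks, 0L)
})

test_that("collinear points order endpoint-to-endpoint; tiny sets error", {
  pts <- cbind(c(6, 0, 4, 2), 0, 0)   # shuffled collinear points
  path <- order_centerline(pts)
  expect_equal(path$points[, 1], c(0, 2, 4, 6))
  expect_false(path$closed)
  expect_error(order_centerline(pts[1:2, ]), class = "mv_degenerate_error")
})

test_that("ordering logs a backtrack when forced to reverse direction", {
  # two arms meeting at the start point: finishing the second arm requires a
  # step against the travel direction
  pts <- cbind(c(0, 1, 2, 0, 0), c(0, 0, 0, 1, 2), 0)
  path <- order_centerline(pts)
  expect_equal(nrow(path$points), 5L)
  expect_gte(path$backtracks, 1L)
})

test_that("PCA plane is exact on a coplanar ring and accurate on a saddle", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  flat <- cbind(14 * cos(th), 14 * sin(th), 0)
  pl <- fit_valve_plane(flat)
  expect_gte(abs(sum(pl$normal * c(0, 0, 1))), 1 - 1e-9)
  expect_lt(max(abs(sweep(flat, 2, pl$centroid) %*% pl$normal)), 1e-9)
  # right-handed orthonormal frame
  B <- cbind(pl$basis_u, pl$basis_v, pl$normal)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-12)
  expect_equal(det(B), 1, tolerance = 1e-12)
  # saddle ring, h = 2 mm, R = 14 mm: normal within 2 degrees of the axis
  saddle <- cbind(14 * cos(th), 14 * sin(th), 2 * cos(2 * th))
  pls <- fit_valve_plane(saddle)
  ang <- acos(min(1, abs(sum(pls$normal * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 2)
  # permutation invariance
  pls2 <- fit_valve_plane(saddle[sample(180), ])
  expect_equal(abs(sum(pls$normal * pls2$normal)), 1, tolerance = 1e-9)
  expect_error(fit_valve_plane(cbind(1:5, 0, 0)), class = "mv_degenerate_error")
})

test_that("projected disc area matches the analytic disc", {
  vol <- centered_template(64L, 0.5)
  idx <- which(array(TRUE, dim(vol$voxels)), arr.ind = TRUE)
  w <- t(vol$affine %*% t(cbind(idx - 1, 1)))[, 1:3]
  disc <- sqrt(w[, 1]^2 + w[, 2]^2) <= 10 & abs(w[, 3]) < 0.3  # one voxel layer
  vol$voxels[idx[disc, ]] <- 1L
  proj <- project_to_plane(vol, axis_plane(), pixel_size_mm = 0.5)
  a <- structure_areas(proj)[["anterior"]]
  expect_lt(abs(a - pi * 100) / (pi * 100), 0.05)
})

test_that("a single labelled voxel projects to exactly one pixel region", {
  vol <- centered_template(16L, 0.5)
  vol$voxels[8, 8, 8] <- 1L
  proj <- project_to_plane(vol, axis_plane())
  expect_gt(sum(proj$rasters$anterior), 0)
  expect_equal(max(EBImage::bwlabel(proj$rasters$anterior)), 1)
  expect_equal(sum(proj$rasters$posterior), 0)
  expect_error(project_to_plane(centered_template(8L), axis_plane()),
               class = "mv_empty_error")
})

test_that("structure areas are pixel count times pixel area", {
  proj <- structure(list(
    rasters = list(anterior = matrix(c(rep(TRUE, 100), rep(FALSE, 44)), 12, 12),
                   posterior = matrix(FALSE, 12, 12)),
    pixel_size_mm = c(0.25, 0.25)), class = "planar_projection")
  expect_equal(structure_areas(proj),
               c(anterior = 100 * 0.0625, posterior = 0))
})

test_that("effective area recovers the analytic orifice of a phantom frame", {
  spec <- phantom_spec(orifice_radius_max_mm = 8)
  m <- quantify_frame(make_phantom_frame(spec, 8L), 8L)  # r(t) = 8 mm exactly
  expect_lt(abs(m$effective_area_mm2 - pi * 64) / (pi * 64), 0.07)
})

test_that("a fully closed orifice yields an effective area of at most 2 pixels", {
  spec <- tiny_spec(saddle_height_mm = 0, tilt_deg = 0)
  fr <- make_phantom_frame(spec, 0L)
  idx <- which(fr$voxels == 0L, arr.ind = TRUE)
  w <- t(fr$affine %*% t(cbind(idx - 1, 1)))[, 1:3]
  plug <- sqrt(w[, 1]^2 + w[, 2]^2) < orifice_radius(spec, 0) + 0.5 & abs(w[, 3]) <= 0.5
  fr$voxels[idx[plug, , drop = FALSE]] <- 1L
  m <- quantify_frame(fr)
  expect_lte(m$effective_area_mm2, 2 * 0.25^2)
})

test_that("effective area grows when the leaflets are eroded", {
  fr <- tiny_sequence()$frames[[3]]
  m0 <- quantify_frame(fr, 2L)
  # erode the leaflets by one voxel (6-neighbourhood)
  leaf <- fr$voxels %in% c(1L, 2L); dim(leaf) <- dim(fr$voxels)
  shrink <- leaf
  d <- dim(leaf)
  shift <- function(m, s) {
    out <- array(FALSE, dim(m))
    src <- lapply(seq_along(d), function(k) pmin(pmax(seq_len(d[k]) + s[k], 1), d[k]))
    out[] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    shrink <- shrink & shift(leaf, s)
  er <- fr
  er$voxels[leaf & !shrink] <- 0L
  m1 <- quantify_frame(er, 2L)
  expect_gte(m1$effective_area_mm2, m0$effective_area_mm2)
})

test_that("an annulus ring with a large gap raises an open-ring error", {
  spec <- tiny_spec(saddle_height_mm = 0, tilt_deg = 0)
  fr <- make_phantom_frame(spec, 0L)
  idx <- which(fr$voxels == 3L, arr.ind = TRUE)
  w <- t(fr$affine %*% t(cbind(idx - 1, 1)))[, 1:3]
  cut <- atan2(w[, 2], w[, 1]) > 0  # remove half the ring (gap >> closing radius)
  fr$voxels[idx[cut, , drop = FALSE]] <- 0L
  plane <- axis_plane()
  proj <- project_to_plane(fr, plane)
  err <- tryCatch(effective_area(proj), mv_open_ring_error = function(e) e)
  expect_s3_class(err, "mv_open_ring_error")
  expect_gt(err$gap_mm, 3 * 1.5)
})

test_that("structure areas and effective area are stable under a 30 degree tilt", {
  m0 <- quantify_frame(make_phantom_frame(tiny_spec(), 4L), 4L)
  m30 <- quantify_frame(make_phantom_frame(tiny_spec(tilt_deg = 30), 4L), 4L)
  rel <- abs(m30$structure_areas_mm2 - m0$structure_areas_mm2) / m0$structure_areas_mm2
  expect_true(all(rel <= 0.05))
  expect_lte(abs(m30$effective_area_mm2 - m0$effective_area_mm2) /
             m0$effective_area_mm2, 0.05)
})
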