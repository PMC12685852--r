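# Segmentation objectives: brute-force per-pixel oracles, analytic scalar
# cases, downsampling, metrics and a descent sanity check.

brute_gdl <- function(p, g, eps = 1e-6) {
  d <- dim(p); terms <- numeric(0)
  for (cc in seq_len(d[3])) {
    si <- 0; sp <- 0; sg <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      si <- si + p[i, j, cc] * g[i, j, cc]
      sp <- sp + p[i, j, cc]; sg <- sg + g[i, j, cc]
    }
    if (sg > 0) terms <- c(terms, (2 * si + eps) / (sp + sg + eps))
  }
  1 - mean(terms)
}

brute_focal <- function(p, g, gamma = 2, clip = 1e-7) {
  d <- dim(p); tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (cc in seq_len(d[3])) {
    pc <- min(max(p[i, j, cc], clip), 1 - clip)
    tot <- tot + (1 - pc)^gamma * g[i, j, cc] * (-log(pc))
  }
  tot / (d[1] * d[2])
}

test_that("losses match brute-force per-pixel summation to 1e-9", {
  set.seed(3)
  for (rep in 1:3) {
    H <- sample(5:12, 1); W <- sample(5:12, 1); C <- sample(c(3, 11), 1)
    p <- random_prob_map(H, W, C)
    g <- random_one_hot(H, W, C)
    expect_equal(generalized_dice_loss(p, g), brute_gdl(p, g), tolerance = 1e-9)
    expect_equal(focal_loss(p, g), brute_focal(p, g), tolerance = 1e-9)
    expect_equal(combined_loss(p, g),
                 (brute_gdl(p, g) + brute_focal(p, g)) / 2, tolerance = 1e-9)
  }
})

test_that("analytic scalar cases evaluate exactly", {
  C <- 11; H <- 8; W <- 8
  p <- array(1 / C, c(H, W, C))
  g <- array(0, c(H, W, C)); g[, , 1] <- 1
  # analytic values hold up to the epsilon guard in the Dice denominator
  expect_equal(generalized_dice_loss(p, g), 5 / 6, tolerance = 1e-6)
  expect_equal(focal_loss(p, g), (10 / 11)^2 * log(11), tolerance = 1e-9)
  expect_equal(combined_loss(p, g), (5 / 6 + (10 / 11)^2 * log(11)) / 2,
               tolerance = 1e-6)
  # perfect prediction: all losses vanish
  expect_lt(combined_loss(g, g), 1e-6)
  # gamma = 0 reduces the focal loss to mean cross-entropy
  set.seed(8)
  pr <- random_prob_map(6, 6, 4); gr <- random_one_hot(6, 6, 4)
  ce <- -mean(apply(pr * gr, c(1, 2), sum) |> log())
  expect_equal(focal_loss(pr, gr, loss_config(gamma = 0)), ce, tolerance = 1e-9)
})

test_that("a class absent from the image does not change the Dice loss", {
  set.seed(5)
  p <- random_prob_map(6, 6, 2)
  g <- random_one_hot(6, 6, 2)
  # extend the legend with an absent class: zero probability, zero ground truth
  p3 <- array(0, c(6, 6, 3)); p3[, , 1:2] <- p
  g3 <- array(0, c(6, 6, 3)); g3[, , 1:2] <- g
  expect_equal(generalized_dice_loss(p3, g3), generalized_dice_loss(p, g),
               tolerance = 1e-12)
  empty <- array(0, c(6, 6, 3))
  expect_error(generalized_dice_loss(p3, empty), class = "mv_format_error")
})

test_that("nearest-neighbour downsampling preserves one-hot structure", {
  set.seed(9)
  g <- random_one_hot(16, 16, 5)
  expect_identical(downsample_gt(g, 1L), g)
  const <- one_hot(matrix(2L, 8, 8), 1:4)
  expect_equal(downsample_gt(const, 4L), one_hot(matrix(2L, 2, 2), 1:4))
  # index-arithmetic oracle: output pixel = source at floor(out_idx * scale)
  for (f in c(2L, 4L)) {
    dn <- downsample_gt(g, f)
    expect_true(all(apply(dn, c(1, 2), sum) == 1))
    for (i in seq_len(16 %/% f)) for (j in seq_len(16 %/% f))
      expect_equal(dn[i, j, ], g[(i - 1) * f + 1, (j - 1) * f + 1, ])
  }
  expect_error(downsample_gt(g, 3L), class = "mv_argument_error")
})

test_that("deep supervision equals the sum of per-scale combined losses", {
  set.seed(13)
  C <- 11
  g <- random_one_hot(16, 16, C)
  final <- random_prob_map(16, 16, C)
  ints <- list(random_prob_map(8, 8, C), random_prob_map(4, 4, C),
               random_prob_map(2, 2, C))
  manual <- combined_loss(final, g) +
    combined_loss(ints[[1]], downsample_gt(g, 2L)) +
    combined_loss(ints[[2]], downsample_gt(g, 4L)) +
    combined_loss(ints[[3]], downsample_gt(g, 8L))
  expect_equal(deep_supervision_loss(final, ints, g), manual, tolerance = 1e-9)
  # empty intermediate list reduces to the combined loss
  expect_equal(deep_supervision_loss(final, list(), g), combined_loss(final, g))
  # perfect predictions at all scales give zero
  perf <- deep_supervision_loss(g, list(downsample_gt(g, 2L),
                                        downsample_gt(g, 4L),
                                        downsample_gt(g, 8L)), g)
  expect_lt(perf, 1e-5)
})

test_that("Dice score identities hold", {
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, !a), 0)
  b <- matrix(FALSE, 10, 10); b[3:7, ] <- TRUE    # |A|=|B|=50, overlap 30
  expect_equal(dice_score(a, b), 2 * 30 / 100)
  expect_equal(dice_score(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice_score(a, matrix(FALSE, 9, 9)), class = "mv_format_error")
})

test_that("class metrics equal a confusion-matrix enumeration", {
  set.seed(21)
  pred <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64, 64)
  gt <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64, 64)
  for (cl in 0:3) {
    tp <- sum(pred == cl & gt == cl); fp <- sum(pred == cl & gt != cl)
    fn <- sum(pred != cl & gt == cl); tn <- sum(pred != cl & gt != cl)
    m <- class_metrics(pred, gt, cl)
    expect_equal(as.numeric(m),
                 c(2 * tp / (2 * tp + fp + fn), tp / (tp + fp),
                   tp / (tp + fn), fp / (fp + tn)))
  }
  perfect <- class_metrics(gt, gt, 2L)
  expect_equal(as.numeric(perfect), c(1, 1, 1, 0))
  none <- class_metrics(matrix(0L, 4, 4), matrix(c(1L, rep(0L, 15)), 4, 4), 1L)
  expect_equal(none[["recall"]], 0)
  expect_equal(none[["fpr"]], 0)
  tab <- seg_metrics_table(list(gt, pred), list(gt, gt), 0:3)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$dice_mean >= 0 & tab$dice_mean <= 1))
})

test_that("one gradient step on the combined loss decreases it", {
  set.seed(17)
  C <- 3; H <- 4; W <- 4
  g <- random_one_hot(H, W, C)
  z <- array(stats::rnorm(H * W * C, sd = 0.01), c(H, W, C))  # near-uniform logits
  softmax <- function(z) {
    e <- exp(z - array(rep(apply(z, c(1, 2), max), C), dim(z)))
    e / array(rep(apply(e, c(1, 2), sum), C), dim(z))
  }
  f <- function(z) combined_loss(softmax(z), g)
  l0 <- f(z)
  grad <- array(0, dim(z))
  h <- 1e-5
  for (t in seq_len(length(z))) {
    zp <- z; zp[t] <- zp[t] + h
    zm <- z; zm[t] <- zm[t] - h
    grad[t] <- (f(zp) - f(zm)) / (2 * h)
  }
  l1 <- f(z - 0.1 * grad / max(abs(grad)))
  expect_lt(l1, l0)
})
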