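test_that("quadratic fold fit reproduces exact and least-squares solutions", {
  x <- 1:10
  p <- fit_fold_polynomial(data.frame(x = x, y = 1 + 2 * x + 3 * x^2))
  expect_equal(unname(p$coef), c(1, 2, 3), tolerance = 1e-9)
  expect_lt(p$rms, 1e-9)

  p3 <- fit_fold_polynomial(data.frame(x = c(0, 1, 3), y = c(2, 0, 5)))
  expect_lt(p3$rms, 1e-9)  # three points: exact interpolation

  set.seed(41)
  x <- runif(50, 0, 100)
  y <- 5 - 0.3 * x + 0.01 * x^2 + rnorm(50)
  p2 <- fit_fold_polynomial(data.frame(x = x, y = y))
  expect_equal(unname(p2$coef), quad_fit_brute(x, y), tolerance = 1e-6)

  expect_error(fit_fold_polynomial(data.frame(x = c(1, 1, 1), y = 1:3)),
               class = "thermaseg_degenerate_input")
})

test_that("fold intersection finds the root nearest the midline", {
  mk <- function(a0, a1, a2) {
    structure(list(coef = c(a0 = a0, a1 = a1, a2 = a2), rms = 0, n = 3L),
              class = "polynomial2")
  }
  # y = x^2 and y = (x - 10)^2 cross at x = 5 by symmetry
  s <- intersect_folds(mk(0, 0, 1), mk(100, -20, 1), x_range = c(0, 10))
  expect_equal(s$x, 5)
  expect_equal(s$y, 25)
  expect_false(s$low_confidence)

  # identical polynomials: no crossing, midline fallback is flagged
  s2 <- intersect_folds(mk(1, 2, 3), mk(1, 2, 3), x_range = c(0, 10))
  expect_true(s2$low_confidence)
  expect_equal(s2$x, 5)

  # random pairs vs a dense grid scan of |p_r - p_l|
  set.seed(42)
  for (rep in 1:10) {
    pr <- mk(runif(1, 100, 200), runif(1, -1, 1), -runif(1, 0.01, 0.05))
    pl <- mk(runif(1, 100, 200), runif(1, -1, 1), -runif(1, 0.01, 0.05))
    xr <- c(0, 300)
    grid <- seq(xr[1], xr[2], by = 0.001)
    d <- abs((pr$coef[1] - pl$coef[1]) + (pr$coef[2] - pl$coef[2]) * grid +
               (pr$coef[3] - pl$coef[3]) * grid^2)
    s3 <- intersect_folds(pr, pl, xr)
    if (!s3$low_confidence) {
      roots <- grid[d < 0.005]
      expect_true(min(abs(roots - s3$x)) < 0.01)
    } else {
      expect_gt(min(d), 0)  # fallback only when no root is in range
    }
  }
})

test_that("fold candidates track the phantom ridge curves", {
  ph <- generate_phantom(phantom_spec(seed = 43))
  body <- extract_body_mask(ph$thermogram)
  ev <- detect_fold_candidates(ph$thermogram, body)
  for (side in c("right", "left")) {
    pts <- ev[[side]]
    truth <- ph$truth$ridge_curves[[side]]
    yt <- truth$y[match(pts$x, truth$x)]
    keep <- !is.na(yt)
    expect_gt(sum(keep), 20)
    rms <- sqrt(mean((pts$y[keep] - yt[keep])^2))
    expect_lt(rms, 2)
  }
})

test_that("an excessive fold offset fails cleanly", {
  ph <- generate_phantom(phantom_spec(seed = 44))
  body <- extract_body_mask(ph$thermogram)
  expect_error(detect_fold_candidates(ph$thermogram, body, offset = 300),
               class = "thermaseg_segmentation_failed")
})

test_that("the thick fold outranks a thin hot line in the distance-transform ranking", {
  g <- matrix(40L, 120, 200)
  body <- matrix(TRUE, 120, 200)
  # right half: thick band (fold) and a 1-px bright line, same intensity
  g[80:88, 20:80] <- 250L      # thick fold, interior distance ~4 px
  g[30, 10:90] <- 250L         # thin vessel-like line
  # left half needs a candidate too
  g[80:88, 120:180] <- 250L
  tg <- thermogram(g, radiometric_meta(24, 36))
  ev <- detect_fold_candidates(tg, body, offset = 10, smooth = FALSE)
  expect_true(all(ev$right$y >= 79))   # ridge points come from the band
  expect_false(any(ev$right$y == 30))
})

test_that("two-point secant slopes are exact on straight contours", {
  # a linear profile f(y) = 2y sampled as contour columns
  xs <- 2 * (1:50)
  s <- thermaseg:::two_point_slopes(xs, h = 10)
  expect_true(all(abs(s - 2) < 1e-12))
})

test_that("armpit points sit at the silhouette slope break", {
  ph <- generate_phantom(phantom_spec(seed = 45))
  body <- extract_body_mask(ph$thermogram)
  ap <- find_armpit_points(body, fold_y = ph$truth$split$y)
  for (side in c("right", "left")) {
    truth <- ph$truth$armpit_points[[side]]
    expect_lte(max(abs(ap[[side]] - truth)), 3)
  }
  expect_false(ap$low_confidence)
})

test_that("a straight-sided silhouette gives no confident armpit", {
  body <- matrix(FALSE, 100, 80)
  body[10:90, 20:60] <- TRUE
  ap <- find_armpit_points(body, fold_y = 80)
  expect_true(ap$low_confidence)
  expect_error(find_armpit_points(body, fold_y = 15),
               class = "thermaseg_segmentation_failed")  # contour < 2h + 1
})

test_that("assembled masks recover the phantom breasts", {
  ph <- generate_phantom(phantom_spec(seed = 46))
  seg <- segment_breasts(ph$thermogram)
  expect_gte(iou(seg$right_mask, ph$truth$right_breast_mask), 0.70)
  expect_gte(iou(seg$left_mask, ph$truth$left_breast_mask), 0.70)
  # disjoint, inside the body
  expect_false(any(seg$right_mask & seg$left_mask))
  expect_true(all(seg$body$mask[seg$right_mask | seg$left_mask]))
  # strict side convention around the split column
  expect_true(all(col(seg$right_mask)[seg$right_mask] < seg$split$x))
  expect_true(all(col(seg$left_mask)[seg$left_mask] > seg$split$x))
  # symmetric phantom: mirrored pixel counts within 5%
  expect_lt(abs(sum(seg$right_mask) - sum(seg$left_mask)) /
              sum(seg$right_mask), 0.05)
})

test_that("a split point outside the body is rejected", {
  ph <- generate_phantom(phantom_spec(seed = 47))
  seg <- segment_breasts(ph$thermogram)
  bad_split <- list(x = 2, y = 2, low_confidence = FALSE)
  expect_error(
    assemble_breast_masks(seg$body, seg$fold_right, seg$fold_left,
                          bad_split, seg$armpits),
    class = "thermaseg_segmentation_failed"
  )
})

test_that("mirroring the thermogram swaps the left and right masks exactly", {
  ph <- generate_phantom(phantom_spec(
    seed = 48, lesion = list(side = "left", dt = 2, radius = 9)))
  tg <- ph$thermogram
  tgm <- thermogram(mirror_cols(tg$pixels), tg$meta)
  seg <- segment_breasts(tg)
  segm <- segment_breasts(tgm)
  expect_identical(seg$right_mask, mirror_cols(segm$left_mask))
  expect_identical(seg$left_mask, mirror_cols(segm$right_mask))
})
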