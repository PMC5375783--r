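test_that("gray-to-temperature mapping hits both endpoints and the midpoint", {
  meta <- radiometric_meta(24.04, 36.5)
  tg <- thermogram(matrix(c(0L, 128L, 255L, 64L), 2, 2), meta)
  th <- to_thermal(tg)
  expect_equal(th$temps[1, 1], 24.04)                    # gray 0 -> t_min
  expect_equal(th$temps[1, 2], 36.5)                     # gray Tvgm -> t_max
  expect_equal(th$temps[2, 1], 24.04 + (128 / 255) * (36.5 - 24.04))

  # Tvgm is the max gray PRESENT, not L - 1
  tg2 <- thermogram(matrix(c(0L, 100L), 1, 2), meta)
  expect_equal(to_thermal(tg2)$temps[1, 2], 36.5)
})

test_that("the thermal map is affine and strictly order-preserving", {
  meta <- radiometric_meta(20, 40)
  set.seed(11)
  for (rep in 1:20) {
    tg <- random_thermogram(8, 8, meta)
    th <- to_thermal(tg)
    o <- order(as.vector(tg$pixels))
    expect_true(all(diff(as.vector(th$temps)[o]) >= 0))
    g <- as.vector(tg$pixels); t <- as.vector(th$temps)
    expect_true(all(abs(diff(t[o]) - diff(g[o]) / max(g) * 20) < 1e-9))
    expect_equal(max(th$temps), 40)
    if (any(g == 0)) expect_equal(min(th$temps), 20)
  }
})

test_that("an all-zero image has no thermal scale", {
  tg <- thermogram(matrix(0L, 3, 3), radiometric_meta(24, 36))
  expect_error(to_thermal(tg), class = "thermaseg_degenerate_input")
})

test_that("region statistics match a brute-force pixel loop", {
  m <- matrix(c(25, 27, 99, 99), 2, 2)
  s <- region_stats(m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(s$avg, 26); expect_equal(s$max, 27)
  expect_equal(s$min, 25); expect_equal(s$sd, 1); expect_equal(s$pixel_count, 2)

  s2 <- region_stats(matrix(30, 4, 4), matrix(TRUE, 4, 4))
  expect_equal(s2$avg, 30); expect_equal(s2$sd, 0)
  expect_equal(s2$max, s2$min)

  set.seed(5)
  for (rep in 1:10) {
    t <- matrix(runif(25, 20, 40), 5, 5)
    mask <- matrix(runif(25) < 0.5, 5, 5)
    if (!any(mask)) mask[1, 1] <- TRUE
    expect_equal(unclass(region_stats(t, mask))[1:5], region_stats_brute(t, mask))
  }
  expect_error(region_stats(m, matrix(FALSE, 2, 2)),
               class = "thermaseg_degenerate_input")
})

test_that("spot size reproduces the sensor optics and scales linearly", {
  expect_equal(spot_size(1.36, 1.2), 0.001632)
  expect_equal(spot_size(1.36, 1.2, 3), 0.004896)  # ~0.5 cm MFOV spot
  set.seed(3)
  for (rep in 1:10) {
    i <- runif(1, 0.5, 3); d <- runif(1, 0.5, 3); k <- sample(1:4, 1)
    expect_equal(spot_size(2 * i, d, k), 2 * spot_size(i, d, k))
    expect_equal(spot_size(i, 2 * d, k), 2 * spot_size(i, d, k))
  }
  expect_error(spot_size(1.36, 0), class = "thermaseg_degenerate_input")
  expect_error(spot_size(-1, 1.2), class = "thermaseg_degenerate_input")
})

test_that("stabilization time is found by scanning successive slopes", {
  # exponential skin-temperature decay; oracle scan over slopes
  tt <- seq(0, 45, by = 5)
  temp <- 33 + 4 * exp(-tt / 12)
  tol <- 0.05
  slopes <- abs(diff(temp) / diff(tt))
  expected <- tt[which(rev(cumprod(rev(slopes <= tol))) == 1)[1]]
  expect_equal(stabilization_time(tt, temp, tol), expected)
  expect_equal(expected, 25)  # decay constant chosen to stabilize at 25 min

  expect_equal(stabilization_time(c(0, 5, 10), c(34, 34, 34), tol), 0)
  expect_equal(stabilization_time(c(0, 5, 10), c(36, 34, 32), tol), Inf)
  expect_error(stabilization_time(c(0, 5), c(36, 34)),
               class = "thermaseg_degenerate_input")
  expect_error(stabilization_time(c(0, 10, 5), c(36, 34, 33)),
               class = "thermaseg_degenerate_input")
})
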