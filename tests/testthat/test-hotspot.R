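# Smooth two-peak temperature field used across several tests.
two_peak_field <- function(nr = 60, nc = 120, a1 = 3, a2 = 3,
                           c1 = c(30, 30), c2 = c(30, 90), s2 = 60) {
  r <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  30 + a1 * exp(-((r - c1[1])^2 + (cc - c1[2])^2) / s2) +
    a2 * exp(-((r - c2[1])^2 + (cc - c2[2])^2) / s2)
}

test_that("two hot peaks yield two basins split between the peaks", {
  t <- two_peak_field()
  ws <- watershed_segment(t, matrix(TRUE, 60, 120), delta = 0.5)
  expect_equal(length(ws$basin_ids), 2L)
  expect_true(ws$labels[30, 30] != ws$labels[30, 90])
  expect_true(all(ws$labels[30, c(30, 90)] > 0))
  # the dividing line runs near the mid-column between the peaks
  line_cols <- col(ws$lines)[ws$lines]
  expect_lt(abs(mean(line_cols) - 60), 2)
  # lines and basins tile the mask
  expect_true(all((ws$labels > 0) | ws$lines | !ws$mask))
  expect_false(any(ws$lines & ws$labels > 0))
})

test_that("a constant region is a single basin without lines", {
  ws <- watershed_segment(matrix(31.5, 20, 30), matrix(TRUE, 20, 30))
  expect_equal(length(ws$basin_ids), 1L)
  expect_false(any(ws$lines))
  expect_true(all(ws$labels == 1))
})

test_that("peaks shallower than the suppression depth are merged", {
  t <- two_peak_field(a1 = 3, a2 = 3)
  # third peak of prominence 0.3 < delta = 0.5
  r <- row(t); cc <- col(t)
  t <- t + 0.3 * exp(-((r - 45)^2 + (cc - 60)^2) / 30)
  ws <- watershed_segment(t, matrix(TRUE, nrow(t), ncol(t)), delta = 0.5)
  expect_equal(length(ws$basin_ids), 2L)
  # with a smaller depth it separates
  ws2 <- watershed_segment(t, matrix(TRUE, nrow(t), ncol(t)), delta = 0.1)
  expect_equal(length(ws2$basin_ids), 3L)
})

test_that("basin count is non-increasing in the suppression depth", {
  set.seed(61)
  t <- two_peak_field(a1 = 2, a2 = 2.5)
  r <- row(t); cc <- col(t)
  for (k in 1:4) {
    t <- t + runif(1, 0.2, 1.5) *
      exp(-((r - runif(1, 10, 50))^2 + (cc - runif(1, 10, 110))^2) / 40)
  }
  mask <- matrix(TRUE, nrow(t), ncol(t))
  counts <- vapply(c(0.05, 0.2, 0.5, 1, 2, 4),
                   function(d) length(watershed_segment(t, mask, d)$basin_ids),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the hotspot basin contains the global temperature maximum", {
  t <- two_peak_field(a1 = 2, a2 = 3.5)   # right peak hotter
  mask <- matrix(TRUE, 60, 120)
  ws <- watershed_segment(t, mask, delta = 0.5)
  hs <- locate_hotspot(t, ws)
  expect_equal(hs$basin_id, ws$labels[30, 90])
  expect_true(hs$contains_global_max)
  expect_equal(hs$max_temp, max(t[ws$labels > 0]))
  # elevation-weighted centroid sits near the hot peak
  expect_lt(abs(hs$centroid[["x"]] - 90), 3)
  expect_lt(abs(hs$centroid[["y"]] - 30), 3)

  # single basin: centroid is the weighted centroid of the whole mask
  ws1 <- watershed_segment(t, mask, delta = 10)
  expect_equal(length(ws1$basin_ids), 1L)
  hs1 <- locate_hotspot(t, ws1)
  w <- t[mask] - min(t[mask])
  expect_equal(hs1$centroid[["x"]], sum(w * col(t)[mask]) / sum(w))
})

test_that("shape descriptors separate compact from vessel-like basins", {
  # compact hot disk, analysed over its own mask
  m <- matrix(25, 80, 80)
  d2 <- (row(m) - 40)^2 + (col(m) - 40)^2
  m[d2 <= 15^2] <- 30
  ws <- watershed_segment(m, d2 <= 15^2, delta = 0.5)
  hs <- locate_hotspot(m, ws)
  disk <- describe_pattern(ws, hs$basin_id)
  expect_lt(disk$eccentricity, 0.3)

  # 1-px-wide gently curved hot line (vessel-like)
  m2 <- matrix(25, 80, 80)
  arc_mask <- matrix(FALSE, 80, 80)
  xs <- 10:70
  pts <- unique(cbind(round(30 + 0.005 * (xs - 40)^2), xs))
  m2[pts] <- 30
  arc_mask[pts] <- TRUE
  ws2 <- watershed_segment(m2, arc_mask, delta = 0.5)
  hs2 <- locate_hotspot(m2, ws2)
  arc <- describe_pattern(ws2, hs2$basin_id)
  expect_gt(arc$elongation, 5)
  expect_gt(arc$elongation, disk$elongation)
})
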