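test_that("the same seed reproduces the phantom bit for bit", {
  a <- generate_phantom(phantom_spec(seed = 71))
  b <- generate_phantom(phantom_spec(seed = 71))
  expect_identical(a$thermogram$pixels, b$thermogram$pixels)
  expect_identical(a$thermal, b$thermal)
  c <- generate_phantom(phantom_spec(seed = 72))
  expect_false(identical(a$thermogram$pixels, c$thermogram$pixels))
})

test_that("quantization round-trips within half a gray step", {
  ph <- generate_phantom(phantom_spec(seed = 73))
  rec <- to_thermal(ph$thermogram)$temps
  step <- (ph$thermogram$meta$t_max_c - ph$thermogram$meta$t_min_c) / 255
  expect_lt(max(abs(rec - ph$thermal)), step / 2 + 1e-9)
})

test_that("truth masks are mutually consistent", {
  ph <- generate_phantom(phantom_spec(
    seed = 74, lesion = list(side = "left", dt = 2, radius = 8)))
  tr <- ph$truth
  expect_false(any(tr$right_breast_mask & tr$left_breast_mask))
  expect_true(all(tr$body_mask[tr$right_breast_mask | tr$left_breast_mask]))
  expect_true(all(tr$body_mask[tr$lesion_mask]))
  # the lesion sits in the declared breast
  expect_gte(mean(tr$left_breast_mask[tr$lesion_mask]), 0.95)
  expect_false(any(tr$right_breast_mask & tr$lesion_mask))
})

test_that("a noiseless lesion phantom is flagged with the correct hotter side", {
  ph <- generate_phantom(phantom_spec(
    seed = 75, noise_sd = 0,
    lesion = list(side = "right", dt = 2.0, radius = 9)))
  expect_equal(ph$truth$expected_verdict, "problem_detected")
  rep <- analyze_thermogram(ph$thermogram)
  expect_equal(rep$status, "problem")
  expect_gt(rep$evaluation$diff_avg, 0)
  expect_equal(rep$evaluation$hotter_side, "right")
})

test_that("a noiseless symmetric phantom is nearly perfectly balanced", {
  ph <- generate_phantom(phantom_spec(seed = 76, noise_sd = 0))
  expect_equal(ph$truth$expected_verdict, "no_problem")
  rep <- analyze_thermogram(ph$thermogram)
  expect_equal(rep$status, "no_problem")
  expect_lt(rep$evaluation$diff_avg, 0.1)
  expect_null(rep$hotspot)
})

test_that("detected asymmetry grows with the lesion contrast", {
  diffs <- vapply(c(1.5, 2.2, 3.0), function(dt) {
    ph <- generate_phantom(phantom_spec(
      seed = 77, lesion = list(side = "left", dt = dt, radius = 9)))
    analyze_thermogram(ph$thermogram)$evaluation$diff_avg
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(background_t = 35, body_t = 30),
               class = "thermaseg_degenerate_input")
  expect_error(phantom_spec(lesion = list(side = "left", dt = 2, radius = 1)),
               class = "thermaseg_degenerate_input")
  expect_error(
    generate_phantom(phantom_spec(
      seed = 1, lesion = list(side = "left", dt = 2, radius = 8,
                              center = c(x = 2, y = 2)))),
    class = "thermaseg_degenerate_input"
  )
})

test_that("a tiny sweep produces a coherent case table", {
  sw <- phantom_sweep(4, seed = 5)
  expect_equal(nrow(sw$cases), 4L)
  expect_equal(sum(sw$table), 4)
  expect_true(all(sw$cases$predicted %in% c("healthy", "sick", "unknown")))
  # row sums match class totals
  expect_equal(as.numeric(rowSums(sw$table)),
               as.numeric(table(factor(sw$cases$truth, c("healthy", "sick")))))
})
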