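# Voxel volumetrics and the calculated-vs-measured error analysis.

test_that("measured volume is voxel count times voxel volume", {
  # 1000 supra-threshold voxels at 0.5 mm isotropic -> 125 mm^3
  arr <- array(0, c(20, 10, 10))
  arr[seq_len(1000)] <- 200
  expect_equal(measure_volume(arr, threshold = 150, voxel_size = 0.5),
               125)
  # noiseless image of a rasterized 5 mm sphere at 0.2 mm voxels
  plan <- trajectory_plan(c(0, 0, 40), c(0, 0, 0), 0L)
  est <- compose_plan(plan, 5)          # n = 0: hemisphere only
  cx <- seq(-6, 6, by = 0.2)
  X <- array(cx, c(61, 61, 61))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  sphere <- X^2 + Y^2 + Z^2 <= 25
  img <- make_postop_image(sphere, voxel_size = 0.2, contrast = 100,
                           noise_sd = 0)
  v <- measure_volume(img)
  expect_lt(abs(v - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.01)
})

test_that("measured volume is monotone non-increasing in threshold", {
  set.seed(3)
  arr <- array(stats::rnorm(8000, 100, 30), c(20, 20, 20))
  vols <- vapply(seq(40, 180, by = 20), function(th)
    suppressWarnings(measure_volume(arr, th, voxel_size = 1)),
    numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("percentage error uses the calculated-volume denominator", {
  expect_equal(percentage_error(100, 100), 0)
  expect_equal(percentage_error(1867.87, 1841), 1.4)
  expect_equal(percentage_error(100, 90), 10.0)
  expect_error(percentage_error(0, 10), "undefined")
  # scale invariance on the unrounded value
  e1 <- percentage_error(123.4, 111.1, digits = NULL)
  e2 <- percentage_error(123.4 * 7, 111.1 * 7, digits = NULL)
  expect_equal(e1, e2)
})

test_that("error summaries give mean and n-1 standard deviation", {
  expect_equal(summarize_errors(c(5, 5, 5)), c(mean = 5, sd = 0))
  expect_equal(summarize_errors(c(1, 2, 3)), c(mean = 2, sd = 1))
  expect_equal(summarize_errors(4.2), c(mean = 4.2, sd = 0))
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("published volume series summarizes to 2.3 +/- 0.9", {
  cases <- reference_cases()
  pe <- percentage_error(cases$v_calc, cases$v_meas, digits = NULL)
  expect_equal(round(pe, 3), c(2.238, 1.439, 3.326))
  expect_equal(summarize_errors(pe), c(mean = 2.3, sd = 0.9))
  rep <- volume_report(cases$case_id, cases$v_calc, cases$v_meas)
  expect_equal(rep$cases$pct_error, c(2.2, 1.4, 3.3))
  expect_equal(rep$mean_error, 2.3)
  expect_output(print(rep), "mean error: 2.3")
})
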