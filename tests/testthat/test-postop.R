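# Synthetic post-ablation images: threshold recovery, determinism,
# noise behaviour.

ball_mask <- function(n = 24, radius = 8) {
  cx <- (n + 1) / 2
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  array(with(idx, (i - cx)^2 + (j - cx)^2 + (k - cx)^2) <= radius^2,
        dim = c(n, n, n))
}

test_that("noiseless midpoint threshold recovers the mask exactly", {
  m <- ball_mask()
  img <- make_postop_image(m, voxel_size = 1, contrast = 100,
                           noise_sd = 0)
  rec <- img$intensities >= img$background + img$contrast / 2
  expect_identical(as.vector(rec), as.vector(m))
  expect_equal(measure_volume(img), sum(m))
})

test_that("image generation is seed-deterministic and RNG-clean", {
  m <- ball_mask(16, 5)
  a <- make_postop_image(m, 1, contrast = 100, noise_sd = 10, seed = 7)
  b <- make_postop_image(m, 1, contrast = 100, noise_sd = 10, seed = 7)
  d <- make_postop_image(m, 1, contrast = 100, noise_sd = 10, seed = 8)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, d$intensities))
  # caller's RNG stream is untouched
  set.seed(123); x1 <- rnorm(3)
  set.seed(123); invisible(
    make_postop_image(m, 1, noise_sd = 10, seed = 7)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("misclassification at a 5-sigma contrast gap is negligible", {
  # 1000 lesion voxels, contrast 100, sd 10: Gaussian tail beyond 5 sd
  # predicts a misclassification rate ~3e-7, i.e. << 1e-4
  m <- array(FALSE, c(30, 30, 30))
  set.seed(1)
  m[sample.int(27000, 1000)] <- TRUE   # position is irrelevant
  img <- make_postop_image(m, 1, contrast = 100, noise_sd = 10,
                           seed = 7)
  rec <- img$intensities >= img$background + img$contrast / 2
  mis <- sum(rec != m)
  expect_lt(mis / length(m), 1e-4)
})

test_that("threshold recovery degrades monotonically with noise", {
  m <- ball_mask(20, 6)
  mis <- vapply(c(10, 30, 60, 120), function(sd_) {
    img <- make_postop_image(m, 1, contrast = 100, noise_sd = sd_,
                             seed = 42)
    sum((img$intensities >= img$background + 50) != m)
  }, numeric(1))
  expect_true(all(diff(mis) >= 0))
})

test_that("parameter errors are caught; empty mask is allowed", {
  m <- ball_mask(10, 3)
  expect_error(make_postop_image(m, 1, noise_sd = -1), "noise_sd")
  expect_error(make_postop_image(m, 1, contrast = 0), "contrast")
  empty <- array(FALSE, c(5, 5, 5))
  img <- make_postop_image(empty, 1, contrast = 100, noise_sd = 0)
  expect_warning(v <- measure_volume(img), "no voxel")
  expect_equal(v, 0)
})
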