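test_that("fft_reconstruct agrees with the analytic inverse and a dense solve", {
  expect_equal(fft_reconstruct(raw_code(c(1L, 1L, 0L)), c(3, 4, 5)), c(1, 2, 3))
  set.seed(21)
  for (code in list(qr_code(3), qr_code(7), twin_prime_code(3, 5),
                    qr_code(19), qr_code(31))) {
    y <- rnorm(code$order)
    xf <- fft_reconstruct(code, y)
    expect_equal(xf, analytic_inverse_apply(code, y), tolerance = 1e-8)
  }
  # dense linear solve at N = 15
  code <- twin_prime_code(3, 5)
  y <- rnorm(15)
  expect_equal(fft_reconstruct(code, y),
               solve(dense_smatrix(code$bits), y), tolerance = 1e-8)
  # forward check for the all-ones measurement
  x1 <- fft_reconstruct(code, rep(1, 15))
  expect_equal(project(code, x1), rep(1, 15), tolerance = 1e-9)

  expect_error(fft_reconstruct(raw_code(rep(1L, 7)), rnorm(7)), "singular")
  expect_error(fft_reconstruct(code, 1:3), "length")
})

test_that("round trip recovers the object at experimental scale, quickly", {
  code <- twin_prime_code(101, 103)
  set.seed(22)
  x <- runif(code$order)
  elapsed <- system.time({
    xr <- fft_reconstruct(code, project(code, x))
  })[["elapsed"]]
  expect_lt(max(abs(xr - x)), 1e-6)
  expect_lt(elapsed, 1)
})

test_that("demux splits a trace into its M interleaved datasets", {
  code <- twin_prime_code(3, 5)
  set.seed(23)
  x <- runif(15)
  t1 <- acquire(code, x, acquisition_config(M = 1))
  expect_equal(demux(t1), list(project(code, x)))
  t5 <- acquire(code, x, acquisition_config(M = 5))
  ds <- demux(t5)
  expect_length(ds, 5)
  expect_equal(ds[[1]], project(code, x))
  # interleave inverse reproduces the trace
  rebuilt <- numeric(75)
  for (m in 1:5) rebuilt[seq(m, 75, by = 5)] <- ds[[m]]
  expect_equal(rebuilt, t5$samples)
  expect_error(demux(runif(10), n = 3, M = 4), "length")
})

test_that("subpixel_align applies exact fractional cyclic shifts", {
  set.seed(24)
  v <- rnorm(19)
  expect_equal(subpixel_align(v, 0), v)
  expect_equal(subpixel_align(subpixel_align(v, 0.37), -0.37), v, tolerance = 1e-9)
  # delta -> 1 equals a unit roll on band-limited content
  n <- 19
  smooth <- cos(2 * pi * (0:(n - 1)) / n) + 0.5 * sin(4 * pi * (0:(n - 1)) / n)
  rolled <- smooth[c(2:n, 1)]          # content at i+1 moves to i
  expect_equal(subpixel_align(smooth, 1), rolled, tolerance = 1e-9)
  # and on a rough vector too: integer shifts are exact for any content
  expect_equal(subpixel_align(v, 1), v[c(2:19, 1)], tolerance = 1e-9)
})

test_that("dataset-m reconstruction is exactly the (1-d, d) blend of x and roll(x, 1)", {
  for (code in list(qr_code(19), twin_prime_code(101, 103))) {
    n <- code$order
    set.seed(25)
    x <- runif(n)
    tr <- acquire(code, x, acquisition_config(M = 5))
    ds <- demux(tr)
    for (m in c(1L, 3L, 5L)) {
      d <- (m - 1) / 5
      xm <- fft_reconstruct(code, ds[[m]])
      expect_equal(xm, (1 - d) * x + d * x[c(n, 1:(n - 1))], tolerance = 1e-8)
    }
  }
})

test_that("fuse reproduces the phantom exactly for noiseless M = 1", {
  code <- twin_prime_code(101, 103)
  lay <- fold_crt(code, 101, 103)
  ph <- resolution_target(101, 103)
  tr <- acquire(code, unfold(lay, ph$image), acquisition_config(M = 1))
  est <- fuse(tr, code, lay)
  expect_lt(max(abs(est$image - ph$image)), 1e-6)
  expect_equal(est$n_datasets_used, 1L)
  expect_lt(est$residual_norm, 1e-6)
})

test_that("fused M = 5 reconstruction improves RMSE by about sqrt(5) under gaussian noise", {
  code <- qr_code(1019)
  x <- bandlimited_object(code$order)
  sigma <- default_gaussian_sigma(code, x)
  ratios <- vapply(1:100, function(r) {
    e1 <- fuse(acquire(code, x, acquisition_config(
      M = 1, noise = "gaussian", sigma = sigma, seed = r)), code)
    e5 <- fuse(acquire(code, x, acquisition_config(
      M = 5, noise = "gaussian", sigma = sigma, seed = r + 7000)), code)
    sqrt(mean((e1$x_code_domain - x)^2)) / sqrt(mean((e5$x_code_domain - x)^2))
  }, numeric(1))
  expect_gt(mean(ratios), 0.7 * sqrt(5))
  expect_lt(mean(ratios), 1.1 * sqrt(5))
})

test_that("grayscale values are recovered with small bias at the default noise level", {
  code <- qr_code(1019)
  x <- bandlimited_object(code$order)
  sigma <- default_gaussian_sigma(code, x)  # ~20 dB single-reconstruction SNR
  errs <- vapply(1:100, function(r) {
    fuse(acquire(code, x, acquisition_config(
      M = 5, noise = "gaussian", sigma = sigma, seed = r)), code)$x_code_domain - x
  }, numeric(code$order))
  bias_rms <- sqrt(mean(rowMeans(errs)^2))
  expect_lt(bias_rms, 0.01 * diff(range(x)))
})

test_that("the deblend flag sharpens noiseless fused reconstructions", {
  code <- qr_code(103)
  x <- bandlimited_object(code$order, cutoff = 103 / 8, seed = 3)
  tr <- acquire(code, x, acquisition_config(M = 5))
  plain <- fuse(tr, code)
  sharp <- fuse(tr, code, deblend = TRUE)
  expect_lt(max(abs(sharp$x_code_domain - x)), max(abs(plain$x_code_domain - x)))
})

test_that("cs_reconstruct matches the direct inversion when unregularized and full", {
  code <- twin_prime_code(3, 5)
  set.seed(26)
  x <- runif(15)
  y <- project(code, x)
  est <- cs_reconstruct(code, y, 0:14, sparsity_weight = 0)
  expect_true(est$converged)
  expect_lt(sqrt(sum((est$x_code_domain - fft_reconstruct(code, y))^2)) /
              sqrt(sum(x^2)), 1e-3)
  expect_error(cs_reconstruct(code, numeric(0), integer(0)), "empty")
  expect_error(cs_reconstruct(code, y[1:3], c(0, 0, 1)), "distinct")
})

test_that("cs_reconstruct recovers a piecewise-constant phantom from half the patterns", {
  code <- twin_prime_code(3, 5)
  lay <- fold_crt(code, 3, 5)
  img <- matrix(0, 3, 5); img[2, 2:3] <- 1      # one constant block
  x <- unfold(lay, img)
  y <- project(code, x)
  set.seed(1)
  keep <- sort(sample(0:14, 8))                 # ~50% of the patterns
  est <- cs_reconstruct(code, y[keep + 1], keep, sparsity_weight = 0.05,
                        layout = lay)
  # exact support recovery on the thresholded estimate
  expect_identical(est$x_code_domain > 0.5, x > 0.5)
  # against the dense minimum-norm least-squares oracle: the TV solution
  # stays data-consistent while strictly reducing the prior it minimizes
  s_sub <- dense_smatrix(code$bits)[keep + 1, ]
  x_ls <- as.numeric(pinv(s_sub) %*% y[keep + 1])
  tv2d <- function(v) {
    a <- fold_vector(lay, v)
    sum(abs(diff(a))) + sum(abs(t(diff(t(a)))))
  }
  expect_lt(tv2d(est$x_code_domain), tv2d(x_ls))
  expect_lt(est$residual_norm, 0.5)
  expect_lt(max(abs(s_sub %*% x_ls - y[keep + 1])), 1e-9)  # oracle sanity
})

test_that("image_metrics reports RMSE, PSNR and bar contrast with guards", {
  ph <- resolution_target(31, 33, bar_widths = c(1, 2))
  lay <- fold_crt(31 * 33, 31, 33)
  exact <- structure(list(image = ph$image), class = "spi_estimate")
  m <- image_metrics(exact, ph)
  expect_equal(m$rmse, 0)
  expect_equal(m$psnr_db, Inf)
  expect_equal(m$bar_contrast, 1)  # bars 1, background 0

  shifted <- structure(list(image = ph$image + 0.25), class = "spi_estimate")
  expect_equal(image_metrics(shifted, ph)$rmse, 0.25)

  zero <- structure(list(image = ph$image * 0), class = "spi_estimate")
  expect_true(is.na(image_metrics(zero, ph)$bar_contrast))  # guarded denominator

  expect_error(image_metrics(exact, resolution_target(10, 52, 1)), "shape")
})
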