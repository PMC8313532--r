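# Independent oracles and fixture builders, deliberately naive:
# dense matrices and direct summation, never the FFT path under test.

# dense circulant under the package convention S[k, i] = bits[(i+k) mod N]
dense_smatrix <- function(bits) {
  n <- length(bits)
  s <- matrix(0L, n, n)
  for (k in 0:(n - 1)) s[k + 1L, ] <- bits[((0:(n - 1) + k) %% n) + 1L]
  s
}

# direct-summation forward projection
dense_project <- function(bits, x) {
  as.numeric(dense_smatrix(bits) %*% x)
}

# brute-force cyclic autocorrelation at all lags
brute_autocorrelation <- function(bits) {
  n <- length(bits)
  vapply(0:(n - 1), function(tau) {
    sum(bits * bits[((0:(n - 1) + tau) %% n) + 1L])
  }, numeric(1))
}

# hand-rolled code object so tests can feed invalid bit patterns
raw_code <- function(bits, method = "manual") {
  structure(list(order = length(bits), bits = as.integer(bits),
                 method = method, weight = sum(bits)),
            class = "spi_code")
}

# grayscale object band-limited along the code axis: harmonics |k| <= cutoff,
# rescaled into [0.1, 0.9]. The smooth "stated world" for the fusion
# Monte-Carlo checks (see the methods vignette).
bandlimited_object <- function(n, cutoff = n / 16, seed = 42) {
  set.seed(seed)
  sp <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  k <- 0:(n - 1)
  ks <- ifelse(k <= n / 2, k, k - n)
  sp[abs(ks) > cutoff] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  (x - min(x)) / diff(range(x)) * 0.8 + 0.1
}

# SVD pseudo-inverse (minimum-norm least-squares oracle)
pinv <- function(a, tol = 1e-10) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

expect_valid_code <- function(code) {
  rep <- validate_code(code)
  expect_true(rep$weight_ok, info = paste("weight, N =", code$order))
  expect_true(rep$autocorrelation_ok, info = paste("autocorrelation, N =", code$order))
  expect_true(rep$ok)
  invisible(rep)
}
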