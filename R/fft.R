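# Length-N DFT helpers.
#
# All cyclic-code orders used here are odd and frequently prime (quadratic
# residue orders) or products of two large primes (twin-prime orders).
# stats::fft uses Singleton's mixed-radix algorithm whose cost is O(N * f)
# for the largest prime factor f, i.e. O(N^2) at prime N. To keep the
# advertised O(N log N) reconstruction cost at arbitrary valid orders, large
# rough lengths are transformed with Bluestein's chirp-z algorithm on a
# zero-padded power-of-two length, where stats::fft is genuinely fast.

.largest_prime_factor <- function(n) {
  f <- 1L
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) {
      f <- d
      n <- n %/% d
    }
    d <- d + 1L
  }
  max(f, n)
}

.use_bluestein <- function(n) {
  n > 64L && .largest_prime_factor(n) > 31L
}

# Bluestein chirp-z DFT: X_k = w^{k^2/2} * sum_n (x_n w^{n^2/2}) w^{-(k-n)^2/2}
# with w = exp(-2i*pi/N); the sum is a linear convolution evaluated circularly
# at padded power-of-two length L >= 2N - 1.
.bluestein_dft <- function(x) {
  n <- length(x)
  L <- 2^ceiling(log2(2 * n - 1))
  idx <- 0:(n - 1)
  # k^2/2 mod N taken in exact double arithmetic: k^2 can exceed 2^53 for
  # N ~ 1e8; here N <= ~1e6 so k^2 <= 1e12 is exact in doubles.
  chirp <- exp(-1i * pi * (idx^2 %% (2 * n)) / n)
  a <- c(x * chirp, rep(0 + 0i, L - n))
  b <- rep(0 + 0i, L)
  b[1:n] <- Conj(chirp)
  b[(L - n + 2):L] <- Conj(chirp[n:2])
  conv <- stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE) / L
  conv[1:n] * chirp
}

#' Discrete Fourier transform at arbitrary length
#'
#' Forward DFT with the same sign convention as [stats::fft()], but with
#' O(N log N) cost at every length: smooth lengths go to `stats::fft`
#' directly, rough lengths (largest prime factor above 31) are handled by
#' Bluestein's chirp-z algorithm on a zero-padded power-of-two grid.
#'
#' @param x real or complex vector.
#' @return complex vector of DFT coefficients, unnormalized.
#' @keywords internal
spi_fft <- function(x) {
  if (.use_bluestein(length(x))) .bluestein_dft(as.complex(x)) else stats::fft(x)
}

#' @rdname spi_fft
#' @keywords internal
spi_ifft <- function(x) {
  Conj(spi_fft(Conj(x))) / length(x)
}
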