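# Forward model of the spinning-mask acquisition.
#
# One frame: the mask advances through all N patterns; during each
# transition interval T the detector takes M samples. Because the mask
# translates continuously, sample m of transition k sees a convex blend of
# the two adjacent patterns: (1-d) y[k] + d y[k+1] with d = d0 + m/M — the
# exact signal of a uniformly moving binary mask with cell-aligned
# pixelation and an ideal (instantaneous-sampling) detector. Intra-frame
# object motion is ignored: frames are reconstructed as static.

#' Circulant projection (forward model, one sample per pattern)
#'
#' `y[k] = sum_i bits[(i+k) mod N] * x[i]` — the detector reading for the
#' pattern at shift k. Evaluated via FFT-based cyclic correlation, O(N log N)
#' at any order.
#'
#' @param code an `spi_code`.
#' @param x transmittance vector of length N (code-index order, see
#'   [unfold()]).
#' @return numeric vector of length N.
#' @export
project <- function(code, x) {
  n <- code$order
  if (length(x) != n) stop("x has length ", length(x), ", expected N = ", n)
  if (any(!is.finite(x))) stop("x must be finite")
  Re(spi_ifft(spi_fft(as.numeric(code$bits)) * Conj(spi_fft(as.numeric(x)))))
}

#' Detector sample during a pattern transition
#'
#' The mask midway between patterns k and k+1 produces the linear blend
#' `(1-delta) y[k] + delta y[(k+1) mod N]` where `y = project(code, x)`.
#'
#' @param code an `spi_code`.
#' @param x transmittance vector of length N.
#' @param k transition index, `0 <= k < N`.
#' @param delta sub-pixel mask displacement in [0, 1).
#' @return scalar detector value.
#' @export
blended_measurement <- function(code, x, k, delta) {
  n <- code$order
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta >= 1)
    stop("delta must be in [0, 1), got ", delta)
  if (k < 0 || k >= n || k != as.integer(k)) stop("k must be an integer in [0, N)")
  y <- project(code, x)
  (1 - delta) * y[k + 1L] + delta * y[(k + 1L) %% n + 1L]
}

#' Acquisition configuration
#'
#' @param M oversampling factor: samples per transition interval (the
#'   reference system uses M = 5).
#' @param noise one of `"none"`, `"gaussian"`, `"shot"`.
#' @param sigma gaussian noise standard deviation, detector units.
#' @param photons_per_unit shot-noise scale: a value v is replaced by
#'   `Poisson(v * photons_per_unit) / photons_per_unit`.
#' @param seed integer seed for the noise draw.
#' @param delta0 sampling phase offset in [0, 1/M): real systems do not
#'   sample at exactly delta = 0; default 0.
#' @param geometry optional `spi_geometry` used to attach a physical time
#'   axis (`time_step = T / M` seconds) to traces.
#' @return object of class `spi_acq_config`.
#' @export
acquisition_config <- function(M = 5L, noise = c("none", "gaussian", "shot"),
                               sigma = 0, photons_per_unit = 1e4, seed = 1L,
                               delta0 = 0, geometry = NULL) {
  M <- .check_count(M, "M")
  noise <- match.arg(noise)
  if (sigma < 0) stop("sigma must be >= 0")
  if (photons_per_unit <= 0) stop("photons_per_unit must be > 0")
  if (delta0 < 0 || delta0 >= 1 / M) stop("delta0 must be in [0, 1/M)")
  structure(list(M = M, noise = noise, sigma = sigma,
                 photons_per_unit = photons_per_unit, seed = as.integer(seed),
                 delta0 = delta0, geometry = geometry),
            class = "spi_acq_config")
}

.new_trace <- function(samples, n, cfg, frame_index = 1L) {
  time_step <- if (!is.null(cfg$geometry))
    transition_time(cfg$geometry) * 1e-6 / cfg$M else NULL
  structure(list(samples = samples, order = n, M = cfg$M,
                 time_step = time_step, frame_index = frame_index,
                 noise = list(model = cfg$noise, sigma = cfg$sigma,
                              photons_per_unit = cfg$photons_per_unit,
                              seed = cfg$seed, delta0 = cfg$delta0)),
            class = "spi_trace")
}

#' @export
print.spi_trace <- function(x, ...) {
  cat(sprintf("<spi_trace> M*N = %d x %d = %d samples, noise = %s, frame %d\n",
              x$M, x$order, length(x$samples), x$noise$model, x$frame_index))
  invisible(x)
}

#' Simulate one frame of the spinning-mask acquisition
#'
#' Produces the M*N detector samples of a frame:
#' `samples[k*M + m] = (1-d) y[k] + d y[k+1]` with `d = delta0 + m/M`, plus
#' noise per the configuration. Deterministic given `cfg$seed`.
#'
#' @param code an `spi_code`.
#' @param x transmittance vector of length N.
#' @param cfg an `spi_acq_config`.
#' @param frame_index frame label stored in the trace.
#' @return an `spi_trace` (fields `samples`, `order`, `M`, `time_step`,
#'   `frame_index`, `noise`).
#' @export
acquire <- function(code, x, cfg = acquisition_config(), frame_index = 1L) {
  if (!inherits(cfg, "spi_acq_config")) stop("cfg must be an spi_acq_config")
  n <- code$order
  y <- project(code, x)
  y_next <- y[c(2:n, 1L)]
  m <- cfg$M
  deltas <- cfg$delta0 + (0:(m - 1L)) / m
  # samples laid out transition-major: index k*M + m
  blended <- outer(y, 1 - deltas) + outer(y_next, deltas)  # N x M, row k = transition k
  clean <- as.vector(t(blended))
  samples <- .with_seed(cfg$seed, switch(
    cfg$noise,
    none = clean,
    gaussian = clean + stats::rnorm(length(clean), 0, cfg$sigma),
    shot = stats::rpois(length(clean),
                        pmax(clean, 0) * cfg$photons_per_unit) / cfg$photons_per_unit
  ))
  .new_trace(samples, n, cfg, frame_index)
}

#' Simulate a video: one trace per frame
#'
#' Each frame is acquired with a seed derived deterministically from
#' `(cfg$seed, frame_index)`, so noise realizations differ across frames
#' while the whole video is reproducible.
#'
#' @param code an `spi_code`.
#' @param phantoms list of `spi_phantom`s (all the same shape) or of
#'   length-N vectors.
#' @param layout `spi_layout` used to unfold phantom images (required when
#'   `phantoms` are 2D).
#' @param cfg an `spi_acq_config`.
#' @return list of `spi_trace`s.
#' @export
acquire_video <- function(code, phantoms, layout = NULL,
                          cfg = acquisition_config()) {
  if (length(phantoms) == 0) stop("empty phantom list")
  lapply(seq_along(phantoms), function(f) {
    ph <- phantoms[[f]]
    x <- if (inherits(ph, "spi_phantom")) {
      if (is.null(layout)) stop("layout required to unfold 2D phantoms")
      unfold(layout, ph$image)
    } else ph
    cfg_f <- cfg
    cfg_f$seed <- (cfg$seed %% 100003L) * 10007L + f  # < 2^31, frame-unique
    acquire(code, x, cfg_f, frame_index = f)
  })
}

#' Default gaussian noise level for a target reconstruction SNR
#'
#' For a valid order-N S-matrix, the single-dataset reconstruction of
#' i.i.d. detector noise of sd sigma has rms ~ `2 sigma / sqrt(N+1)` (the
#' non-DC singular values of S are `sqrt((N+1)/4)`). Choosing
#' `sigma = rms(x) * sqrt(N+1) / (2 * 10^(snr_db/20))` therefore gives a
#' single-reconstruction SNR of about `snr_db` (default 20 dB) on the given
#' object — the package's documented default noise scale.
#'
#' @param code an `spi_code`.
#' @param x the object vector the SNR refers to.
#' @param snr_db target reconstruction signal-to-noise ratio, dB.
#' @return gaussian sigma in detector units.
#' @export
default_gaussian_sigma <- function(code, x, snr_db = 20) {
  sqrt(mean(x^2)) * sqrt(code$order + 1) / (2 * 10^(snr_db / 20))
}
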