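# 1D -> 2D mask layout and physical timing.
#
# The mask carries a 1D cyclic code; the projected pattern is 2D. For orders
# N = p*q with gcd(p,q) = 1 the Chinese remainder theorem gives the
# canonical bijection i -> (i mod p, i mod q): a +1 cyclic shift of the code
# then appears as a diagonal (+1 mod p, +1 mod q) displacement of the 2D
# pattern, which is what a rotating mask realizes. Timing quantities follow
# from the tangential speed at the pattern radius.

#' Mask geometry
#'
#' Physical parameters of the spinning photomask that set all timing
#' quantities. Defaults reproduce the reference configuration: 1.5 um cells
#' fabricated 55 mm from the center of rotation, spun at 600 rpm (the upper
#' end of the operated 540-600 rpm range, which reproduces the printed
#' transition time of ~0.43 us).
#'
#' @param cell_width_um cell size in micrometers.
#' @param pattern_radius_mm distance of the pattern from the rotation center,
#'   millimeters.
#' @param rotation_rpm rotation speed, revolutions per minute.
#' @return object of class `spi_geometry`.
#' @export
mask_geometry <- function(cell_width_um = 1.5, pattern_radius_mm = 55,
                          rotation_rpm = 600) {
  if (!all(is.finite(c(cell_width_um, pattern_radius_mm, rotation_rpm))) ||
      cell_width_um <= 0 || pattern_radius_mm <= 0 || rotation_rpm <= 0)
    stop("all geometry parameters must be strictly positive and finite")
  if (cell_width_um * 1e-3 > 2 * pi * pattern_radius_mm * (1 + 1e-9))
    stop("cell_width cannot exceed the pattern circumference")
  structure(list(cell_width_um = cell_width_um,
                 pattern_radius_mm = pattern_radius_mm,
                 rotation_rpm = rotation_rpm),
            class = "spi_geometry")
}

#' @export
print.spi_geometry <- function(x, ...) {
  cat(sprintf("<spi_geometry> cell %.3g um, radius %.3g mm, %.4g rpm -> T = %.4g us (%.4g patterns/s)\n",
              x$cell_width_um, x$pattern_radius_mm, x$rotation_rpm,
              transition_time(x), modulation_rate(x)))
  invisible(x)
}

#' Pattern transition time
#'
#' Time for the mask to advance by one cell width at the pattern radius:
#' `T = w / (2 pi r * rps)`. With the default geometry (1.5 um, 55 mm,
#' 600 rpm) this is ~0.43 us.
#'
#' @param geom an `spi_geometry`.
#' @return transition time T in microseconds.
#' @export
transition_time <- function(geom) {
  t_s <- (geom$cell_width_um * 1e-6) /
    (2 * pi * geom$pattern_radius_mm * 1e-3 * geom$rotation_rpm / 60)
  t_s * 1e6
}

#' Spatial modulation rate
#'
#' Patterns presented per second, `1 / T`. The default geometry gives
#' ~2.3e6 patterns/s (megahertz-scale modulation).
#'
#' @param geom an `spi_geometry`.
#' @return modulation rate in patterns per second (Hz).
#' @export
modulation_rate <- function(geom) {
  1e6 / transition_time(geom)
}

#' Frame rate from recording rate
#'
#' `fps = recording_rate / n_pixels`; e.g. 0.75e6 pixels/s over
#' 10,403-pixel frames gives 72.09... -> 72 fps.
#'
#' @param recording_rate_px_s total recording rate, pixels per second.
#' @param n_pixels pixels per frame.
#' @return list with `exact` (the ratio) and `fps` (nearest integer).
#' @export
frame_rate <- function(recording_rate_px_s, n_pixels) {
  if (recording_rate_px_s < 0 || n_pixels <= 0)
    stop("recording rate must be >= 0 and n_pixels > 0")
  exact <- recording_rate_px_s / n_pixels
  list(exact = exact, fps = round(exact))
}

#' Radial cell-size variation across a pattern
#'
#' The tangential width of a cell grows with radius, so a pattern of finite
#' height spans a fractional cell-size spread of
#' `(r_outer - r_inner) / r_center = pattern_height / pattern_radius`.
#'
#' @param geom an `spi_geometry`.
#' @param pattern_height_mm radial extent of the pattern, millimeters.
#' @return dimensionless relative variation.
#' @export
cell_size_variation <- function(geom, pattern_height_mm) {
  if (pattern_height_mm < 0 || pattern_height_mm >= 2 * geom$pattern_radius_mm)
    stop("pattern_height must be in [0, 2 * pattern_radius)")
  pattern_height_mm / geom$pattern_radius_mm
}

#' CRT folding of a cyclic code onto a p x q grid
#'
#' Builds the bijection `i -> (i mod p, i mod q)` between code indices
#' 0..N-1 and pixels of a p x q rectangle, valid whenever `gcd(p, q) = 1`
#' (Chinese remainder theorem). Under this folding a +1 cyclic shift of the
#' code displaces the 2D pattern by (+1 mod p, +1 mod q) — the diagonal
#' scan axis recorded in the layout. Sub-pixel alignment downstream operates
#' in the 1D code domain; the layout is bookkeeping for rendering.
#'
#' @param code an `spi_code` of order `p * q` (or the order itself).
#' @param p,q grid dimensions, coprime, with `p * q == N`.
#' @return object of class `spi_layout` with fields `p`, `q`, `order`,
#'   `method`, and 1-based index vectors `row_of`, `col_of` (pixel of code
#'   index i at `[row_of[i+1], col_of[i+1]]`).
#' @examples
#' lay <- fold_crt(twin_prime_code(3, 5), 3, 5)
#' img <- fold_vector(lay, 1:15)
#' all(unfold(lay, img) == 1:15)
#' @export
fold_crt <- function(code, p, q) {
  n <- if (inherits(code, "spi_code")) code$order else .check_count(code, "code")
  p <- .check_count(p, "p"); q <- .check_count(q, "q")
  if (.gcd(p, q) != 1) stop("p and q must be coprime; gcd(", p, ",", q, ") = ", .gcd(p, q))
  if (p * q != n) stop("p * q = ", p * q, " does not match code order N = ", n)
  i <- 0:(n - 1)
  structure(list(p = p, q = q, order = n, method = "crt",
                 row_of = i %% p + 1L, col_of = i %% q + 1L,
                 scan_axis = c(row = 1L, col = 1L)),
            class = "spi_layout")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' @export
print.spi_layout <- function(x, ...) {
  cat(sprintf("<spi_layout> %d x %d (N = %d), method = %s, +1 code shift -> (+%d mod p, +%d mod q)\n",
              x$p, x$q, x$order, x$method, x$scan_axis["row"], x$scan_axis["col"]))
  invisible(x)
}

#' Fold a length-N vector into its 2D image
#'
#' @param layout an `spi_layout`.
#' @param x numeric vector of length N in code-index order.
#' @return p x q matrix with `img[layout$row_of[i+1], layout$col_of[i+1]] = x[i+1]`.
#' @export
fold_vector <- function(layout, x) {
  if (length(x) != layout$order)
    stop("vector length ", length(x), " != layout order ", layout$order)
  img <- matrix(NA_real_, layout$p, layout$q)
  img[cbind(layout$row_of, layout$col_of)] <- x
  img
}

#' Unfold a 2D image into the 1D code domain
#'
#' Inverse of [fold_vector()]: `x[i] = image[i mod p, i mod q]`. This is the
#' vector the circulant forward model acts on.
#'
#' @param layout an `spi_layout`.
#' @param image2d p x q matrix.
#' @return numeric vector of length N.
#' @export
unfold <- function(layout, image2d) {
  if (!is.matrix(image2d) || nrow(image2d) != layout$p || ncol(image2d) != layout$q)
    stop("image must be a ", layout$p, " x ", layout$q, " matrix")
  image2d[cbind(layout$row_of, layout$col_of)]
}

#' Write / read a layout as JSON
#'
#' @param layout an `spi_layout`.
#' @param path destination JSON file.
#' @return `write_layout` returns `path` invisibly; `read_layout` an
#'   `spi_layout` (the index map is reconstructed from p, q).
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(p = layout$p, q = layout$q, method = layout$method),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$method, "crt")) stop("unsupported layout method: ", obj$method)
  fold_crt(as.integer(obj$p) * as.integer(obj$q), obj$p, obj$q)
}
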