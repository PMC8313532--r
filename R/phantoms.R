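# Synthetic imaged objects with known ground truth.
#
# Phantom values are transmittance: the fraction of incident light a pixel
# passes toward the detector, in [0, 1]. Absorption and scattering are
# treated identically (both darken the pixel). Relay optics are ideal — no
# PSF or diffraction model.

.new_phantom <- function(image, kind, ground_truth = list()) {
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("phantom values must be finite and in [0, 1]")
  structure(list(image = image, kind = kind, ground_truth = ground_truth),
            class = "spi_phantom")
}

#' @export
print.spi_phantom <- function(x, ...) {
  cat(sprintf("<spi_phantom> %d x %d, kind = %s, range [%.3g, %.3g]\n",
              nrow(x$image), ncol(x$image), x$kind,
              min(x$image), max(x$image)))
  invisible(x)
}

#' Binary resolution-target phantom
#'
#' Grouped triplets of vertical bars, one group per requested bar width,
#' value 1 (transparent) inside bars on a 0 (opaque) background — the
#' synthetic stand-in for a USAF-style resolution target. Groups are laid
#' out left to right with a one-widest-bar margin between them.
#'
#' @param p,q image dimensions (rows, columns).
#' @param bar_widths integer bar widths in pixels, one group of three bars
#'   per entry. Empty vector gives an all-zeros image.
#' @param bar_height bar height in pixels (default: 60% of p).
#' @return an `spi_phantom` whose `ground_truth` records `bar_widths`,
#'   `bar_mask` (logical matrix of bar pixels) and `bar_area`.
#' @export
resolution_target <- function(p, q, bar_widths = c(1, 2, 4, 8),
                              bar_height = max(1L, floor(0.6 * p))) {
  p <- .check_count(p, "p"); q <- .check_count(q, "q")
  bar_widths <- as.integer(bar_widths)
  if (any(bar_widths < 1)) stop("bar widths must be positive integers")
  img <- matrix(0, p, q)
  if (bar_height > p) stop("bar_height exceeds image height")
  rows <- seq_len(bar_height) + floor((p - bar_height) / 2)
  col <- 2L
  for (w in bar_widths) {
    group_w <- 5L * w                       # 3 bars + 2 gaps of width w
    if (col + group_w - 1L > q)
      stop("bar group of width ", w, " does not fit in ", q, " columns")
    for (b in 0:2) {
      cols <- col + b * 2L * w + 0:(w - 1L)
      img[rows, cols] <- 1
    }
    col <- col + group_w + max(bar_widths)  # inter-group margin
  }
  mask <- img > 0.5
  .new_phantom(img, "resolution_target",
               list(bar_widths = bar_widths, bar_mask = mask,
                    bar_area = sum(mask)))
}

#' Worm-like moving grayscale phantom sequence
#'
#' Emulates videos of freely moving C. elegans worms: each frame holds a
#' smooth random curve (a spline backbone with a Gaussian cross-section)
#' whose transmittance dips below the bright background — a scattering worm
#' appears dark because less light from its region reaches the detector.
#' The worm translates rigidly between frames by at most `speed` pixels per
#' frame (direction follows a smooth random walk, reflected at the image
#' margins); the backbone shape is fixed within a sequence so the motion is
#' purely a trajectory. Fully deterministic given `seed`.
#'
#' @param p,q image dimensions.
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed.
#' @param speed maximum centroid displacement per frame, pixels.
#' @param dip peak transmittance dip at the worm midline, in [0, 1]
#'   (default drawn uniformly in 0.3-0.7 per the grayscale design).
#' @param half_width Gaussian cross-section sigma, pixels.
#' @return list of `spi_phantom`s; each `ground_truth` records the frame's
#'   backbone `center` and the sequence parameters.
#' @export
worm_like_sequence <- function(p, q, n_frames, seed = 1L, speed = 2,
                               dip = NULL, half_width = max(1.5, min(p, q) / 30)) {
  p <- .check_count(p, "p"); q <- .check_count(q, "q")
  n_frames <- .check_count(n_frames, "n_frames")
  .with_seed(seed, {
    if (is.null(dip)) dip <- stats::runif(1, 0.3, 0.7)
    margin <- 4 * half_width + speed + 1
    span <- 0.5 * min(p, q)
    # backbone: smooth open curve from a few control points, centered at 0
    nc <- 5L
    ctrl_r <- cbind(stats::runif(nc, -span / 2, span / 2),
                    stats::runif(nc, -span / 2, span / 2))
    tt <- seq(0, 1, length.out = nc)
    ts <- seq(0, 1, length.out = 20L * nc)
    bb <- cbind(stats::spline(tt, ctrl_r[, 1], xout = ts)$y,
                stats::spline(tt, ctrl_r[, 2], xout = ts)$y)
    bb <- sweep(bb, 2, colMeans(bb))
    center <- vapply(c(p, q), function(lim) {
      lo <- margin + span / 2; hi <- lim - margin - span / 2
      if (hi <= lo) lim / 2 else stats::runif(1, lo, hi)
    }, numeric(1))
    heading <- stats::runif(1, 0, 2 * pi)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        heading <- heading + stats::rnorm(1, 0, 0.4)
        step <- stats::runif(1, 0.5, 1) * speed
        prop <- center + step * c(cos(heading), sin(heading))
        # reflect off margins so the worm stays inside
        lim <- c(p, q)
        for (d in 1:2) {
          lo <- margin + span / 2; hi <- lim[d] - margin - span / 2
          if (hi <= lo) { prop[d] <- lim[d] / 2; next }
          if (prop[d] < lo) { prop[d] <- 2 * lo - prop[d]; heading <- heading + pi / 2 }
          if (prop[d] > hi) { prop[d] <- 2 * hi - prop[d]; heading <- heading + pi / 2 }
        }
        center <- prop
      }
      pts <- sweep(bb, 2, center, `+`)
      img <- 1 - dip * .tube_profile(p, q, pts, half_width)
      frames[[f]] <- .new_phantom(
        pmin(pmax(img, 0), 1), "worm_like",
        list(center = center, dip = dip, speed = speed,
             half_width = half_width, frame = f, seed = seed))
    }
    frames
  })
}

# Gaussian tube around a polyline: exp(-d^2 / (2 hw^2)) with d the distance
# to the nearest backbone sample; evaluated only near the backbone.
.tube_profile <- function(p, q, pts, hw) {
  prof <- matrix(0, p, q)
  reach <- ceiling(4 * hw)
  for (s in seq_len(nrow(pts))) {
    r0 <- max(1L, floor(pts[s, 1] - reach)); r1 <- min(p, ceiling(pts[s, 1] + reach))
    c0 <- max(1L, floor(pts[s, 2] - reach)); c1 <- min(q, ceiling(pts[s, 2] + reach))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pts[s, 1])^2, (cc - pts[s, 2])^2, `+`)
    prof[rr, cc] <- pmax(prof[rr, cc], exp(-d2 / (2 * hw^2)))
  }
  prof
}

#' Load a user-supplied grayscale image as a phantom
#'
#' Reads an ASCII PGM (P2) image or a CSV matrix, rescales values to [0, 1]
#' by the declared maximum (PGM maxval; CSV values already in [0, 1] pass
#' through, otherwise the matrix maximum), and resamples bilinearly to
#' p x q.
#'
#' @param path image file (`.pgm` or `.csv`).
#' @param p,q target dimensions.
#' @return an `spi_phantom` of kind `user_image`.
#' @export
load_user_image <- function(path, p, q) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    pg <- read_pgm(path)
    img <- pg$pixels / pg$maxval
  } else {
    img <- unname(as.matrix(utils::read.csv(path, header = FALSE)))
    storage.mode(img) <- "double"
    if (any(!is.finite(img))) stop("non-numeric values in image: ", path)
    if (max(img) > 1) img <- img / max(img)
    img <- pmax(img, 0)
  }
  .new_phantom(.resample_bilinear(img, p, q), "user_image", list(source = path))
}

.resample_bilinear <- function(img, p, q) {
  pr <- nrow(img); pc <- ncol(img)
  if (pr == p && pc == q) return(img)
  rs <- if (p == 1) rep(1, 1) else seq(1, pr, length.out = p)
  cs <- if (q == 1) rep(1, 1) else seq(1, pc, length.out = q)
  r0 <- pmin(floor(rs), pr - 1L); r0 <- pmax(r0, 1L); fr <- rs - r0
  c0 <- pmin(floor(cs), pc - 1L); c0 <- pmax(c0, 1L); fc <- cs - c0
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    img[r0 + 1L, c0, drop = FALSE] * outer(fr, 1 - fc) +
    img[r0, c0 + 1L, drop = FALSE] * outer(1 - fr, fc) +
    img[r0 + 1L, c0 + 1L, drop = FALSE] * outer(fr, fc)
  a
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
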