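# Optional compressed-sensing reconstruction from a subset of patterns.
#
# Solves min_x 0.5 ||S_sub x - y||^2 + lambda * TV(fold(x)) with S_sub the
# selected rows of the circulant operator and TV the anisotropic total
# variation on the folded 2D grid. Solved by FISTA (accelerated proximal
# gradient); the TV proximal step uses the dual fast-gradient-projection
# scheme. With all rows kept and lambda = 0 this reduces to the
# unregularized least-squares problem whose solution is fft_reconstruct's.
# Per-iteration cost is dominated by two circulant applies, but the
# iteration count makes the overall method far costlier than the O(N log N)
# direct inversion — it exists for undersampled acquisitions only.

# anisotropic TV prox via dual fast gradient projection (Beck-Teboulle FGP)
.tv_prox <- function(v, lambda, iters = 40L) {
  if (lambda <= 0) return(v)
  p <- nrow(v); q <- ncol(v)
  dr <- matrix(0, p - 1, q)   # dual vars for row differences
  dc <- matrix(0, p, q - 1)
  dr_prev <- dr; dc_prev <- dc
  tk <- 1
  L <- 8  # Lipschitz bound of the dual gradient for the 2D difference operator
  for (it in seq_len(iters)) {
    # divergence of the dual field
    div <- matrix(0, p, q)
    if (p > 1) { div[1:(p - 1), ] <- div[1:(p - 1), ] + dr
                 div[2:p, ] <- div[2:p, ] - dr }
    if (q > 1) { div[, 1:(q - 1)] <- div[, 1:(q - 1)] + dc
                 div[, 2:q] <- div[, 2:q] - dc }
    u <- v - lambda * div
    gr <- if (p > 1) u[1:(p - 1), , drop = FALSE] - u[2:p, , drop = FALSE] else dr
    gc <- if (q > 1) u[, 1:(q - 1), drop = FALSE] - u[, 2:q, drop = FALSE] else dc
    dr_new <- dr + gr / (L * lambda)
    dc_new <- dc + gc / (L * lambda)
    dr_new <- pmin(pmax(dr_new, -1), 1)   # anisotropic: box projection
    dc_new <- pmin(pmax(dc_new, -1), 1)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    dr <- dr_new + ((tk - 1) / tk1) * (dr_new - dr_prev)
    dc <- dc_new + ((tk - 1) / tk1) * (dc_new - dc_prev)
    dr_prev <- dr_new; dc_prev <- dc_new; tk <- tk1
  }
  div <- matrix(0, p, q)
  if (p > 1) { div[1:(p - 1), ] <- div[1:(p - 1), ] + dr_prev
               div[2:p, ] <- div[2:p, ] - dr_prev }
  if (q > 1) { div[, 1:(q - 1)] <- div[, 1:(q - 1)] + dc_prev
               div[, 2:q] <- div[, 2:q] - dc_prev }
  v - lambda * div
}

#' Compressed-sensing reconstruction from a pattern subset
#'
#' Recovers the image from measurements of only `length(indices)` of the N
#' patterns by accelerated proximal-gradient (FISTA) minimization of
#' `0.5 ||S_sub x - y||^2 + sparsity_weight * TV(fold(x))`, with
#' anisotropic total variation on the folded grid as the sparsity prior.
#' Non-convergence within `max_iter` yields a flagged estimate (check
#' `$converged`), never an error. With `indices = 0:(N-1)` and weight 0 the
#' minimizer coincides with [fft_reconstruct()].
#'
#' @param code an `spi_code`.
#' @param y_subset measurements for the selected patterns, same length and
#'   order as `indices`.
#' @param indices 0-based pattern (shift) indices actually measured;
#'   must be non-empty, within 0..N-1, distinct.
#' @param sparsity_weight TV regularization weight, >= 0.
#' @param layout `spi_layout` defining the 2D grid the TV acts on
#'   (required when `sparsity_weight > 0`).
#' @param max_iter,tol FISTA iteration cap and relative-change stopping
#'   tolerance.
#' @return an `spi_estimate` (method `"cs"`) with extra fields
#'   `converged` and `iterations`.
#' @export
cs_reconstruct <- function(code, y_subset, indices, sparsity_weight = 0,
                           layout = NULL, max_iter = 500L, tol = 1e-6) {
  n <- code$order
  indices <- as.integer(indices)
  if (length(indices) == 0) stop("empty index set: nothing to reconstruct from")
  if (anyDuplicated(indices) || any(indices < 0 | indices >= n))
    stop("indices must be distinct values in 0..N-1")
  if (length(y_subset) != length(indices))
    stop("y_subset and indices must have equal length")
  if (sparsity_weight < 0) stop("sparsity_weight must be >= 0")
  if (sparsity_weight > 0 && is.null(layout))
    stop("a layout is required for the TV prior")
  sel <- indices + 1L
  forward <- function(x) project(code, x)[sel]
  adjoint <- function(r) {
    full <- numeric(n); full[sel] <- r
    project(code, full)  # S is symmetric under the package convention
  }
  L <- ((n + 1) / 2)^2   # sigma_max(S)^2 bounds ||S_sub||^2
  prox <- function(v, step) {
    if (sparsity_weight == 0) return(v)
    img <- .tv_prox(fold_vector(layout, v), step * sparsity_weight)
    unfold(layout, img)
  }
  # warm start: zero-fill the unmeasured patterns and invert directly; exact
  # for the full unregularized problem, a good basin elsewhere
  y_fill <- numeric(n); y_fill[sel] <- y_subset
  x <- fft_reconstruct(code, y_fill)
  z <- x
  tk <- 1
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    grad <- adjoint(forward(z) - y_subset)
    x_new <- prox(z - grad / L, 1 / L)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- x_new + ((tk - 1) / tk1) * (x_new - x)
    delta <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x_new^2)), 1e-12)
    x <- x_new
    tk <- tk1
    if (delta < tol) { converged <- TRUE; break }
  }
  residual <- sqrt(sum((forward(x) - y_subset)^2))
  est <- structure(
    list(image = if (is.null(layout)) NULL else fold_vector(layout, x),
         x_code_domain = x, n_datasets_used = 1L,
         residual_norm = residual, method = "cs",
         converged = converged, iterations = iters),
    class = "spi_estimate")
  est
}
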