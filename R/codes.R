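# Cyclic S-matrix codes.
#
# A cyclic S-matrix of order N is a {0,1} circulant whose rows are the N
# single-cell shifts of one binary sequence ("the code"). Printing that one
# sequence on a spinning mask therefore realizes a complete, well-conditioned
# single-pixel-imaging basis: each cell-width advance of the mask presents
# the next basis pattern. Valid codes are the indicator sequences of cyclic
# difference sets with parameters (N, (N+1)/2, (N+1)/4); three classical
# families are constructed here (quadratic residue, twin prime, m-sequence).
#
# Global circulant convention (shared by every module):
#   S[k, i] = bits[(i + k) mod N],  k, i = 0..N-1  (0-based)
# Note S is symmetric under this convention, so S == t(S).

.is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

# indicator of nonzero quadratic residues mod p, over 0..p-1
.qr_indicator <- function(p) {
  ind <- logical(p)
  i <- as.numeric(seq_len((p - 1) / 2))  # doubles: i^2 stays exact past 2^31
  ind[(i * i) %% p + 1L] <- TRUE
  ind
}

.new_code <- function(bits, method) {
  structure(
    list(order = length(bits), bits = as.integer(bits), method = method,
         weight = sum(bits)),
    class = "spi_code"
  )
}

#' @export
print.spi_code <- function(x, ...) {
  cat(sprintf("<spi_code> order N = %d, method = %s, weight = %d (= (N+1)/2: %s)\n",
              x$order, x$method, x$weight,
              if (x$weight == (x$order + 1) / 2) "yes" else "NO"))
  if (x$order <= 64) cat("  bits:", paste0(x$bits, collapse = ""), "\n")
  invisible(x)
}

#' Quadratic-residue cyclic S-matrix code
#'
#' Constructs the order-`p` cyclic code whose support is `{0}` together with
#' the nonzero quadratic residues modulo `p`. For a prime `p = 3 (mod 4)` the
#' quadratic residues form a cyclic difference set, so the circulant of the
#' resulting bits is an S-matrix: weight `(p+1)/2` and every nonzero-lag
#' cyclic autocorrelation equal to `(p+1)/4`. The order-19 mask is an
#' instance of this family.
#'
#' @param p prime with `p = 3 (mod 4)`, `p >= 3`.
#' @return an object of class `spi_code` with fields `order`, `bits`
#'   (integer 0/1, 1 = transparent cell), `method`, `weight`.
#' @examples
#' qr_code(7)$bits   # 1 1 1 0 1 0 0
#' validate_code(qr_code(19))
#' @export
qr_code <- function(p) {
  p <- .check_count(p, "p")
  if (!.is_prime(p)) stop("p = ", p, " is not prime; no quadratic-residue S-matrix code")
  if (p %% 4 != 3) stop("p = ", p, " is = 1 (mod 4); quadratic residues mod p are not a ",
                        "difference set, so this construction yields no S-matrix")
  bits <- integer(p)
  bits[.qr_indicator(p)] <- 1L
  bits[1L] <- 1L  # index 0 included so weight = (p+1)/2
  .new_code(bits, "quadratic_residue")
}

#' Twin-prime cyclic S-matrix code
#'
#' Constructs the order `N = p*q` code from the classical twin-prime
#' difference set on `Z_N` (with `q = p + 2`, both prime):
#' `D = {i : i = 0 (mod q)} u {i : chi_p(i) = chi_q(i) != 0}` where `chi` is
#' the Legendre symbol. `D` has size `(N-1)/2`; the code is the indicator of
#' the complement of `D`, cyclically translated so `bits[0] = 1`, giving
#' weight `(N+1)/2` and off-peak autocorrelation `(N+1)/4`. Because
#' `gcd(p, q) = 1`, these orders fold to exact `p x q` rectangles (see
#' [fold_crt()]); the 101 x 103 mask (N = 10,403) is an instance.
#'
#' @param p,q twin primes, `q = p + 2`.
#' @return an `spi_code` of order `p*q`.
#' @examples
#' twin_prime_code(3, 5)  # order 15, weight 8
#' @export
twin_prime_code <- function(p, q) {
  p <- .check_count(p, "p"); q <- .check_count(q, "q")
  if (!.is_prime(p)) stop("p = ", p, " is not prime")
  if (!.is_prime(q)) stop("q = ", q, " is not prime")
  if (q != p + 2) stop("(", p, ", ", q, ") are not twin primes (need q == p + 2)")
  n <- p * q
  i <- 0:(n - 1)
  qr_p <- .qr_indicator(p)[i %% p + 1L]
  qr_q <- .qr_indicator(q)[i %% q + 1L]
  nz_p <- i %% p != 0L
  nz_q <- i %% q != 0L
  in_d <- (i %% q == 0L) | (nz_p & nz_q & (qr_p == qr_q))
  comp <- which(!in_d) - 1L            # complement support, 0-based
  shift <- comp[1L]                    # translate so 0 is in the support
  bits <- integer(n)
  bits[(comp - shift) %% n + 1L] <- 1L
  .new_code(bits, "twin_prime")
}

# known primitive polynomials over GF(2), exponents of nonzero terms
.default_taps <- list(
  `2` = c(2, 1, 0),  `3` = c(3, 1, 0),  `4` = c(4, 1, 0),  `5` = c(5, 2, 0),
  `6` = c(6, 1, 0),  `7` = c(7, 1, 0),  `8` = c(8, 4, 3, 2, 0),
  `9` = c(9, 4, 0),  `10` = c(10, 3, 0), `11` = c(11, 2, 0),
  `12` = c(12, 6, 4, 1, 0), `13` = c(13, 4, 3, 1, 0), `14` = c(14, 5, 3, 1, 0),
  `15` = c(15, 1, 0), `16` = c(16, 12, 3, 1, 0), `17` = c(17, 3, 0),
  `18` = c(18, 7, 0), `19` = c(19, 5, 2, 1, 0), `20` = c(20, 3, 0),
  `21` = c(21, 2, 0), `22` = c(22, 1, 0), `23` = c(23, 5, 0),
  `24` = c(24, 7, 2, 1, 0)
)

#' Maximal-length-sequence (m-sequence) cyclic S-matrix code
#'
#' Runs a Fibonacci linear-feedback shift register defined by a primitive
#' polynomial of degree `m` over GF(2) for one full period `N = 2^m - 1` and
#' returns the output bits, rotated so `bits[0] = 1`. An m-sequence contains
#' `2^(m-1)` ones per period, so the code has weight `(N+1)/2` and ideal
#' two-level autocorrelation — the third classical cyclic S-matrix family,
#' covering orders `2^m - 1` unavailable from the other two constructions.
#'
#' Primitivity is verified operationally: if the register state returns to
#' its start in fewer than `N` steps the polynomial is not primitive and the
#' construction is rejected.
#'
#' @param m register length, `2 <= m <= 24`.
#' @param taps exponents of the nonzero terms of the feedback polynomial,
#'   including `m` and `0` (e.g. `c(4, 1, 0)` for x^4 + x + 1). Defaults to a
#'   table of known primitive polynomials.
#' @return an `spi_code` of order `2^m - 1`.
#' @examples
#' m_sequence_code(3)                 # order 7, weight 4
#' m_sequence_code(4, c(4, 1, 0))    # order 15
#' @export
m_sequence_code <- function(m, taps = NULL) {
  m <- .check_count(m, "m")
  if (m < 2 || m > 24) stop("m must be in 2..24, got ", m)
  if (is.null(taps)) taps <- .default_taps[[as.character(m)]]
  taps <- sort(unique(as.integer(taps)), decreasing = TRUE)
  if (max(taps) != m || !(0L %in% taps))
    stop("taps must include the leading exponent m = ", m, " and the constant term 0")
  n <- 2L^m - 1L
  fb <- setdiff(taps, m)          # feedback positions: bits at distance 'fb' from output
  state <- c(1L, integer(m - 1L)) # state[1] = oldest bit (the output)
  start <- state
  out <- integer(n)
  for (t in seq_len(n)) {
    out[t] <- state[1L]
    new_bit <- 0L
    for (f in fb) {
      # recurrence s[t+m] = XOR_f s[t+f] over the non-leading exponents f
      new_bit <- bitwXor(new_bit, state[f + 1L])
    }
    state <- c(state[-1L], new_bit)
    if (t < n && identical(state, start))
      stop("polynomial with taps {", paste(taps, collapse = ","),
           "} is not primitive: LFSR period ", t, " < ", n)
  }
  if (!identical(state, start))
    stop("LFSR did not return to its initial state after ", n, " steps")
  shift <- which(out == 1L)[1L] - 1L
  bits <- out[(((0:(n - 1)) + shift) %% n) + 1L]
  .new_code(bits, "m_sequence")
}

#' Validate a cyclic code as an S-matrix generator
#'
#' Checks the S-matrix invariants via the length-N DFT (O(N log N), so it
#' scales to the experimental orders 10,403 and 25,111 without forming dense
#' matrices): weight `(N+1)/2`, nonzero-lag cyclic autocorrelation
#' `(N+1)/4`, and invertibility of the circulant (no vanishing DFT
#' coefficient). For a valid code the DFT has DC coefficient `(N+1)/2` and
#' squared magnitude `(N+1)/4` at every other frequency, so the circulant's
#' condition number is `((N+1)/2) / sqrt((N+1)/4)`.
#'
#' Invalid codes yield a failing report, not an error.
#'
#' @param code an `spi_code` (or anything with `$bits`).
#' @param tol relative tolerance for the spectral checks.
#' @return a list of class `spi_code_report`: `order`, `weight_ok`,
#'   `autocorrelation_ok`, `min_abs_dft`, `condition_number`, `ok`.
#' @export
validate_code <- function(code, tol = 1e-6) {
  bits <- as.numeric(code$bits)
  n <- length(bits)
  ft <- spi_fft(bits)
  mag <- Mod(ft)
  weight_ok <- isTRUE(sum(bits) == (n + 1) / 2)
  # circular autocorrelation via the Wiener-Khinchin identity
  ac <- Re(spi_ifft(mag^2))
  target <- (n + 1) / 4
  ac_ok <- n > 1 && all(abs(ac[-1L] - target) <= tol * max(1, target)) &&
    abs(ac[1L] - sum(bits)) <= tol * max(1, n)
  min_abs <- min(mag)
  cond <- if (min_abs > 0) max(mag) / min_abs else Inf
  structure(
    list(order = n, weight_ok = weight_ok, autocorrelation_ok = ac_ok,
         min_abs_dft = min_abs, condition_number = cond,
         ok = weight_ok && ac_ok && min_abs > tol),
    class = "spi_code_report"
  )
}

#' @export
print.spi_code_report <- function(x, ...) {
  cat(sprintf("<spi_code_report> N = %d: weight %s, autocorrelation %s, min|DFT| = %.6g, cond = %.6g -> %s\n",
              x$order, if (x$weight_ok) "ok" else "FAIL",
              if (x$autocorrelation_ok) "ok" else "FAIL",
              x$min_abs_dft, x$condition_number,
              if (x$ok) "valid S-matrix code" else "NOT a valid S-matrix code"))
  invisible(x)
}

#' Row of the cyclic S-matrix
#'
#' Row `k` of the circulant S-matrix is the code advanced by `k` cells:
#' `row[i] = bits[(i + k) mod N]` — on the physical mask, the pattern
#' presented after `k` single-cell shifts.
#'
#' @param code an `spi_code`.
#' @param k shift index, `0 <= k < N` (raw out-of-range values are rejected,
#'   not reduced).
#' @return integer 0/1 vector of length N.
#' @export
smatrix_row <- function(code, k) {
  n <- code$order
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 0 || k >= n)
    stop("shift index k must be an integer in [0, ", n - 1, "], got ", k)
  code$bits[((0:(n - 1) + k) %% n) + 1L]
}

#' Dense S-matrix (small orders)
#'
#' Materializes the full N x N circulant under the package convention
#' `S[k, i] = bits[(i + k) mod N]`. Intended for oracle checks at small N;
#' refuses orders above `max_order`.
#'
#' @param code an `spi_code`.
#' @param max_order guard against accidental huge allocations.
#' @return integer N x N matrix.
#' @export
smatrix <- function(code, max_order = 512L) {
  n <- code$order
  if (n > max_order) stop("refusing to build a dense ", n, " x ", n, " S-matrix")
  t(vapply(0:(n - 1), function(k) smatrix_row(code, k), integer(n)))
}

#' Closed-form S-matrix inverse applied to a vector
#'
#' For a valid S-matrix, `S^{-1} = (2/(N+1)) (2 S^T - J)` with `J` the
#' all-ones matrix, so `x = (2/(N+1)) (2 S^T y - sum(y) 1)`. Under the
#' package's circulant convention S is symmetric, so `S^T y` is the same
#' cyclic correlation as the forward projection; it is evaluated here by
#' direct summation (O(N^2)) to stay independent of the FFT path it serves
#' as an oracle for. Because the sampling matrix is well-conditioned no
#' regularization is involved.
#'
#' @param code an `spi_code`.
#' @param y numeric vector of length N (one detector sample per pattern).
#' @return numeric vector of length N.
#' @examples
#' code <- qr_code(7)
#' x <- rnorm(7)
#' y <- project(code, x)
#' max(abs(analytic_inverse_apply(code, y) - x))
#' @export
analytic_inverse_apply <- function(code, y) {
  n <- code$order
  if (length(y) != n) stop("y has length ", length(y), ", expected N = ", n)
  bits <- as.numeric(code$bits)
  sty <- vapply(0:(n - 1), function(i) {
    sum(bits[((0:(n - 1) + i) %% n) + 1L] * y)
  }, numeric(1))
  (2 / (n + 1)) * (2 * sty - sum(y))
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < 1)
    stop(name, " must be a single positive integer")
  as.integer(x)
}

#' Write / read a cyclic code as plain text
#'
#' Line 1 is a header `order method`, line 2 the N bits as a contiguous 0/1
#' string — the interoperable ground truth for mask fabrication. A `.json`
#' path serializes the same fields as JSON.
#'
#' @param code an `spi_code`.
#' @param path destination (a `.json` extension selects JSON).
#' @return `write_code` returns `path` invisibly; `read_code` an `spi_code`.
#' @export
write_code <- function(code, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(order = code$order, method = code$method,
           bits = paste0(code$bits, collapse = "")),
      path, auto_unbox = TRUE)
  } else {
    writeLines(c(paste(code$order, code$method),
                 paste0(code$bits, collapse = "")), path)
  }
  invisible(path)
}

#' @rdname write_code
#' @export
read_code <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    bits <- as.integer(strsplit(obj$bits, "")[[1]])
    if (length(bits) != obj$order) stop("corrupt code file: ", path)
    return(.new_code(bits, obj$method))
  }
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  bits <- as.integer(strsplit(trimws(lines[2L]), "")[[1]])
  if (length(bits) != as.integer(hdr[1L])) stop("corrupt code file: ", path)
  .new_code(bits, hdr[2L])
}
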