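test_that("qr_code reproduces enumerated quadratic residues and rejects bad orders", {
  # residues mod 7: {1, 2, 4}; support {0} u residues
  expect_equal(qr_code(7)$bits, c(1L, 1L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(qr_code(7)$weight, 4L)

  c19 <- qr_code(19)
  expect_equal(c19$order, 19L)
  expect_equal(c19$weight, 10L)
  # pairwise row overlap 5 = (N+1)/4, by brute force
  expect_true(all(brute_autocorrelation(c19$bits)[-1] == 5))

  expect_error(qr_code(9), "not prime")
  expect_error(qr_code(13), "mod 4")
  expect_error(qr_code(2), "mod 4")
})

test_that("twin_prime_code builds difference-set complements with exact autocorrelation", {
  c15 <- twin_prime_code(3, 5)
  expect_equal(c15$order, 15L)
  expect_equal(c15$weight, 8L)
  expect_equal(c15$bits[1], 1L)
  expect_true(all(brute_autocorrelation(c15$bits)[-1] == 4))
  # dense oracle: S S^T == ((N+1)/4)(I + J)
  s <- dense_smatrix(c15$bits)
  expect_identical(s %*% t(s), 4L * (diag(15L) + matrix(1L, 15, 15)))

  expect_error(twin_prime_code(5, 9), "not prime")
  expect_error(twin_prime_code(5, 11), "twin primes")
  expect_error(twin_prime_code(13, 15), "not prime")
})

test_that("m_sequence_code runs the LFSR for a full period and rejects non-primitive taps", {
  c7 <- m_sequence_code(3, c(3, 1, 0))
  expect_equal(c7$order, 7L)
  expect_equal(c7$weight, 4L)
  expect_true(all(brute_autocorrelation(c7$bits)[-1] == 2))

  c15 <- m_sequence_code(4, c(4, 1, 0))
  expect_equal(c15$order, 15L)
  expect_equal(c15$weight, 8L)
  expect_valid_code(c15)

  # x^4 + x^2 + 1 = (x^2 + x + 1)^2 is not primitive: period 6
  expect_error(m_sequence_code(4, c(4, 2, 0)), "period 6")
  expect_error(m_sequence_code(1), "2\\.\\.24")
  expect_error(m_sequence_code(4, c(4, 1)), "constant term")
})

test_that("all three families pass the dense S-matrix oracle for N <= 31", {
  codes <- list(qr_code(7), qr_code(11), qr_code(19), qr_code(23), qr_code(31),
                twin_prime_code(3, 5), twin_prime_code(5, 7),
                m_sequence_code(3), m_sequence_code(4))
  for (code in codes) {
    n <- code$order
    s <- dense_smatrix(code$bits)
    expect_identical(s %*% t(s),
                     as.integer((n + 1) / 4) * (diag(n) + matrix(1L, n, n)))
    expect_valid_code(code)
  }
})

test_that("validate_code computes DFT-based diagnostics and flags invalid codes", {
  rep19 <- validate_code(qr_code(19))
  expect_true(rep19$weight_ok && rep19$autocorrelation_ok)
  expect_equal(rep19$condition_number, 10 / sqrt(5), tolerance = 1e-10)
  expect_equal(rep19$min_abs_dft, sqrt(5), tolerance = 1e-10)

  all_ones <- validate_code(raw_code(rep(1L, 7)))
  expect_false(all_ones$autocorrelation_ok)
  expect_equal(all_ones$min_abs_dft, 0)
  expect_false(all_ones$ok)

  # spectral invariant at experimental scale: |DFT|^2 = (N+1)^2/4 at DC,
  # (N+1)/4 elsewhere
  big <- twin_prime_code(101, 103)
  mag2 <- Mod(cyclospi:::spi_fft(as.numeric(big$bits)))^2
  n <- big$order
  expect_equal(mag2[1], ((n + 1) / 2)^2, tolerance = 1e-6)
  expect_equal(max(abs(mag2[-1] - (n + 1) / 4)) / ((n + 1) / 4), 0, tolerance = 1e-6)

  # 25,111 (the circular-field order) is prime and = 3 (mod 4), so the
  # quadratic-residue family covers it; validated spectrally, never densely
  expect_true(cyclospi:::.is_prime(25111) && 25111 %% 4 == 3)
  expect_true(validate_code(qr_code(25111))$ok)
})

test_that("construction preconditions hold exactly over orders below 200", {
  for (n in 3:199) {
    ok_qr <- cyclospi:::.is_prime(n) && n %% 4 == 3
    if (ok_qr) expect_valid_code(qr_code(n)) else expect_error(qr_code(n))
  }
  for (p in 2:13) {
    ok_tp <- cyclospi:::.is_prime(p) && cyclospi:::.is_prime(p + 2)
    if (ok_tp) expect_valid_code(twin_prime_code(p, p + 2))
    else expect_error(twin_prime_code(p, p + 2))
  }
})

test_that("smatrix_row shifts cyclically and rejects out-of-range shifts", {
  c7 <- qr_code(7)
  expect_equal(smatrix_row(c7, 0), c7$bits)
  expect_error(smatrix_row(c7, 7))
  expect_error(smatrix_row(c7, -1))
  # N successive unit shifts compose to the identity
  v <- c7$bits
  for (i in 1:7) v <- raw_code(v)$bits[c(2:7, 1)]
  expect_equal(v, c7$bits)
  expect_equal(smatrix(c7)[3, ], smatrix_row(c7, 2))
})

test_that("analytic_inverse_apply inverts the projection", {
  # hand computation: bits (1,1,0), y = (3,4,5): S^T y = (7,8,9) -> x = (1,2,3)
  c3 <- raw_code(c(1L, 1L, 0L))
  expect_equal(analytic_inverse_apply(c3, c(3, 4, 5)), c(1, 2, 3))
  expect_equal(analytic_inverse_apply(c3, c(0, 0, 0)), c(0, 0, 0))
  expect_error(analytic_inverse_apply(c3, 1:4), "length")

  set.seed(11)
  for (code in list(qr_code(3), qr_code(7), twin_prime_code(3, 5), qr_code(19), qr_code(31))) {
    x <- rnorm(code$order)
    y <- dense_project(code$bits, x)
    expect_lt(max(abs(analytic_inverse_apply(code, y) - x)), 1e-9 * max(1, max(abs(x))))
  }
})

test_that("codes round-trip through text and JSON serialization", {
  code <- twin_prime_code(5, 7)
  txt <- tempfile(fileext = ".txt")
  js <- tempfile(fileext = ".json")
  write_code(code, txt)
  write_code(code, js)
  for (back in list(read_code(txt), read_code(js))) {
    expect_identical(back$bits, code$bits)
    expect_identical(back$method, code$method)
    expect_identical(back$order, code$order)
  }
})
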