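test_that("split_shift rounds to the nearest integer with fraction in [-0.5, 0.5)", {
  s <- split_shift(c(5.75, -2.25))
  expect_identical(s$s_int, c(6L, -2L))
  expect_equal(s$s_sub, c(-0.25, -0.25))

  s <- split_shift(c(3, 0))
  expect_identical(s$s_int, c(3L, 0L))
  expect_equal(s$s_sub, c(0, 0))

  # ties: the fraction must land in the half-open interval
  s <- split_shift(c(0.5, -0.5))
  expect_identical(s$s_int, c(1L, 0L))
  expect_equal(s$s_sub, c(-0.5, -0.5))

  expect_error(split_shift(c(NaN, 0)), "finite")
})

test_that("split_shift reassembles exactly and stays in range for random inputs", {
  r <- withr::with_seed(42, matrix(runif(2e5, -1e3, 1e3), ncol = 2))
  got <- apply(r, 1, function(ri) {
    s <- split_shift(ri)
    identical(s$s_int + s$s_sub, ri) &&
      all(s$s_sub >= -0.5 & s$s_sub < 0.5)
  })
  expect_true(all(got))
})

test_that("subpixel probe shift is energy-preserving, invertible, and matches the impulse closed form", {
  P <- random_complex(8, 8, 1)
  expect_equal(shift_probe_subpixel(P, c(0, 0)), P)
  sh <- shift_probe_subpixel(P, c(0.3, -0.45))
  expect_equal(sum(Mod(sh)^2), sum(Mod(P)^2), tolerance = 1e-12)
  back <- shift_probe_subpixel(sh, c(-0.3, 0.45))
  expect_equal(back, P, tolerance = 1e-10)
  expect_error(shift_probe_subpixel(P, c(0.6, 0)), "magnitude")

  # half-pixel shift of a unit impulse: closed-form Fourier interpolation
  n <- 8
  delta <- matrix(0 + 0i, n, n); delta[1, 1] <- 1
  got <- shift_probe_subpixel(delta, c(0.5, 0))
  k <- c(0:(n / 2 - 1), -(n / 2):-1)
  expected_col <- Re(vapply(0:(n - 1), function(a)
    sum(exp(2i * pi * k * (a - 0.5) / n)) / n, complex(1)))
  expect_equal(Re(got[, 1]), expected_col, tolerance = 1e-10)
  expect_equal(max(Mod(got[, -1])), 0, tolerance = 1e-12)
})

test_that("object patch extraction and write-back are exact adjoint partners", {
  O <- matrix(1 + 0i, 8, 8)
  patch <- object_patch(O, c(2L, 2L), c(4L, 4L))
  expect_identical(dim(patch), c(4L, 4L))
  O2 <- write_patch(O, c(2L, 2L), patch)
  expect_identical(O2, O)

  O3 <- write_patch(O, c(2L, 2L), matrix(0 + 0i, 4, 4))
  expect_identical(sum(O3 == 0), 16L)
  expect_identical(sum(O3 == 1), 48L)

  # overlapping writes on a 6x6 canvas: the second write wins on the overlap
  O4 <- matrix(0 + 0i, 6, 6)
  O4 <- write_patch(O4, c(0L, 0L), matrix(1 + 0i, 3, 3))
  O4 <- write_patch(O4, c(1L, 1L), matrix(2 + 0i, 3, 3))
  brute <- matrix(0 + 0i, 6, 6)
  for (i in 1:3) for (j in 1:3) brute[i, j] <- 1
  for (i in 2:4) for (j in 2:4) brute[i, j] <- 2
  expect_identical(O4, brute)

  expect_error(object_patch(O, c(5L, 5L), c(4L, 4L)), "outside")
})

test_that("exit wave is the element-wise product of probe and patch", {
  P <- random_complex(4, 4, 2)
  expect_equal(exit_wave(matrix(1 + 0i, 4, 4), P), P)
  expect_equal(exit_wave(P, matrix(0 + 0i, 4, 4)), matrix(0 + 0i, 4, 4))
  O2 <- matrix(c(1 + 1i, 2, -1i, 0.5), 2, 2)
  P2 <- matrix(c(2, 1i, 3, -1), 2, 2)
  expect_equal(exit_wave(O2, P2), O2 * P2)
  expect_error(exit_wave(matrix(0i, 2, 2), P), "shapes")
})

test_that("propagation is unitary and agrees with the brute-force DFT", {
  psi <- random_complex(4, 4, 3)
  expect_equal(sum(Mod(propagate(psi))^2), sum(Mod(psi)^2),
               tolerance = 1e-12)
  expect_equal(back_propagate(propagate(psi)), psi, tolerance = 1e-10)
  expect_equal(propagate(psi), dft2(psi), tolerance = 1e-10)

  # impulse: flat modulus 1/4 on a 4x4 grid under unitary scaling
  imp <- matrix(0 + 0i, 4, 4); imp[1, 1] <- 1
  expect_equal(Mod(propagate(imp)), matrix(0.25, 4, 4), tolerance = 1e-12)

  # constant field: impulse at zero frequency
  const <- matrix(1 + 0i, 4, 4)
  F <- propagate(const)
  expect_equal(F[1, 1], 4 + 0i, tolerance = 1e-12)
  expect_equal(max(Mod(F[-1])), 0, tolerance = 1e-12)
})

test_that("clean intensity is nonnegative and satisfies Parseval", {
  expect_equal(clean_intensity(matrix(0 + 0i, 3, 3)), matrix(0, 3, 3))
  psi <- random_complex(8, 8, 4)
  I <- clean_intensity(psi)
  expect_true(all(I >= 0))
  expect_equal(sum(I), sum(Mod(psi)^2), tolerance = 1e-10)
  # 2x2 worked case against the brute-force DFT
  psi2 <- matrix(c(1 + 1i, 2, 0, -1i), 2, 2)
  expect_equal(clean_intensity(psi2), Mod(dft2(psi2))^2, tolerance = 1e-12)
})

test_that("Poisson noise has the right first two moments and is seed-stable", {
  expect_equal(apply_poisson_noise(matrix(0, 4, 4), 1), matrix(0, 4, 4))
  expect_error(apply_poisson_noise(matrix(-1, 2, 2), 1), "nonnegative")

  draws <- apply_poisson_noise(matrix(1e4, 100, 100), 7)
  se <- sqrt(1e4 / length(draws))
  expect_lt(abs(mean(draws) - 1e4), 3 * se)
  expect_lt(abs(var(as.numeric(draws)) / 1e4 - 1), 0.1)
  expect_identical(apply_poisson_noise(matrix(1e4, 10, 10), 5),
                   apply_poisson_noise(matrix(1e4, 10, 10), 5))

  # large-mean branch keeps the Poisson moments
  big <- apply_poisson_noise(matrix(1e9, 50, 50), 11)
  expect_lt(abs(mean(big) - 1e9), 3 * sqrt(1e9 / length(big)))
  expect_lt(abs(var(as.numeric(big)) / 1e9 - 1), 0.15)
})

test_that("magnitude projection reproduces the measured intensity exactly", {
  # worked 2x2 case via the brute-force DFT oracle
  psi <- matrix(c(1 + 1i, -2, 0.5i, 3), 2, 2)
  I <- matrix(c(4, 1, 2.25, 0.25), 2, 2)
  F <- dft2(psi)
  s <- ifelse(Mod(F) == 0, 1 + 0i, F / Mod(F))
  expected <- dft2(sqrt(I) * s, inverse = TRUE)
  expect_equal(revised_exit_wave(psi, I), expected, tolerance = 1e-10)

  # identity when the model already matches the data
  I0 <- clean_intensity(psi)
  expect_equal(revised_exit_wave(psi, I0), psi, tolerance = 1e-10)

  # zero field: sign(0) := 1 keeps the measured modulus with zero phase
  z <- matrix(0 + 0i, 2, 2)
  expect_equal(revised_exit_wave(z, I), back_propagate(sqrt(I) + 0i),
               tolerance = 1e-12)

  # projection exactness on 100 seeded random pairs
  for (i in 1:100) {
    psi <- random_complex(8, 8, 100 + i)
    I <- Mod(random_complex(8, 8, 200 + i))^2
    got <- clean_intensity(revised_exit_wave(psi, I))
    expect_lt(max(abs(got - I)) / max(I), 1e-8)
  }
})
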