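test_that("polynomial aberration surfaces evaluate monomials exactly", {
  # pure-y term vanishes on the first row (y = 0)
  s <- aberration_spec(0, 1, 1e-2)
  a <- aberration_surface(s, 32, 32)
  expect_equal(a$values[1, ], rep(0, 32))
  expect_false(a$wrapped)

  # independent scalar evaluation of a single monomial
  a2 <- aberration_surface(aberration_spec(2, 1, 1e-8), 256, 256)
  expect_equal(a2$values[201, 101], 1e-8 * 100^2 * 200)  # x = 100, y = 200

  # tilt magnitude across a 512-px grid matches the coefficient scale
  a3 <- aberration_surface(aberration_spec(c(3, 0), c(0, 1), c(1e-8, 1e-2)),
                           512, 512)
  expect_equal(a3$values[512, 1], 1e-2 * 511)
  expect_equal(a3$values[1, 512], 1e-8 * 511^3)
})

test_that("aberration specs validate their terms and expose cross terms", {
  expect_error(aberration_spec(-1, 0, 1), "non-negative")
  expect_error(aberration_spec(c(1, 1), c(2, 2), c(1, 2)), "duplicate")
  s <- aberration_spec(k = c(0, 1, 2), l = c(1, 0, 3), value = c(1, 1, 1))
  expect_equal(cross_terms(s), c(FALSE, FALSE, TRUE))
  expect_equal(attr(s, "K"), 2)
  expect_equal(attr(s, "L"), 3)
})

test_that("surface evaluation is linear in the coefficients", {
  s1 <- aberration_spec(c(2, 0), c(1, 2), c(3e-6, -1e-4))
  s2 <- aberration_spec(c(1, 0), c(1, 0), c(2e-5, 0.3))
  both <- aberration_spec(c(2, 0, 1, 0), c(1, 2, 1, 0),
                          c(2 * 3e-6, 2 * -1e-4, 2e-5, 0.3))
  lhs <- aberration_surface(both, 48, 40)$values
  rhs <- 2 * aberration_surface(s1, 48, 40)$values +
    aberration_surface(s2, 48, 40)$values
  expect_equal(lhs, rhs, tolerance = 1e-14)
})

test_that("separable (non-cross) surfaces give a rank-1 complex field", {
  s <- aberration_spec(c(3, 0, 2), c(0, 1, 0), c(1e-6, 5e-2, -1e-4))
  a <- aberration_surface(s, 96, 96)
  d <- svd(exp(1i * a$values), nu = 0, nv = 0)$d
  expect_lt(d[2] / d[1], 1e-10)
})

test_that("sample phase composes a Gaussian spot and a letter step", {
  null <- sample_phase(32, 32, gaussian_peak = 0, mask = matrix(0L, 32, 32),
                       mask_height = 0)
  expect_equal(null$values, matrix(0, 32, 32))

  g <- sample_phase(101, 101, gaussian_peak = 1, gaussian_sigma = 50,
                    gaussian_center = c(50, 50), mask = matrix(0L, 101, 101))
  expect_equal(g$values[51, 51], 1)  # Gaussian maximum at the center pixel
  expect_lt(max(g$values[1, ]), 1)

  m <- letter_mask(256, 256, scale = 4)
  expect_true(all(m %in% c(0L, 1L)))
  expect_lt(mean(m), 0.05)  # letters cover under 5% of pixels
  expect_gt(sum(m), 0)
  s <- sample_phase(256, 256, gaussian_peak = 0, mask = m, mask_height = 1.5)
  expect_equal(sum(s$values == 1.5), sum(m))

  expect_error(sample_phase(32, 32, mask = matrix(0L, 16, 16)),
               "dimensions")
  expect_error(sample_phase(32, 32, gaussian_sigma = 0), "sigma")
})

test_that("wrapping reduces onto (-pi, pi] and inverts through unwrapping", {
  z <- wrap_phase(matrix(0, 8, 8))
  expect_equal(z$values, matrix(0, 8, 8))
  expect_true(z$wrapped)

  w <- wrap_phase(matrix(3 * pi / 2, 8, 8))
  expect_equal(w$values, matrix(-pi / 2, 8, 8))
  expect_equal(wrap_phase(matrix(pi, 2, 2))$values, matrix(pi, 2, 2))

  # wrap(unwrap(wrap(phi))) == wrap(phi) for a smooth surface
  phi <- aberration_surface(aberration_spec(c(0, 1), c(1, 1), c(1e-2, 1e-4)),
                            64, 64)
  w1 <- wrap_phase(phi)
  w2 <- wrap_phase(unwrap_phase(w1))
  expect_equal(w2$values, w1$values, tolerance = 1e-12)
})

test_that("phase noise is reproducible, unbiased, and leaves the RNG alone", {
  p <- phase_image(matrix(0, 80, 80))
  expect_identical(add_phase_noise(p, 0, seed = 3)$values, p$values)

  n1 <- add_phase_noise(p, 0.1, seed = 11)
  n2 <- add_phase_noise(p, 0.1, seed = 11)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values,
                         add_phase_noise(p, 0.1, seed = 12)$values))

  # sample STD close to sigma (chi-distribution spread ~ sigma/sqrt(2N))
  N <- length(p$values)
  expect_lt(abs(sd(n1$values) - 0.1), 3 * 0.1 / sqrt(2 * N))

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(add_phase_noise(p, 0.5, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})
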