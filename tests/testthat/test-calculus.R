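test_that("j-fold forward difference of x^j is exactly j! on integer grids", {
  for (j in 1:4) {
    # independent oracle: repeated base-R diff on the 1D sequence
    v <- (0:40)^j
    for (s in seq_len(j)) v <- diff(v)
    expect_identical(v, rep(factorial(j), 41 - j))

    ph <- monomial_phase(j, 0, 1, 16, 48)
    out <- phase_derivative(ph, "x", j)
    expect_equal(out$derivative$values,
                 matrix(factorial(j), 16, 48 - j))
  }
})

test_that("differencing a cross term along x leaves a pure-y surface", {
  ph <- monomial_phase(2, 1, 1e-8, 64, 64)
  out <- phase_derivative(ph, "x", 2)
  expected <- matrix(rep(2e-8 * (0:63), 62), 64, 62)  # 2 P y, no x content
  expect_lt(max(abs(out$derivative$values - expected)), 1e-16)
  fit <- fit_phase_surface(out$derivative, 2, 1)
  expect_true(all(abs(fit$value[cross_terms(fit)]) < 1e-18))
})

test_that("integration exactly inverts differentiation with saved boundaries", {
  set.seed(7)
  ph <- aberration_surface(
    aberration_spec(c(2, 1, 3, 0), c(0, 1, 1, 2),
                    c(2e-4, 1e-4, 1e-7, 5e-4)), 48, 56)
  for (axis in c("x", "y")) for (j in 1:3) {
    out <- phase_derivative(ph, axis, j)
    expect_equal(length(out$record$saved), j)
    back <- phase_integral(out$derivative, out$record)
    expect_lt(max(abs(back$values - ph$values)), 1e-9)
  }

  # full-scale round trip on the combined demo surface
  big <- aberration_surface(combined_aberration_spec(), 512, 512)
  out <- phase_derivative(big, "x", 1)
  back <- phase_integral(out$derivative, out$record)
  expect_lt(max(abs(back$values - big$values)), 1e-9)
})

test_that("cumulative sums follow the closed-form ramp on constants", {
  # zero derivative with the record of a constant image gives it back
  const <- phase_image(matrix(2.5, 10, 12))
  out <- phase_derivative(const, "x", 1)
  expect_equal(out$derivative$values, matrix(0, 10, 11))
  expect_equal(phase_integral(out$derivative, out$record)$values,
               const$values)

  # constant surface with a zero boundary integrates to c * x
  rec <- phase_derivative(phase_image(matrix(0, 10, 12)), "x", 1)$record
  ramp <- phase_integral(phase_image(matrix(0.3, 10, 11)), rec)
  expect_equal(ramp$values, matrix(rep(0.3 * (0:11), each = 10), 10, 12))
})

test_that("differentiation rejects wrapped input and over-long orders", {
  w <- wrap_phase(matrix(1, 8, 8))
  expect_error(phase_derivative(w, "x", 1), "unwrapped")
  expect_error(phase_derivative(phase_image(matrix(0, 4, 4)), "x", 4),
               "extent")
  out <- phase_derivative(phase_image(matrix(rnorm(64), 8, 8)), "y", 2)
  bad <- out$record; bad$saved[[1]] <- bad$saved[[1]][1:3]
  expect_error(phase_integral(out$derivative, bad), "length")
})

test_that("boundary smoothing fits the border and leaves the interior alone", {
  ph <- aberration_surface(
    aberration_spec(c(2, 0), c(1, 3), c(1e-6, 1e-5)), 64, 64)
  sm <- smooth_boundaries(ph, 2, fit_degree = 5)
  # a polynomial surface of compatible degree is reproduced by its fits
  expect_lt(max(abs(sm$values - ph$values)), 1e-9)

  noisy <- add_phase_noise(ph, 0.05, seed = 5)$values
  noisy[2:63, 2:63] <- ph$values[2:63, 2:63]  # noise on the border only
  sm2 <- smooth_boundaries(phase_image(noisy), 1, fit_degree = 3)
  expect_identical(sm2$values[3:60, 3:60], noisy[3:60, 3:60])
  expect_lt(sd(sm2$values[1, ] - ph$values[1, ]),
            sd(noisy[1, ] - ph$values[1, ]))
})
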