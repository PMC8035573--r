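test_that("variance spectrum separates separable from cross-term phases", {
  # constant phase: rank-1 matrix, all variance on PC1
  vs <- variance_spectrum(phase_image(matrix(0.7, 32, 32)))
  expect_equal(vs[1], 1)
  expect_lt(max(vs[-1]), 1e-12)
  expect_equal(sum(vs), 1, tolerance = 1e-12)
  expect_true(all(diff(vs) <= 1e-15))

  # separable cubic + tilt: PC1 dominant
  sep <- aberration_surface(aberration_spec(c(3, 0), c(0, 1), c(1e-8, 1e-2)),
                            512, 512)
  expect_gte(variance_spectrum(sep)[1], 0.999)

  # cross term: PC1 no longer dominant, next components comparable among
  # themselves instead of negligible (PC2 fraction ~1e-2 here vs ~1e-30 for
  # the separable surface above)
  cross <- aberration_surface(aberration_spec(2, 1, 1e-8), 512, 512)
  vsx <- variance_spectrum(cross)
  expect_lt(vsx[1], 0.99)
  expect_gt(vsx[2], 1e-3)
})

test_that("rank-1 estimation reconstructs separable phases to 1e-6", {
  tilt <- aberration_surface(aberration_spec(0, 1, 1e-2), 256, 256)
  est <- estimate_separable_aberration(tilt)
  expect_lt(residual_std(est$reconstructed, tilt), 1e-6)
  expect_equal(est$reconstructed$values,
               outer(est$u_fit, rep(1, 256)) + outer(rep(1, 256), est$v_fit))

  zero <- phase_image(matrix(0, 64, 64))
  est0 <- suppressWarnings(estimate_separable_aberration(zero))
  expect_lt(residual_std(est0$reconstructed), 1e-9)
})

test_that("rank-1 estimation fails on cross terms, the dPCA motivation", {
  cross <- aberration_surface(aberration_spec(2, 1, 1e-8), 512, 512)
  est <- estimate_separable_aberration(cross)
  resid <- cross$values - est$reconstructed$values
  expect_gt(sqrt(mean((resid - mean(resid))^2)), 0.1)
})

test_that("random separable polynomial phases are recovered exactly", {
  set.seed(42)
  for (rep in 1:4) {
    kx <- sample(1:5, 1); ly <- sample(1:5, 1)
    s <- aberration_spec(c(kx, 0), c(0, ly),
                         c(monomial_coef(kx, 0, runif(1, 0.5, 3), 128, 128),
                           monomial_coef(0, ly, runif(1, 0.5, 3), 128, 128)))
    ph <- aberration_surface(s, 128, 128)
    est <- estimate_separable_aberration(ph)
    expect_lt(residual_std(est$reconstructed, ph), 1e-6)
  }
})

test_that("estimation is invariant under piston and unit complex scaling", {
  s <- aberration_spec(c(2, 0), c(0, 1), c(1e-5, 2e-2))
  ph <- aberration_surface(s, 128, 128)
  est <- estimate_separable_aberration(ph)
  shifted <- phase_image(ph$values + 0.37)
  est2 <- estimate_separable_aberration(shifted)
  d <- est2$reconstructed$values - est$reconstructed$values
  expect_lt(max(abs(d - mean(d))), 1e-6)

  # variance fractions unchanged by a global phase factor
  expect_equal(variance_spectrum(shifted), variance_spectrum(ph),
               tolerance = 1e-9)
})
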