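# Shared fixtures, all generated in code.

# Single monomial P * x^k * y^l as a phase_image.
monomial_phase <- function(k, l, value, height = 64, width = 64) {
  aberration_surface(aberration_spec(k, l, value), height, width)
}

# Coefficient giving a monomial surface a max of `amp` radians on the grid.
monomial_coef <- function(k, l, amp, height, width) {
  amp / ((width - 1)^k * (height - 1)^l)
}

# Piston-free standard deviation over the whole image.
residual_std <- function(phase, truth = 0) {
  r <- phase_values(phase) - phase_values(truth)
  sqrt(mean((r - mean(r))^2))
}

full_region <- function(height, width) {
  background_region(c(1, 1, height, width))
}

# The five-coefficient combined aberration used in the worked demo
# (quadratic field curvature, astigmatism, and third/fourth-order coma-like
# cross terms).
combined_aberration_spec <- function() {
  aberration_spec(k = c(2, 1, 3, 1, 1), l = c(0, 1, 1, 3, 2),
                  value = c(1e-5, 1e-5, 1e-11, 1e-11, 1e-8))
}
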