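#' Variance spectrum of the complex phase field
#'
#' Maps the phase to the unit-modulus complex field `exp(i*phase)`, takes
#' its singular value decomposition (no mean-centering: centering would
#' destroy the rank-1 factorisation `exp(i*(f(x)+g(y))) = u v^H` that the
#' method relies on), and returns the fraction of variance carried by each
#' component, `sigma_m^2 / sum(sigma^2)`.
#'
#' A phase that is separable as `f(x) + g(y)` yields a rank-1 field: the
#' first fraction is ~1.  Cross terms `x^k y^l` (k, l both nonzero) spread
#' the spectrum over several comparable components — the diagnostic failure
#' mode of conventional PCA aberration estimation.
#'
#' @param phase A `phase_image` (wrapped or unwrapped) or numeric matrix.
#' @return Numeric vector of variance fractions, non-increasing, summing
#'   to 1.
#' @export
variance_spectrum <- function(phase) {
  v <- phase_values(phase)
  if (!all(is.finite(v))) stop("phase must be finite")
  d <- svd(exp(1i * v), nu = 0, nv = 0)$d
  d^2 / sum(d^2)
}

#' Estimate a separable aberration surface by rank-1 PCA
#'
#' The work-horse of both conventional PCA compensation and each dPCA
#' iteration.  The complex field `exp(i*phase)` is decomposed by SVD; the
#' first left/right singular vectors are the rank-1 factors whose phases
#' are (up to wrapping) the row profile `g(y)` and column profile `f(x)` of
#' a separable phase surface.  Both phases are unwrapped with
#' [unwrap_phase_1d()] and replaced by their ordinary least-squares
#' polynomial fits of degree `fit_degree` to get rid of noise; the
#' reconstructed aberration is the outer sum of the two fitted profiles.
#'
#' The global phase of the rank-1 product is split arbitrarily between the
#' two singular vectors by the decomposition; it is reassigned wholly to
#' the column profile (`v_phase`), a fixed piston convention.  All
#' downstream evaluations remove piston anyway.
#'
#' @param phase A `phase_image` or numeric matrix (radians).
#' @param fit_degree Polynomial degree of the singular-vector fits
#'   (default 5, covering the below-fourth-order aberrations of a normal
#'   DHM system with margin).
#' @return An object of class `pca_result`: list with `variance_fractions`,
#'   `u_phase` (unwrapped row-profile phase, length = height), `v_phase`
#'   (column profile, length = width), `u_fit`, `v_fit` (their polynomial
#'   fits), `fit_degree`, and `reconstructed` (unwrapped `phase_image`,
#'   `reconstructed[y, x] = u_fit[y] + v_fit[x]`).
#' @export
estimate_separable_aberration <- function(phase, fit_degree = 5) {
  v <- phase_values(phase)
  if (fit_degree < 1) stop("fit_degree must be >= 1")
  if (min(dim(v)) <= fit_degree)
    stop("image must exceed fit_degree + 1 pixels in each dimension")
  field <- exp(1i * v)
  s <- svd(field, nu = 1, nv = 1)
  if (length(s$d) > 1 && s$d[1] - s$d[2] < 1e-12)
    warning("degenerate leading singular values; taking the first component as returned")
  u_phase <- unwrap_phase_1d(Arg(s$u[, 1]))
  v_phase <- unwrap_phase_1d(-Arg(s$v[, 1]))  # field ~ d1 * u %*% Conj(t(v))
  piston <- u_phase[1]
  u_phase <- u_phase - piston
  v_phase <- v_phase + piston
  u_fit <- polyfit_1d(u_phase, fit_degree)
  v_fit <- polyfit_1d(v_phase, fit_degree)
  # The singular-vector phases represent the surface only modulo a global
  # 2*pi (the Arg branch): realign to the input surface by the nearest
  # multiple.  Essential when the reconstruction is integrated later -- a
  # spurious 2*pi piston in a derivative becomes a 2*pi*x ramp.
  branch <- 2 * pi * round(mean(v - (mean(u_fit) + mean(v_fit))) / (2 * pi))
  v_fit <- v_fit + branch
  v_phase <- v_phase + branch
  rec <- outer(u_fit, rep(1, length(v_fit))) +
    outer(rep(1, length(u_fit)), v_fit)
  structure(list(
    variance_fractions = s$d^2 / sum(s$d^2),
    u_phase = u_phase, v_phase = v_phase,
    u_fit = u_fit, v_fit = v_fit,
    fit_degree = fit_degree,
    reconstructed = phase_image(rec, wrapped = FALSE)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> PC1 variance fraction %.4f, fit degree %d, %d x %d px\n",
    x$variance_fractions[1], x$fit_degree,
    length(x$u_fit), length(x$v_fit)))
  invisible(x)
}

# Ordinary least-squares polynomial fit of a vector over its 0-based index;
# returns the fitted values.  Orthogonal polynomials keep the normal
# equations well conditioned at index^degree ~ 511^5.
polyfit_1d <- function(y, degree) {
  t <- seq_along(y) - 1
  degree <- min(degree, length(y) - 1)
  as.numeric(stats::fitted(stats::lm(y ~ stats::poly(t, degree))))
}
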