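#' Smooth the leading boundary rows and columns
#'
#' Before a j'th-order forward difference, the data in the first `j` rows
#' and columns act as initial values for the later cumulative-sum
#' integration, so noise there propagates into the whole recovered surface.
#' This replaces each of the first `j` rows, and then each of the first `j`
#' columns, by its own 1D least-squares polynomial fit; all other pixels
#' are untouched.
#'
#' @param phase A `phase_image` or numeric matrix (unwrapped).
#' @param j Number of leading rows/columns to smooth (>= 1).
#' @param fit_degree Polynomial degree of the 1D fits.
#' @return A `phase_image` with smoothed borders.
#' @export
smooth_boundaries <- function(phase, j, fit_degree = 5) {
  v <- phase_values(phase)
  if (j < 1) stop("j must be >= 1")
  if (j >= min(dim(v))) stop("j must be smaller than the image extent")
  for (r in seq_len(j)) v[r, ] <- polyfit_1d(v[r, ], fit_degree)
  for (c in seq_len(j)) v[, c] <- polyfit_1d(v[, c], fit_degree)
  phase_image(v, wrapped = FALSE)
}

#' Forward-difference partial derivative with boundary bookkeeping
#'
#' Applies `order` successive first-order forward differences along one
#' axis (`out[i] = in[i+1] - in[i]`, unit pixel spacing, no division).
#' Before each difference the current first column (axis `"x"`) or row
#' (axis `"y"`) is saved into a boundary record; these vectors are the
#' initial data that make [phase_integral()] an exact inverse.  The image
#' extent along the axis shrinks by one per difference — it is tracked
#' explicitly, never padded, so the inverse property is not silently
#' corrupted.
#'
#' On integer pixel grids the j-fold forward difference of `x^j` is exactly
#' `j!`, so a cross term `P * x^k * y^l` differenced `k` times along x
#' becomes the separable surface `P * k! * y^l` with the coefficient
#' preserved — the identity the dPCA method rests on.
#'
#' @param phase An unwrapped `phase_image` (wrapped input is an error: the
#'   2*pi jumps of wrapped phase would alias into the differences).
#' @param axis `"x"` (along columns) or `"y"` (along rows).
#' @param order Derivative order `j >= 1`; must be below the extent along
#'   `axis`.
#' @return List with `derivative` (unwrapped `phase_image`, extent along
#'   `axis` reduced by `order`) and `record` (a `boundary_record`: `axis`,
#'   `order`, and `saved`, the list of captured boundary vectors).
#' @export
phase_derivative <- function(phase, axis = c("x", "y"), order = 1) {
  axis <- match.arg(axis)
  if (inherits(phase, "phase_image") && phase$wrapped)
    stop("phase must be unwrapped before differentiation")
  v <- phase_values(phase)
  if (order < 1) stop("order must be >= 1")
  extent <- if (axis == "x") ncol(v) else nrow(v)
  if (extent <= order) stop("image extent along axis must exceed order")
  saved <- vector("list", order)
  for (s in seq_len(order)) {
    if (axis == "x") {
      saved[[s]] <- v[, 1]
      v <- v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE]
    } else {
      saved[[s]] <- v[1, ]
      v <- v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
    }
  }
  list(
    derivative = phase_image(v, wrapped = FALSE),
    record = structure(list(axis = axis, order = order, saved = saved),
                       class = "boundary_record")
  )
}

row_cumsum <- function(m) {
  if (ncol(m) == 1) m else t(apply(m, 1, cumsum))
}

col_cumsum <- function(m) {
  if (nrow(m) == 1) m else apply(m, 2, cumsum)
}

#' Cumulative-sum integral, the exact inverse of [phase_derivative()]
#'
#' Applies `order` successive cumulative sums along the recorded axis, each
#' prepended with the corresponding saved boundary vector (in reverse
#' capture order).  `phase_integral(phase_derivative(p, a, j))` reproduces
#' `p` to floating-point summation error.  In the dPCA pipeline the
#' integrand is not the raw derivative but its PCA-reconstructed separable
#' part; the boundary record captured from the measured phase still
#' provides the initial data.
#'
#' @param derivative A `phase_image` or numeric matrix (the derivative
#'   surface, possibly PCA-reconstructed).
#' @param record A `boundary_record` from [phase_derivative()], consistent
#'   with the surface shape.
#' @return An unwrapped `phase_image` restored to full size.
#' @export
phase_integral <- function(derivative, record) {
  stopifnot(inherits(record, "boundary_record"))
  v <- phase_values(derivative)
  for (s in rev(seq_len(record$order))) {
    b <- record$saved[[s]]
    if (record$axis == "x") {
      if (length(b) != nrow(v))
        stop("boundary vector length does not match the surface")
      v <- cbind(b, b + row_cumsum(v), deparse.level = 0)
    } else {
      if (length(b) != ncol(v))
        stop("boundary vector length does not match the surface")
      v <- rbind(b, sweep(col_cumsum(v), 2, b, `+`), deparse.level = 0)
    }
  }
  dimnames(v) <- NULL
  phase_image(v, wrapped = FALSE)
}
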