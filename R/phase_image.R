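#' Phase image
#'
#' A `phase_image` is a 2D map of optical phase values in radians on an
#' integer pixel grid, together with a flag saying whether the values are
#' wrapped into the principal interval.  The grid convention used throughout
#' the package is: `x` is the 0-based column index, `y` is the 0-based row
#' index, origin at the top-left corner, unit pixel spacing and no centering.
#' Polynomial aberration coefficients are therefore in units of
#' radians/pixel^(k+l).
#'
#' Wrapped images hold values in the half-open interval `(-pi, pi]`.
#'
#' @param values Numeric matrix of phase values in radians (rows = y,
#'   columns = x).
#' @param wrapped Logical; `TRUE` if the values are wrapped into `(-pi, pi]`.
#' @return An object of class `phase_image` with fields `values` and
#'   `wrapped`.
#' @examples
#' p <- phase_image(matrix(0, 4, 4))
#' p$wrapped
#' @export
phase_image <- function(values, wrapped = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  if (isTRUE(wrapped) && length(values) &&
      (min(values) <= -pi - 1e-12 || max(values) > pi + 1e-12))
    stop("wrapped phase values must lie in (-pi, pi]")
  structure(list(values = values, wrapped = isTRUE(wrapped)),
            class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %d x %d px, %s, range [%.4g, %.4g] rad\n",
              nrow(x$values), ncol(x$values),
              if (x$wrapped) "wrapped" else "unwrapped",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.phase_image <- function(x) dim(x$values)

# Accept either a phase_image or a bare numeric matrix.
as_phase_image <- function(x, wrapped = FALSE) {
  if (inherits(x, "phase_image")) x else phase_image(x, wrapped = wrapped)
}

phase_values <- function(x) {
  if (inherits(x, "phase_image")) x$values else x
}

# Principal-value reduction onto (-pi, pi].
wrap_values <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Wrap phase into the principal interval
#'
#' Reduces phase values modulo 2*pi onto `(-pi, pi]`, the convention used by
#' all wrapped images in this package (so e.g. a constant `3*pi/2` wraps to
#' `-pi/2`, and `pi` itself is left at `pi`).
#'
#' @param phase A `phase_image` or numeric matrix (radians).
#' @return A wrapped `phase_image`.
#' @seealso [unwrap_phase()]
#' @export
wrap_phase <- function(phase) {
  phase_image(wrap_values(phase_values(phase)), wrapped = TRUE)
}

#' Remove piston (constant phase offset)
#'
#' Subtracts the mean value.  Holographic phase is only defined up to a
#' constant, so all residual metrics in this package are computed after
#' piston removal.
#'
#' @param phase A `phase_image` or numeric matrix.
#' @return Object of the same type with zero mean.
#' @export
remove_piston <- function(phase) {
  if (inherits(phase, "phase_image")) {
    phase_image(phase$values - mean(phase$values), wrapped = FALSE)
  } else {
    phase - mean(phase)
  }
}
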