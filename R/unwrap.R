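#' Unwrap a 1D phase vector
#'
#' Itoh's method: whenever a successive difference exceeds pi in magnitude,
#' an integer multiple of 2*pi is added to the remainder of the vector so
#' that all successive differences fall in `(-pi, pi]`.  Exact (up to a
#' global 2*pi*integer) whenever the true underlying signal satisfies the
#' Itoh condition |true difference| < pi; a genuine jump larger than pi is
#' necessarily altered.
#'
#' @param wrapped Numeric vector of phase values, radians.
#' @return Numeric vector congruent to the input modulo 2*pi.
#' @export
unwrap_phase_1d <- function(wrapped) {
  if (length(wrapped) < 2) return(wrapped)
  steps <- round(diff(wrapped) / (2 * pi))
  wrapped - 2 * pi * cumsum(c(0, steps))
}

#' Unwrap a 2D phase image
#'
#' Sequential Itoh unwrapping: the first column is unwrapped as a 1D signal,
#' then each row is unwrapped and shifted by the 2*pi multiple that makes it
#' consistent with the unwrapped first column.  For wrapped versions of a
#' smooth surface (adjacent-pixel true differences below pi) this recovers
#' the surface exactly up to one global 2*pi*integer offset; inputs that
#' violate the condition (phase residues) yield a best-effort result.
#'
#' @param wrapped A wrapped `phase_image` (or numeric matrix of values in
#'   `(-pi, pi]`).
#' @return An unwrapped `phase_image`, pointwise congruent to the input
#'   modulo 2*pi.
#' @seealso [wrap_phase()], [unwrap_phase_1d()]
#' @export
unwrap_phase <- function(wrapped) {
  w <- phase_values(wrapped)
  ref <- unwrap_phase_1d(w[, 1])
  out <- t(apply(w, 1, unwrap_phase_1d))
  if (ncol(w) == 1) out <- w  # single column: the reference is everything
  out <- out - out[, 1] + ref
  phase_image(out, wrapped = FALSE)
}
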