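#' Form a phase-shifting hologram frame
#'
#' Interferes an object wave `O` with a reference wave `R` whose phase is
#' offset by `shift`, giving the detector intensity
#' `I = |O|^2 + |R|^2 + conj(O)*R*exp(i*shift) + O*conj(R)*exp(-i*shift)`.
#' The shift is applied to the reference arm, as a spatial light modulator
#' would do in a phase-shifting DHM system.
#'
#' @param object_wave,reference_wave Complex matrices of equal dimension
#'   (dimensionless amplitudes).
#' @param shift Reference phase offset, radians.
#' @return Real non-negative intensity matrix.
#' @export
form_hologram <- function(object_wave, reference_wave, shift = 0) {
  if (!all(dim(object_wave) == dim(reference_wave)))
    stop("object and reference waves must have the same dimensions")
  cross <- object_wave * Conj(reference_wave) * exp(-1i * shift)
  Re(Mod(object_wave)^2 + Mod(reference_wave)^2 + cross + Conj(cross))
}

#' Canonical four-step phase shifts
#' @return `c(0, pi/2, pi, 3*pi/2)`.
#' @export
four_step_shifts <- function() c(0, pi / 2, pi, 3 * pi / 2)

#' Record a four-step hologram stack
#'
#' Convenience wrapper recording [form_hologram()] frames at the four
#' canonical reference shifts 0, pi/2, pi, 3*pi/2.
#'
#' @inheritParams form_hologram
#' @return A list with `frames` (list of four intensity matrices) and
#'   `shifts`.
#' @export
hologram_stack <- function(object_wave, reference_wave) {
  shifts <- four_step_shifts()
  list(frames = lapply(shifts, function(s)
    form_hologram(object_wave, reference_wave, s)), shifts = shifts)
}

#' Extract the complex field by four-step phase shifting
#'
#' Recovers the interference cross term `O * conj(R)` from four hologram
#' intensities taken at reference shifts 0, pi/2, pi, 3*pi/2:
#' `field = [(I_0 - I_pi) - i (I_{3pi/2} - I_{pi/2})] / 4`.
#' Its argument is the measured phase, the sum of sample phase and
#' aberration phase, wherever `|O||R| > 0`; its modulus is `|O| |R|`.
#'
#' @param stack A list with `frames` (four intensity matrices) and `shifts`
#'   (must equal the canonical four within 1e-9).
#' @return Complex matrix `O * conj(R)`.
#' @export
extract_field_four_step <- function(stack) {
  if (length(stack$frames) != 4L || length(stack$shifts) != 4L)
    stop("four-step extraction needs exactly four frames and shifts")
  if (max(abs(stack$shifts - four_step_shifts())) > 1e-9)
    stop("shifts must be the canonical (0, pi/2, pi, 3*pi/2)")
  d <- dim(stack$frames[[1]])
  if (!all(vapply(stack$frames, function(f) all(dim(f) == d), TRUE)))
    stop("all frames must share one dimension")
  ((stack$frames[[1]] - stack$frames[[3]]) -
     1i * (stack$frames[[4]] - stack$frames[[2]])) / 4
}

#' Measured phase from a four-step hologram stack
#'
#' @inheritParams extract_field_four_step
#' @return A wrapped `phase_image` of the argument of the extracted field.
#' @export
measured_phase <- function(stack) {
  wrap_phase(Arg(extract_field_four_step(stack)))
}
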