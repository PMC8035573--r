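#' Read a run configuration from YAML
#'
#' Fills in pipeline defaults for keys that are absent.  Recognised keys:
#' `grid` (`height`, `width`), `coefficients` (map `"k,l": value`),
#' `sample` (`gaussian_peak`, `gaussian_sigma`, `gaussian_center`,
#' `mask_height`, `mask_scale`), `noise` (`sigma`, `seed`), `plan`
#' (`max_order`, `include_pca0`, or explicit `steps` as a list of
#' `[j, axis]` pairs), `fit_degree`, `std_threshold`, `improvement_floor`,
#' `boundary` (`measured` | `extrapolated`), `background` (list of
#' `[row0, col0, row1, col1]` boxes, 1-based inclusive), `seed`.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    grid = list(height = 512L, width = 512L),
    sample = list(gaussian_peak = 1, gaussian_sigma = 50,
                  mask_height = 1.5, mask_scale = 8),
    noise = list(sigma = 0, seed = 1L),
    plan = list(max_order = 2L, include_pca0 = TRUE),
    fit_degree = 5L,
    std_threshold = 0.1,
    improvement_floor = 0.05,
    boundary = "measured",
    background = NULL,
    seed = 1L
  )
  out <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  out
}

config_plan <- function(cfg) {
  p <- cfg$plan
  if (!is.null(p$steps)) {
    iteration_plan(include_pca0 = isTRUE(p$include_pca0), steps = p$steps)
  } else {
    iteration_plan(max_order = if (is.null(p$max_order)) 2L else p$max_order,
                   include_pca0 = !isFALSE(p$include_pca0))
  }
}

config_region <- function(cfg) {
  if (is.null(cfg$background)) NULL
  else background_region(lapply(cfg$background, as.numeric))
}

#' Simulate a synthetic DHM measurement from a configuration
#'
#' Builds the ground-truth sample phase and aberration surface, composes
#' the measured phase, optionally adds Gaussian noise, and wraps the
#' result.  Optionally also records a four-step phase-shifting hologram
#' stack of the measurement with a unit plane reference wave.
#'
#' @param cfg A configuration list as returned by [read_run_config()].
#' @param holograms Also form the four-frame hologram stack.
#' @return List with `truth` (sample `phase_image`), `aberration`
#'   (`phase_image`), `measured` (wrapped `phase_image`) and, when
#'   requested, `stack`.
#' @export
simulate_measurement <- function(cfg, holograms = FALSE) {
  h <- cfg$grid$height; w <- cfg$grid$width
  spec <- read_aberration_yaml(cfg)
  ab <- aberration_surface(spec, h, w)
  sp <- cfg$sample
  center <- if (is.null(sp$gaussian_center)) c((h - 1) / 2, (w - 1) / 2)
            else as.numeric(sp$gaussian_center)
  truth <- sample_phase(h, w,
                        gaussian_peak = sp$gaussian_peak,
                        gaussian_sigma = sp$gaussian_sigma,
                        gaussian_center = center,
                        mask = letter_mask(h, w, scale = sp$mask_scale),
                        mask_height = sp$mask_height)
  total <- phase_image(truth$values + ab$values)
  if (!is.null(cfg$noise) && cfg$noise$sigma > 0)
    total <- add_phase_noise(total, cfg$noise$sigma,
                             seed = cfg$noise$seed)
  out <- list(truth = truth, aberration = ab,
              measured = wrap_phase(total))
  if (holograms) {
    obj <- exp(1i * total$values)
    ref <- matrix(1 + 0i, h, w)
    out$stack <- hologram_stack(obj, ref)
  }
  out
}

#' Run the dPCA pipeline under a configuration
#'
#' @param phase Input `phase_image` (wrapped or unwrapped).
#' @param cfg Configuration list from [read_run_config()].
#' @return A `dpca_report`.
#' @export
compensate_with_config <- function(phase, cfg) {
  dpca(phase,
       plan = config_plan(cfg),
       region = config_region(cfg),
       std_threshold = cfg$std_threshold,
       improvement_floor = cfg$improvement_floor,
       fit_degree = cfg$fit_degree,
       boundary = cfg$boundary)
}
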