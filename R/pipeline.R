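#' Background region
#'
#' A union of rectangular pixel boxes over which background flatness is
#' evaluated.  Boxes are `(row0, col0, row1, col1)`, 1-based and inclusive.
#'
#' @param rectangles A list of length-4 integer vectors, or a single such
#'   vector.
#' @return An object of class `background_region`.
#' @export
background_region <- function(rectangles) {
  if (is.numeric(rectangles)) rectangles <- list(rectangles)
  if (length(rectangles) == 0) stop("background region must be nonempty")
  for (b in rectangles) {
    if (length(b) != 4 || b[1] > b[3] || b[2] > b[4] || any(b < 1))
      stop("each rectangle must be (row0, col0, row1, col1), 1-based inclusive, nonempty")
  }
  structure(list(rectangles = rectangles), class = "background_region")
}

#' Default border-frame background region
#'
#' When no explicit background is supplied the pipeline evaluates flatness
#' over a border frame of the given margin fraction: samples in DHM phase
#' images are typically centred, leaving the frame sample-free.
#'
#' @param height,width Image size in pixels.
#' @param margin Fraction of each dimension used as frame width.
#' @return A `background_region` of four rectangles.
#' @export
border_region <- function(height, width, margin = 0.1) {
  mr <- max(1L, round(margin * height))
  mc <- max(1L, round(margin * width))
  background_region(list(
    c(1, 1, mr, width),                       # top
    c(height - mr + 1, 1, height, width),     # bottom
    c(mr + 1, 1, height - mr, mc),            # left
    c(mr + 1, width - mc + 1, height - mr, width)  # right
  ))
}

region_mask <- function(region, height, width) {
  stopifnot(inherits(region, "background_region"))
  m <- matrix(FALSE, height, width)
  for (b in region$rectangles) {
    if (b[3] > height || b[4] > width)
      stop("background rectangle outside image bounds")
    m[b[1]:b[3], b[2]:b[4]] <- TRUE
  }
  m
}

#' Background standard deviation
#'
#' Flatness metric of a compensated phase: the standard deviation (root
#' mean square after mean removal, i.e. piston-free) of the phase over the
#' union of the background boxes.
#'
#' @param phase A `phase_image` or numeric matrix.
#' @param region A [background_region()], or `NULL` for the default
#'   [border_region()].
#' @return Standard deviation in radians.
#' @export
background_std <- function(phase, region = NULL) {
  v <- phase_values(phase)
  if (is.null(region)) region <- border_region(nrow(v), ncol(v))
  sel <- v[region_mask(region, nrow(v), ncol(v))]
  if (length(sel) == 0) stop("background region is empty")
  sqrt(mean((sel - mean(sel))^2))
}

#' One aberration-compensation step
#'
#' For `j = 0` this is conventional PCA compensation: the separable
#' aberration estimated by [estimate_separable_aberration()] is subtracted
#' from the phase.  For `j >= 1` it is one dPCA iteration: the boundary
#' rows/columns are smoothed, the phase is differenced `j` times along axis
#' `d` (saving boundary data), PCA estimates the now-separable aberration
#' derivative, the reconstruction is integrated back with the saved
#' boundary data, and the recovered aberration is subtracted:
#' `phase' = phase - aberration`.
#'
#' @param phase An unwrapped `phase_image`.
#' @param j Derivative order (0 = conventional PCA pre-pass).
#' @param axis `"x"` or `"y"` (ignored when `j = 0`).
#' @param fit_degree Polynomial degree for singular-vector and boundary
#'   fits.
#' @param boundary `"measured"` (default): integrate with the boundary
#'   vectors saved from the phase being differenced, the rule that makes
#'   the residual at the first rows/columns self-correcting across
#'   iterations.  `"extrapolated"`: replace each saved vector by its own
#'   polynomial fit, which avoids leaking sharp sample structure that
#'   touches the image border at the cost of that self-correction.
#' @return List with `phase` (compensated, unwrapped), `aberration`
#'   (recovered surface, full size) and `pca` (the `pca_result`).
#' @export
compensate_step <- function(phase, j, axis = "x", fit_degree = 5,
                            boundary = c("measured", "extrapolated")) {
  boundary <- match.arg(boundary)
  phase <- as_phase_image(phase)
  if (phase$wrapped) stop("phase must be unwrapped; see unwrap_phase()")
  if (j == 0) {
    pca <- estimate_separable_aberration(phase, fit_degree)
    ab <- pca$reconstructed$values
  } else {
    smoothed <- smooth_boundaries(phase, j, fit_degree)
    pd <- phase_derivative(smoothed, axis, j)
    rec <- pd$record
    if (boundary == "extrapolated")
      rec$saved <- lapply(rec$saved, polyfit_1d, degree = fit_degree)
    pca <- estimate_separable_aberration(pd$derivative, fit_degree)
    ab <- phase_integral(pca$reconstructed, rec)$values
  }
  list(phase = phase_image(phase$values - ab, wrapped = FALSE),
       aberration = phase_image(ab, wrapped = FALSE),
       pca = pca)
}

#' Iteration plan for the dPCA ladder
#'
#' The default schedule alternates the derivative axis while gradually
#' raising the order: `(1,x), (1,y), (2,x), (2,y), ...` up to `max_order`.
#' Aberrations of a normal optical system are below fourth order, so the
#' default `max_order = 2` ladder (four dPCA steps) covers them; an
#' optional conventional-PCA pre-pass (`j = 0`) handles purely separable
#' aberrations first, which is cheaper and less noise-sensitive than
#' differentiating.
#'
#' @param max_order Highest derivative order in the default ladder.
#' @param include_pca0 Prepend a conventional PCA (`j = 0`) pre-pass.
#' @param steps Optional explicit schedule overriding the ladder: a data
#'   frame (or list of pairs) with columns `j` and `axis`.
#' @return An object of class `iteration_plan`: data frame with columns
#'   `j`, `axis`.
#' @export
iteration_plan <- function(max_order = 2, include_pca0 = TRUE, steps = NULL) {
  if (is.null(steps)) {
    steps <- data.frame(
      j = rep(seq_len(max_order), each = 2),
      axis = rep(c("x", "y"), max_order)
    )
  } else if (!is.data.frame(steps)) {
    steps <- data.frame(
      j = vapply(steps, function(s) as.numeric(s[[1]]), 1),
      axis = vapply(steps, function(s) as.character(s[[2]]), "")
    )
  }
  if (include_pca0) steps <- rbind(data.frame(j = 0, axis = "x"), steps)
  if (nrow(steps) == 0) stop("iteration plan must contain at least one step")
  structure(steps, class = c("iteration_plan", "data.frame"))
}

#' Run the full dPCA compensation loop
#'
#' Unwraps the input if needed, then executes the plan step by step.  After
#' every step the background standard deviation is evaluated over `region`;
#' the loop stops early once the background is flat enough
#' (`std < std_threshold`) or a step no longer helps (relative improvement
#' below `improvement_floor`).  The recovered aberration surfaces of all
#' executed steps are summed into one total surface for reporting (piston
#' is removed once, at the end, in the report summary).
#'
#' @param phase A `phase_image`, wrapped or unwrapped.
#' @param plan An [iteration_plan()].
#' @param region A [background_region()] or `NULL` for the default border
#'   frame.
#' @param std_threshold Background STD (radians) below which compensation
#'   is declared complete (default 0.1).  Set to 0 (with
#'   `improvement_floor = 0`) to always run the full plan.
#' @param improvement_floor Minimum relative STD improvement per step
#'   (default 0.05); a step improving less ends the loop.
#' @param fit_degree Polynomial degree for all least-squares fits.
#' @param boundary Boundary mode passed to [compensate_step()].
#' @param final_pca0 Run one extra conventional PCA pass after the loop to
#'   absorb separable aberrations introduced by fitting errors of
#'   higher-order derivative steps.
#' @return An object of class `dpca_report`: list with `steps` (per-step
#'   records: `j`, `axis`, `background_std`, `pc1_fraction`, `aberration`),
#'   `phase` (final compensated `phase_image`), `total_aberration`
#'   (`phase_image`), `std_trace`, `stop_reason`.
#' @export
dpca <- function(phase, plan = iteration_plan(), region = NULL,
                 std_threshold = 0.1, improvement_floor = 0.05,
                 fit_degree = 5, boundary = "measured",
                 final_pca0 = FALSE) {
  phase <- as_phase_image(phase, wrapped = FALSE)
  if (phase$wrapped) phase <- unwrap_phase(phase)
  stopifnot(inherits(plan, "iteration_plan"))
  h <- nrow(phase$values); w <- ncol(phase$values)
  if (is.null(region)) region <- border_region(h, w)
  total <- matrix(0, h, w)
  records <- list()
  trace <- numeric(0)
  reason <- "plan_exhausted"
  prev_std <- NA_real_
  for (i in seq_len(nrow(plan))) {
    st <- compensate_step(phase, plan$j[i], plan$axis[i], fit_degree,
                          boundary)
    phase <- st$phase
    total <- total + st$aberration$values
    std <- background_std(phase, region)
    trace <- c(trace, std)
    records[[i]] <- list(j = plan$j[i], axis = plan$axis[i],
                         background_std = std,
                         pc1_fraction = st$pca$variance_fractions[1],
                         aberration = st$aberration)
    if (std < std_threshold) { reason <- "std_threshold"; break }
    if (!is.na(prev_std) && prev_std > 0 &&
        (prev_std - std) / prev_std < improvement_floor) {
      reason <- "improvement_floor"; break
    }
    prev_std <- std
  }
  if (final_pca0) {
    st <- compensate_step(phase, 0, fit_degree = fit_degree)
    phase <- st$phase
    total <- total + st$aberration$values
    trace <- c(trace, background_std(phase, region))
    records[[length(records) + 1]] <- list(
      j = 0, axis = "x", background_std = trace[length(trace)],
      pc1_fraction = st$pca$variance_fractions[1],
      aberration = st$aberration)
  }
  structure(list(steps = records, phase = phase,
                 total_aberration = phase_image(total, wrapped = FALSE),
                 std_trace = trace, stop_reason = reason),
            class = "dpca_report")
}

#' @export
print.dpca_report <- function(x, ...) {
  cat(sprintf("<dpca_report> %d step(s), stop: %s\n",
              length(x$steps), x$stop_reason))
  for (s in x$steps)
    cat(sprintf("  j=%d d=%s  PC1 %.4f  background STD %.3g rad\n",
                s$j, s$axis, s$pc1_fraction, s$background_std))
  ab <- remove_piston(x$total_aberration)
  cat(sprintf("  total recovered aberration (piston removed): range [%.3g, %.3g] rad\n",
              min(ab$values), max(ab$values)))
  invisible(x)
}

#' Fit a 2D polynomial surface to a phase image
#'
#' Ordinary least-squares fit of `sum P[k,l] x^k y^l` over the full pixel
#' grid for all `k <= max_k`, `l <= max_l`.  Exact for noise-free
#' polynomial inputs of compatible degree, and used as the
#' coefficient-recovery metric when validating compensation against a
#' known synthetic aberration.  Coordinates are scaled to [0, 1]
#' internally for conditioning; the returned coefficients are on the raw
#' pixel-index scale.
#'
#' @param phase A `phase_image` or numeric matrix.
#' @param max_k,max_l Largest monomial order in x (columns) and y (rows).
#' @return An [aberration_spec()] with `(max_k+1)*(max_l+1)` terms.
#' @export
fit_phase_surface <- function(phase, max_k = 3, max_l = 3) {
  v <- phase_values(phase)
  h <- nrow(v); w <- ncol(v)
  if ((max_k + 1) * (max_l + 1) > length(v))
    stop("more coefficients than pixels")
  xs <- (0:(w - 1)) / max(1, w - 1)
  ys <- (0:(h - 1)) / max(1, h - 1)
  terms <- expand.grid(k = 0:max_k, l = 0:max_l)
  design <- matrix(0, length(v), nrow(terms))
  for (i in seq_len(nrow(terms))) {
    design[, i] <- as.vector(outer(ys^terms$l[i], xs^terms$k[i]))
  }
  fit <- stats::lm.fit(design, as.vector(v))
  beta <- fit$coefficients
  if (anyNA(beta)) stop("rank-deficient polynomial design")
  coef <- beta / (max(1, w - 1)^terms$k * max(1, h - 1)^terms$l)
  aberration_spec(terms$k, terms$l, coef)
}

#' Look up one coefficient of an aberration spec
#'
#' @param spec An `aberration_spec`.
#' @param k,l Monomial orders.
#' @return The coefficient `P[k,l]` (0 if the term is absent).
#' @export
spec_coefficient <- function(spec, k, l) {
  i <- which(spec$k == k & spec$l == l)
  if (length(i) == 0) 0 else spec$value[i]
}
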