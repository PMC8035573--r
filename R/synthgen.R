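#' Polynomial aberration specification
#'
#' Describes a phase aberration surface as a sparse sum of monomials
#' `P[k,l] * x^k * y^l` over the pixel grid (x = column index, y = row index,
#' both 0-based).  Terms with both `k != 0` and `l != 0` are *cross terms*
#' (astigmatism `xy`, coma-like `x^2*y`, ...): they are not separable as
#' `f(x) + g(y)` and are exactly the terms conventional rank-1 PCA cannot
#' recover.
#'
#' @param k,l Integer vectors of non-negative monomial orders (recycled to a
#'   common length).
#' @param value Numeric vector of coefficients, radians/pixel^(k+l).
#' @return An object of class `aberration_spec`: a data frame with columns
#'   `k`, `l`, `value` and attributes `K`, `L` (largest orders present).
#' @examples
#' # the classic non-cross demo surface: P30 x^3 + P01 y
#' aberration_spec(k = c(3, 0), l = c(0, 1), value = c(1e-8, 1e-2))
#' @export
aberration_spec <- function(k, l, value) {
  n <- max(length(k), length(l), length(value))
  k <- rep_len(as.numeric(k), n)
  l <- rep_len(as.numeric(l), n)
  value <- rep_len(as.numeric(value), n)
  if (n == 0) stop("aberration spec must contain at least one term")
  if (any(k < 0) || any(l < 0) || any(k != floor(k)) || any(l != floor(l)))
    stop("monomial orders k, l must be non-negative integers")
  if (anyDuplicated(paste(k, l)))
    stop("duplicate (k, l) terms in aberration spec")
  structure(data.frame(k = as.integer(k), l = as.integer(l), value = value),
            K = max(as.integer(k)), L = max(as.integer(l)),
            class = c("aberration_spec", "data.frame"))
}

#' Identify cross terms of an aberration spec
#'
#' @param spec An `aberration_spec`.
#' @return Logical vector, `TRUE` for terms with both `k != 0` and `l != 0`.
#' @export
cross_terms <- function(spec) {
  stopifnot(inherits(spec, "aberration_spec"))
  spec$k != 0 & spec$l != 0
}

#' Evaluate a polynomial aberration surface
#'
#' Evaluates `sum_k sum_l P[k,l] * x^k * y^l` on an integer pixel grid with
#' x the 0-based column index and y the 0-based row index (unit spacing, no
#' centering; the printed coefficient magnitudes of typical DHM systems,
#' e.g. 1e-2 rad/px tilt over 512 px, assume this raw-index convention).
#'
#' @param spec An [aberration_spec()].
#' @param height,width Grid size in pixels (both >= 2).
#' @return An unwrapped `phase_image`.
#' @examples
#' s <- aberration_spec(2, 1, 1e-8)
#' a <- aberration_surface(s, 256, 256)
#' a$values[201, 101]  # x = 100, y = 200 -> 1e-8 * 100^2 * 200 = 0.02 rad
#' @export
aberration_surface <- function(spec, height = 512, width = 512) {
  stopifnot(inherits(spec, "aberration_spec"))
  if (height < 2 || width < 2) stop("grid must be at least 2 x 2")
  x <- 0:(width - 1)
  y <- 0:(height - 1)
  vals <- matrix(0, height, width)
  for (i in seq_len(nrow(spec))) {
    vals <- vals + spec$value[i] * outer(y^spec$l[i], x^spec$k[i])
  }
  phase_image(vals, wrapped = FALSE)
}

# Blocky 5x7 glyphs used by letter_mask(); independent of any font rendering.
.dpca_glyphs <- list(
  d = c("....#", "....#", ".####", "#...#", "#...#", "#...#", ".####"),
  `-` = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  C = c(".####", "#....", "#....", "#....", "#....", "#....", ".####"),
  A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#")
)

#' Procedural binary letter mask
#'
#' Renders the text "d-PCA" as a binary mask of blocky 5x7 glyphs scaled by
#' an integer factor.  The mask stands in for a sharply changing sample
#' structure (a resolution-target-like print) next to the smooth Gaussian
#' spot of [sample_phase()]; it is generated procedurally so tests never
#' depend on font rendering.
#'
#' @param height,width Mask size in pixels.
#' @param scale Integer pixels per glyph cell (default 8 gives about 2%
#'   coverage on a 512 x 512 grid).
#' @param center `(row, col)` center of the text block, 0-based pixels;
#'   default places it at 70% height, horizontally centered.
#' @return A 0/1 integer matrix of dimension `height x width`.
#' @export
letter_mask <- function(height = 512, width = 512, scale = 8,
                        center = c(0.7 * (height - 1), 0.5 * (width - 1))) {
  stopifnot(scale >= 1, scale == floor(scale))
  glyphs <- .dpca_glyphs[c("d", "-", "P", "C", "A")]
  gap <- 1  # blank columns between glyphs, in cells
  ncell_w <- sum(vapply(glyphs, function(g) nchar(g[1]), 1L)) +
    gap * (length(glyphs) - 1)
  ncell_h <- length(glyphs[[1]])
  mask <- matrix(0L, height, width)
  row0 <- round(center[1] - scale * ncell_h / 2)
  col0 <- round(center[2] - scale * ncell_w / 2)
  cc <- col0
  for (g in glyphs) {
    bits <- do.call(rbind, lapply(g, function(s) {
      as.integer(strsplit(s, "")[[1]] == "#")
    }))
    for (r in seq_len(nrow(bits))) for (c in seq_len(ncol(bits))) {
      if (bits[r, c] == 1L) {
        rr <- row0 + (r - 1) * scale + seq_len(scale) - 1
        ccx <- cc + (c - 1) * scale + seq_len(scale) - 1
        rr <- rr[rr >= 0 & rr < height]
        ccx <- ccx[ccx >= 0 & ccx < width]
        mask[rr + 1, ccx + 1] <- 1L
      }
    }
    cc <- cc + (ncol(bits) + gap) * scale
  }
  mask
}

#' Synthetic sample phase: Gaussian spot plus letter step
#'
#' Builds the object (sample) phase used by the simulator: a smooth,
#' gradually changing component (an isotropic Gaussian spot, mimicking e.g.
#' a rounded cell) plus a sharply changing component (a binary letter mask
#' offset by a constant step).
#'
#' @param height,width Grid size in pixels.
#' @param gaussian_peak Peak phase of the Gaussian spot, radians (>= 0).
#' @param gaussian_sigma Standard deviation of the spot, pixels (> 0).
#' @param gaussian_center `(row, col)` center, 0-based pixels; defaults to
#'   the grid center.
#' @param mask Binary 0/1 matrix of dimension `height x width`, or `NULL`
#'   for the default [letter_mask()].
#' @param mask_height Phase step added where `mask == 1`, radians.
#' @return An unwrapped `phase_image`.
#' @export
sample_phase <- function(height = 512, width = 512,
                         gaussian_peak = 1, gaussian_sigma = 50,
                         gaussian_center = c((height - 1) / 2, (width - 1) / 2),
                         mask = NULL, mask_height = 1.5) {
  if (gaussian_peak < 0) stop("gaussian_peak must be >= 0")
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0")
  if (is.null(mask)) mask <- letter_mask(height, width)
  if (!all(dim(mask) == c(height, width)))
    stop("mask dimensions must match the grid")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  y <- 0:(height - 1)
  x <- 0:(width - 1)
  r2 <- outer((y - gaussian_center[1])^2, (x - gaussian_center[2])^2, `+`)
  vals <- gaussian_peak * exp(-r2 / (2 * gaussian_sigma^2)) +
    mask_height * mask
  phase_image(vals, wrapped = FALSE)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add Gaussian phase noise
#'
#' Adds independent zero-mean Gaussian noise to each pixel.  The caller's
#' RNG state is left untouched, so for a fixed `seed` the output is a pure
#' function of its inputs.
#'
#' @param phase A `phase_image` or numeric matrix.
#' @param sigma Noise standard deviation in radians (>= 0).
#' @param seed Integer seed.
#' @return A `phase_image` with the same `wrapped` flag semantics as the
#'   input if unwrapped; wrapped inputs are returned unwrapped (noise can
#'   push values outside the principal interval).
#' @export
add_phase_noise <- function(phase, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  v <- phase_values(phase)
  if (sigma == 0) return(phase_image(v, wrapped = FALSE))
  noise <- with_local_seed(seed, matrix(stats::rnorm(length(v), 0, sigma),
                                        nrow(v), ncol(v)))
  phase_image(v + noise, wrapped = FALSE)
}
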