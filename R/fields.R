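#' Complex object transmission function on the full canvas
#'
#' An `object_field` wraps a complex 2-D transmission map `O`. Its modulus
#' encodes absorption (<= 1 for a passive specimen) and its argument the
#' phase shift imparted to the illumination. The canvas must be strictly
#' larger than the probe window in both axes so that every scan placement
#' fits inside it.
#'
#' @param values complex (or numeric, promoted) matrix of transmission
#'   values; all entries must be finite.
#' @param pixel_pitch physical length of one pixel, in the same units as
#'   scan positions. Purely metadata; all computations are in pixels.
#' @return an object of class `object_field` with elements `values` and
#'   `pixel_pitch`.
#' @export
object_field <- function(values, pixel_pitch = 1) {
  values <- as_complex_matrix(values, "values")
  stopifnot(is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0)
  structure(list(values = values, pixel_pitch = pixel_pitch),
            class = "object_field")
}

#' Complex probe (illumination) field on the probe window
#'
#' A `probe_field` wraps the complex illumination wavefield `P` sampled on
#' the probe window, which is smaller than the object canvas. The field
#' must not be identically zero.
#'
#' @inheritParams object_field
#' @return an object of class `probe_field`.
#' @export
probe_field <- function(values, pixel_pitch = 1) {
  values <- as_complex_matrix(values, "values")
  if (all(values == 0)) stop("probe field is identically zero")
  stopifnot(is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0)
  structure(list(values = values, pixel_pitch = pixel_pitch),
            class = "probe_field")
}

#' Ordered scan plan with integer/subpixel split
#'
#' Scan positions are real-valued offsets (in object pixels) of the probe
#' window origin from the object-canvas origin: position `(0, 0)` places
#' the window in the top-left corner. Each position is decomposed by
#' [split_shift()] into an integer part (used to address the object patch)
#' and a subpixel part in `[-0.5, 0.5)` (applied to the probe by a Fourier
#' phase ramp), so that the two parts always reassemble exactly.
#'
#' @param positions N x 2 numeric matrix of `(row, col)` positions in
#'   object pixels, N >= 1; all finite.
#' @return an object of class `scan_plan` with elements `positions`,
#'   `s_int` (integer matrix) and `s_sub` (numeric matrix).
#' @export
scan_plan <- function(positions) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 2 || nrow(positions) < 1)
    stop("positions must be an N x 2 numeric matrix with N >= 1")
  if (!all(is.finite(positions))) stop("positions must be finite")
  s_int <- floor(positions + 0.5)
  s_sub <- positions - s_int
  storage.mode(s_int) <- "integer"
  structure(list(positions = positions, s_int = s_int, s_sub = s_sub),
            class = "scan_plan")
}

#' Set of measured diffraction intensity patterns
#'
#' Holds N nonnegative intensity patterns, one per scan position, as an
#' `N x H x W` array matched to the probe window shape. Intensities are in
#' photon counts; the noise model tag records whether they are clean
#' (noise-free forward model) or carry Poisson counting noise.
#'
#' @param intensities `N x H x W` numeric array, or a list of N identical
#'   shaped matrices; all entries nonnegative and finite.
#' @param noise_model `"clean"` or `"poisson"`.
#' @param seed integer seed used for the noise draw (`NA` for clean data).
#' @return an object of class `diffraction_set`.
#' @export
diffraction_set <- function(intensities, noise_model = c("clean", "poisson"),
                            seed = NA_integer_) {
  noise_model <- match.arg(noise_model)
  if (is.list(intensities)) {
    dims <- unique(lapply(intensities, dim))
    if (length(dims) != 1) stop("all intensity patterns must share one shape")
    arr <- array(0, dim = c(length(intensities), dims[[1]]))
    for (n in seq_along(intensities)) arr[n, , ] <- intensities[[n]]
    intensities <- arr
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be an N x H x W array")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  structure(list(intensities = intensities, noise_model = noise_model,
                 seed = seed),
            class = "diffraction_set")
}

#' @export
print.object_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<object_field %d x %d, pixel_pitch = %g>\n", d[1], d[2],
              x$pixel_pitch))
  invisible(x)
}

#' @export
print.probe_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<probe_field %d x %d, energy = %.6g>\n", d[1], d[2],
              sum(Mod(x$values)^2)))
  invisible(x)
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan with %d positions>\n", nrow(x$positions)))
  invisible(x)
}

#' @export
print.diffraction_set <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<diffraction_set: %d patterns of %d x %d, noise = %s>\n",
              d[1], d[2], d[3], x$noise_model))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_complex_matrix <- function(x, what) {
  if (inherits(x, "object_field") || inherits(x, "probe_field")) x <- x$values
  if (!is.matrix(x)) stop(sprintf("%s must be a matrix", what))
  if (!all(is.finite(x))) stop(sprintf("%s must have finite entries", what))
  x + 0i  # promote numeric to complex
}

field_values <- function(x) {
  if (inherits(x, "object_field") || inherits(x, "probe_field")) x$values else x
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# K fresh random permutations of 1..N drawn from a dedicated, seeded stream;
# returned as an N x K integer matrix (column k = visiting order at iter k).
make_permutations <- function(N, K, seed) {
  with_seed(seed, {
    m <- matrix(0L, nrow = N, ncol = K)
    for (k in seq_len(K)) m[, k] <- sample.int(N)
    m
  })
}
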