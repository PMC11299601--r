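#' Split a scan position into integer and subpixel shifts
#'
#' Decomposes a real-valued scan position into an integer part (handled by
#' patch addressing on the object canvas) and a subpixel remainder
#' (handled by a Fourier phase ramp on the probe). The integer part is the
#' nearest integer with ties resolved so that the remainder always lies in
#' the half-open interval `[-0.5, 0.5)`; the two parts reassemble to the
#' input exactly.
#'
#' @param r finite numeric 2-vector (row, col) in object pixels.
#' @return list with `s_int` (integer 2-vector) and `s_sub` (numeric
#'   2-vector in `[-0.5, 0.5)`).
#' @examples
#' split_shift(c(5.75, -2.25))  # s_int (6, -2), s_sub (-0.25, -0.25)
#' @export
split_shift <- function(r) {
  if (!is.numeric(r) || length(r) != 2 || !all(is.finite(r)))
    stop("r must be a finite numeric 2-vector")
  s_int <- floor(r + 0.5)
  list(s_int = as.integer(s_int), s_sub = r - s_int)
}

# Translate a complex field by an arbitrary real shift via a linear phase
# ramp in the frequency domain (band-limited interpolation). Unit-modulus
# ramp => Frobenius norm preserved exactly.
fourier_shift <- function(x, shift) {
  d <- dim(x)
  fy <- fft_freq(d[1])
  fx <- fft_freq(d[2])
  ramp <- exp(-2i * pi * (outer(fy * shift[1], fx * shift[2], `+`)))
  stats::fft(stats::fft(x) * ramp, inverse = TRUE) / length(x)
}

# Centered integer frequency offsets k/n for an n-point DFT axis.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  (((k + floor(n / 2)) %% n) - floor(n / 2)) / n
}

#' Subpixel translation of the probe field
#'
#' Shifts the probe by at most half a pixel along each axis using a linear
#' phase ramp in the spatial-frequency domain. The ramp has unit modulus,
#' so the total field energy is preserved. Integer parts of a scan
#' position must be routed through [split_shift()] and patch addressing;
#' larger shifts are rejected.
#'
#' @param P `probe_field` or complex matrix.
#' @param s_sub numeric 2-vector with components of magnitude <= 0.5.
#' @return same type as `P`, translated by `s_sub`.
#' @export
shift_probe_subpixel <- function(P, s_sub) {
  if (!is.numeric(s_sub) || length(s_sub) != 2 || !all(is.finite(s_sub)))
    stop("s_sub must be a finite numeric 2-vector")
  if (any(abs(s_sub) > 0.5))
    stop("subpixel shift components must have magnitude <= 0.5; ",
         "route integer parts through split_shift()")
  v <- fourier_shift(as_complex_matrix(P, "P"), s_sub)
  if (inherits(P, "probe_field")) probe_field(v, P$pixel_pitch) else v
}

#' Extract the object patch seen by one scan placement
#'
#' Returns the probe-window-sized patch of the object canvas whose origin
#' sits at the integer offset `s_int` (zero-based: `c(0, 0)` is the
#' top-left corner). Placements that do not fit inside the canvas are an
#' error; there is no wrap-around.
#'
#' @param O `object_field` or complex matrix (the full canvas).
#' @param s_int integer 2-vector offset of the window origin.
#' @param window integer 2-vector (rows, cols) of the probe window.
#' @return complex matrix of shape `window`.
#' @export
object_patch <- function(O, s_int, window) {
  v <- field_values(O)
  idx <- patch_index(dim(v), s_int, window)
  v[idx$rows, idx$cols, drop = FALSE]
}

#' Write a patch back into the object canvas (adjoint of extraction)
#'
#' Replaces exactly the pixels of the window placed at `s_int` with
#' `patch`, leaving every other canvas pixel untouched.
#'
#' @inheritParams object_patch
#' @param patch complex matrix of the window shape.
#' @return the updated canvas, same type as `O`.
#' @export
write_patch <- function(O, s_int, patch) {
  v <- field_values(O)
  idx <- patch_index(dim(v), s_int, dim(patch))
  v[idx$rows, idx$cols] <- patch
  if (inherits(O, "object_field")) object_field(v, O$pixel_pitch) else v
}

patch_index <- function(canvas, s_int, window) {
  s_int <- as.integer(round(s_int))
  if (any(s_int < 0L) || any(s_int + window > canvas))
    stop(sprintf(
      "probe window [%d x %d] at offset (%d, %d) lies outside the %d x %d canvas",
      window[1], window[2], s_int[1], s_int[2], canvas[1], canvas[2]))
  list(rows = s_int[1] + seq_len(window[1]),
       cols = s_int[2] + seq_len(window[2]))
}

#' Exit wavefield of one scan placement
#'
#' Under the thin-object (multiplicative) approximation the wavefield
#' leaving the specimen is the element-wise product of the shifted probe
#' and the local object patch.
#'
#' @param O_n complex matrix, object patch.
#' @param P_n `probe_field` or complex matrix, shifted probe.
#' @return complex matrix `psi = P_n * O_n`.
#' @export
exit_wave <- function(O_n, P_n) {
  P_n <- field_values(P_n)
  if (!identical(dim(O_n), dim(P_n)))
    stop("object patch and probe shapes differ")
  P_n * O_n
}

#' Unitary Fourier propagation to the detector plane
#'
#' Far-field (Fraunhofer) propagation is modeled by the 2-D discrete
#' Fourier transform with unitary normalization `1/sqrt(M*N)` in both
#' directions, so that Parseval's identity holds: real-space and
#' reciprocal-space energies (and squared errors) coincide.
#' `back_propagate()` is the exact inverse.
#'
#' @param psi complex matrix.
#' @return complex matrix of the same shape.
#' @export
propagate <- function(psi) {
  if (!all(is.finite(psi))) stop("non-finite field")
  stats::fft(psi) / sqrt(length(psi))
}

#' @rdname propagate
#' @export
back_propagate <- function(psi) {
  if (!all(is.finite(psi))) stop("non-finite field")
  stats::fft(psi, inverse = TRUE) / sqrt(length(psi))
}

#' Noise-free diffraction intensity of an exit wavefield
#'
#' The detector records the squared modulus of the propagated exit wave.
#' Under the unitary transform the total intensity equals the real-space
#' field energy.
#'
#' @param psi complex matrix (exit wave).
#' @return nonnegative numeric matrix `|F psi|^2`.
#' @export
clean_intensity <- function(psi) {
  Mod(propagate(psi))^2
}

#' Apply Poisson counting noise to an intensity pattern
#'
#' Draws each pixel independently from a Poisson law with the clean pixel
#' value as mean, deterministically under a fixed seed. For means above
#' `1e7` the rounded normal limit `N(lambda, lambda)` is used (the
#' relative skew at such counts is below 1e-3, far under the shot-noise
#' scale itself).
#'
#' @param I_clean nonnegative numeric matrix/array of mean counts.
#' @param seed integer RNG seed.
#' @return integer-valued numeric object of the same shape.
#' @export
apply_poisson_noise <- function(I_clean, seed) {
  if (any(I_clean < 0)) stop("intensities must be nonnegative")
  with_seed(seed, {
    out <- I_clean
    big <- I_clean > 1e7
    if (any(!big)) out[!big] <- stats::rpois(sum(!big), I_clean[!big])
    if (any(big)) {
      lam <- I_clean[big]
      out[big] <- pmax(0, round(stats::rnorm(length(lam), lam, sqrt(lam))))
    }
    out
  })
}

#' Magnitude projection: the revised exit wavefield
#'
#' Replaces the modulus of the propagated exit wave by the square root of
#' the measured intensity while keeping its phase, then propagates back:
#' `psi' = F^-1( sqrt(I) * sign(F psi) )` with `sign(z) = z/|z|` and the
#' convention `sign(0) = 1` (the measured modulus is kept with zero
#' phase). Consequently the revised wave reproduces the measurement:
#' `|F psi'|^2 = I` to round-off.
#'
#' @param psi complex matrix (current model exit wave).
#' @param I nonnegative numeric matrix, measured intensity, same shape.
#' @return complex matrix `psi'`.
#' @export
revised_exit_wave <- function(psi, I) {
  if (!identical(dim(psi), dim(I))) stop("psi and I shapes differ")
  if (any(I < 0)) stop("intensities must be nonnegative")
  Fpsi <- propagate(psi)
  m <- Mod(Fpsi)
  s <- ifelse(m == 0, 1 + 0i, Fpsi / m)
  back_propagate(sqrt(I) * s)
}
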