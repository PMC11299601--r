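#' R-factor between measured and modeled diffraction moduli
#'
#' Convergence monitor pooled over all patterns and pixels:
#' `R_F = sum_n sum_px | sqrt(I_n) - |F psi_n| | / sum_n sum_px sqrt(I_n)`
#' with `psi_n` formed from the supplied object, probe and scan. Zero for
#' a model that reproduces every measured modulus; invariant to a common
#' rescaling of all intensities by `t^2` with moduli by `t`.
#'
#' @inheritParams run_pie
#' @param object,probe current estimates.
#' @return nonnegative scalar.
#' @export
r_factor <- function(dataset, object, probe, scan) {
  geom <- check_geometry(dataset, scan, object, probe)
  num <- 0
  den <- 0
  for (n in seq_len(geom$N)) {
    sv <- view_at(object$values, probe$values, dataset, scan, n, geom$window)
    modelled <- Mod(propagate(sv$P_n * sv$O_n))
    measured <- sqrt(sv$I_n)
    num <- num + sum(abs(measured - modelled))
    den <- den + sum(measured)
  }
  if (den == 0) stop("all-zero dataset: R_F undefined")
  num / den
}

#' Remove the global phase and translation ambiguities
#'
#' A ptychographic solution is determined only up to a global phase factor
#' and a lateral translation (compensated by the probe). Before any image
#' comparison these ambiguities are removed: the translation is estimated
#' from the modulus of the circular cross-correlation peak, refined to
#' subpixel precision by a parabolic fit and applied via a Fourier phase
#' ramp; the phase is then removed via the argument of the global inner
#' product with the reference.
#'
#' @param O_est complex matrix, estimate to align.
#' @param O_ref complex matrix, reference (must not be all zero).
#' @return list with `aligned` (complex matrix), and `transform` holding
#'   `phase` (unit-modulus factor) and `shift` (numeric 2-vector applied
#'   to `O_est`).
#' @export
align_global <- function(O_est, O_ref) {
  if (!identical(dim(O_est), dim(O_ref))) stop("shapes differ")
  if (all(O_ref == 0)) stop("zero reference")
  d <- dim(O_ref)
  cc <- stats::fft(stats::fft(O_ref + 0i) * Conj(stats::fft(O_est + 0i)),
                   inverse = TRUE) / prod(d)
  m <- Mod(cc)
  peak <- as.integer(arrayInd(which.max(m), d))
  shift <- integer_offset(peak, d)
  shift <- shift + parabolic_refine(m, peak, d)
  shifted <- fourier_shift(O_est + 0i, shift)
  ip <- sum(O_ref * Conj(shifted))
  phase <- if (Mod(ip) == 0) 1 + 0i else ip / Mod(ip)
  list(aligned = phase * shifted,
       transform = list(phase = phase, shift = shift))
}

# Convert a 1-based peak index to a signed circular offset.
integer_offset <- function(peak, d) {
  s <- peak - 1
  ifelse(s > d / 2, s - d, s)
}

# Parabolic (3-point) subpixel refinement of a correlation peak along each
# axis, on the circular grid.
parabolic_refine <- function(m, peak, d) {
  ref <- numeric(2)
  for (ax in 1:2) {
    i0 <- peak[ax]
    im <- ((i0 - 2) %% d[ax]) + 1
    ip <- (i0 %% d[ax]) + 1
    idx <- function(i) if (ax == 1) m[i, peak[2]] else m[peak[1], i]
    y0 <- idx(i0); ym <- idx(im); yp <- idx(ip)
    den <- ym - 2 * y0 + yp
    if (den < 0) ref[ax] <- 0.5 * (ym - yp) / den
  }
  pmax(pmin(ref, 0.5), -0.5)
}

#' Fourier ring correlation between two complex images
#'
#' Correlates the Fourier transforms of an aligned estimate and a
#' reference over annuli of integer radius (1 frequency-pixel wide):
#' `FRC(S) = |sum F_est conj(F_ref)| / sqrt(sum |F_est|^2 sum |F_ref|^2)`
#' over the ring `Omega_S`. Values near 1 indicate agreement at that
#' spatial frequency. Alignment ([align_global()]) must be applied first;
#' an unremoved translation shows up as ring decorrelation.
#'
#' @param O_est,O_ref complex matrices of equal shape.
#' @param ring_width annulus width in frequency pixels (default 1).
#' @return data.frame of class `frc_curve` with columns `ring` (index),
#'   `frequency` (cycles/pixel, `ring * ring_width / min(dim)`), `frc` and
#'   `count` (pixels in the ring); empty rings are dropped.
#' @export
frc <- function(O_est, O_ref, ring_width = 1) {
  if (!identical(dim(O_est), dim(O_ref))) stop("shapes differ")
  stopifnot(ring_width >= 1)
  d <- dim(O_ref)
  Fe <- stats::fft(O_est + 0i)
  Fr <- stats::fft(O_ref + 0i)
  ky <- fft_freq(d[1]) * d[1]
  kx <- fft_freq(d[2]) * d[2]
  radius <- sqrt(outer(ky^2, kx^2, `+`))
  ring <- as.integer(round(radius / ring_width))
  rmax <- floor(min(d) / 2 / ring_width)
  keep <- ring <= rmax
  num <- Mod(tapply_sum(Fe * Conj(Fr), ring, keep, rmax))
  p1 <- tapply_sum(Mod(Fe)^2, ring, keep, rmax)
  p2 <- tapply_sum(Mod(Fr)^2, ring, keep, rmax)
  count <- tapply_sum(array(1, d), ring, keep, rmax)
  ok <- Re(count) >= 1 & Re(p1) > 0 & Re(p2) > 0
  out <- data.frame(ring = (0:rmax)[ok],
                    frequency = (0:rmax)[ok] * ring_width / min(d),
                    frc = (num / sqrt(Re(p1) * Re(p2)))[ok],
                    count = Re(count)[ok])
  class(out) <- c("frc_curve", "data.frame")
  out
}

# Sum `x` over ring labels 0..rmax (complex-safe tapply).
tapply_sum <- function(x, ring, keep, rmax) {
  out <- rep(0 + 0i, rmax + 1)
  s <- tapply(x[keep], ring[keep], sum)
  out[as.integer(names(s)) + 1] <- s
  out
}

#' Pairwise dissimilarity of two reconstructions (tau score)
#'
#' After removing the global phase/translation ambiguity of `O_i` against
#' `O_j`, `tau_ij = ||O_i_aligned - O_j||_F^2 / (||O_i||_F ||O_j||_F)`.
#' Lower values mean more similar reconstructions; the score is used to
#' quantify the run-to-run dispersion of an engine under randomized update
#' orders, where its ordering (not its absolute value) is the meaningful
#' quantity.
#'
#' @param O_i,O_j complex matrices of equal shape, both nonzero.
#' @return nonnegative scalar, symmetric up to alignment tolerance.
#' @export
tau_score <- function(O_i, O_j) {
  ni <- sqrt(sum(Mod(O_i)^2))
  nj <- sqrt(sum(Mod(O_j)^2))
  if (ni == 0 || nj == 0) stop("zero-norm input")
  al <- align_global(O_i, O_j)
  sum(Mod(al$aligned - O_j)^2) / (ni * nj)
}

#' Reciprocal-space correlation of two probes
#'
#' Modulus of the normalized complex inner product of the propagated
#' (far-field) probes, restricted to an aperture mask — the support of
#' the illumination optics in the frequency plane. 1 for identical
#' probes, 0 for orthogonal fields on the mask; invariant to global
#' phase.
#'
#' @param P_est,P_ref `probe_field`s or complex matrices.
#' @param aperture_mask logical matrix of the probe shape selecting the
#'   frequency pixels to compare; default all `TRUE`.
#' @return scalar in `[0, 1]`.
#' @export
probe_correlation <- function(P_est, P_ref, aperture_mask = NULL) {
  pe <- field_values(P_est)
  pr <- field_values(P_ref)
  if (!identical(dim(pe), dim(pr))) stop("shapes differ")
  if (is.null(aperture_mask)) aperture_mask <- array(TRUE, dim(pe))
  if (!any(aperture_mask)) stop("empty aperture mask")
  Fe <- propagate(pe)[aperture_mask]
  Fr <- propagate(pr)[aperture_mask]
  den <- sqrt(sum(Mod(Fe)^2) * sum(Mod(Fr)^2))
  if (den == 0) stop("zero probe on the mask")
  Mod(sum(Fe * Conj(Fr))) / den
}

#' Crop an object canvas to the scan-covered region
#'
#' Pixels outside the union of probe windows are never constrained by the
#' data, so image-quality metrics (FRC, tau) are computed on the covered
#' sub-canvas only. Returns the bounding box of all window placements,
#' optionally shrunk by `margin` pixels per side: the window border beyond
#' the nominal probe diameter is only grazed by the weak illumination
#' tail, converges arbitrarily slowly, and would dominate an FRC or tau
#' comparison; trimming `(window - diameter)/2` restricts the comparison
#' to pixels the data actually constrain.
#'
#' @param O `object_field` or complex matrix.
#' @param scan `scan_plan`.
#' @param window integer 2-vector, probe window shape.
#' @param margin nonnegative pixels trimmed from each side of the box.
#' @return complex matrix, the cropped region.
#' @export
crop_to_scan <- function(O, scan, window, margin = 0) {
  v <- field_values(O)
  margin <- as.integer(margin)
  stopifnot(margin >= 0)
  r0 <- min(scan$s_int[, 1]) + margin
  c0 <- min(scan$s_int[, 2]) + margin
  r1 <- max(scan$s_int[, 1]) + window[1] - margin
  c1 <- max(scan$s_int[, 2]) + window[2] - margin
  if (r1 - r0 < 2 || c1 - c0 < 2) stop("margin leaves no evaluation region")
  v[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
}
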