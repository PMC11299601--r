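#' Particle-filled film phantom
#'
#' A statistical stand-in for a particle-filled polymer film: a uniform
#' background transmission with seeded random disks, each carrying an
#' amplitude drawn from `amp_range` (a passive object, so amplitudes stay
#' in `(0, 1]`) and a phase drawn from `phase_range`. Disks may overlap;
#' later disks overwrite earlier ones.
#'
#' @param shape integer 2-vector, canvas size in pixels.
#' @param n_particles number of disks (0 gives the bare background).
#' @param radius_range numeric 2-vector of disk radii in pixels.
#' @param amp_range amplitude range, a subset of `(0, 1]`. The default
#'   emulates a weakly absorbing film with dense inclusions, the regime of
#'   hard-X-ray transmission specimens (phase contrast dominant).
#' @param phase_range phase range in radians.
#' @param background background transmission amplitude in `(0, 1]`.
#' @param seed RNG seed; the phantom is bit-reproducible under it.
#' @param pixel_pitch pixel size metadata.
#' @return an `object_field`.
#' @export
make_particle_phantom <- function(shape = c(64, 64), n_particles = 40,
                                  radius_range = c(2, 5),
                                  amp_range = c(0.7, 0.95),
                                  phase_range = c(-0.4, 0.2),
                                  background = 1, seed = 1L,
                                  pixel_pitch = 1) {
  stopifnot(length(shape) == 2, all(shape >= 4), n_particles >= 0,
            all(amp_range > 0), all(amp_range <= 1),
            background > 0, background <= 1,
            diff(radius_range) >= 0)
  v <- matrix(background + 0i, shape[1], shape[2])
  if (n_particles > 0) {
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    with_seed(seed, {
      for (i in seq_len(n_particles)) {
        cy <- stats::runif(1, 1, shape[1])
        cx <- stats::runif(1, 1, shape[2])
        rad <- stats::runif(1, radius_range[1], radius_range[2])
        amp <- stats::runif(1, amp_range[1], amp_range[2])
        ph <- stats::runif(1, phase_range[1], phase_range[2])
        inside <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
        v[inside] <- amp * exp(1i * ph)
      }
    })
  }
  object_field(v, pixel_pitch)
}

#' Siemens-star resolution phantom
#'
#' A binary-amplitude radial spoke pattern with a smooth central hub: the
#' classic resolution target whose spoke width shrinks linearly toward
#' the center. Transmission alternates between 1 and `low` over equal
#' angular sectors.
#'
#' @param shape integer 2-vector, canvas size.
#' @param spokes number of bright/dark spoke pairs per revolution is
#'   `spokes / 2`; must be an even integer >= 2 so the duty cycle is even.
#' @param low transmission of the dark sectors, in `[0, 1)`.
#' @param hub_radius radius of the uniform central hub in pixels.
#' @param pixel_pitch pixel size metadata.
#' @return an `object_field` with `|values| <= 1`.
#' @export
make_siemens_star <- function(shape = c(64, 64), spokes = 8, low = 0.2,
                              hub_radius = 3, pixel_pitch = 1) {
  stopifnot(spokes >= 2, spokes %% 2 == 0, low >= 0, low < 1)
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  theta <- atan2(rows - cy, cols - cx)
  sector <- floor((theta + pi) / (2 * pi / spokes))
  amp <- ifelse(sector %% 2 == 0, 1, low)
  r <- sqrt((rows - cy)^2 + (cols - cx)^2)
  amp[r <= hub_radius] <- 1
  object_field(matrix(amp + 0i, shape[1], shape[2]), pixel_pitch)
}

#' Soft-edged disk probe
#'
#' An idealized localized illumination: a radially symmetric disk of the
#' given diameter with a logistic (sigmoid) edge of width `softness`
#' pixels and an optional quadratic phase (defocus) reaching
#' `defocus` radians at the nominal radius. The field is normalized to
#' unit total energy; dose scaling is applied later at simulation time.
#'
#' @param window integer 2-vector, probe window size in pixels.
#' @param diameter nominal disk diameter in pixels, positive and smaller
#'   than the window extent.
#' @param softness edge width in pixels; 0 gives a hard disk.
#' @param defocus quadratic phase at the nominal radius, in radians.
#' @param pixel_pitch pixel size metadata.
#' @return a `probe_field` with `sum(|P|^2) = 1`.
#' @export
make_probe <- function(window = c(16, 16), diameter = 12, softness = 0.3,
                       defocus = 0, pixel_pitch = 1) {
  stopifnot(diameter > 0, diameter < min(window), softness >= 0)
  cy <- (window[1] + 1) / 2
  cx <- (window[2] + 1) / 2
  rows <- matrix(seq_len(window[1]), window[1], window[2])
  cols <- matrix(seq_len(window[2]), window[1], window[2], byrow = TRUE)
  r <- sqrt((rows - cy)^2 + (cols - cx)^2)
  R <- diameter / 2
  amp <- if (softness == 0) (r <= R) * 1
         else 1 / (1 + exp((r - R) / softness))
  phase <- if (defocus == 0) 0 else defocus * (r / R)^2
  v <- amp * exp(1i * phase)
  v <- v / sqrt(sum(Mod(v)^2))
  out <- probe_field(v, pixel_pitch)
  attr(out, "nominal_diameter") <- diameter
  out
}

#' Jittered raster scan plan
#'
#' Rows x cols raster lattice with the given step, centered on the object
#' canvas, plus seeded uniform jitter in `[-jitter, jitter]` per axis.
#' The step must be smaller than the probe diameter so neighboring
#' illuminations overlap (the redundancy that makes ptychography solvable)
#' and every window placement must fit in the canvas.
#'
#' @param rows,cols lattice size.
#' @param step lattice step in object pixels.
#' @param canvas integer 2-vector, object canvas shape.
#' @param window integer 2-vector, probe window shape.
#' @param jitter maximum jitter amplitude in pixels.
#' @param seed RNG seed for the jitter.
#' @return a `scan_plan` with `rows * cols` positions.
#' @export
make_scan <- function(rows = 5, cols = 5, step = 2, canvas = c(64, 64),
                      window = c(16, 16), jitter = 0, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, step > 0, jitter >= 0)
  extent <- c((rows - 1) * step, (cols - 1) * step) + window
  if (any(extent + 2 * jitter > canvas))
    stop("scan grid (plus jitter margin) does not fit in the canvas")
  off <- floor((canvas - extent) / 2)
  grid <- cbind(rep(off[1] + (seq_len(rows) - 1) * step, each = cols),
                rep(off[2] + (seq_len(cols) - 1) * step, times = rows))
  if (jitter > 0)
    grid <- grid + with_seed(seed,
      matrix(stats::runif(2 * nrow(grid), -jitter, jitter), ncol = 2))
  scan_plan(grid)
}

#' Simulate a dose-scaled ptychographic dataset
#'
#' Computes the clean diffraction intensity at every scan position with
#' the forward model, applies one global scale factor so that the maximum
#' over positions of the zero-frequency (DC-bin) intensity equals the
#' requested dose `I0`, then (optionally) draws Poisson counting noise.
#' The ground truth and the scale factor are stored alongside the data so
#' metrics can be computed without re-deriving them.
#'
#' @param object ground-truth `object_field`.
#' @param probe ground-truth `probe_field` (unit energy; the dose scale
#'   supplies the photon budget).
#' @param scan `scan_plan`.
#' @param I0 target zero-frequency intensity (photons), e.g. `1e10`
#'   (high dose) or `1e8` (low dose).
#' @param noise `"poisson"` or `"clean"`.
#' @param noise_seed seed for the noise draw (a stream separate from any
#'   scan/phantom seed); draws happen once here, never during
#'   reconstruction.
#' @return list of class `ptycho_sim` with elements `dataset`
#'   (`diffraction_set`), `scan`, `truth` (list `object`, `probe`),
#'   `clean` (the scaled noise-free intensities), and `attrs`
#'   (`dose_I0`, `dose_scale`, `noise_model`, `seed`, `pixel_pitch`).
#' @export
simulate_dataset <- function(object, probe, scan, I0 = 1e10,
                             noise = c("poisson", "clean"),
                             noise_seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(object, "object_field"), inherits(probe, "probe_field"),
            inherits(scan, "scan_plan"), I0 > 0)
  window <- dim(probe$values)
  N <- nrow(scan$positions)
  clean <- array(0, dim = c(N, window[1], window[2]))
  for (n in seq_len(N)) {
    sv <- split_shift(scan$positions[n, ])
    P_n <- fourier_shift(probe$values, sv$s_sub)
    O_n <- object_patch(object, sv$s_int, window)
    clean[n, , ] <- clean_intensity(P_n * O_n)
  }
  dc <- max(clean[, 1, 1])  # DC bin of the unshifted transform
  if (dc == 0) stop("zero origin intensity: cannot scale to the target dose")
  scale <- I0 / dc
  clean <- clean * scale
  intensities <- if (noise == "poisson")
    apply_poisson_noise(clean, noise_seed) else clean
  # The dose scale is carried by the probe amplitude (x sqrt(scale)), so the
  # stored truth reproduces the scaled data exactly and the object keeps its
  # passive |O| <= 1 transmission.
  probe_scaled <- probe_field(probe$values * sqrt(scale), probe$pixel_pitch)
  structure(list(
    dataset = diffraction_set(intensities, noise_model = noise,
                              seed = if (noise == "poisson")
                                as.integer(noise_seed) else NA_integer_),
    scan = scan,
    truth = list(object = object, probe = probe_scaled),
    clean = clean,
    attrs = list(dose_I0 = I0, dose_scale = scale, noise_model = noise,
                 seed = if (noise == "poisson") as.integer(noise_seed)
                        else NA_integer_,
                 pixel_pitch = object$pixel_pitch,
                 probe_diameter = attr(probe, "nominal_diameter"))),
    class = "ptycho_sim")
}

#' Named simulation/engine presets
#'
#' The two study conditions: `"high_dose"` (`I0 = 1e10`; engine settings
#' `alpha_o = lambda_o = 1.0`, `alpha_p = lambda_p = 0.4`,
#' `gamma = (0.1, 1.0)`, `c = 0.5`, 300 iterations) and `"low_dose"`
#' (`I0 = 1e8`; `alpha_o = lambda_o = 0.4`, `alpha_p = lambda_p = 0.2`,
#' `gamma = (0.1, 5.0)`, `c = 0.01`, 400 iterations), both with ePIE-like
#' clipping `(nu_o, nu_p) = (1, 1)`.
#'
#' @param name `"high_dose"` or `"low_dose"`.
#' @param seed seed forwarded to the engine parameter objects.
#' @return list with `I0`, `pie` (`pie_params`) and `crisp`
#'   (`crisp_params`).
#' @export
crisp_preset <- function(name = c("high_dose", "low_dose"), seed = 1L) {
  name <- match.arg(name)
  if (name == "high_dose") {
    list(I0 = 1e10,
         pie = pie_params(alpha_o = 1, alpha_p = 0.4, gamma_o = 0.1,
                          gamma_p = 1, K = 300, seed = seed),
         crisp = crisp_params(lambda_o = 1, lambda_p = 0.4, nu = "epie_like",
                              c_tune = 0.5, K = 300, seed = seed))
  } else {
    list(I0 = 1e8,
         pie = pie_params(alpha_o = 0.4, alpha_p = 0.2, gamma_o = 0.1,
                          gamma_p = 5, K = 400, seed = seed),
         crisp = crisp_params(lambda_o = 0.4, lambda_p = 0.2,
                              nu = "epie_like", c_tune = 0.01, K = 400,
                              seed = seed))
  }
}

#' Demagnified image diameter of a beam-defining aperture
#'
#' In an illumination train where the aperture, focusing lens and
#' specimen obey the thin-lens imaging condition, the aperture image on
#' the specimen is its physical diameter divided by the demagnification
#' ratio. The nominal geometry (20 micrometer aperture, demagnification
#' 5) gives the 4 micrometer illumination diameter used throughout.
#'
#' @param bda_diameter aperture diameter (default 20, micrometers).
#' @param demagnification demagnification ratio (default 5).
#' @return the image diameter in the same units.
#' @export
bda_image_diameter <- function(bda_diameter = 20, demagnification = 5) {
  stopifnot(bda_diameter > 0, demagnification > 0)
  bda_diameter / demagnification
}
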