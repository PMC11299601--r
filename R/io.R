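#' Write / read a simulated dataset bundle
#'
#' Serializes a `ptycho_sim` bundle (patterns, positions, optional truth,
#' and attributes `pixel_pitch`, `dose_I0`, `seed`, `noise_model`,
#' `dose_scale`) to a single file with a fixed logical layout:
#' `data$intensities` (N x H x W), `data$positions` (N x 2, object
#' pixels, row-major y,x), `truth$object`, `truth$probe`, `attrs`. The
#' round trip is bit-exact.
#'
#' @param sim a `ptycho_sim` from [simulate_dataset()].
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(sim, path) {
  stopifnot(inherits(sim, "ptycho_sim"))
  bundle <- list(
    format = "ptycrisp-dataset-v1",
    data = list(intensities = sim$dataset$intensities,
                positions = sim$scan$positions),
    truth = list(object = sim$truth$object$values,
                 probe = sim$truth$probe$values),
    attrs = sim$attrs)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname write_dataset
#' @return for `read_dataset`, the reconstructed `ptycho_sim`-like list
#'   with elements `dataset`, `scan`, `truth` and `attrs` (`clean`
#'   intensities are not stored).
#' @export
read_dataset <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "ptycrisp-dataset-v1"))
    stop("not a ptycrisp dataset file: ", path)
  pitch <- bundle$attrs$pixel_pitch
  truth <- NULL
  if (!is.null(bundle$truth$object))
    truth <- list(object = object_field(bundle$truth$object, pitch),
                  probe = probe_field(bundle$truth$probe, pitch))
  structure(list(
    dataset = diffraction_set(bundle$data$intensities,
                              noise_model = bundle$attrs$noise_model,
                              seed = bundle$attrs$seed),
    scan = scan_plan(bundle$data$positions),
    truth = truth,
    attrs = bundle$attrs), class = "ptycho_sim")
}

#' Write a per-iteration trace as CSV
#'
#' Columns: `k`, `rf`, `cost`, and for CRISP runs `xi` (the threshold in
#' effect during iteration `k`).
#'
#' @param result a `recon_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "recon_result"))
  df <- data.frame(k = seq_len(result$iterations),
                   rf = result$rf, cost = result$cost)
  if (!is.null(result$xi_trace))
    df$xi <- result$xi_trace[seq_len(result$iterations)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an FRC curve as CSV
#'
#' @param curve an `frc_curve` from [frc()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write amplitude/phase TIFF previews of a complex field
#'
#' Writes two float32 TIFF planes, `<stem>_amplitude.tif` and
#' `<stem>_phase.tif` (phase in radians, wrapped to `(-pi, pi]`).
#' Requires the `tiff` package.
#'
#' @param field `object_field`, `probe_field` or complex matrix.
#' @param stem output path stem (without suffix).
#' @return character vector of the two paths, invisibly.
#' @export
write_preview_tiff <- function(field, stem) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF previews")
  v <- field_values(field)
  paths <- paste0(stem, c("_amplitude.tif", "_phase.tif"))
  tiff::writeTIFF(Mod(v) / max(Mod(v), 1e-300), paths[1],
                  bits.per.sample = 32L)
  tiff::writeTIFF((Arg(v) + pi) / (2 * pi), paths[2],
                  bits.per.sample = 32L)
  invisible(paths)
}
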