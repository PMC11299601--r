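#' Parameters for the sequential PIE engines
#'
#' @param alpha_o,alpha_p ePIE step sizes in `(0, 1]` for the object and
#'   probe updates. Within this range a single update never increases the
#'   exit-wave subproblem cost (the step stays below the reciprocal
#'   Lipschitz constant of the gradient).
#' @param gamma_o,gamma_p positive rPIE balancing parameters weighting the
#'   element-wise denominator between `|Q|^2` and `|Q|^2_max`; `gamma = 1`
#'   recovers the ePIE denominator with unit step.
#' @param K number of outer iterations (full sweeps), >= 1.
#' @param seed integer seed for the per-iteration random visiting order
#'   (a stream separate from any noise seed).
#' @return a list of class `pie_params`.
#' @export
pie_params <- function(alpha_o = 1, alpha_p = 0.4, gamma_o = 0.1,
                       gamma_p = 1, K = 100, seed = 1L) {
  stopifnot(alpha_o > 0, alpha_o <= 1, alpha_p > 0, alpha_p <= 1,
            gamma_o > 0, gamma_p > 0, K >= 1)
  structure(list(alpha_o = alpha_o, alpha_p = alpha_p, gamma_o = gamma_o,
                 gamma_p = gamma_p, K = as.integer(K), seed = as.integer(seed)),
            class = "pie_params")
}

#' One ePIE update of an object patch and probe
#'
#' Applies the classic extended-PIE update with the residual
#' `delta = psi' - psi`:
#' `O' = O + alpha_o * conj(P) / |P|^2_max * delta` and
#' `P' = P + alpha_p * conj(O) / |O|^2_max * delta`,
#' where both updates read the same pre-update fields. This is the
#' gradient step on the exit-wave least-squares subproblem with step size
#' `alpha / |Q|^2_max` (the reciprocal Lipschitz constant scaled by
#' `alpha`).
#'
#' @param O_n,P_n complex matrices: object patch and shifted probe.
#' @param psi,psi_prime complex matrices: model and revised exit waves.
#' @param alpha_o,alpha_p step sizes in `(0, 1]`.
#' @return list with updated `O_n` and `P_n`.
#' @export
epie_step <- function(O_n, P_n, psi, psi_prime, alpha_o, alpha_p) {
  pmax2 <- max(Mod(P_n))^2
  omax2 <- max(Mod(O_n))^2
  if (pmax2 == 0 || omax2 == 0)
    stop("degenerate input: identically zero probe or object patch")
  delta <- psi_prime - psi
  list(O_n = O_n + alpha_o * Conj(P_n) / pmax2 * delta,
       P_n = P_n + alpha_p * Conj(O_n) / omax2 * delta)
}

#' One rPIE update of an object patch and probe
#'
#' The regularized-PIE update replaces ePIE's global denominator by the
#' element-wise mixture `(1 - gamma) |Q|^2 + gamma |Q|^2_max`, which
#' penalizes large changes where the co-factor field is weak:
#' `O' = O + conj(P) * delta / ((1 - gamma_o)|P|^2 + gamma_o |P|^2_max)`
#' and analogously for the probe with `gamma_p` and `|O|`. With
#' `gamma = 1` the object update equals ePIE's with `alpha = 1`.
#'
#' @inheritParams epie_step
#' @param gamma_o,gamma_p positive balancing parameters.
#' @return list with updated `O_n` and `P_n`.
#' @export
rpie_step <- function(O_n, P_n, psi, psi_prime, gamma_o, gamma_p) {
  stopifnot(gamma_o > 0, gamma_p > 0)
  pmax2 <- max(Mod(P_n))^2
  omax2 <- max(Mod(O_n))^2
  den_o <- (1 - gamma_o) * Mod(P_n)^2 + gamma_o * pmax2
  den_p <- (1 - gamma_p) * Mod(O_n)^2 + gamma_p * omax2
  if (any(den_o == 0) || any(den_p == 0))
    stop("degenerate input: zero rPIE denominator")
  delta <- psi_prime - psi
  list(O_n = O_n + Conj(P_n) * delta / den_o,
       P_n = P_n + Conj(O_n) * delta / den_p)
}

#' Run a sequential PIE reconstruction (ePIE or rPIE)
#'
#' Sweeps the scan positions in a fresh random order every iteration. At
#' each position the probe is shifted by the subpixel part of the scan
#' position, the object patch is extracted at the integer part, the exit
#' wave and its magnitude projection are formed, the variant's update is
#' applied, the patch is written back and the updated probe is un-shifted.
#' The residual `R_F` factor and the mean per-sample exit-wave cost are
#' recorded once per iteration.
#'
#' @param dataset `diffraction_set`.
#' @param scan `scan_plan` with as many positions as patterns.
#' @param object initial `object_field`.
#' @param probe initial `probe_field` (window shape = pattern shape).
#' @param params `pie_params`.
#' @param variant `"epie"` or `"rpie"`.
#' @param trace_rf compute the `R_F` trace (one extra forward pass per
#'   iteration); disable for speed in dispersion studies.
#' @return a `recon_result`: final `object`, `probe`, numeric traces
#'   `rf` and `cost` of length `K`, plus bookkeeping (`variant`,
#'   `iterations`, `seed`, `skipped`).
#' @export
run_pie <- function(dataset, scan, object, probe, params,
                    variant = c("epie", "rpie"), trace_rf = TRUE) {
  variant <- match.arg(variant)
  geom <- check_geometry(dataset, scan, object, probe)
  O <- object$values
  P <- probe$values
  K <- params$K
  perms <- make_permutations(geom$N, K, params$seed)
  rf <- rep(NA_real_, K)
  cost <- numeric(K)
  e <- numeric(geom$N)
  for (k in seq_len(K)) {
    for (n in perms[, k]) {
      sv <- view_at(O, P, dataset, scan, n, geom$window)
      psi <- sv$P_n * sv$O_n
      psi_prime <- revised_exit_wave(psi, sv$I_n)
      e[n] <- sum(Mod(psi_prime - psi)^2)
      upd <- if (variant == "epie")
        epie_step(sv$O_n, sv$P_n, psi, psi_prime, params$alpha_o, params$alpha_p)
      else
        rpie_step(sv$O_n, sv$P_n, psi, psi_prime, params$gamma_o, params$gamma_p)
      O[sv$rows, sv$cols] <- upd$O_n
      P <- fourier_shift(upd$P_n, -scan$s_sub[n, ])
    }
    cost[k] <- mean(e)
    if (trace_rf)
      rf[k] <- r_factor(dataset, object_field(O, object$pixel_pitch),
                        probe_field(P, probe$pixel_pitch), scan)
  }
  recon_result(object_field(O, object$pixel_pitch),
               probe_field(P, probe$pixel_pitch),
               rf = rf, cost = cost, variant = variant, params = params)
}

recon_result <- function(object, probe, rf, cost, variant, params,
                         xi_trace = NULL, skipped = 0L) {
  structure(list(object = object, probe = probe, rf = rf, cost = cost,
                 variant = variant, iterations = length(cost),
                 seed = params$seed, params = params,
                 xi_trace = xi_trace, skipped = skipped),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result: %s, %d iterations, final R_F = %s>\n",
              x$variant, x$iterations,
              if (all(is.na(x$rf))) "not traced"
              else format(x$rf[x$iterations], digits = 4)))
  invisible(x)
}

# Shared geometry validation for the sequential engines and metrics.
check_geometry <- function(dataset, scan, object, probe) {
  stopifnot(inherits(dataset, "diffraction_set"), inherits(scan, "scan_plan"),
            inherits(object, "object_field"), inherits(probe, "probe_field"))
  d <- dim(dataset$intensities)
  N <- d[1]
  window <- d[2:3]
  if (nrow(scan$positions) != N)
    stop("scan plan and diffraction set disagree on the number of samples")
  if (!all(dim(probe$values) == window))
    stop("probe window shape must match the diffraction patterns")
  canvas <- dim(object$values)
  if (!all(canvas > window))
    stop("object canvas must be strictly larger than the probe window")
  for (n in seq_len(N))  # fail fast, before any mutation
    patch_index(canvas, scan$s_int[n, ], window)
  list(N = N, window = window, canvas = canvas)
}

# Per-sample view: shifted probe, object patch, measured pattern, indices.
view_at <- function(O, P, dataset, scan, n, window) {
  idx <- patch_index(dim(O), scan$s_int[n, ], window)
  list(P_n = fourier_shift(P, scan$s_sub[n, ]),
       O_n = O[idx$rows, idx$cols, drop = FALSE],
       I_n = dataset$intensities[n, , ],
       rows = idx$rows, cols = idx$cols)
}
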