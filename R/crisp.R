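#' Parameters for the CRISP engine
#'
#' CRISP (clipped reliable iterative subgradient projection) replaces the
#' fixed PIE step size by a subgradient-projection coefficient that adapts
#' to the per-sample residual cost, clips that coefficient to keep it
#' bounded where the gradient vanishes, and retunes the projection
#' threshold `xi` from the mean cost after every sweep.
#'
#' @param lambda_o,lambda_p step sizes playing the role of ePIE's
#'   `alpha_o`, `alpha_p`. Subgradient projection admits `(0, 2)`; values
#'   above 1 trigger a warning since the experiments' stable range is
#'   `(0, 1]`.
#' @param nu either the string `"epie_like"` (clipping caps
#'   `(nu_o, nu_p) = (1, 1)`, limiting each step to ePIE's), the string
#'   `"scale_adaptive"` (caps `(|P_n|_max, |O_n|_max)`, an adaptive limit
#'   following the field scales), or a numeric 2-vector of fixed positive
#'   `(nu_o, nu_p)`.
#' @param c_tune threshold tuning parameter in `(0, 1)`: after each sweep
#'   `xi <- c_tune * mean(e)`, keeping the threshold below the current
#'   mean cost so updates continue until the cost is small.
#' @param K number of outer iterations.
#' @param seed permutation-stream seed.
#' @param xi_mode `"auto"` (initialize from the data and retune every
#'   iteration) or `"fixed"` (hold `xi_fixed` constant; diagnostic use).
#' @param xi_fixed constant threshold used when `xi_mode = "fixed"`.
#' @param force_cap diagnostic switch: bypass the step-size function and
#'   always apply the clipping cap, which realizes the exact ePIE
#'   equivalence of the `"epie_like"` parameterization.
#' @return a list of class `crisp_params`.
#' @export
crisp_params <- function(lambda_o = 1, lambda_p = 0.4, nu = "epie_like",
                         c_tune = 0.5, K = 100, seed = 1L,
                         xi_mode = c("auto", "fixed"), xi_fixed = 0,
                         force_cap = FALSE) {
  xi_mode <- match.arg(xi_mode)
  stopifnot(lambda_o > 0, lambda_o < 2, lambda_p > 0, lambda_p < 2,
            c_tune > 0, c_tune < 1, K >= 1, xi_fixed >= 0)
  if (lambda_o > 1 || lambda_p > 1)
    warning("lambda above 1: admissible for subgradient projection but ",
            "outside the empirically stable range (0, 1]")
  if (is.character(nu)) nu <- match.arg(nu, c("epie_like", "scale_adaptive"))
  else stopifnot(is.numeric(nu), length(nu) == 2, all(nu > 0))
  structure(list(lambda_o = lambda_o, lambda_p = lambda_p, nu = nu,
                 c_tune = c_tune, K = as.integer(K), seed = as.integer(seed),
                 xi_mode = xi_mode, xi_fixed = xi_fixed,
                 force_cap = isTRUE(force_cap)),
            class = "crisp_params")
}

#' Per-sample exit-wave cost
#'
#' The squared Frobenius distance between the revised and the model exit
#' wave, `e = ||psi' - psi||_F^2`; the quantity the engines drive to zero
#' and the input to the `xi` tuning rule.
#'
#' @param psi,psi_prime complex matrices of equal shape.
#' @return nonnegative scalar.
#' @export
sample_cost <- function(psi, psi_prime) {
  if (!identical(dim(psi), dim(psi_prime))) stop("shapes differ")
  sum(Mod(psi_prime - psi)^2)
}

no_direction_error <- function(msg) {
  stop(errorCondition(msg, class = "ptycrisp_no_direction"))
}

#' One subgradient-projection step for a differentiable cost
#'
#' `x' = x - lambda * (g(x) - xi)_+ / ||grad||^2 * grad`. The step is the
#' identity once the cost is at or below the threshold `xi`; where the
#' gradient vanishes while the thresholded cost is positive there is no
#' update direction, and a condition of class `ptycrisp_no_direction` is
#' signalled so callers can skip that visit.
#'
#' @param x numeric (or complex) vector, current point.
#' @param grad gradient of the cost at `x`.
#' @param g_value cost value at `x`.
#' @param xi threshold (nonnegative).
#' @param lambda relaxation in `(0, 2)`.
#' @return the updated point.
#' @export
subgradient_step <- function(x, grad, g_value, xi, lambda) {
  stopifnot(lambda > 0, lambda < 2, all(is.finite(grad)))
  excess <- max(0, g_value - xi)
  if (excess == 0) return(x)
  ng2 <- sum(Mod(grad)^2)
  if (ng2 == 0)
    no_direction_error("zero gradient with cost above threshold")
  x - lambda * excess / ng2 * grad
}

#' Adaptive step-size function of the CRISP update
#'
#' The scalar factor `G = (e - xi)_+ / ||conj(Q) * delta||_F^2` replacing
#' the fixed `alpha/|Q|^2_max` of ePIE, where `Q` is the co-factor field
#' (the probe for the object update, the object patch for the probe
#' update) and `delta = psi' - psi` the residual. `G` is zero once the
#' sample cost meets the threshold and grows where the gradient
#' `conj(Q) * delta` is small while the cost is not — the mechanism that
#' lets CRISP escape shallow stagnation (and the reason clipping is
#' needed).
#'
#' @param Q complex matrix, co-factor field.
#' @param delta complex matrix, exit-wave residual.
#' @param e sample cost `||delta||_F^2` (passed in, not recomputed, so the
#'   threshold bookkeeping stays exact).
#' @param xi threshold.
#' @return nonnegative scalar; signals `ptycrisp_no_direction` when the
#'   denominator vanishes while `e > xi`.
#' @export
step_size_G <- function(Q, delta, e, xi) {
  excess <- max(0, e - xi)
  if (excess == 0) return(0)
  den <- sum(Mod(Conj(Q) * delta)^2)
  if (den == 0)
    no_direction_error("zero update direction with cost above threshold")
  excess / den
}

#' Clip the CRISP step-size coefficient
#'
#' Caps the subgradient coefficient at `nu / |Q|^2_max`. With `nu = 1` the
#' clipped coefficient never exceeds ePIE's `1/|Q|^2_max`, so CRISP with
#' `(lambda_o, lambda_p) = (alpha_o, alpha_p)` can never step further than
#' ePIE; with `nu = |Q'|_max` (the other field's maximum modulus) the cap
#' follows the scales of the current iterates.
#'
#' @param G nonnegative coefficient from [step_size_G()].
#' @param Q complex matrix, the same co-factor field.
#' @param nu positive clipping parameter.
#' @return `min(G, nu / |Q|^2_max)`.
#' @export
clip_G <- function(G, Q, nu) {
  stopifnot(nu > 0)
  qmax2 <- max(Mod(Q))^2
  if (qmax2 == 0) stop("degenerate input: |Q|_max = 0")
  min(G, nu / qmax2)
}

#' CRISP update directions for one sample
#'
#' Computes the residual `delta = psi' - P_n * O_n`, the sample cost
#' `e = ||delta||_F^2`, and the clipped subgradient directions
#' `D_o = min{G_o, nu_o/|P_n|^2_max} * conj(P_n) * delta` and
#' `D_p = min{G_p, nu_p/|O_n|^2_max} * conj(O_n) * delta`, both read from
#' the same pre-update fields.
#'
#' @param O_n,P_n complex matrices: object patch and shifted probe.
#' @param psi_prime complex matrix, revised exit wave.
#' @param xi current threshold.
#' @param nu_o,nu_p positive clipping parameters.
#' @param force_cap bypass `G` and use the cap directly (diagnostic).
#' @return list with `D_o`, `D_p`, `e`, and the applied scalar
#'   coefficients `coef_o`, `coef_p`.
#' @export
crisp_direction <- function(O_n, P_n, psi_prime, xi, nu_o, nu_p,
                            force_cap = FALSE) {
  if (!identical(dim(O_n), dim(P_n)) || !identical(dim(O_n), dim(psi_prime)))
    stop("shapes differ")
  delta <- psi_prime - P_n * O_n
  e <- sum(Mod(delta)^2)
  cap_o <- nu_o / max(Mod(P_n))^2
  cap_p <- nu_p / max(Mod(O_n))^2
  if (force_cap) {
    coef_o <- cap_o
    coef_p <- cap_p
  } else {
    coef_o <- min(step_size_G(P_n, delta, e, xi), cap_o)
    coef_p <- min(step_size_G(O_n, delta, e, xi), cap_p)
  }
  list(D_o = coef_o * Conj(P_n) * delta,
       D_p = coef_p * Conj(O_n) * delta,
       e = e, coef_o = coef_o, coef_p = coef_p)
}

#' Per-iteration retuning of the projection threshold
#'
#' `xi' = c * mean(e)`: the threshold is reset to a fraction `c` of the
#' mean per-sample cost of the completed sweep, so it tracks the cost
#' downward and the updates keep going until the cost itself is small.
#'
#' @param e numeric vector of nonnegative per-sample costs.
#' @param c_tune tuning parameter in `(0, 1)`.
#' @return the new threshold.
#' @export
update_xi <- function(e, c_tune) {
  if (length(e) == 0) stop("empty cost vector")
  stopifnot(all(e >= 0), c_tune > 0, c_tune < 1)
  c_tune * mean(e)
}

#' Initialize the projection threshold from the data
#'
#' Evaluates the per-sample cost of the initial object and probe against
#' every measured pattern (forming `psi` and its magnitude projection for
#' each scan position) and returns `c * mean(e)`. Nothing is modified.
#'
#' @inheritParams run_pie
#' @param c_tune tuning parameter in `(0, 1)`.
#' @return nonnegative scalar `xi0`.
#' @export
initialize_xi <- function(dataset, scan, object, probe, c_tune) {
  geom <- check_geometry(dataset, scan, object, probe)
  e <- numeric(geom$N)
  for (n in seq_len(geom$N)) {
    sv <- view_at(object$values, probe$values, dataset, scan, n, geom$window)
    psi <- sv$P_n * sv$O_n
    e[n] <- sample_cost(psi, revised_exit_wave(psi, sv$I_n))
  }
  update_xi(e, c_tune)
}

#' Run a CRISP reconstruction
#'
#' The full loop: `xi` is initialized from the data ([initialize_xi()]),
#' then each iteration visits the scan positions in a fresh random order,
#' applies the clipped subgradient directions
#' `O_n <- O_n + lambda_o D_o`, `P_n <- P_n + lambda_p D_p`
#' ([crisp_direction()]), stores each pre-update sample cost, and after
#' the sweep retunes `xi <- c * mean(e)` ([update_xi()]). Samples with no
#' defined direction (zero denominator at positive cost) are skipped for
#' that visit and counted.
#'
#' @inheritParams run_pie
#' @param params `crisp_params`.
#' @return a `recon_result` with traces `rf`, `cost` (mean stored cost per
#'   iteration) and `xi_trace` of length `K + 1` (`xi_trace[1]` is the
#'   initial threshold, `xi_trace[k + 1]` the value set after sweep `k`).
#' @export
run_crisp <- function(dataset, scan, object, probe, params, trace_rf = TRUE) {
  stopifnot(inherits(params, "crisp_params"))
  geom <- check_geometry(dataset, scan, object, probe)
  O <- object$values
  P <- probe$values
  K <- params$K
  auto_xi <- params$xi_mode == "auto"
  xi <- if (auto_xi)
    initialize_xi(dataset, scan, object, probe, params$c_tune)
  else params$xi_fixed
  perms <- make_permutations(geom$N, K, params$seed)
  rf <- rep(NA_real_, K)
  cost <- numeric(K)
  xi_trace <- numeric(K + 1)
  xi_trace[1] <- xi
  e <- numeric(geom$N)
  skipped <- 0L
  for (k in seq_len(K)) {
    for (n in perms[, k]) {
      sv <- view_at(O, P, dataset, scan, n, geom$window)
      psi <- sv$P_n * sv$O_n
      psi_prime <- revised_exit_wave(psi, sv$I_n)
      dir <- tryCatch(
        crisp_direction(sv$O_n, sv$P_n, psi_prime, xi,
                        nu_of(params$nu, 1, sv$P_n, sv$O_n),
                        nu_of(params$nu, 2, sv$P_n, sv$O_n),
                        force_cap = params$force_cap),
        ptycrisp_no_direction = function(cnd) NULL)
      if (is.null(dir)) {
        skipped <- skipped + 1L
        e[n] <- sample_cost(psi, psi_prime)
        next
      }
      e[n] <- dir$e
      O[sv$rows, sv$cols] <- sv$O_n + params$lambda_o * dir$D_o
      P <- fourier_shift(sv$P_n + params$lambda_p * dir$D_p, -scan$s_sub[n, ])
    }
    cost[k] <- mean(e)
    if (auto_xi) xi <- update_xi(e, params$c_tune)
    xi_trace[k + 1] <- xi
    if (trace_rf)
      rf[k] <- r_factor(dataset, object_field(O, object$pixel_pitch),
                        probe_field(P, probe$pixel_pitch), scan)
  }
  recon_result(object_field(O, object$pixel_pitch),
               probe_field(P, probe$pixel_pitch),
               rf = rf, cost = cost, variant = "crisp", params = params,
               xi_trace = xi_trace, skipped = skipped)
}

# Resolve the clipping parameter for one sample: side 1 = object update
# (co-factor P), side 2 = probe update (co-factor O).
nu_of <- function(nu, side, P_n, O_n) {
  if (is.numeric(nu)) return(nu[side])
  switch(nu,
    epie_like = 1,
    scale_adaptive = if (side == 1) max(Mod(P_n)) else max(Mod(O_n)))
}
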