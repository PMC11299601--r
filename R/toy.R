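#' A 2-D toy cost for studying subgradient projection
#'
#' Bundles a differentiable scalar cost `g` over 2-D points with its
#' analytic gradient, its minimum value `E`, and a start point. Used to
#' demonstrate the three regimes of iterative subgradient projection:
#' gradient-descent-like convergence when the minimum value and the
#' threshold are both zero, step-size blow-up when the minimum value is
#' positive but the threshold is zero, and termination inside the sublevel
#' set when the threshold exceeds the minimum value.
#'
#' @param g function of a numeric 2-vector returning a scalar >= `E`.
#' @param grad function returning the analytic gradient 2-vector.
#' @param E minimum value of `g` (>= 0).
#' @param start numeric 2-vector, initial point.
#' @return a list of class `toy_problem`.
#' @export
toy_problem <- function(g, grad, E, start) {
  stopifnot(is.function(g), is.function(grad), E >= 0,
            is.numeric(start), length(start) == 2)
  structure(list(g = g, grad = grad, E = E, start = start),
            class = "toy_problem")
}

#' Offset quadratic bowl `g(x) = ||x||^2 + E`
#'
#' The canonical toy cost: a single global minimizer at the origin with
#' minimum value `E` and gradient `2x`.
#'
#' @param E nonnegative offset (minimum value).
#' @param start initial point.
#' @return a `toy_problem`.
#' @export
quadratic_bowl <- function(E = 0, start = c(2, 1)) {
  toy_problem(g = function(x) sum(x^2) + E,
              grad = function(x) 2 * x,
              E = E, start = start)
}

#' Iterate subgradient projection on a toy cost
#'
#' Runs `x <- subgradient_step(x, grad(x), g(x), xi, lambda)` with an
#' optional cap on the scalar coefficient, recording the trajectory.
#' Iteration stops early when the threshold is met (`g(x) <= xi`, a fixed
#' point), when the gradient vanishes at positive thresholded cost (an
#' infinite implied step), or when the iterate norm exceeds
#' `divergence_bound` — the latter two set the `diverged` flag rather than
#' raising an error. For `g = ||x||^2 + E` with `E > 0` and `xi = 0` the
#' coefficient `(g - xi)/||grad||^2 = (||x||^2 + E)/(4||x||^2)` blows up
#' near the minimizer, producing unbounded excursions that trip the bound;
#' with `xi > E` the iteration instead settles in `{x : g(x) <= xi}`.
#'
#' @param problem a `toy_problem`.
#' @param xi threshold (>= 0).
#' @param lambda relaxation in `(0, 2)`.
#' @param K maximum iterations.
#' @param clip optional positive cap on the coefficient
#'   `lambda (g - xi)_+ / ||grad||^2` (mirrors CRISP's step clipping).
#' @param divergence_bound iterate norm beyond which the run is flagged
#'   as diverged.
#' @return list with `points` (matrix, one row per recorded iterate
#'   including the start), `g_values`, `diverged` (logical), and
#'   `stopped_inside` (`g(final) <= xi`).
#' @export
run_toy_subgradient <- function(problem, xi = 0, lambda = 1, K = 2000,
                                clip = NULL, divergence_bound = 1e3) {
  stopifnot(inherits(problem, "toy_problem"), xi >= 0,
            lambda > 0, lambda < 2, K >= 1, divergence_bound > 0)
  x <- problem$start
  pts <- matrix(NA_real_, nrow = K + 1, ncol = 2)
  gv <- numeric(K + 1)
  pts[1, ] <- x
  gv[1] <- problem$g(x)
  diverged <- FALSE
  last <- 1L
  for (k in seq_len(K)) {
    g_here <- problem$g(x)
    if (g_here <= xi) break  # fixed point of the projection
    grad <- problem$grad(x)
    ng2 <- sum(grad^2)
    if (ng2 == 0) { diverged <- TRUE; break }  # infinite implied step
    coef <- lambda * (g_here - xi) / ng2
    if (!is.null(clip)) coef <- min(coef, clip)
    x <- x - coef * grad
    last <- k + 1L
    pts[last, ] <- x
    gv[last] <- problem$g(x)
    if (!all(is.finite(x)) || sqrt(sum(x^2)) > divergence_bound) {
      diverged <- TRUE
      break
    }
  }
  list(points = pts[seq_len(last), , drop = FALSE],
       g_values = gv[seq_len(last)],
       diverged = diverged,
       stopped_inside = !diverged && gv[last] <= xi)
}
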