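# ODE integration of the cycle models, used to confirm the analytic steady
# states and the convergence-speed predictions. Integration uses lsoda
# (stiff-capable) at tight tolerances; outcomes are classified against a
# divergence cap and a flux-residual convergence threshold.

classify_trajectory <- function(times, states, rhs_fun, x_cap, v_scale,
                                conv_tol = 1e-10, zero_tol) {
  nmax <- apply(states, 1, max)
  over <- which(nmax > x_cap)
  if (length(over) > 0L) {
    cut <- over[1L]
    return(list(outcome = "diverged", times = times[seq_len(cut)],
                states = states[seq_len(cut), , drop = FALSE]))
  }
  final <- pmax(states[nrow(states), ], 0)
  rate <- max(abs(rhs_fun(final)))
  outcome <- if (rate < conv_tol * v_scale) {
    if (max(final) < zero_tol) "converged_zero" else "converged_positive"
  } else {
    "undecided"
  }
  list(outcome = outcome, times = times, states = states)
}

run_ode <- function(y0, t_max, deriv, rtol = 1e-9, atol = 1e-12, n_out = 200L) {
  t_lo <- t_max / 1e6
  times <- unique(c(0, exp(seq(log(t_lo), log(t_max), length.out = n_out))))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  list(times = sol[, 1L], states = as.matrix(sol[, -1L, drop = FALSE]))
}

finalize_trajectory <- function(res, spec) {
  st <- res$states
  if (min(st) < -1e-12) {
    warning("integrator produced concentrations below -1e-12; clipping",
            call. = FALSE)
  }
  st <- pmax(st, 0)
  structure(list(times = res$times, states = st, outcome = res$outcome,
                 final_state = st[nrow(st), ], spec = spec),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points to t = %g; outcome: %s; final = %s\n",
              length(x$times), max(x$times), x$outcome,
              paste(signif(x$final_state, 6), collapse = ", ")))
  invisible(x)
}

#' Simulate the single-intermediate cycle
#'
#' Integrates `dX/dt = delta*fa(X) + fi - fb(X)` from `X0` and classifies
#' the outcome: `diverged` once `X` exceeds `x_cap` (default `1e6` times
#' the larger Michaelis constant — both enzymes fully saturated with a
#' positive imbalance), `converged_zero`/`converged_positive` when the
#' residual rate falls below `1e-10` of the plateau scale, `undecided`
#' otherwise.
#'
#' @param spec A [simple_cycle_spec()].
#' @param X0 Initial concentration (non-negative).
#' @param t_max Integration horizon; default `1e3` characteristic times
#'   `KM,a/Vmax,a`.
#' @param x_cap Divergence cap.
#' @return A `"trajectory"` object (fields `times`, `states`, `outcome`,
#'   `final_state`).
#' @export
#' @examples
#' tr <- simulate_simple(simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4)), X0 = 0.5)
#' tr$outcome; tr$final_state  # converges to X* = 2
simulate_simple <- function(spec, X0, t_max = NULL,
                            x_cap = 1e6 * max(spec$fa$KM, spec$fb$KM)) {
  stopifnot(inherits(spec, "simple_cycle_spec"))
  if (!is.numeric(X0) || length(X0) != 1L || X0 < 0) {
    stop("X0 must be a non-negative number", call. = FALSE)
  }
  if (is.null(t_max)) t_max <- 1e3 * spec$fa$KM / spec$fa$Vmax
  deriv <- function(t, y, p) list(xdot(spec, max(y, 0)))
  res <- tryCatch(run_ode(c(X = X0), t_max, deriv),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) {
    return(structure(list(times = numeric(), states = matrix(numeric(), 0, 1),
                          outcome = "undecided", final_state = NA_real_,
                          spec = spec), class = "trajectory"))
  }
  v_scale <- spec$delta * spec$fa$Vmax + spec$fb$Vmax + spec$fi
  cls <- classify_trajectory(res$times, res$states,
                             function(x) xdot(spec, x), x_cap, v_scale,
                             zero_tol = 1e-8 * max(spec$fa$KM, spec$fb$KM))
  finalize_trajectory(cls, spec)
}

#' Simulate an n-reaction autocatalytic cycle
#'
#' Integrates the chain `dX1/dt = (1+delta)*fa_n - fa_1 - fb_1`,
#' `dXi/dt = fa_{i-1} - fa_i - fb_i` and classifies the outcome as in
#' [simulate_simple()].
#'
#' @param spec A [multi_cycle_spec()].
#' @param X0 Initial concentrations (length n, non-negative).
#' @param t_max Integration horizon; default `1e3` characteristic times of
#'   the first cycle reaction.
#' @param x_cap Divergence cap (default `1e6` times the largest `KM`).
#' @return A `"trajectory"` object.
#' @export
simulate_multi <- function(spec, X0, t_max = NULL, x_cap = NULL) {
  stopifnot(inherits(spec, "multi_cycle_spec"))
  X0 <- as.numeric(X0)
  if (length(X0) != spec$n || any(X0 < 0)) {
    stop("X0 must be non-negative of length n", call. = FALSE)
  }
  kms <- c(vapply(spec$cycle_kinetics, `[[`, numeric(1), "KM"),
           vapply(Filter(Negate(is.null), spec$branch_kinetics), `[[`,
                  numeric(1), "KM"))
  if (is.null(x_cap)) x_cap <- 1e6 * max(kms)
  if (is.null(t_max)) {
    t_max <- 1e3 * spec$cycle_kinetics[[1L]]$KM / spec$cycle_kinetics[[1L]]$Vmax
  }
  deriv <- function(t, y, p) list(cycle_rhs(spec, y))
  y0 <- stats::setNames(X0, paste0("X", seq_len(spec$n)))
  res <- tryCatch(run_ode(y0, t_max, deriv),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) {
    return(structure(list(times = numeric(),
                          states = matrix(numeric(), 0, spec$n),
                          outcome = "undecided",
                          final_state = rep(NA_real_, spec$n), spec = spec),
                     class = "trajectory"))
  }
  v_scale <- max(vapply(spec$cycle_kinetics, `[[`, numeric(1), "Vmax"))
  cls <- classify_trajectory(res$times, res$states,
                             function(x) cycle_rhs(spec, x), x_cap, v_scale,
                             zero_tol = 1e-8 * max(kms))
  finalize_trajectory(cls, spec)
}

#' Time to converge within a fraction of the initial deviation
#'
#' First time at which the sup-norm deviation from the final (steady) state
#' drops below `fraction` times the initial deviation and stays below for
#' the rest of the trajectory.
#'
#' @param traj A converged `"trajectory"`.
#' @param fraction Target fraction of the initial deviation (e.g. 0.01).
#' @return Time (same units as the trajectory).
#' @export
convergence_time <- function(traj, fraction) {
  stopifnot(inherits(traj, "trajectory"))
  if (!(traj$outcome %in% c("converged_positive", "converged_zero"))) {
    stop("convergence_time() requires a converged trajectory", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0) {
    stop("fraction must be positive", call. = FALSE)
  }
  dev <- apply(traj$states, 1, function(x) max(abs(x - traj$final_state)))
  d0 <- dev[1L]
  if (d0 == 0 || fraction >= 1) return(0)
  below <- dev < fraction * d0
  # last index still at/above threshold; stay-below from the next point on
  idx <- which(!below)
  if (length(idx) == 0L) return(traj$times[1L])
  last_above <- max(idx)
  if (last_above == length(dev)) {
    stop("trajectory never stays below the requested fraction", call. = FALSE)
  }
  traj$times[last_above + 1L]
}
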