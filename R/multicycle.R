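# Stability of n-reaction autocatalytic cycles. The cycle is a chain
# X1 -> X2 -> ... -> Xn with per-position branch reactions fbi, closed by
# the assimilating reaction fan which returns (1+delta) units of X1 per
# unit of Xn consumed. Linearization at a steady state is captured by the
# derivative pairs alpha_i = dfa_i/dX_i and beta_i = dfb_i/dX_i.

#' Linearization of an n-reaction autocatalytic cycle
#'
#' @param alphas Positive derivatives of the cycle reactions at the steady
#'   state, position by position.
#' @param betas Non-negative derivatives of the branch reactions (0 where a
#'   position has no branch).
#' @param factor Autocatalytic factor `1 + delta` applied to the closing
#'   reaction, in `(1, 2]` (the analysis covers ratios up to 1:2).
#' @return An object of class `"cycle_linearization"`.
#' @export
cycle_linearization <- function(alphas, betas, factor = 2) {
  alphas <- as.numeric(alphas)
  betas <- as.numeric(betas)
  if (length(alphas) < 1L || length(betas) != length(alphas)) {
    stop("alphas and betas must have equal positive length", call. = FALSE)
  }
  if (any(!is.finite(alphas)) || any(alphas <= 0)) {
    stop("all alphas must be positive", call. = FALSE)
  }
  if (any(!is.finite(betas)) || any(betas < 0)) {
    stop("all betas must be non-negative", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1 || factor > 2) {
    stop("factor must lie in (1, 2]: the analysis is valid up to 1:2 autocatalysis",
         call. = FALSE)
  }
  structure(list(alphas = alphas, betas = betas, factor = factor,
                 n = length(alphas)),
            class = "cycle_linearization")
}

#' Jacobian of an n-reaction autocatalytic cycle at steady state
#'
#' Builds the cyclic bidiagonal Jacobian: diagonal `-(alpha_i + beta_i)`,
#' subdiagonal `alpha_i` (flux handed to the next intermediate), and corner
#' `factor * alpha_n` (the closing reaction amplifies what it passes on by
#' the autocatalytic factor). For `n = 1` the three entries coincide in the
#' scalar `(factor - 1)*alpha_1 - beta_1`, the derivative criterion of the
#' single-intermediate model.
#'
#' @param lin A [cycle_linearization()].
#' @return An `n x n` numeric matrix.
#' @export
#' @examples
#' build_jacobian(cycle_linearization(c(1, 1), c(0, 2)))
build_jacobian <- function(lin) {
  stopifnot(inherits(lin, "cycle_linearization"))
  n <- lin$n
  if (n == 1L) {
    return(matrix((lin$factor - 1) * lin$alphas[1] - lin$betas[1], 1, 1))
  }
  J <- diag(-(lin$alphas + lin$betas))
  for (i in seq_len(n - 1L)) J[i + 1L, i] <- lin$alphas[i]
  J[1L, n] <- lin$factor * lin$alphas[n]
  J
}

#' Eigenvalue stability test
#'
#' @param J Square Jacobian matrix.
#' @param tol Margin below zero required of the largest eigenvalue real
#'   part; real parts within `[-tol, tol]` give `"marginal"`.
#' @return `TRUE` (stable), `FALSE` (unstable), or the string `"marginal"`.
#' @export
eigen_stability <- function(J, tol = 1e-10) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  mx <- max(Re(eigen(J, only.values = TRUE)$values))
  if (mx < -tol) TRUE else if (mx > tol) FALSE else "marginal"
}

#' Sufficient stability condition for an n-reaction cycle
#'
#' A steady state of the cycle is stable if at any position the branch
#' derivative exceeds the cycle derivative (`beta_i > alpha_i`). The
#' associated product criterion `prod(1 + beta_i/alpha_i) > factor` is the
#' boundary quantity: the characteristic polynomial
#' `prod(lambda + alpha_i + beta_i) = factor * prod(alpha_i)` has a zero
#' root exactly when the product equals `factor`.
#'
#' @param lin A [cycle_linearization()].
#' @return A list with `sufficient` (does some `beta_i > alpha_i` hold),
#'   `product` (`prod(1 + beta_i/alpha_i)`), `threshold` (`factor`) and
#'   `product_exceeds` (`product > threshold`).
#' @export
sufficient_stability <- function(lin) {
  stopifnot(inherits(lin, "cycle_linearization"))
  prod_val <- prod(1 + lin$betas / lin$alphas)
  list(sufficient = any(lin$betas > lin$alphas),
       product = prod_val,
       threshold = lin$factor,
       product_exceeds = prod_val > lin$factor)
}

#' First-order response of the cycle to a localized perturbation
#'
#' Returns `J %*% delta` for a deviation `dXj` at position `j`: the
#' perturbed position self-damps at rate `-(alpha_j + beta_j)*dXj` and
#' hands `alpha_j*dXj` to its successor — amplified to
#' `factor*alpha_n*dXj` when the perturbed position feeds the closing,
#' assimilating reaction. Larger branch derivatives therefore both damp
#' the perturbation faster and shrink what propagates around the cycle.
#'
#' @param lin A [cycle_linearization()].
#' @param j Perturbed position (1..n).
#' @param dXj Size of the deviation.
#' @return Numeric vector of length n: instantaneous rate of change of each
#'   intermediate.
#' @export
perturbation_response <- function(lin, j, dXj) {
  stopifnot(inherits(lin, "cycle_linearization"))
  if (j < 1L || j > lin$n) stop("j out of range", call. = FALSE)
  delta <- numeric(lin$n)
  delta[j] <- dXj
  drop(build_jacobian(lin) %*% delta)
}

# ---- kinetic cycle specifications --------------------------------------

#' Kinetic specification of an n-reaction autocatalytic cycle
#'
#' @param cycle_kinetics List of n [mm_kinetics()] for the cycle reactions
#'   `fa_1..fa_n` (`fa_i` consumes `X_i`; `fa_n` is the closing,
#'   assimilating reaction returning `1 + delta` units of `X_1`).
#' @param branch_kinetics List of n entries, each an [mm_kinetics()] or
#'   `NULL` for a position without a branch; at least one branch must be
#'   present (something must drain the autocatalytic gain).
#' @param delta Autocatalytic gain per unit consumed, in `(0, 1]`.
#' @return An object of class `"multi_cycle_spec"`.
#' @export
multi_cycle_spec <- function(cycle_kinetics, branch_kinetics, delta = 1) {
  stopifnot(is.list(cycle_kinetics), is.list(branch_kinetics))
  n <- length(cycle_kinetics)
  if (n < 1L || length(branch_kinetics) != n) {
    stop("cycle_kinetics and branch_kinetics must have equal positive length",
         call. = FALSE)
  }
  for (k in cycle_kinetics) {
    if (!inherits(k, "mm_kinetics")) stop("cycle_kinetics must be mm_kinetics", call. = FALSE)
  }
  has_branch <- !vapply(branch_kinetics, is.null, logical(1))
  for (k in branch_kinetics[has_branch]) {
    if (!inherits(k, "mm_kinetics")) {
      stop("branch_kinetics entries must be mm_kinetics or NULL", call. = FALSE)
    }
  }
  if (!any(has_branch)) stop("at least one branch reaction is required", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]: the analysis is valid up to 1:2 autocatalysis",
         call. = FALSE)
  }
  structure(list(cycle_kinetics = cycle_kinetics,
                 branch_kinetics = branch_kinetics,
                 delta = delta, n = n),
            class = "multi_cycle_spec")
}

cycle_fluxes <- function(spec, X) {
  fa <- vapply(seq_len(spec$n), function(i) mm_flux(spec$cycle_kinetics[[i]], X[i]),
               numeric(1))
  fb <- vapply(seq_len(spec$n), function(i) {
    k <- spec$branch_kinetics[[i]]
    if (is.null(k)) 0 else mm_flux(k, X[i])
  }, numeric(1))
  list(fa = fa, fb = fb)
}

cycle_rhs <- function(spec, X) {
  fl <- cycle_fluxes(spec, pmax(X, 0))
  n <- spec$n
  inflow <- c((1 + spec$delta) * fl$fa[n], fl$fa[-n])
  inflow - fl$fa - fl$fb
}

#' Linearize a kinetic cycle at a steady state
#'
#' Evaluates the analytic Michaelis-Menten derivatives
#' `alpha_i = dfa_i/dX_i` and `beta_i = dfb_i/dX_i` at the supplied
#' concentrations.
#'
#' @param spec A [multi_cycle_spec()].
#' @param Xstars Steady-state concentrations (length n).
#' @return A [cycle_linearization()] with `factor = 1 + delta`.
#' @export
linearize_cycle <- function(spec, Xstars) {
  stopifnot(inherits(spec, "multi_cycle_spec"), length(Xstars) == spec$n)
  alphas <- vapply(seq_len(spec$n), function(i) {
    mm_derivative(spec$cycle_kinetics[[i]], Xstars[i])
  }, numeric(1))
  betas <- vapply(seq_len(spec$n), function(i) {
    k <- spec$branch_kinetics[[i]]
    if (is.null(k)) 0 else mm_derivative(k, Xstars[i])
  }, numeric(1))
  cycle_linearization(alphas, betas, factor = 1 + spec$delta)
}

#' Solve for a steady state of a kinetic cycle
#'
#' Damped Newton iteration on the cycle balance equations using the
#' analytic Jacobian, falling back on halved steps when the residual does
#' not improve. Intended for positive steady states; start it away from
#' zero.
#'
#' @param spec A [multi_cycle_spec()].
#' @param X0 Starting concentrations (default all 1).
#' @param tol Residual tolerance relative to the largest plateau rate.
#' @param max_iter Iteration cap.
#' @return List with `Xstar`, `converged`, `residual`.
#' @export
solve_cycle_steady_state <- function(spec, X0 = rep(1, spec$n), tol = 1e-12,
                                     max_iter = 200L) {
  stopifnot(inherits(spec, "multi_cycle_spec"))
  vscale <- max(vapply(spec$cycle_kinetics, `[[`, numeric(1), "Vmax"))
  X <- pmax(as.numeric(X0), 1e-12)
  f <- cycle_rhs(spec, X)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol * vscale) break
    J <- build_jacobian(linearize_cycle(spec, X))
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      Xn <- pmax(X + lambda * step, 1e-15)
      fn <- cycle_rhs(spec, Xn)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    X <- Xn
    f <- fn
  }
  list(Xstar = X, converged = max(abs(f)) < tol * vscale, residual = max(abs(f)))
}

#' Check the steady-state flux ordering of a cycle
#'
#' At a steady state of the chain the fluxes are ordered
#' `fb_i <= fa_n <= fa_i` for every position, and the total branch outflow
#' balances the autocatalytic gain, `sum(fb_i) = delta * fa_n`. Verifies the
#' supplied concentrations are a steady state (by substitution) and reports
#' the per-position slack in each inequality.
#'
#' @param spec A [multi_cycle_spec()].
#' @param Xstars Candidate steady-state concentrations.
#' @param tol Relative residual tolerance for accepting `Xstars`.
#' @return A list with `is_steady_state`, `ordering_ok`, `balance_ok`,
#'   `fa`, `fb`, and slack vectors `slack_lower` (`fa_n - fb_i`) and
#'   `slack_upper` (`fa_i - fa_n`).
#' @export
flux_ordering_check <- function(spec, Xstars, tol = 1e-8) {
  stopifnot(inherits(spec, "multi_cycle_spec"), length(Xstars) == spec$n)
  vscale <- max(vapply(spec$cycle_kinetics, `[[`, numeric(1), "Vmax"))
  resid <- max(abs(cycle_rhs(spec, Xstars)))
  if (resid > tol * vscale) {
    return(list(is_steady_state = FALSE, residual = resid,
                ordering_ok = NA, balance_ok = NA))
  }
  fl <- cycle_fluxes(spec, Xstars)
  fan <- fl$fa[spec$n]
  slack_lower <- fan - fl$fb
  slack_upper <- fl$fa - fan
  list(is_steady_state = TRUE, residual = resid,
       ordering_ok = all(slack_lower >= -tol * vscale) &&
         all(slack_upper >= -tol * vscale),
       balance_ok = abs(sum(fl$fb) - spec$delta * fan) <= tol * vscale,
       fa = fl$fa, fb = fl$fb,
       slack_lower = slack_lower, slack_upper = slack_upper)
}

#' Construct a kinetic cycle with a prescribed steady state
#'
#' Design helper inverting the steady-state conditions: given target
#' concentrations and a consistent set of fluxes (satisfying the chain
#' balance `fa_{i-1} = fa_i + fb_i` and `(1+delta)*fa_n = fa_1 + fb_1`),
#' picks `Vmax` values so each Michaelis-Menten reaction carries its target
#' flux at its target concentration with the requested `KM`.
#'
#' @param Xstars Target steady-state concentrations (length n).
#' @param fa_fluxes Target cycle fluxes (length n, consistent with the
#'   balance; checked).
#' @param KM_cycle,KM_branch `KM` values (length n; `KM_branch` entries
#'   `NA` where a position has no branch).
#' @param delta Autocatalytic gain in `(0, 1]`.
#' @return A [multi_cycle_spec()] whose steady state is `Xstars`.
#' @export
design_cycle <- function(Xstars, fa_fluxes, KM_cycle, KM_branch, delta = 1) {
  n <- length(Xstars)
  stopifnot(length(fa_fluxes) == n, length(KM_cycle) == n, length(KM_branch) == n)
  inflow <- c((1 + delta) * fa_fluxes[n], fa_fluxes[-n])
  fb_fluxes <- inflow - fa_fluxes
  if (any(fb_fluxes < -1e-12)) {
    stop("inconsistent fluxes: implied branch flux negative", call. = FALSE)
  }
  if (any(fb_fluxes > 1e-12 & is.na(KM_branch))) {
    stop("position carries branch flux but KM_branch is NA", call. = FALSE)
  }
  mk <- function(flux, KM, X) mm_kinetics(flux * (KM + X) / X, KM)
  cyc <- lapply(seq_len(n), function(i) mk(fa_fluxes[i], KM_cycle[i], Xstars[i]))
  br <- lapply(seq_len(n), function(i) {
    if (fb_fluxes[i] <= 1e-12) NULL else mk(fb_fluxes[i], KM_branch[i], Xstars[i])
  })
  multi_cycle_spec(cyc, br, delta = delta)
}
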