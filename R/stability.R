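# Analytic steady-state existence and stability for the single-intermediate
# autocatalytic cycle: an autocatalytic reaction fa turning one unit of the
# intermediate X (plus an assimilated external metabolite at constant
# concentration) into 1 + delta units, balanced by a branch reaction fb
# consuming X out of the cycle, optionally with a constant input flux fi.

#' Specification of the single-intermediate autocatalytic cycle
#'
#' @param fa [mm_kinetics()] of the autocatalytic reaction (per unit of X
#'   consumed it returns `1 + delta` units).
#' @param fb [mm_kinetics()] of the branch reaction.
#' @param delta Net gain per unit of X consumed by `fa` (default 1, the 1:2
#'   stoichiometry; the carbon-fixation lump has `delta = 1/5`).
#' @param fi Constant input flux into X from outside the cycle (default 0).
#' @return An object of class `"simple_cycle_spec"`.
#' @export
#' @examples
#' simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4))
simple_cycle_spec <- function(fa, fb, delta = 1, fi = 0) {
  stopifnot(inherits(fa, "mm_kinetics"), inherits(fb, "mm_kinetics"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop("delta must be a positive number", call. = FALSE)
  }
  if (!is.numeric(fi) || length(fi) != 1L || !is.finite(fi) || fi < 0) {
    stop("fi must be a non-negative number", call. = FALSE)
  }
  structure(list(fa = fa, fb = fb, delta = delta, fi = fi),
            class = "simple_cycle_spec")
}

# production rate of X and its derivative
xdot <- function(spec, X) {
  spec$fi + spec$delta * mm_flux(spec$fa, X) - mm_flux(spec$fb, X)
}
xdot_prime <- function(spec, X) {
  spec$delta * mm_derivative(spec$fa, X) - mm_derivative(spec$fb, X)
}

new_report <- function(states, zero_state, domain, spec, divergent = FALSE) {
  structure(list(states = states, zero_state = zero_state, domain = domain,
                 divergent = divergent, spec = spec),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat(sprintf("<steady_state_report> domain %s\n", x$domain))
  if (!is.null(x$zero_state) && x$zero_state$exists) {
    cat(sprintf("  X* = 0: %s\n", if (x$zero_state$stable) "stable" else "unstable"))
  }
  if (nrow(x$states) == 0L) {
    cat("  no positive steady state\n")
  } else {
    for (i in seq_len(nrow(x$states))) {
      cat(sprintf("  X* = %g: %s, f* = %g\n", x$states$Xstar[i],
                  if (x$states$stable[i]) "stable" else "unstable",
                  x$states$fstar[i]))
    }
  }
  if (isTRUE(x$divergent)) cat("  divergent: branch cannot absorb the input\n")
  invisible(x)
}

#' Classify the kinetic-parameter domain of a simple cycle
#'
#' The four-domain phase diagram of the closed cycle (`fi = 0`), determined
#' by two independent inequalities (with `Vmax,a` pre-scaled by `delta`):
#' whether the branch plateau exceeds the autocatalytic plateau
#' (`Vmax,b > delta*Vmax,a`, guaranteeing large concentrations are pulled
#' back down) and whether the branch is steeper at the origin
#' (`Vmax,b/KM,b > delta*Vmax,a/KM,a`, making the empty state stable):
#' \describe{
#'   \item{I}{plateau condition holds, slope condition fails: a positive
#'     stable steady state exists and zero is unstable.}
#'   \item{II}{both hold: no positive state; zero is the global attractor.}
#'   \item{III}{plateau fails, slope holds: a positive unstable threshold
#'     state; zero stable below it, divergence above.}
#'   \item{IV}{both fail: no positive state and zero unstable; divergence.}
#' }
#'
#' @param spec A [simple_cycle_spec()] with `fi = 0`.
#' @param tol Relative tolerance below which an inequality margin is called
#'   degenerate (default 1e-12).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"degenerate"`.
#' @export
classify_domain <- function(spec, tol = 1e-12) {
  stopifnot(inherits(spec, "simple_cycle_spec"))
  if (spec$fi != 0) stop("domain classification is defined for fi = 0", call. = FALSE)
  Va <- spec$delta * spec$fa$Vmax
  Vb <- spec$fb$Vmax
  sa <- Va / spec$fa$KM
  sb <- Vb / spec$fb$KM
  m1 <- Vb - Va         # branch plateau margin
  m2 <- sb - sa         # zero-state stability margin
  if (abs(m1) <= tol * max(Vb, Va) || abs(m2) <= tol * max(sb, sa)) {
    return("degenerate")
  }
  if (m1 > 0 && m2 < 0) "I"
  else if (m1 > 0 && m2 > 0) "II"
  else if (m1 < 0 && m2 > 0) "III"
  else "IV"
}

#' Steady states of the closed simple cycle
#'
#' Solves `delta*fa(X) = fb(X)` analytically. Besides the ever-present empty
#' state, the unique candidate positive state is
#' `X* = (Vmax,b*KM,a - delta*Vmax,a*KM,b) / (delta*Vmax,a - Vmax,b)`,
#' included when positive; stability of each state follows the sign of
#' `d(delta*fa - fb)/dX` there, and the empty state is stable iff the branch
#' slope at the origin exceeds the autocatalytic slope
#' (`Vmax,b/KM,b > delta*Vmax,a/KM,a`).
#'
#' @param spec A [simple_cycle_spec()] with `fi = 0`.
#' @param tol Degeneracy tolerance forwarded to [classify_domain()].
#' @return A `"steady_state_report"`: `states` (data frame of `Xstar`,
#'   `stable`, `fstar`), `zero_state`, `domain`.
#' @export
#' @examples
#' steady_state_simple(simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4)))
steady_state_simple <- function(spec, tol = 1e-12) {
  stopifnot(inherits(spec, "simple_cycle_spec"))
  if (spec$fi != 0) stop("use steady_states_with_input() when fi > 0", call. = FALSE)
  Va <- spec$delta * spec$fa$Vmax
  Ka <- spec$fa$KM
  Vb <- spec$fb$Vmax
  Kb <- spec$fb$KM
  domain <- classify_domain(spec, tol = tol)
  zero <- list(exists = TRUE, stable = Vb / Kb > Va / Ka)
  states <- data.frame(Xstar = numeric(), stable = logical(), fstar = numeric())
  if (domain != "degenerate") {
    Xs <- (Vb * Ka - Va * Kb) / (Va - Vb)
    if (is.finite(Xs) && Xs > 0) {
      states <- data.frame(Xstar = Xs,
                           stable = xdot_prime(spec, Xs) < 0,
                           fstar = mm_flux(spec$fb, Xs))
    }
  }
  new_report(states, zero, domain, spec)
}

#' Steady states of a simple cycle with constant input flux
#'
#' Solves `fi + delta*fa(X) = fb(X)`, a quadratic in `X` for
#' Michaelis-Menten forms. With `fi > 0` the empty state disappears. If the
#' branch plateau exceeds `fi + delta*Vmax,a` exactly one positive state
#' exists and it is stable; otherwise either two positive states exist (the
#' lower one stable, the upper a threshold) or none, in which case the
#' concentration grows without bound (`divergent`).
#'
#' @param spec A [simple_cycle_spec()] with `fi > 0`.
#' @return A `"steady_state_report"` with `zero_state$exists = FALSE` and
#'   `domain` one of `"input_I"` (single stable state), `"input_II"` (two
#'   states) or `"input_III"` (none, divergent).
#' @export
steady_states_with_input <- function(spec) {
  stopifnot(inherits(spec, "simple_cycle_spec"))
  if (spec$fi <= 0) stop("steady_states_with_input() requires fi > 0", call. = FALSE)
  Va <- spec$delta * spec$fa$Vmax
  Ka <- spec$fa$KM
  Vb <- spec$fb$Vmax
  Kb <- spec$fb$KM
  fi <- spec$fi
  # fi*(Ka+X)(Kb+X) + Va*X*(Kb+X) - Vb*X*(Ka+X) = 0
  a <- fi + Va - Vb
  b <- fi * (Ka + Kb) + Va * Kb - Vb * Ka
  cc <- fi * Ka * Kb
  roots <- if (abs(a) < 1e-14 * max(fi, Va, Vb)) {
    if (b == 0) numeric() else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric()
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- sort(roots[is.finite(roots) & roots > 0])
  states <- data.frame(Xstar = roots,
                       stable = vapply(roots, function(x) xdot_prime(spec, x) < 0,
                                       logical(1)),
                       fstar = vapply(roots, function(x) mm_flux(spec$fb, x),
                                      numeric(1)))
  domain <- if (Vb > fi + Va) "input_I" else if (nrow(states) > 0) "input_II" else "input_III"
  new_report(states, list(exists = FALSE, stable = NA), domain, spec,
             divergent = nrow(states) == 0L)
}

#' Sensitivity of the steady-state concentration to kinetic parameters
#'
#' Closed-form derivatives of `X*` with respect to the four kinetic
#' parameters, valid in domain I (with `Vmax,a` scaled by `delta`):
#' `dX*/dKM,a = Vb/(Va - Vb) < 0`, `dX*/dKM,b = -Va/(Va - Vb) > 0`,
#' `dX*/dVmax,a = delta*Vb*(KM,b - KM,a)/(Va - Vb)^2 > 0`,
#' `dX*/dVmax,b = Va*(KM,a - KM,b)/(Va - Vb)^2 < 0`. Activating the
#' autocatalytic reaction raises the steady state; activating the branch
#' lowers it.
#'
#' @param spec A [simple_cycle_spec()] in domain I.
#' @return Data frame with columns `parameter`, `derivative`, `sign`.
#' @export
sensitivity_signs <- function(spec) {
  stopifnot(inherits(spec, "simple_cycle_spec"))
  if (classify_domain(spec) != "I") {
    stop("sensitivity formulas assume domain I (stable positive state)", call. = FALSE)
  }
  Va <- spec$delta * spec$fa$Vmax
  Vb <- spec$fb$Vmax
  Ka <- spec$fa$KM
  Kb <- spec$fb$KM
  d <- c(KM_a = Vb / (Va - Vb),
         KM_b = -Va / (Va - Vb),
         Vmax_a = spec$delta * Vb * (Kb - Ka) / (Va - Vb)^2,
         Vmax_b = Va * (Ka - Kb) / (Va - Vb)^2)
  data.frame(parameter = names(d), derivative = unname(d),
             sign = ifelse(d > 0, "+", "-"))
}

# ---- bisubstrate autocatalytic reaction --------------------------------

#' Stability constraints for a bisubstrate autocatalytic reaction
#'
#' Maps the two simple-cycle conditions (branch plateau above the
#' autocatalytic plateau; branch origin-slope below the autocatalytic
#' origin-slope) through the apparent constants of each bisubstrate
#' mechanism, yielding scheme-specific bounds:
#' \describe{
#'   \item{ping_pong}{No bound on `A` (the origin-slope ratio is
#'     `Vmax/KX` independent of `A`); conditions are
#'     `Vmax,b > Vmax*A/(KA+A)` and `Vmax,b/KM,b < Vmax/KX`, i.e.
#'     `KM,b > KX*Vmax,b/Vmax`.}
#'   \item{random_order}{`A > KiA / (KM,b*Vmax/(Vmax,b*KX) - 1)` and
#'     `KM,b > KX / max(1, KA/KiA)`.}
#'   \item{ordered_A_first}{Same `A` bound; absolute affinity bound
#'     `KM,b > KX`; additionally `Vmax,b > Vmax` outright (the apparent
#'     plateau does not shrink with `A`).}
#'   \item{ordered_X_first}{`A > Vmax,b*KiX*KA/(KM,b*Vmax)`; no bound on
#'     `KM,b` (the most robust scheme).}
#' }
#' When the `A`-bound denominator is non-positive the slope condition is
#' unsatisfiable at any finite `A` and `satisfiable` is `FALSE`.
#'
#' @param b A [bisubstrate_kinetics()] bundle (autocatalytic reaction).
#' @param branch An [mm_kinetics()] bundle (branch reaction).
#' @return A list with `scheme`, `A_lower`, `A_upper` (above which the
#'   branch plateau is exceeded and `X*` runs to infinity; `Inf` when never),
#'   `KMb_lower` (`NA` when no bound exists), `satisfiable`, `conditions`
#'   (human-readable inequality strings).
#' @export
bisubstrate_stable_region <- function(b, branch) {
  stopifnot(inherits(b, "bisubstrate_kinetics"), inherits(branch, "mm_kinetics"))
  V <- b$Vmax; KA <- b$KA; KX <- b$KX
  Vb <- branch$Vmax; Kb <- branch$KM
  A_upper <- if (b$scheme == "ordered_A_first") {
    if (Vb > V) Inf else 0   # plateau condition independent of A
  } else {
    if (V > Vb) Vb * KA / (V - Vb) else Inf
  }
  res <- switch(b$scheme,
    ping_pong = {
      list(A_lower = 0,
           KMb_lower = KX * Vb / V,
           satisfiable = Kb > KX * Vb / V,
           conditions = c("Vmax,b > Vmax*A/(KA+A)",
                          "Vmax,b/KM,b < Vmax/KX"))
    },
    random_order = {
      den <- Kb * V / (Vb * KX) - 1
      list(A_lower = if (den > 0) b$KiA / den else Inf,
           KMb_lower = KX / max(1, KA / b$KiA),
           satisfiable = den > 0,
           conditions = c("A > KiA/(KM,b*Vmax/(Vmax,b*KX) - 1)",
                          "KM,b > KX/max(1, KA/KiA)"))
    },
    ordered_A_first = {
      den <- Kb * V / (Vb * KX) - 1
      list(A_lower = if (den > 0) b$KiA / den else Inf,
           KMb_lower = KX,
           satisfiable = den > 0 && Vb > V,
           conditions = c("Vmax,b > Vmax",
                          "A > KiA/(KM,b*Vmax/(Vmax,b*KX) - 1)",
                          "KM,b > KX"))
    },
    ordered_X_first = {
      list(A_lower = Vb * b$KiX * KA / (Kb * V),
           KMb_lower = NA_real_,
           satisfiable = TRUE,
           conditions = c("A > Vmax,b*KiX*KA/(KM,b*Vmax)",
                          "Vmax,b > Vmax*A/(KA+A)"))
    })
  c(list(scheme = b$scheme), res, list(A_upper = A_upper))
}

#' Steady-state concentration as a function of the assimilated metabolite
#'
#' Scheme-specific closed form for `X*(A)` of the cycle formed by a
#' bisubstrate autocatalytic reaction (at constant assimilated concentration
#' `A`) and a Michaelis-Menten branch; identical to composing
#' [apparent_constants()] with [steady_state_simple()]. `X*` vanishes as `A`
#' approaches the scheme's lower bound and diverges at the upper bound where
#' the apparent autocatalytic plateau reaches the branch plateau.
#'
#' @param b A [bisubstrate_kinetics()] bundle.
#' @param branch An [mm_kinetics()] bundle.
#' @param A Assimilated-metabolite concentration; must be at or above the
#'   scheme's lower bound (at the bound `X* = 0`, below it an error).
#' @return The positive steady-state concentration (0 exactly at the bound).
#' @export
xstar_vs_A <- function(b, branch, A) {
  stopifnot(inherits(b, "bisubstrate_kinetics"), inherits(branch, "mm_kinetics"))
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("A must be a positive finite number", call. = FALSE)
  }
  reg <- bisubstrate_stable_region(b, branch)
  tol <- 1e-12 * max(1, reg$A_lower)
  if (is.finite(reg$A_lower) && A < reg$A_lower - tol) {
    stop(sprintf("A = %g is below the scheme's lower bound %g", A, reg$A_lower),
         call. = FALSE)
  }
  if (is.finite(reg$A_lower) && abs(A - reg$A_lower) <= tol) return(0)
  if (is.finite(reg$A_upper) && A >= reg$A_upper) {
    # apparent autocatalytic plateau reaches the branch plateau: no finite state
    return(Inf)
  }
  V <- b$Vmax; KA <- b$KA; KX <- b$KX
  Vb <- branch$Vmax; Kb <- branch$KM
  switch(b$scheme,
    ping_pong = A * (Vb * KX - V * Kb) / (V * A - Vb * (KA + A)),
    random_order = (Vb * KX * (b$KiA + A) - V * A * Kb) / (V * A - Vb * (KA + A)),
    ordered_A_first = (Vb * KX * (b$KiA + A) - V * A * Kb) / (A * (V - Vb)),
    ordered_X_first = (Vb * b$KiX * KA - V * A * Kb) / (V * A - Vb * (KA + A)))
}

# ---- reversible branch reaction ----------------------------------------

#' Specification of a cycle with a reversible branch reaction
#'
#' The branch reaction `fb` is reversible with product `Y`
#' (`fb = Vmax,b*(X - Y) / (KX + X + KX*Y/KY)` with the equilibrium constant
#' normalized to 1 by measuring `Y` in units of `Keq*X`), and a downstream
#' reaction `fc = D*Y` consumes `Y` irreversibly at first-order rate `D`.
#'
#' @param fa [mm_kinetics()] of the autocatalytic reaction (1:2
#'   stoichiometry).
#' @param Vmax_b,KX,KY Reversible branch parameters.
#' @param D First-order consumption rate of `Y` (1/time).
#' @return An object of class `"reversible_branch_spec"`.
#' @export
reversible_branch_spec <- function(fa, Vmax_b, KX, KY, D) {
  stopifnot(inherits(fa, "mm_kinetics"))
  for (nm in c("Vmax_b", "KX", "KY", "D")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a positive finite number", nm), call. = FALSE)
    }
  }
  structure(list(fa = fa, Vmax_b = Vmax_b, KX = KX, KY = KY, D = D),
            class = "reversible_branch_spec")
}

reversible_fb <- function(spec, X, Y) {
  spec$Vmax_b * (X - Y) / (spec$KX + X + spec$KX * Y / spec$KY)
}

reversible_jacobian <- function(spec, X, Y) {
  Va <- spec$fa$Vmax; Ka <- spec$fa$KM
  Vb <- spec$Vmax_b; KX <- spec$KX; KY <- spec$KY; D <- spec$D
  den <- (KX + X + KX * Y / KY)^2
  alpha <- Va * Ka / (Ka + X)^2
  beta_x <- Vb * (KX + Y * (1 + KX / KY)) / den
  beta_y <- -Vb * (KX + X * (1 + KX / KY)) / den
  list(alpha = alpha, beta_x = beta_x, beta_y = beta_y,
       J = matrix(c(alpha - beta_x, beta_x, -beta_y, beta_y - D), nrow = 2,
                  dimnames = list(c("X", "Y"), c("X", "Y"))))
}

#' Steady states of the cycle with a reversible branch
#'
#' Solves the quadratic for the positive steady state(s) of
#' `Xdot = fa - fb`, `Ydot = fb - D*Y`, evaluates
#' `Y* = (Vmax,a/D) * X*/(KM,a + X*)`, and decides stability from the 2x2
#' Jacobian trace/determinant conditions (`b = beta_x - alpha - beta_y + D
#' > 0` and `c = beta_x*D + alpha*beta_y - alpha*D > 0`). The regime label
#' distinguishes fast removal of `Y` (`D > Vmax,a/KM,a`, irreversible-like)
#' from slow removal.
#'
#' @param spec A [reversible_branch_spec()].
#' @return A `"steady_state_report"` whose `states` gains columns `Ystar`,
#'   plus fields `regime` and `globally_stable_possible` (`FALSE` when
#'   `Vmax,b <= Vmax,a`, in which case large `X` always diverges).
#' @export
reversible_branch_analysis <- function(spec) {
  stopifnot(inherits(spec, "reversible_branch_spec"))
  Va <- spec$fa$Vmax; Ka <- spec$fa$KM
  Vb <- spec$Vmax_b; KX <- spec$KX; KY <- spec$KY; D <- spec$D
  globally <- Vb > Va
  states <- data.frame(Xstar = numeric(), Ystar = numeric(),
                       stable = logical(), fstar = numeric())
  if (abs(Vb - Va) > 1e-14 * max(Va, Vb)) {
    den <- Vb - Va
    bq <- (2 * Ka * Vb - (Ka + KX) * Va - KX * Va^2 / (KY * D) - Va * Vb / D) / den
    cq <- Ka * (Vb * Ka - Va * KX - Va * Vb / D) / den
    disc <- bq^2 - 4 * cq
    roots <- if (disc < 0) numeric() else (-bq + c(-1, 1) * sqrt(disc)) / 2
    roots <- sort(unique(roots[is.finite(roots) & roots > 0]))
    if (length(roots) > 0L) {
      ys <- (Va / D) * roots / (Ka + roots)
      stable <- vapply(seq_along(roots), function(i) {
        jj <- reversible_jacobian(spec, roots[i], ys[i])
        bcoef <- jj$beta_x - jj$alpha - jj$beta_y + D
        ccoef <- jj$beta_x * D + jj$alpha * jj$beta_y - jj$alpha * D
        bcoef > 0 && ccoef > 0
      }, logical(1))
      states <- data.frame(Xstar = roots, Ystar = ys, stable = stable,
                           fstar = vapply(roots, function(x) mm_flux(spec$fa, x),
                                          numeric(1)))
    }
  }
  rep <- new_report(states, list(exists = TRUE, stable = Vb / KX > Va / Ka),
                    if (D > Va / Ka) "fast_D" else "slow_D", spec)
  rep$regime <- rep$domain
  rep$globally_stable_possible <- globally
  rep
}

#' Sufficient condition for a positive state with a reversible cycle reaction
#'
#' When the autocatalytic reaction itself is reversible (driven by the
#' displacement of the assimilated metabolite from equilibrium), a positive
#' steady state is guaranteed whenever the slope of `fa` at `X = 0` (at the
#' fixed assimilated concentration) exceeds the branch origin slope
#' `Vmax,b/KM,b`; raising the autocatalytic enzyme level always reaches
#' this, so a minimal `Vmax,a` exists above which the state appears.
#'
#' @param fa_slope_at_zero Slope of the reversible autocatalytic flux at
#'   `X = 0` (rate per concentration, positive).
#' @param branch [mm_kinetics()] of the branch reaction.
#' @return `TRUE` iff the sufficient condition holds (strict inequality).
#' @export
reversible_autocatalytic_min_Vmax <- function(fa_slope_at_zero, branch) {
  stopifnot(inherits(branch, "mm_kinetics"))
  if (!is.numeric(fa_slope_at_zero) || length(fa_slope_at_zero) != 1L ||
      !is.finite(fa_slope_at_zero) || fa_slope_at_zero <= 0) {
    stop("fa_slope_at_zero must be a positive number", call. = FALSE)
  }
  fa_slope_at_zero > branch$Vmax / branch$KM
}
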