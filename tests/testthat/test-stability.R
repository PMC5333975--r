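test_that("worked steady states of the closed cycle", {
  # branch plateau above, branch shallower at origin: stable positive state
  rep1 <- steady_state_simple(simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4)))
  expect_equal(rep1$domain, "I")
  expect_equal(rep1$states$Xstar, 2)
  expect_true(rep1$states$stable)
  expect_false(rep1$zero_state$stable)
  expect_equal(rep1$states$fstar, 2 / 3)

  # swapped roles: positive threshold state, unstable
  rep3 <- steady_state_simple(simple_cycle_spec(mm_kinetics(2, 4), mm_kinetics(1, 1)))
  expect_equal(rep3$domain, "III")
  expect_equal(rep3$states$Xstar, 2)
  expect_false(rep3$states$stable)
  expect_true(rep3$zero_state$stable)

  # branch dominates everywhere: no positive state
  rep2 <- steady_state_simple(simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 1)))
  expect_equal(rep2$domain, "II")
  expect_equal(nrow(rep2$states), 0L)
  expect_true(rep2$zero_state$stable)

  # equal plateaus: degenerate
  repd <- steady_state_simple(simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(1, 2)))
  expect_equal(repd$domain, "degenerate")
})

test_that("delta rescaling moves the phase boundaries", {
  # 5:6 stoichiometry: delta = 1/5 shrinks the effective autocatalytic plateau
  spec <- simple_cycle_spec(mm_kinetics(5, 1), mm_kinetics(2, 4), delta = 1 / 5)
  expect_equal(classify_domain(spec), "I")
  rep <- steady_state_simple(spec)
  # delta*fa(X*) = fb(X*) by substitution
  expect_lt(abs(spec$delta * mm_flux(spec$fa, rep$states$Xstar) -
                mm_flux(spec$fb, rep$states$Xstar)), 1e-12)
})

test_that("existence and stability hold iff the two parameter conditions hold", {
  set.seed(4)
  for (i in 1:3000) {
    delta <- sample(c(1, 1, 0.5, 0.2), 1)
    spec <- simple_cycle_spec(random_mm(), random_mm(), delta = delta)
    rep <- steady_state_simple(spec)
    if (rep$domain == "degenerate") next
    Va <- delta * spec$fa$Vmax; Ka <- spec$fa$KM
    Vb <- spec$fb$Vmax; Kb <- spec$fb$KM
    cond <- (Vb > Va) && (Vb / Kb < Va / Ka)
    has_stable_positive <- nrow(rep$states) > 0 && any(rep$states$stable)
    expect_identical(has_stable_positive, cond)
    if (has_stable_positive) {
      expect_gt(Kb, Ka)  # weak-affinity requirement on the branch
      Xs <- rep$states$Xstar[rep$states$stable]
      # substitution residual
      expect_lt(abs(delta * mm_flux(spec$fa, Xs) - mm_flux(spec$fb, Xs)),
                1e-9 * Vb)
      # elasticity form of the stability criterion
      expect_gt(elasticity(spec$fb, Xs), elasticity(spec$fa, Xs))
      # bisection oracle on delta*fa - fb over (0, huge)
      root <- stats::uniroot(function(x) delta * mm_flux(spec$fa, x) - mm_flux(spec$fb, x),
                             c(1e-12, 1e6 * max(Ka, Kb)), tol = 1e-12)$root
      expect_equal(Xs, root, tolerance = 1e-6)
    }
  }
})

test_that("input flux removes the zero state and follows the three regimes", {
  rep <- steady_states_with_input(
    simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(3, 1), fi = 0.5))
  expect_equal(rep$domain, "input_I")
  expect_equal(rep$states$Xstar, 1 / 3, tolerance = 1e-12)
  expect_true(rep$states$stable)
  expect_false(rep$zero_state$exists)

  # branch plateau below the input: nothing can absorb it
  repd <- steady_states_with_input(
    simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(0.4, 1), fi = 0.5))
  expect_true(repd$divergent)
  expect_equal(nrow(repd$states), 0L)

  # two-root regime: lower state stable, upper unstable
  rep2 <- steady_states_with_input(
    simple_cycle_spec(mm_kinetics(2, 4), mm_kinetics(1.6, 1), fi = 0.01))
  expect_equal(nrow(rep2$states), 2L)
  expect_identical(rep2$states$stable, c(TRUE, FALSE))
  for (x in rep2$states$Xstar) {
    expect_lt(abs(0.01 + 2 * x / (4 + x) - 1.6 * x / (1 + x)), 1e-9)
  }

  # fi -> 0 limit reproduces the closed-cycle positive state
  spec0 <- simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4))
  eps <- steady_states_with_input(
    simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4), fi = 1e-9))
  expect_equal(max(eps$states$Xstar), steady_state_simple(spec0)$states$Xstar,
               tolerance = 1e-6)
})

test_that("steady-state sensitivities match closed forms and finite differences", {
  spec <- simple_cycle_spec(mm_kinetics(1, 1), mm_kinetics(2, 4))
  s <- sensitivity_signs(spec)
  expect_equal(s$derivative[s$parameter == "KM_a"], -2)
  expect_identical(s$sign, c("-", "+", "+", "-"))

  xstar <- function(Va, Ka, Vb, Kb) {
    steady_state_simple(simple_cycle_spec(mm_kinetics(Va, Ka),
                                          mm_kinetics(Vb, Kb)))$states$Xstar
  }
  h <- 1e-6
  fd <- c(KM_a = (xstar(1, 1 + h, 2, 4) - xstar(1, 1 - h, 2, 4)) / (2 * h),
          KM_b = (xstar(1, 1, 2, 4 + h) - xstar(1, 1, 2, 4 - h)) / (2 * h),
          Vmax_a = (xstar(1 + h, 1, 2, 4) - xstar(1 - h, 1, 2, 4)) / (2 * h),
          Vmax_b = (xstar(1, 1, 2 + h, 4) - xstar(1, 1, 2 - h, 4)) / (2 * h))
  expect_equal(stats::setNames(s$derivative, s$parameter), fd, tolerance = 1e-5)

  # scaling both plateaus leaves X* unchanged
  expect_equal(xstar(3, 1, 6, 4), xstar(1, 1, 2, 4))
  expect_error(sensitivity_signs(simple_cycle_spec(mm_kinetics(2, 4), mm_kinetics(1, 1))),
               "domain I")
})

test_that("bisubstrate stable regions reproduce the scheme-specific bounds", {
  ro <- bisubstrate_stable_region(
    bisubstrate_kinetics("random_order", Vmax = 2, KA = 1, KX = 2, KiA = 1),
    mm_kinetics(1, 4))
  expect_equal(ro$A_lower, 1 / 3)       # KiA / (KM,b*Vmax/(Vmax,b*KX) - 1)
  expect_equal(ro$KMb_lower, 2)         # KX / max(1, KA/KiA)
  expect_true(ro$satisfiable)

  oa <- bisubstrate_stable_region(
    bisubstrate_kinetics("ordered_A_first", Vmax = 1, KA = 2, KX = 3, KiA = 0.7),
    mm_kinetics(2, 8))
  expect_equal(oa$KMb_lower, 3)         # absolute bound KM,b > KX
  expect_true(oa$satisfiable)
  expect_equal(oa$A_lower, 0.7 / (8 / 6 - 1))

  ox <- bisubstrate_stable_region(
    bisubstrate_kinetics("ordered_X_first", Vmax = 2, KA = 1, KX = 2, KiX = 3),
    mm_kinetics(1, 4))
  expect_equal(ox$A_lower, 1 * 3 * 1 / (4 * 2))  # Vb*KiX*KA/(KM,b*Vmax)
  expect_true(is.na(ox$KMb_lower))

  # slope condition unsatisfiable at any A
  bad <- bisubstrate_stable_region(
    bisubstrate_kinetics("random_order", Vmax = 1, KA = 1, KX = 5, KiA = 1),
    mm_kinetics(2, 1))
  expect_false(bad$satisfiable)
  expect_identical(bad$A_lower, Inf)
})

test_that("X*(A) matches the composed pipeline and vanishes at the bound", {
  set.seed(5)
  n_ok <- 0L
  for (i in 1:400) {
    scheme <- sample(c("ping_pong", "random_order", "ordered_A_first",
                       "ordered_X_first"), 1)
    b <- random_bisubstrate(scheme)
    branch <- random_mm(v_range = c(0.2, 5), k_range = c(0.2, 5))
    reg <- bisubstrate_stable_region(b, branch)
    if (!reg$satisfiable) next
    lo <- max(reg$A_lower, 0)
    hi <- if (is.finite(reg$A_upper)) reg$A_upper else max(4 * lo, 10)
    if (hi <= lo * 1.01) next
    A <- lo + stats::runif(1, 0.1, 0.9) * (hi - lo)
    direct <- xstar_vs_A(b, branch, A)
    comp <- steady_state_simple(simple_cycle_spec(apparent_constants(b, A), branch))
    if (nrow(comp$states) == 0L) {
      # no positive state from the composition either
      expect_lte(direct, 0)
      next
    }
    expect_equal(direct, comp$states$Xstar, tolerance = 1e-9)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 100L)

  ro_b <- bisubstrate_kinetics("random_order", Vmax = 2, KA = 1, KX = 2, KiA = 1)
  branch <- mm_kinetics(1, 4)
  bound <- bisubstrate_stable_region(ro_b, branch)$A_lower
  expect_equal(xstar_vs_A(ro_b, branch, bound), 0)
  expect_gt(xstar_vs_A(ro_b, branch, bound * 1.001), 0)
  expect_lt(xstar_vs_A(ro_b, branch, bound * 1.001), 0.05)
  expect_error(xstar_vs_A(ro_b, branch, bound * 0.9), "below")
  # approaching the upper bound the steady state runs away
  upper <- bisubstrate_stable_region(ro_b, branch)$A_upper
  expect_gt(xstar_vs_A(ro_b, branch, upper * 0.999), 100)
})

test_that("reversible branch: limits and Jacobian verdicts", {
  fa <- mm_kinetics(1, 1)
  # fast removal of Y reduces to the irreversible analysis
  fastD <- reversible_branch_analysis(
    reversible_branch_spec(fa, Vmax_b = 2, KX = 4, KY = 1, D = 1e3))
  irrev <- steady_state_simple(simple_cycle_spec(fa, mm_kinetics(2, 4)))
  expect_equal(fastD$regime, "fast_D")
  stable_x <- fastD$states$Xstar[fastD$states$stable]
  expect_equal(stable_x, irrev$states$Xstar, tolerance = 1e-2)

  # huge branch plateau at small D: X* -> Vmax,a/D - KM,a
  slow <- reversible_branch_analysis(
    reversible_branch_spec(fa, Vmax_b = 1e7, KX = 4, KY = 1, D = 0.2))
  expect_equal(max(slow$states$Xstar), 1 / 0.2 - 1, tolerance = 1e-3)
  expect_equal(slow$regime, "slow_D")

  # trace/determinant verdicts equal numeric eigenvalues
  set.seed(6)
  n_states <- 0L
  for (i in 1:300) {
    spec <- reversible_branch_spec(random_mm(),
                                   Vmax_b = exp(stats::runif(1, log(0.5), log(20))),
                                   KX = exp(stats::runif(1, log(0.2), log(10))),
                                   KY = exp(stats::runif(1, log(0.2), log(10))),
                                   D = exp(stats::runif(1, log(0.05), log(50))))
    rep <- reversible_branch_analysis(spec)
    if (nrow(rep$states) == 0L) next
    for (j in seq_len(nrow(rep$states))) {
      jj <- autocat:::reversible_jacobian(spec, rep$states$Xstar[j], rep$states$Ystar[j])
      ev <- max(Re(eigen(jj$J, only.values = TRUE)$values))
      if (abs(ev) < 1e-10) next
      expect_identical(rep$states$stable[j], ev < 0)
      n_states <- n_states + 1L
    }
  }
  expect_gte(n_states, 50L)

  expect_false(reversible_branch_analysis(
    reversible_branch_spec(mm_kinetics(2, 1), Vmax_b = 1, KX = 1, KY = 1, D = 1))$
      globally_stable_possible)
})

test_that("reversible autocatalytic reaction needs slope above the branch slope", {
  branch <- mm_kinetics(1, 1)
  expect_true(reversible_autocatalytic_min_Vmax(2, branch))
  expect_false(reversible_autocatalytic_min_Vmax(1, branch))  # strict
  verdicts <- vapply(seq(0.1, 3, by = 0.1), reversible_autocatalytic_min_Vmax,
                     logical(1), branch = branch)
  expect_equal(sum(diff(verdicts) != 0), 1L)  # flips exactly once
})
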