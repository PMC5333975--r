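# Synthetic-data generators: random networks with planted autocatalytic
# cycles (ground truth for detection tests) and condition-by-condition
# flux/enzyme tables generated from a kinetic cycle model at its steady
# state (ground truth for the saturation audit).

#' Generate a random network with planted cycles
#'
#' Plants `n_cycles` node-disjoint cycles among otherwise acyclic
#' background reactions. Two motifs are available:
#' \describe{
#'   \item{autocatalytic}{A chain `X1 -> X2 -> ... -> XL` whose closing
#'     reaction assimilates an external substrate and emits an extra
#'     product `G` that returns to `X1` through its own reaction — a
#'     branch-product-path autocatalysis with unit stoichiometry (the full
#'     loop through `G` is a multi-product cycle).}
#'   \item{plain}{A futile loop `X1 -> ... -> XL -> X1` with no gain.}
#' }
#' Background reactions form a random directed acyclic chain over separate
#' metabolites (some consuming the external substrate), so planted cycles
#' are exactly the cycles of the graph.
#'
#' @param n_cycles Number of planted cycles.
#' @param cycle_len Reactions per planted chain (>= 2).
#' @param n_background Number of background reactions.
#' @param motif `"autocatalytic"` or `"plain"`.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return List with `network`, and `planted`: per cycle, its reaction ids
#'   (`reactions`), loop backbone ids (`backbone`), and intermediates.
#' @export
generate_planted_network <- function(n_cycles = 1L, cycle_len = 3L,
                                     n_background = 10L,
                                     motif = c("autocatalytic", "plain"),
                                     seed = 1L) {
  motif <- match.arg(motif)
  if (cycle_len < 2L) stop("cycle_len must be >= 2", call. = FALSE)
  set.seed(seed)
  mets <- list(metabolite("ext", is_external = TRUE))
  rxns <- list()
  planted <- list()
  for (ci in seq_len(n_cycles)) {
    xs <- sprintf("c%d_x%d", ci, seq_len(cycle_len))
    for (x in xs) mets[[length(mets) + 1L]] <- metabolite(x)
    rids <- sprintf("c%d_r%d", ci, seq_len(cycle_len))
    for (i in seq_len(cycle_len - 1L)) {
      rxns[[length(rxns) + 1L]] <- reaction(rids[i],
                                            stats::setNames(1, xs[i]),
                                            stats::setNames(1, xs[i + 1L]))
    }
    if (motif == "autocatalytic") {
      g <- sprintf("c%d_g", ci)
      ret <- sprintf("c%d_ret", ci)
      mets[[length(mets) + 1L]] <- metabolite(g)
      rxns[[length(rxns) + 1L]] <- reaction(rids[cycle_len],
                                            c(stats::setNames(1, xs[cycle_len]),
                                              ext = 1),
                                            c(stats::setNames(1, xs[1L]),
                                              stats::setNames(1, g)))
      rxns[[length(rxns) + 1L]] <- reaction(ret, stats::setNames(1, g),
                                            stats::setNames(1, xs[1L]))
      planted[[ci]] <- list(reactions = c(rids, ret), backbone = rids,
                            intermediates = c(xs, g))
    } else {
      rxns[[length(rxns) + 1L]] <- reaction(rids[cycle_len],
                                            stats::setNames(1, xs[cycle_len]),
                                            stats::setNames(1, xs[1L]))
      planted[[ci]] <- list(reactions = rids, backbone = rids,
                            intermediates = xs)
    }
  }
  if (n_background > 0L) {
    bmets <- sprintf("b%d", seq_len(n_background + 1L))
    for (b in bmets) mets[[length(mets) + 1L]] <- metabolite(b)
    for (i in seq_len(n_background)) {
      subs <- stats::setNames(1, bmets[i])
      if (stats::runif(1) < 0.3) subs <- c(subs, ext = 1)
      rxns[[length(rxns) + 1L]] <- reaction(sprintf("bg%d", i), subs,
                                            stats::setNames(1, bmets[i + 1L]))
    }
  }
  list(network = metabolic_network(mets, rxns), planted = planted)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default kinetic cycle used by the table generator
#'
#' A three-reaction 1:2 autocatalytic cycle designed around the steady
#' state `X* = (1, 1, 1)` with branch points at positions 1 and 2. Branch
#' affinities are weaker than the competing cycle affinities (`KM` 4 and 3
#' vs 1), placing branch saturations at 0.2 and 0.25 against cycle
#' saturations of 0.5, as stability demands; the linearization satisfies
#' `beta_1 > alpha_1` and the state is eigen-stable.
#'
#' @return A [multi_cycle_spec()].
#' @export
example_audit_cycle <- function() {
  design_cycle(Xstars = c(1, 1, 1),
               fa_fluxes = c(1.2, 1, 1),
               KM_cycle = c(1, 1, 1),
               KM_branch = c(4, 3, NA),
               delta = 1)
}

#' Generate synthetic flux and enzyme tables from a kinetic cycle
#'
#' Emulates the structure of paired fluxomics and proteomics measurements
#' for a cycle operating at steady state across growth conditions. For each
#' condition every enzyme level is scaled by a lognormal factor
#' (coefficient of variation `condition_cv`), the perturbed cycle's stable
#' steady state is re-solved (conditions that lose stability are redrawn),
#' and observed fluxes and enzyme abundances are the steady-state values
#' times lognormal measurement noise of coefficient of variation
#' `noise_cv`. The ground truth records, per reaction and condition, the
#' true saturation `X*/(KM + X*)`, the method-recoverable saturation
#' (true saturation divided by its across-condition maximum — what a
#' capacity estimate built on the maximal flux/enzyme ratio can recover),
#' and the argmax condition.
#'
#' A deterministic capacity-probe condition (id `"probe"`) is appended by
#' default: branch enzymes are expressed at half their reference level, so
#' the intermediates pile up and every reaction approaches saturation.
#' This emulates the role of condition diversity in real capacity
#' estimation — without at least one near-saturated condition the maximal
#' flux/enzyme ratio badly underestimates capacity and the audit
#' overestimates saturation.
#'
#' @param kinetics A [multi_cycle_spec()] with an eigen-stable positive
#'   steady state (default [example_audit_cycle()]).
#' @param n_conditions Number of randomly perturbed conditions.
#' @param noise_cv Measurement noise CV (0 for noiseless tables).
#' @param seed Integer seed; same seed, same tables.
#' @param condition_cv CV of the between-condition enzyme-level variation.
#' @param probe_condition Append the capacity-probe condition (default
#'   `TRUE`).
#' @return List with `flux` and `enzyme` [condition_table()]s,
#'   `branch_points` (data frame for [audit_branch_points()]), and `truth`
#'   (data frame: reaction, condition, saturation_true,
#'   saturation_recoverable, capacity_true, argmax flag).
#' @export
generate_synthetic_tables <- function(kinetics = example_audit_cycle(),
                                      n_conditions = 3L, noise_cv = 0,
                                      seed = 1L, condition_cv = 0.4,
                                      probe_condition = TRUE) {
  stopifnot(inherits(kinetics, "multi_cycle_spec"))
  n <- kinetics$n
  base <- solve_cycle_steady_state(kinetics)
  if (!base$converged) stop("base kinetics has no solvable steady state", call. = FALSE)
  if (!isTRUE(eigen_stability(build_jacobian(linearize_cycle(kinetics, base$Xstar))))) {
    stop("base kinetics steady state is not stable; refusing to generate",
         call. = FALSE)
  }
  set.seed(seed)
  has_branch <- !vapply(kinetics$branch_kinetics, is.null, logical(1))
  rxn_ids <- c(paste0("fa", seq_len(n)), paste0("fb", which(has_branch)))

  scale_spec <- function(mult) {
    # mult named by reaction id; Vmax scales with enzyme level
    cyc <- lapply(seq_len(n), function(i) {
      k <- kinetics$cycle_kinetics[[i]]
      mm_kinetics(k$Vmax * mult[[paste0("fa", i)]], k$KM)
    })
    br <- lapply(seq_len(n), function(i) {
      k <- kinetics$branch_kinetics[[i]]
      if (is.null(k)) NULL else mm_kinetics(k$Vmax * mult[[paste0("fb", i)]], k$KM)
    })
    multi_cycle_spec(cyc, br, delta = kinetics$delta)
  }

  conditions <- paste0("cond", seq_len(n_conditions))
  if (probe_condition) conditions <- c(conditions, "probe")
  rows_flux <- list(); rows_enz <- list(); rows_truth <- list()
  for (cond in conditions) {
    if (cond == "probe") {
      # branch enzymes halved: intermediates pile up toward saturation
      mult <- stats::setNames(ifelse(startsWith(rxn_ids, "fb"), 0.5, 1), rxn_ids)
      sp <- scale_spec(mult)
      sol <- solve_cycle_steady_state(sp, X0 = 5 * base$Xstar)
      if (!sol$converged ||
          !isTRUE(eigen_stability(build_jacobian(linearize_cycle(sp, sol$Xstar))))) {
        stop("capacity-probe condition has no stable steady state for these kinetics",
             call. = FALSE)
      }
    } else {
      found <- FALSE
      for (attempt in 1:100) {
        mult <- stats::setNames(lognormal_noise(length(rxn_ids), condition_cv),
                                rxn_ids)
        sp <- scale_spec(mult)
        sol <- solve_cycle_steady_state(sp, X0 = base$Xstar)
        if (!sol$converged || any(sol$Xstar <= 1e-9)) next
        if (!isTRUE(eigen_stability(build_jacobian(linearize_cycle(sp, sol$Xstar))))) next
        found <- TRUE
        break
      }
      if (!found) {
        stop("could not find a stable perturbed steady state; lower condition_cv",
             call. = FALSE)
      }
    }
    fl <- cycle_fluxes(sp, sol$Xstar)
    for (rid in rxn_ids) {
      is_branch <- startsWith(rid, "fb")
      pos <- as.integer(sub("f[ab]", "", rid))
      k <- if (is_branch) sp$branch_kinetics[[pos]] else sp$cycle_kinetics[[pos]]
      flux_true <- if (is_branch) fl$fb[pos] else fl$fa[pos]
      sat_true <- sol$Xstar[pos] / (k$KM + sol$Xstar[pos])
      rows_flux[[length(rows_flux) + 1L]] <- data.frame(
        reaction = rid, condition = cond,
        value = flux_true * lognormal_noise(1, noise_cv))
      rows_enz[[length(rows_enz) + 1L]] <- data.frame(
        reaction = rid, condition = cond,
        value = mult[[rid]] * lognormal_noise(1, noise_cv))
      rows_truth[[length(rows_truth) + 1L]] <- data.frame(
        reaction = rid, condition = cond,
        saturation_true = sat_true,
        capacity_true = k$Vmax, enzyme_true = mult[[rid]],
        flux_true = flux_true)
    }
  }
  truth <- do.call(rbind, rows_truth)
  truth$saturation_recoverable <- NA_real_
  truth$argmax <- FALSE
  for (rid in rxn_ids) {
    sel <- truth$reaction == rid
    smax <- max(truth$saturation_true[sel])
    truth$saturation_recoverable[sel] <- truth$saturation_true[sel] / smax
    truth$argmax[sel] <- truth$saturation_true[sel] == smax
  }
  bp <- data.frame(metabolite = paste0("X", which(has_branch)),
                   cycle_reaction = paste0("fa", which(has_branch)),
                   branch_reaction = paste0("fb", which(has_branch)))
  list(flux = condition_table(do.call(rbind, rows_flux), "flux"),
       enzyme = condition_table(do.call(rbind, rows_enz), "enzyme"),
       branch_points = bp,
       truth = truth)
}
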