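# Shared fixture builders and independent oracles used across the suite.

# Tiny three-reaction branch-product-path motif:
#   R1: S + X1 -> X2 ; R2: X2 -> X1 + X3 ; R3: X3 -> X1
branch_return_network <- function() {
  metabolic_network(
    list(metabolite("S", is_external = TRUE), metabolite("X1"),
         metabolite("X2"), metabolite("X3")),
    list(reaction("R1", c(S = 1, X1 = 1), c(X2 = 1)),
         reaction("R2", c(X2 = 1), c(X1 = 1, X3 = 1)),
         reaction("R3", c(X3 = 1), c(X1 = 1))))
}

futile_pair_network <- function() {
  metabolic_network(
    list(metabolite("X1"), metabolite("X2")),
    list(reaction("F1", c(X1 = 1), c(X2 = 1)),
         reaction("F2", c(X2 = 1), c(X1 = 1))))
}

# Random small network over n_mets internal metabolites (+1 external),
# unit-free random integer stoichiometry; used for oracle comparisons.
random_small_network <- function(n_mets = 4L, n_rxns = 4L, max_coef = 2L) {
  mids <- paste0("m", seq_len(n_mets))
  mets <- c(lapply(mids, metabolite), list(metabolite("xext", is_external = TRUE)))
  rxns <- lapply(seq_len(n_rxns), function(i) {
    repeat {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      subs <- sample(c(mids, "xext"), ns)
      prods <- sample(c(mids, "xext"), np)
      if (length(intersect(subs, prods)) == 0L) break
    }
    reaction(paste0("r", i),
             stats::setNames(sample(seq_len(max_coef), length(subs), replace = TRUE), subs),
             stats::setNames(sample(seq_len(max_coef), length(prods), replace = TRUE), prods))
  })
  metabolic_network(mets, rxns)
}

# Brute-force oracle for the formal verifier: exhaustive expand.grid over
# all multiplier vectors, direct matrix arithmetic, independent subset
# check. Returns NULL or list(multipliers, sum).
brute_force_autocat <- function(net, reaction_ids, intermediates, max_multiplier) {
  S <- stoich_matrix(net)[intermediates, reaction_ids, drop = FALSE]
  # gross-sign matrices
  cons <- matrix(0, length(intermediates), length(reaction_ids),
                 dimnames = list(intermediates, reaction_ids))
  prod <- cons
  for (rid in reaction_ids) {
    r <- net$reactions[[rid]]
    s <- r$substrates[names(r$substrates) %in% intermediates]
    p <- r$products[names(r$products) %in% intermediates]
    if (length(s)) cons[names(s), rid] <- s
    if (length(p)) prod[names(p), rid] <- p
  }
  signs_ok <- function(cols) {
    touched <- rowSums(cons[, cols, drop = FALSE]) +
      rowSums(prod[, cols, drop = FALSE]) > 0
    if (!any(touched)) return(FALSE)
    all(rowSums(cons[touched, cols, drop = FALSE] > 0) > 0 &
          rowSums(prod[touched, cols, drop = FALSE] > 0) > 0) &&
      all(colSums(cons[touched, cols, drop = FALSE] > 0) > 0 &
            colSums(prod[touched, cols, drop = FALSE] > 0) > 0)
  }
  sub <- function(cols) {
    touched <- rowSums(cons[, cols, drop = FALSE]) +
      rowSums(prod[, cols, drop = FALSE]) > 0
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(seq_len(max_multiplier)), length(cols))))
    res <- grid %*% t(S[touched, cols, drop = FALSE])
    hit <- apply(res, 1, function(r) all(r >= 0) && any(r > 0))
    if (!any(hit)) return(NULL)
    g <- grid[hit, , drop = FALSE]
    g[order(rowSums(g))[1L], ]
  }
  if (!signs_ok(seq_along(reaction_ids))) return(NULL)
  if (!all(rowSums(cons) + rowSums(prod) > 0)) return(NULL)  # untouched intermediate
  best <- sub(seq_along(reaction_ids))
  if (is.null(best)) return(NULL)
  k <- length(reaction_ids)
  if (k > 1L) {
    for (mask in 1:(2^k - 2L)) {
      sel <- which(as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L))))
      if (length(sel) == 0L) next
      if (signs_ok(sel) && !is.null(sub(sel))) return(NULL)
    }
  }
  list(multipliers = stats::setNames(as.integer(best), reaction_ids),
       sum = sum(best))
}

# Random Michaelis-Menten bundle on log-uniform scales.
random_mm <- function(v_range = c(0.1, 10), k_range = c(0.1, 10)) {
  mm_kinetics(exp(stats::runif(1, log(v_range[1]), log(v_range[2]))),
              exp(stats::runif(1, log(k_range[1]), log(k_range[2]))))
}

random_bisubstrate <- function(scheme) {
  r <- function() exp(stats::runif(1, log(0.2), log(5)))
  bisubstrate_kinetics(scheme, Vmax = r(), KA = r(), KX = r(),
                       KiA = if (scheme %in% c("random_order", "ordered_A_first")) r(),
                       KiX = if (scheme == "ordered_X_first") r())
}

# A two-reaction kinetic cycle with one branch, stable by construction,
# used in dynamics and multicycle tests.
stable_two_cycle <- function() {
  design_cycle(Xstars = c(1, 2),
               fa_fluxes = c(1.5, 1),
               KM_cycle = c(1, 2),
               KM_branch = c(5, 8),
               delta = 1)
}

# Base (direction-stripped) reaction ids of a detection hit.
base_reactions_of <- function(h) {
  ids <- if (!is.null(h$multipliers)) names(h$multipliers) else h$reactions_path
  unique(sub("__rev$", "", ids))
}

# Serialize a network deterministically (for reproducibility comparisons).
write_network_to_string <- function(net) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_network(net, tmp)
  paste(readLines(tmp), collapse = "\n")
}
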