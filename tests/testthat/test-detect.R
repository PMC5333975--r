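test_that("reaction graph construction counts nodes and edges", {
  net <- metabolic_network(list(metabolite("a"), metabolite("b")),
                           list(reaction("r", c(a = 1), c(b = 1))))
  g <- build_reaction_graph(net)
  expect_length(g$nodes, 3L)
  expect_equal(g$n_edges, 2L)

  gly <- build_reaction_graph(autocat_example("glyoxylate"))
  expect_setequal(gly$nodes, c("mal", "icit", "mal_to_icit", "icl_mas"))
  expect_equal(gly$n_edges, 4L)  # accoa is external and contributes none

  empty <- build_reaction_graph(metabolic_network())
  expect_length(empty$nodes, 0L)
})

test_that("cycle enumeration finds loops, ignores chains, respects bounds", {
  loop <- futile_pair_network()
  cyc <- enumerate_cycles(build_reaction_graph(loop))
  expect_length(cyc, 1L)
  expect_setequal(cyc[[1]]$metabolites, c("X1", "X2"))

  chain <- metabolic_network(
    list(metabolite("a"), metabolite("b"), metabolite("c")),
    list(reaction("r1", c(a = 1), c(b = 1)), reaction("r2", c(b = 1), c(c = 1))))
  expect_length(enumerate_cycles(build_reaction_graph(chain)), 0L)

  # planted node-disjoint plain loops are recovered exactly
  for (k in 1:3) {
    pl <- generate_planted_network(n_cycles = k, cycle_len = 3,
                                   n_background = 6, motif = "plain",
                                   seed = 10 + k)
    cyc <- enumerate_cycles(build_reaction_graph(pl$network))
    expect_length(cyc, k)
  }

  # the length bound is honoured
  pl <- generate_planted_network(1, cycle_len = 5, n_background = 0,
                                 motif = "plain", seed = 3)
  expect_length(enumerate_cycles(build_reaction_graph(pl$network), max_len = 4), 0L)
  expect_length(enumerate_cycles(build_reaction_graph(pl$network), max_len = 5), 1L)
})

test_that("reversible reactions contribute one direction per cycle", {
  net <- metabolic_network(
    list(metabolite("a"), metabolite("b")),
    list(reaction("r", c(a = 1), c(b = 1), reversible = TRUE)))
  g <- build_reaction_graph(net)
  # a -> r -> b -> r__rev -> a is NOT a simple cycle of one reaction twice
  expect_length(enumerate_cycles(g), 0L)
})

test_that("classification follows the three-way screen", {
  net <- branch_return_network()
  g <- build_reaction_graph(net)
  cycles <- enumerate_cycles(g)
  keys <- vapply(cycles, function(cc) paste(sort(cc$base_reactions), collapse = "+"),
                 character(1))

  backbone <- cycles[[which(keys == "R1+R2")]]
  cls <- classify_cycle(net, backbone, g)
  expect_true(cls$accepted)
  expect_equal(cls$classification, "branch_product_path")

  full <- cycles[[which(keys == "R1+R2+R3")]]
  cls2 <- classify_cycle(net, full, g)
  expect_true(cls2$accepted)
  expect_equal(cls2$classification, "multi_product")

  futile <- futile_pair_network()
  gf <- build_reaction_graph(futile)
  cf <- classify_cycle(futile, enumerate_cycles(gf)[[1]], gf)
  expect_false(cf$accepted)
  expect_equal(cf$classification, "rejected")

  # a cycle reaction consuming two intermediates is rejected
  net2 <- metabolic_network(
    list(metabolite("X1"), metabolite("X2"), metabolite("X3")),
    list(reaction("Ra", c(X1 = 1, X2 = 1), c(X3 = 1)),
         reaction("Rb", c(X3 = 1), c(X1 = 1)),
         reaction("Rc", c(X1 = 1), c(X2 = 1))))
  g2 <- build_reaction_graph(net2)
  cyc2 <- enumerate_cycles(g2)
  has_ra <- vapply(cyc2, function(cc) "Ra" %in% cc$base_reactions &&
                     all(c("X1", "X2") %in% cc$metabolites), logical(1))
  expect_true(any(has_ra))
  verdicts <- vapply(cyc2[has_ra], function(cc) {
    classify_cycle(net2, cc, g2)$classification
  }, character(1))
  expect_true(all(verdicts == "rejected"))
})

test_that("the formal verifier certifies the packaged cycles", {
  gly <- verify_autocatalytic(autocat_example("glyoxylate"),
                              c("mal_to_icit", "icl_mas"))
  expect_equal(gly$multipliers, c(mal_to_icit = 1L, icl_mas = 1L))
  expect_equal(gly$net[["mal"]], 1)
  expect_equal(gly$delta, 1)

  cbb <- verify_autocatalytic(autocat_example("cbb"), "cbb_lump")
  expect_equal(cbb$multipliers, c(cbb_lump = 1L))
  expect_equal(cbb$net[["c5"]], 1)
  expect_equal(cbb$consumed[["c5"]], 5)
  expect_equal(cbb$produced[["c5"]], 6)
  expect_equal(cbb$delta, 1 / 5)

  atp <- verify_autocatalytic(autocat_example("glycolysis_atp"),
                              c("priming", "payoff"),
                              intermediates = c("atp", "tp"), gain = "atp")
  expect_equal(atp$multipliers, c(priming = 1L, payoff = 2L))
  expect_equal(atp$consumed[["atp"]], 2)
  expect_equal(atp$produced[["atp"]], 4)
})

test_that("the verifier rejects unions of disjoint cycles (minimality)", {
  net <- metabolic_network(
    list(metabolite("X"), metabolite("Y"), metabolite("Z"),
         metabolite("A", is_external = TRUE)),
    list(reaction("g1", c(X = 1, A = 1), c(Y = 1)),
         reaction("g2", c(Y = 1), c(X = 2)),
         reaction("f1", c(Z = 1), c(X = 1)),  # hangs a consumer of Z on the side
         reaction("f2", c(X = 1), c(Z = 1))))
  expect_s3_class(verify_autocatalytic(net, c("g1", "g2")), "autocatalytic_cycle")
  # adding the futile pair keeps a valid assignment but violates minimality
  expect_null(verify_autocatalytic(net, c("g1", "g2", "f1", "f2")))
})

test_that("the verifier reports undecided when the budget is exhausted", {
  net <- autocat_example("glycolysis_atp")
  res <- verify_autocatalytic(net, c("priming", "payoff"),
                              intermediates = c("atp", "tp"), gain = "atp",
                              max_multiplier = 12L, search_budget = 1)
  expect_identical(res, "undecided")
})

test_that("verifier agrees with the brute-force multiplier oracle", {
  set.seed(99)
  n_checked <- 0L
  for (i in 1:60) {
    net <- random_small_network(n_mets = sample(3:4, 1), n_rxns = sample(2:4, 1))
    rids <- names(net$reactions)
    ints <- internal <- setdiff(names(net$metabolites), "xext")
    got <- verify_autocatalytic(net, rids, intermediates = ints,
                                max_multiplier = 4L)
    want <- brute_force_autocat(net, rids, ints, max_multiplier = 4L)
    if (is.null(want)) {
      expect_null(got, label = sprintf("iteration %d", i))
    } else {
      expect_s3_class(got, "autocatalytic_cycle")
      expect_equal(sum(got$multipliers), want$sum,
                   label = sprintf("iteration %d minimal sum", i))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1L)
})

test_that("returned cycles satisfy the type invariants independently", {
  hits <- list(
    verify_autocatalytic(autocat_example("glyoxylate"), c("mal_to_icit", "icl_mas")),
    verify_autocatalytic(autocat_example("cbb"), "cbb_lump"),
    verify_autocatalytic(autocat_example("pts"),
                         c("pts", "lower_glycolysis"),
                         intermediates = c("pep", "g6p")))
  for (h in hits) {
    expect_true(all(h$multipliers >= 1))
    nets <- h$net[h$intermediates]
    expect_true(all(nets >= 0))
    expect_true(any(nets > 0))
    expect_true(all(h$consumed[h$intermediates] > 0))
    expect_true(all(h$produced[h$intermediates] > 0))
    expect_gt(h$delta, 0)
  }
})

test_that("planted autocatalytic cycles are recovered from random backgrounds", {
  for (seed in 1:20) {
    pl <- generate_planted_network(n_cycles = 1, cycle_len = sample(2:4, 1),
                                   n_background = 8, motif = "autocatalytic",
                                   seed = seed)
    hits <- find_autocatalytic_cycles(pl$network)
    expect_gte(length(hits), 1L)
    sets <- lapply(hits, function(h) sort(base_reactions_of(h)))
    expect_true(any(vapply(sets, identical, logical(1),
                           sort(pl$planted[[1]]$reactions))),
                label = sprintf("seed %d full loop recovered", seed))
  }
})

test_that("whole-network detection matches the worked stoichiometries", {
  pts <- find_autocatalytic_cycles(autocat_example("pts"),
                                   cofactors = c("atp", "adp"))
  expect_length(pts, 1L)
  expect_equal(pts[[1]]$delta, 1)
  expect_setequal(pts[[1]]$intermediates, c("pep", "g6p"))

  gly <- find_autocatalytic_cycles(autocat_example("glycolysis_atp"))
  expect_length(gly, 1L)
  expect_setequal(gly[[1]]$intermediates, c("atp", "tp"))

  # acyclic network: nothing to find
  chain <- metabolic_network(
    list(metabolite("a"), metabolite("b")),
    list(reaction("r1", c(a = 1), c(b = 1))))
  expect_length(find_autocatalytic_cycles(chain), 0L)
})
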