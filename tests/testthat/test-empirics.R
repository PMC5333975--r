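make_tables <- function(flux_df, enz_df) {
  list(flux = condition_table(flux_df, "flux"),
       enzyme = condition_table(enz_df, "enzyme"))
}

test_that("maximal in-vivo rate is the best flux-per-enzyme ratio", {
  t <- make_tables(
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(2, 4)),
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(1, 1)))
  expect_equal(max_in_vivo_rate(t$flux, t$enzyme, "r"), 4)

  t1 <- make_tables(data.frame(reaction = "r", condition = "c1", value = 3),
                    data.frame(reaction = "r", condition = "c1", value = 1.5))
  expect_equal(max_in_vivo_rate(t1$flux, t1$enzyme, "r"), 2)

  t0 <- make_tables(
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(0, 0)),
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(1, 1)))
  expect_error(max_in_vivo_rate(t0$flux, t0$enzyme, "r"), "no usable")

  tbad <- make_tables(data.frame(reaction = "r", condition = "c1", value = 3),
                      data.frame(reaction = "r", condition = "c1", value = 0))
  expect_error(max_in_vivo_rate(tbad$flux, tbad$enzyme, "r"), "inconsistent")
})

test_that("capacity and saturation follow from the rate estimate", {
  t <- make_tables(
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(2, 4)),
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(1, 1)))
  cs <- capacity_and_saturation(t$flux, t$enzyme, "r", "c1")
  expect_equal(cs$capacity, 4)
  expect_equal(cs$saturation, 0.5)
  # the argmax condition is saturated by construction
  expect_equal(capacity_and_saturation(t$flux, t$enzyme, "r", "c2")$saturation, 1)

  # doubling the enzyme at fixed flux halves the saturation
  t2 <- make_tables(
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(2, 4)),
    data.frame(reaction = "r", condition = c("c1", "c2"), value = c(2, 1)))
  expect_equal(capacity_and_saturation(t2$flux, t2$enzyme, "r", "c1")$saturation,
               0.25)
})

test_that("branch-point audit issues the three verdicts", {
  flux <- data.frame(reaction = rep(c("cyc", "br", "sat"), each = 2),
                     condition = rep(c("c1", "c2"), 3),
                     value = c(2, 4, 1, 4, 3.8, 4))
  enz <- data.frame(reaction = rep(c("cyc", "br", "sat"), each = 2),
                    condition = rep(c("c1", "c2"), 3),
                    value = rep(1, 6))
  t <- make_tables(flux, enz)
  bp <- data.frame(metabolite = c("X", "X"),
                   cycle_reaction = c("cyc", "cyc"),
                   branch_reaction = c("br", "sat"))
  res <- audit_branch_points(t$flux, t$enzyme, bp, "c1")
  # S_cyc = 0.5, S_br = 0.25 -> branch less saturated; S_sat = 0.95 -> more
  expect_identical(res$rows$verdict, c("branch_less_saturated",
                                       "branch_more_saturated"))
  expect_equal(res$summary$branch_less_saturated, 1)

  # identical kinetics on both sides: similar
  bp2 <- data.frame(metabolite = "X", cycle_reaction = "cyc",
                    branch_reaction = "cyc2")
  flux2 <- rbind(flux, data.frame(reaction = "cyc2", condition = c("c1", "c2"),
                                  value = c(2, 4)))
  enz2 <- rbind(enz, data.frame(reaction = "cyc2", condition = c("c1", "c2"),
                                value = 1))
  t2 <- make_tables(flux2, enz2)
  expect_identical(audit_branch_points(t2$flux, t2$enzyme, bp2, "c1")$rows$verdict,
                   "similar")
})

test_that("regulation rule table and audits", {
  expect_equal(expected_regulation("cycle_intermediate", "branch_reaction"),
               "activation")
  expect_equal(expected_regulation("assimilated_metabolite", "cycle_reaction"),
               "inhibition")
  expect_equal(expected_regulation("branch_product", "reverse_branch_reaction"),
               "inhibition")
  expect_error(expected_regulation("unknown", "cycle_reaction"))

  # flipping branch -> reverse_branch flips every sign
  for (reg in c("cycle_intermediate", "assimilated_metabolite", "branch_product")) {
    fwd <- expected_regulation(reg, "branch_reaction")
    rev <- expected_regulation(reg, "reverse_branch_reaction")
    expect_false(fwd == rev)
  }

  combos <- expand.grid(
    regulator_class = c("cycle_intermediate", "assimilated_metabolite",
                        "branch_product"),
    target_class = c("cycle_reaction", "branch_reaction",
                     "reverse_branch_reaction"),
    stringsAsFactors = FALSE)
  combos$sign <- mapply(expected_regulation, combos$regulator_class,
                        combos$target_class)
  all_ok <- audit_regulation(combos)
  expect_equal(all_ok$n_consistent, nrow(combos))
  expect_equal(all_ok$n_inconsistent, 0L)

  flipped <- combos
  flipped$sign[1] <- setdiff(c("activation", "inhibition"), flipped$sign[1])
  one_bad <- audit_regulation(flipped)
  expect_equal(one_bad$n_consistent, nrow(combos) - 1L)
  expect_equal(one_bad$n_inconsistent, 1L)

  empty <- audit_regulation(data.frame())
  expect_equal(empty$n_consistent, 0L)
  expect_equal(empty$n_inconsistent, 0L)
})
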