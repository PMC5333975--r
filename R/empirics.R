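# Tabular machinery for testing the theory against flux and enzyme
# abundance data: maximal in-vivo catalytic rates, flux capacities and
# saturation levels, branch-point saturation audits, and the expected
# allosteric-regulation rule table.

#' Construct a flux or enzyme table
#'
#' Long-format reaction-by-condition table. Fluxes must be pre-resolved to
#' non-negative magnitudes in the direction of the audited reaction;
#' enzyme abundances are in arbitrary consistent units.
#'
#' @param df Data frame with columns `reaction`, `condition`, `value`.
#' @param kind `"flux"` or `"enzyme"`.
#' @return An object of class `"condition_table"`.
#' @export
condition_table <- function(df, kind = c("flux", "enzyme")) {
  kind <- match.arg(kind)
  df <- as.data.frame(df)
  need <- c("reaction", "condition", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("table must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop(sprintf("%s values must be finite and non-negative", kind), call. = FALSE)
  }
  if (anyDuplicated(df[c("reaction", "condition")])) {
    stop("duplicated (reaction, condition) entries", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("table is empty", call. = FALSE)
  structure(list(df = df[need], kind = kind,
                 conditions = unique(df$condition)),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("<condition_table:%s> %d reactions x %d conditions\n", x$kind,
              length(unique(x$df$reaction)), length(x$conditions)))
  invisible(x)
}

#' Read a flux or enzyme table from TSV
#'
#' Expects a header row `reaction<TAB>condition<TAB>value` (a third column
#' named `flux` or `abundance` is also accepted).
#'
#' @param path TSV file path.
#' @param kind `"flux"` or `"enzyme"`.
#' @return A [condition_table()].
#' @export
read_condition_table <- function(path, kind = c("flux", "enzyme")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcol <- intersect(c("value", "flux", "abundance"), names(df))
  if (length(vcol) == 0L) stop("no value column found", call. = FALSE)
  names(df)[names(df) == vcol[1L]] <- "value"
  condition_table(df, kind)
}

#' Write a condition table to TSV
#' @param x A [condition_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(x, path) {
  stopifnot(inherits(x, "condition_table"))
  utils::write.table(x$df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

table_value <- function(tab, reaction, condition) {
  hit <- tab$df$value[tab$df$reaction == reaction & tab$df$condition == condition]
  if (length(hit) == 0L) NA_real_ else hit[[1L]]
}

#' Maximal in-vivo catalytic rate of a reaction
#'
#' The maximum across conditions of flux divided by enzyme abundance. Since
#' the enzyme need not be saturated even in its best condition, this is a
#' lower bound on the true maximal rate per enzyme unit — capacities built
#' on it are underestimates and saturations overestimates.
#'
#' @param flux A `"flux"` [condition_table()].
#' @param enzyme An `"enzyme"` [condition_table()].
#' @param reaction Reaction id present in both tables.
#' @return Rate per enzyme unit (a lower bound on the true turnover
#'   capability).
#' @export
max_in_vivo_rate <- function(flux, enzyme, reaction) {
  stopifnot(inherits(flux, "condition_table"), inherits(enzyme, "condition_table"))
  conds <- intersect(flux$conditions, enzyme$conditions)
  ratios <- numeric()
  for (cond in conds) {
    f <- table_value(flux, reaction, cond)
    e <- table_value(enzyme, reaction, cond)
    if (is.na(f) || is.na(e)) next
    if (e == 0) {
      if (f > 0) {
        stop(sprintf("inconsistent data: reaction '%s' carries flux with zero enzyme in '%s'",
                     reaction, cond), call. = FALSE)
      }
      next
    }
    if (f == 0 && e == 0) next
    ratios <- c(ratios, f / e)
  }
  if (length(ratios) == 0L || all(ratios == 0)) {
    stop(sprintf("no usable condition for reaction '%s'", reaction), call. = FALSE)
  }
  max(ratios)
}

#' Flux capacity and saturation of a reaction under one condition
#'
#' Capacity is the maximal in-vivo rate times the enzyme amount expressed
#' under the condition; saturation is the carried flux divided by that
#' capacity. By construction the condition attaining the maximal rate has
#' saturation exactly 1.
#'
#' @inheritParams max_in_vivo_rate
#' @param condition Condition id.
#' @return List with `capacity` and `saturation`.
#' @export
capacity_and_saturation <- function(flux, enzyme, reaction, condition) {
  rate <- max_in_vivo_rate(flux, enzyme, reaction)
  e <- table_value(enzyme, reaction, condition)
  f <- table_value(flux, reaction, condition)
  if (is.na(e) || is.na(f)) {
    stop(sprintf("reaction '%s' missing under condition '%s'", reaction, condition),
         call. = FALSE)
  }
  capacity <- rate * e
  sat <- if (capacity == 0) 0 else f / capacity
  if (sat > 1) {
    if (sat > 1 + 1e-9) {
      warning(sprintf("saturation %.3f > 1 for '%s'/'%s'; capped at 1",
                      sat, reaction, condition), call. = FALSE)
    }
    sat <- 1
  }
  list(capacity = capacity, saturation = sat)
}

#' Audit saturation at the branch points of a cycle
#'
#' For each branch point (a metabolite consumed both by a cycle reaction
#' and by a branch reaction out of the cycle), computes the estimated
#' saturations of the two reactions under the given condition and issues a
#' verdict: a functioning, stably operating autocatalytic cycle is
#' expected to keep its branch reactions less saturated (excess capacity)
#' than the competing cycle reactions.
#'
#' @inheritParams max_in_vivo_rate
#' @param branch_points Data frame with columns `metabolite`,
#'   `cycle_reaction`, `branch_reaction`.
#' @param condition Condition id to audit.
#' @param similar_band Relative band within which the two saturations are
#'   called `"similar"` (default 0.1).
#' @return List with `rows` (data frame: branch point, saturations,
#'   verdict) and `summary` (named verdict counts).
#' @export
audit_branch_points <- function(flux, enzyme, branch_points, condition,
                                similar_band = 0.1) {
  branch_points <- as.data.frame(branch_points)
  need <- c("metabolite", "cycle_reaction", "branch_reaction")
  if (!all(need %in% names(branch_points))) {
    stop(sprintf("branch_points must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(branch_points$cycle_reaction == branch_points$branch_reaction)) {
    stop("cycle and branch reaction must differ", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(branch_points)), function(i) {
    bp <- branch_points[i, ]
    s_cycle <- capacity_and_saturation(flux, enzyme, bp$cycle_reaction,
                                       condition)$saturation
    s_branch <- capacity_and_saturation(flux, enzyme, bp$branch_reaction,
                                        condition)$saturation
    verdict <- if (s_branch < s_cycle * (1 - similar_band)) {
      "branch_less_saturated"
    } else if (s_branch > s_cycle * (1 + similar_band)) {
      "branch_more_saturated"
    } else {
      "similar"
    }
    data.frame(metabolite = bp$metabolite,
               cycle_reaction = bp$cycle_reaction,
               branch_reaction = bp$branch_reaction,
               condition = condition,
               S_cycle = s_cycle, S_branch = s_branch,
               verdict = verdict)
  }))
  counts <- table(factor(rows$verdict,
                         levels = c("branch_less_saturated", "similar",
                                    "branch_more_saturated")))
  list(rows = rows, summary = as.list(counts))
}

# ---- allosteric regulation rules ---------------------------------------

REGULATOR_CLASSES <- c("cycle_intermediate", "assimilated_metabolite",
                       "branch_product")
TARGET_CLASSES <- c("cycle_reaction", "branch_reaction",
                    "reverse_branch_reaction")

#' Expected sign of an allosteric interaction on an autocatalytic cycle
#'
#' The rule table derived from the stability analysis: all three regulator
#' classes (cycle intermediates, the assimilated metabolite, and branch
#' products) are expected to inhibit cycle reactions and activate branch
#' reactions — pushing concentrations down toward the desired steady state
#' whenever intermediates accumulate. Reactions running opposite to branch
#' reactions (consuming branch products back into the cycle) are mirror
#' images of branches and carry the flipped sign.
#'
#' @param regulator_class One of `"cycle_intermediate"`,
#'   `"assimilated_metabolite"`, `"branch_product"`.
#' @param target_class One of `"cycle_reaction"`, `"branch_reaction"`,
#'   `"reverse_branch_reaction"`.
#' @return `"activation"` or `"inhibition"`.
#' @export
#' @examples
#' expected_regulation("cycle_intermediate", "branch_reaction")  # activation
expected_regulation <- function(regulator_class, target_class) {
  regulator_class <- match.arg(regulator_class, REGULATOR_CLASSES)
  target_class <- match.arg(target_class, TARGET_CLASSES)
  switch(target_class,
         cycle_reaction = "inhibition",
         branch_reaction = "activation",
         reverse_branch_reaction = "inhibition")
}

#' Audit a set of allosteric interactions against the expected rules
#'
#' @param edges Data frame with columns `regulator_class`, `target_class`,
#'   `sign` (`"activation"`/`"inhibition"`); extra columns (regulator and
#'   target names) are carried through.
#' @return List with `n_consistent`, `n_inconsistent`, and `rows` (the
#'   input with `expected` and `consistent` columns).
#' @export
audit_regulation <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    return(list(n_consistent = 0L, n_inconsistent = 0L, rows = edges))
  }
  need <- c("regulator_class", "target_class", "sign")
  if (!all(need %in% names(edges))) {
    stop(sprintf("edges must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(edges$sign %in% c("activation", "inhibition"))) {
    stop("sign must be 'activation' or 'inhibition'", call. = FALSE)
  }
  edges$expected <- mapply(expected_regulation, edges$regulator_class,
                           edges$target_class)
  edges$consistent <- edges$sign == edges$expected
  list(n_consistent = sum(edges$consistent),
       n_inconsistent = sum(!edges$consistent),
       rows = edges)
}
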