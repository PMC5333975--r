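# Bipartite metabolite-reaction graph machinery and the two complementary
# detectors of autocatalysis: a graph search (simple-cycle enumeration plus
# a three-way classification of candidate backbones) and a formal
# integer-multiplier verifier working directly on the stoichiometry.

REV_SUFFIX <- "__rev"

is_rev_id <- function(id) endsWith(id, REV_SUFFIX)
base_rid <- function(id) sub(paste0(REV_SUFFIX, "$"), "", id)

# Effective (direction-resolved) substrate/product maps for a reaction node id.
directed_reaction <- function(net, id) {
  r <- net$reactions[[base_rid(id)]]
  if (is.null(r)) stop(sprintf("unknown reaction id: %s", id), call. = FALSE)
  if (is_rev_id(id)) {
    if (!r$reversible) {
      stop(sprintf("reaction '%s' is not reversible", base_rid(id)), call. = FALSE)
    }
    list(id = id, substrates = r$products, products = r$substrates)
  } else {
    list(id = id, substrates = r$substrates, products = r$products)
  }
}

internal_ids <- function(net) {
  keep <- !vapply(net$metabolites, `[[`, logical(1), "is_external")
  names(net$metabolites)[keep]
}

#' Build the bipartite metabolite-reaction graph of a network
#'
#' Nodes are the internal metabolites and the (direction-resolved) reactions;
#' a substrate edge runs metabolite -> reaction and a product edge
#' reaction -> metabolite. Reversible reactions contribute two reaction
#' nodes, one per direction (`id` and `id__rev`). External metabolites are
#' not part of the graph and therefore never count as cycle intermediates.
#'
#' @param net A [metabolic_network()].
#' @return An object of class `"reaction_graph"` with fields `nodes`,
#'   `type` (`"metabolite"`/`"reaction"`), `adj` (successor lists) and
#'   `n_edges`.
#' @export
build_reaction_graph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- internal_ids(net)
  rnodes <- character()
  for (r in net$reactions) {
    rnodes <- c(rnodes, r$id, if (r$reversible) paste0(r$id, REV_SUFFIX))
  }
  nodes <- c(mids, rnodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  n_edges <- 0L
  for (rn in rnodes) {
    d <- directed_reaction(net, rn)
    for (m in intersect(names(d$substrates), mids)) {
      adj[[m]] <- c(adj[[m]], rn)
      n_edges <- n_edges + 1L
    }
    for (m in intersect(names(d$products), mids)) {
      adj[[rn]] <- c(adj[[rn]], m)
      n_edges <- n_edges + 1L
    }
  }
  structure(list(nodes = nodes,
                 type = stats::setNames(c(rep("metabolite", length(mids)),
                                          rep("reaction", length(rnodes))), nodes),
                 adj = adj, n_edges = n_edges, net = net),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph> %d metabolite nodes, %d reaction nodes, %d edges\n",
              sum(x$type == "metabolite"), sum(x$type == "reaction"), x$n_edges))
  invisible(x)
}

#' Enumerate simple cycles of the reaction graph
#'
#' Depth-first enumeration of all simple directed cycles with at most
#' `max_len` reaction nodes (Johnson-style: each cycle is reported once,
#' rooted at its smallest node, so rotations are deduplicated). Cycles that
#' use both directions of the same reversible reaction are discarded, as
#' are direction-variants of an already reported metabolite/reaction set.
#'
#' @param g A [build_reaction_graph()] result.
#' @param max_len Maximum number of reaction nodes per cycle (>= 2 allows
#'   two-reaction loops; a lumped single-reaction self-loop counts as 1).
#' @return A list of cycle candidates; each has `nodes` (closed alternating
#'   walk, first == last), `metabolites`, `reactions` (direction-resolved
#'   node ids) and `base_reactions`.
#' @export
enumerate_cycles <- function(g, max_len = 12L) {
  stopifnot(inherits(g, "reaction_graph"))
  if (max_len < 1L) stop("max_len must be >= 1", call. = FALSE)
  nodes <- g$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  out <- list()
  seen_keys <- character()

  for (start in nodes) {
    # root each cycle at its minimal-index node
    s_i <- idx[[start]]
    path <- character()
    on_path <- character()

    dfs <- function(v, n_reactions) {
      path <<- c(path, v)
      on_path <<- c(on_path, v)
      for (w in g$adj[[v]]) {
        if (idx[[w]] < s_i) next
        if (w == start) {
          cyc <- c(path, start)
          rn <- cyc[g$type[cyc] == "reaction"]
          bases <- base_rid(rn)
          if (anyDuplicated(bases)) next  # both directions of one reaction
          key <- paste(c(sort(unique(cyc[g$type[cyc] == "metabolite"])),
                         sort(unique(bases))), collapse = "|")
          if (!(key %in% seen_keys)) {
            seen_keys <<- c(seen_keys, key)
            out[[length(out) + 1L]] <<- list(
              nodes = cyc,
              metabolites = unique(cyc[g$type[cyc] == "metabolite"]),
              reactions = unique(rn),
              base_reactions = unique(bases))
          }
        } else if (!(w %in% on_path)) {
          n_r <- n_reactions + (g$type[[w]] == "reaction")
          if (n_r <= max_len) dfs(w, n_r)
        }
      }
      path <<- path[-length(path)]
      on_path <<- on_path[-length(on_path)]
    }

    dfs(start, as.integer(g$type[[start]] == "reaction"))
  }
  out
}

# Directed path search used by the branch-product test: can `from` reach any
# of `targets` without traversing `blocked` nodes?
reaches_any <- function(g, from, targets, blocked) {
  if (!(from %in% g$nodes)) return(FALSE)
  visited <- stats::setNames(logical(length(g$nodes)), g$nodes)
  queue <- from
  visited[from] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in g$adj[[v]]) {
      if (w %in% targets) return(TRUE)
      if (!visited[[w]] && !(w %in% blocked)) {
        visited[[w]] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

unit_stoichiometry <- function(net, reaction_node_ids) {
  all(vapply(reaction_node_ids, function(id) {
    d <- directed_reaction(net, id)
    all(d$substrates == 1) && all(d$products == 1) &&
      !any(names(d$substrates) %in% names(d$products))
  }, logical(1)))
}

#' Classify a cycle candidate as an autocatalytic backbone
#'
#' Implements the three-way screen applied to every enumerated graph cycle:
#' \enumerate{
#'   \item Reject if any cycle reaction consumes more than one cycle
#'     intermediate (closing such a cycle cannot gain material).
#'   \item Accept as `"multi_product"` if some cycle reaction produces more
#'     than one cycle intermediate.
#'   \item Accept as `"branch_product_path"` if some cycle reaction produces
#'     a metabolite outside the cycle from which a directed path returns to
#'     the cycle without using cycle reactions or consuming cycle
#'     intermediates.
#' }
#' The screen assumes unit stoichiometry (each reaction consumes/produces one
#' molecule of each of its substrates/products); candidates violating that
#' assumption are returned as `"needs_formal"` and left to
#' [verify_autocatalytic()].
#'
#' @param net A [metabolic_network()].
#' @param cand A cycle candidate from [enumerate_cycles()].
#' @param g Optional pre-built [build_reaction_graph()] (rebuilt if missing).
#' @return A list with `accepted` (logical), `classification` (one of
#'   `"multi_product"`, `"branch_product_path"`, `"needs_formal"`, or
#'   `"rejected"`) and `reason`.
#' @export
classify_cycle <- function(net, cand, g = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(g)) g <- build_reaction_graph(net)
  intermediates <- cand$metabolites
  rxn_nodes <- cand$reactions

  if (!unit_stoichiometry(net, rxn_nodes)) {
    return(list(accepted = FALSE, classification = "needs_formal",
                reason = "non-unit stoichiometry; use the formal verifier"))
  }

  dirs <- lapply(rxn_nodes, function(id) directed_reaction(net, id))

  # step 1: no cycle reaction may consume two intermediates
  for (d in dirs) {
    if (sum(names(d$substrates) %in% intermediates) > 1L) {
      return(list(accepted = FALSE, classification = "rejected",
                  reason = sprintf("reaction '%s' consumes more than one cycle intermediate", d$id)))
    }
  }

  # step 2: a reaction producing >1 intermediate grows the cycle directly
  for (d in dirs) {
    if (sum(names(d$products) %in% intermediates) > 1L) {
      return(list(accepted = TRUE, classification = "multi_product",
                  reason = sprintf("reaction '%s' produces %d cycle intermediates",
                                   d$id, sum(names(d$products) %in% intermediates))))
    }
  }

  # step 3: an external branch product that feeds back into the cycle
  blocked <- c(rxn_nodes, intermediates)
  for (d in dirs) {
    extra <- setdiff(names(d$products), intermediates)
    for (me in extra) {
      if (reaches_any(g, me, intermediates, blocked)) {
        return(list(accepted = TRUE, classification = "branch_product_path",
                    reason = sprintf("product '%s' of '%s' returns to the cycle", me, d$id)))
      }
    }
  }

  list(accepted = FALSE, classification = "rejected",
       reason = "no net gain of cycle intermediates")
}

# ---- formal verifier ---------------------------------------------------

# Net, gross-consumption and gross-production rows of the given (directed)
# reactions restricted to `mets`.
cycle_matrices <- function(net, reaction_ids, mets) {
  k <- length(reaction_ids)
  mk <- function() matrix(0, nrow = length(mets), ncol = k,
                          dimnames = list(mets, reaction_ids))
  cons <- mk(); prod <- mk()
  for (id in reaction_ids) {
    d <- directed_reaction(net, id)
    s <- d$substrates[names(d$substrates) %in% mets]
    p <- d$products[names(d$products) %in% mets]
    if (length(s)) cons[names(s), id] <- s
    if (length(p)) prod[names(p), id] <- p
  }
  list(cons = cons, prod = prod, net = prod - cons)
}

# Enumerate multiplier vectors in 1..max_multiplier^k by increasing total
# sum, calling `test(v)`; stops at the first sum level with hits and returns
# the lexicographically smallest hit (reaction order as supplied). Returns
# NULL when exhausted, or the string "budget" when the budget ran out.
search_multipliers <- function(k, max_multiplier, test, budget = 1e6) {
  tried <- 0L
  for (s in k:(k * max_multiplier)) {
    hits <- list()
    rec <- function(prefix, remaining, left) {
      if (tried > budget) return(invisible())
      if (remaining == 1L) {
        if (left >= 1L && left <= max_multiplier) {
          v <- c(prefix, left)
          tried <<- tried + 1L
          if (test(v)) hits[[length(hits) + 1L]] <<- v
        }
        return(invisible())
      }
      lo <- max(1L, left - (remaining - 1L) * max_multiplier)
      hi <- min(max_multiplier, left - (remaining - 1L))
      if (lo > hi) return(invisible())
      for (x in lo:hi) rec(c(prefix, x), remaining - 1L, left - x)
    }
    rec(integer(), k, s)
    if (tried > budget) return("budget")
    if (length(hits) > 0L) {
      ord <- do.call(order, as.data.frame(do.call(rbind, hits)))
      return(hits[[ord[1L]]])
    }
  }
  NULL
}

#' Formally verify that a reaction set is an autocatalytic cycle
#'
#' Searches for positive integer multipliers (each in `1..max_multiplier`)
#' under which the total reaction vector is non-negative on every cycle
#' intermediate and strictly positive on at least one; verifies the
#' sign condition (every intermediate is both produced and consumed by the
#' set, every reaction both consumes and produces intermediates) and
#' minimality (no proper nonempty subset admits such multipliers, which
#' excludes unions of disjoint cycles). The returned certificate is the
#' multiplier assignment of minimal total sum, ties broken lexicographically
#' in reaction-id order.
#'
#' @param net A [metabolic_network()].
#' @param reaction_ids Character vector of reaction ids forming the cycle;
#'   append `"__rev"` to use the reverse direction of a reversible reaction.
#' @param intermediates Character vector of internal metabolite ids forming
#'   the cycle. Defaults to all internal metabolites touched by the set.
#' @param max_multiplier Search bound per reaction (default 12).
#' @param gain Optional metabolite id: restrict certificates to assignments
#'   with a strict gain of that metabolite (e.g. `"atp"` to pick out ATP
#'   autocatalysis when a smaller certificate grows another intermediate).
#' @param search_budget Maximum number of multiplier vectors tested before
#'   the search is declared undecided.
#' @return An object of class `"autocatalytic_cycle"` (fields `multipliers`,
#'   `intermediates`, `net`, `consumed`, `produced`, `gain_metabolite`,
#'   `delta`, `classification`, `minimality_verified`), or `NULL` if the set
#'   is provably not an autocatalytic cycle within the bound, or the string
#'   `"undecided"` if the search budget was exhausted.
#' @export
#' @examples
#' net <- autocat_example("glyoxylate")
#' verify_autocatalytic(net, c("mal_to_icit", "icl_mas"))
verify_autocatalytic <- function(net, reaction_ids, intermediates = NULL,
                                 max_multiplier = 12L, gain = NULL,
                                 search_budget = 1e6) {
  stopifnot(inherits(net, "metabolic_network"))
  reaction_ids <- as.character(reaction_ids)
  if (length(reaction_ids) == 0L) stop("reaction_ids must be non-empty", call. = FALSE)
  if (anyDuplicated(base_rid(reaction_ids))) {
    stop("only one direction of a reversible reaction may be included", call. = FALSE)
  }
  if (max_multiplier < 1L) stop("max_multiplier must be >= 1", call. = FALSE)
  dirs <- lapply(reaction_ids, function(id) directed_reaction(net, id))
  if (is.null(intermediates)) {
    touched <- unique(unlist(lapply(dirs, function(d) {
      union(names(d$substrates), names(d$products))
    })))
    intermediates <- intersect(touched, internal_ids(net))
  }
  intermediates <- as.character(intermediates)
  if (length(intermediates) == 0L) stop("no intermediates to verify", call. = FALSE)
  unknown <- setdiff(intermediates, names(net$metabolites))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown intermediate(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(gain) && !(gain %in% intermediates)) {
    stop("'gain' must be one of the intermediates", call. = FALSE)
  }

  M <- cycle_matrices(net, reaction_ids, intermediates)

  # sign condition on gross stoichiometry: every intermediate produced and
  # consumed somewhere; every reaction consumes and produces intermediates
  row_ok <- rowSums(M$cons > 0) > 0 & rowSums(M$prod > 0) > 0
  col_ok <- colSums(M$cons > 0) > 0 & colSums(M$prod > 0) > 0
  if (!all(row_ok) || !all(col_ok)) return(NULL)

  ok <- function(v) {
    r <- drop(M$net %*% v)
    all(r >= 0) && any(r > 0) && (is.null(gain) || r[[gain]] > 0)
  }
  hit <- search_multipliers(length(reaction_ids), max_multiplier, ok,
                            budget = search_budget)
  if (identical(hit, "budget")) return("undecided")
  if (is.null(hit)) return(NULL)

  # minimality: no proper nonempty subset may itself be an autocatalytic
  # cycle (sign conditions on its own touched intermediates plus a
  # non-negative gaining assignment); this excludes unions of disjoint
  # cycles without rejecting branch-product return paths
  k <- length(reaction_ids)
  minimality_verified <- k <= 12L
  if (minimality_verified && k > 1L) {
    for (mask in 1:(2^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      if (!any(sel)) next
      cons_s <- M$cons[, sel, drop = FALSE]
      prod_s <- M$prod[, sel, drop = FALSE]
      touched <- rowSums(cons_s) + rowSums(prod_s) > 0
      if (!any(touched)) next
      r_ok <- rowSums(cons_s[touched, , drop = FALSE] > 0) > 0 &
        rowSums(prod_s[touched, , drop = FALSE] > 0) > 0
      c_ok <- colSums(cons_s[touched, , drop = FALSE] > 0) > 0 &
        colSums(prod_s[touched, , drop = FALSE] > 0) > 0
      if (!all(r_ok) || !all(c_ok)) next
      Msub <- M$net[touched, sel, drop = FALSE]
      sub_ok <- function(v) {
        r <- drop(Msub %*% v)
        all(r >= 0) && any(r > 0)
      }
      sub_hit <- search_multipliers(sum(sel), max_multiplier, sub_ok,
                                    budget = search_budget)
      if (!is.null(sub_hit) && !identical(sub_hit, "budget")) return(NULL)
    }
  }

  mult <- stats::setNames(as.integer(hit), reaction_ids)
  net_vec <- drop(M$net %*% hit)
  consumed <- drop(M$cons %*% hit)
  produced <- drop(M$prod %*% hit)
  ref <- intermediates[which.max(net_vec)]
  structure(
    list(multipliers = mult,
         intermediates = intermediates,
         net = net_vec,
         consumed = consumed,
         produced = produced,
         gain_metabolite = ref,
         delta = unname(net_vec[[ref]] / consumed[[ref]]),
         classification = "formal_only",
         minimality_verified = minimality_verified),
    class = "autocatalytic_cycle")
}

#' @export
print.autocatalytic_cycle <- function(x, ...) {
  cat(sprintf("<autocatalytic_cycle> %s\n",
              paste(sprintf("%s x%d", names(x$multipliers), x$multipliers),
                    collapse = ", ")))
  cat(sprintf("  intermediates: %s\n", paste(x$intermediates, collapse = ", ")))
  gains <- x$net[x$net > 0]
  cat(sprintf("  net gain: %s; delta = %g (%s); classification: %s\n",
              paste(sprintf("%s %+g", names(gains), gains), collapse = ", "),
              x$delta, x$gain_metabolite, x$classification))
  invisible(x)
}

#' Find autocatalytic cycles in a network
#'
#' Composition of the graph search and the formal verifier: cofactors are
#' stripped, simple cycles of the bipartite graph are enumerated, each
#' candidate backbone is classified ([classify_cycle()]) and its reaction
#' set is handed to [verify_autocatalytic()] for an integer-multiplier
#' certificate. A candidate is reported if the classifier accepts it or the
#' verifier certifies it; the certificate (multipliers, net gain, delta) is
#' attached when computable.
#'
#' @param net A [metabolic_network()].
#' @param max_len Maximum number of reactions per cycle (default 12; compact
#'   cycles in central metabolism have around ten reactions or fewer).
#' @param max_multiplier Multiplier search bound (default 12).
#' @param cofactors Metabolite ids to strip first (default: the network's
#'   `is_cofactor` flags).
#' @return A list of `autocatalytic_cycle` objects, each with an extra
#'   `reactions_path`/`classification` describing the graph hit. Cycles the
#'   verifier could not decide within budget carry `certificate = NULL` and
#'   `undecided = TRUE`.
#' @export
#' @examples
#' find_autocatalytic_cycles(autocat_example("pts"), cofactors = c("atp", "adp"))
find_autocatalytic_cycles <- function(net, max_len = 12L, max_multiplier = 12L,
                                      cofactors = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(cofactors)) {
    cofactors <- names(net$metabolites)[vapply(net$metabolites, `[[`,
                                               logical(1), "is_cofactor")]
  }
  work <- if (length(cofactors) > 0L) strip_cofactors(net, cofactors) else net
  g <- build_reaction_graph(work)
  cands <- enumerate_cycles(g, max_len = max_len)
  out <- list()
  seen <- character()
  for (cand in cands) {
    cls <- classify_cycle(work, cand, g = g)
    cert <- verify_autocatalytic(work, cand$reactions,
                                 intermediates = cand$metabolites,
                                 max_multiplier = max_multiplier)
    undecided <- identical(cert, "undecided")
    if (undecided) cert <- NULL
    if (!cls$accepted && is.null(cert)) next
    key <- paste(c(sort(cand$base_reactions), sort(cand$metabolites)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    hit <- if (!is.null(cert)) {
      cert$classification <- if (cls$accepted) cls$classification else "formal_only"
      cert
    } else {
      structure(list(multipliers = NULL, intermediates = cand$metabolites,
                     net = NULL, consumed = NULL, produced = NULL,
                     gain_metabolite = NA_character_, delta = NA_real_,
                     classification = cls$classification,
                     minimality_verified = FALSE),
                class = "autocatalytic_cycle")
    }
    hit$reactions_path <- cand$reactions
    hit$undecided <- undecided
    out[[length(out) + 1L]] <- hit
  }
  out
}
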