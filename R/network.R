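#' Construct a metabolite
#'
#' Metabolites are the nodes of a stoichiometric metabolic network. External
#' metabolites sit outside the modelled system boundary (e.g. an assimilated
#' carbon source held at constant concentration) and are never counted as
#' cycle intermediates; cofactors (ATP, NAD(P)H, CoA, ...) can be stripped
#' before cycle detection.
#'
#' @param id Short unique identifier (non-empty string).
#' @param name Free-text name; defaults to `id`.
#' @param is_cofactor Logical; cofactor flag used by [strip_cofactors()].
#' @param is_external Logical; `TRUE` for metabolites outside the system
#'   boundary.
#' @return An object of class `"metabolite"`.
#' @seealso [reaction()], [metabolic_network()]
#' @export
#' @examples
#' metabolite("mal", "malate")
metabolite <- function(id, name = id, is_cofactor = FALSE, is_external = FALSE) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("metabolite 'id' must be a non-empty string", call. = FALSE)
  }
  structure(
    list(id = id, name = as.character(name)[1L],
         is_cofactor = isTRUE(is_cofactor), is_external = isTRUE(is_external)),
    class = "metabolite"
  )
}

#' Construct a reaction
#'
#' A reaction converts substrates into products with positive stoichiometric
#' coefficients. A metabolite may appear on both sides of a lumped reaction
#' (e.g. a carbon-fixation lump consuming 5 five-carbon units and producing
#' 6); the stoichiometric matrix then carries the net coefficient while the
#' gross substrate/product maps are retained for consumption accounting.
#'
#' @param id Short unique identifier.
#' @param substrates Named numeric vector of positive coefficients
#'   (names are metabolite ids). May be empty.
#' @param products Named numeric vector of positive coefficients.
#' @param reversible Logical; reversible reactions are split into two
#'   irreversible directions before graph-based cycle detection.
#' @return An object of class `"reaction"`.
#' @export
#' @examples
#' reaction("icl_mas", c(icit = 1, accoa = 1), c(mal = 2))
reaction <- function(id, substrates = numeric(), products = numeric(),
                     reversible = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction 'id' must be a non-empty string", call. = FALSE)
  }
  substrates <- validate_coeffs(substrates, id, "substrate")
  products <- validate_coeffs(products, id, "product")
  if (length(substrates) == 0L && length(products) == 0L) {
    stop(sprintf("reaction '%s' has neither substrates nor products", id),
         call. = FALSE)
  }
  structure(
    list(id = id, substrates = substrates, products = products,
         reversible = isTRUE(reversible)),
    class = "reaction"
  )
}

validate_coeffs <- function(x, rid, side) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(sprintf("reaction '%s': %s coefficients must be named by metabolite id",
                 rid, side), call. = FALSE)
  }
  x <- vapply(stats::setNames(as.numeric(x), names(x)), identity, numeric(1))
  if (anyDuplicated(names(x))) {
    stop(sprintf("reaction '%s': duplicated %s metabolite", rid, side),
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("reaction '%s': %s coefficients must be positive", rid, side),
         call. = FALSE)
  }
  if (any(abs(x - round(x)) > 1e-9)) {
    stop(sprintf("reaction '%s': %s coefficients must be integer-valued", rid, side),
         call. = FALSE)
  }
  round(x)
}

#' Construct a metabolic network
#'
#' Bundles metabolites and reactions and validates cross-references. The
#' stoichiometric matrix view (rows = metabolites, columns = reactions,
#' entries = product minus substrate coefficient) is available through
#' [stoich_matrix()] and is losslessly reconstructible from the reactions.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects referencing only declared
#'   metabolites.
#' @return An object of class `"metabolic_network"` with fields
#'   `metabolites` (named list) and `reactions` (named list).
#' @export
#' @examples
#' net <- metabolic_network(
#'   list(metabolite("a"), metabolite("b")),
#'   list(reaction("r1", c(a = 1), c(b = 1)))
#' )
#' stoich_matrix(net)
metabolic_network <- function(metabolites = list(), reactions = list()) {
  stopifnot(is.list(metabolites), is.list(reactions))
  for (m in metabolites) {
    if (!inherits(m, "metabolite")) stop("all metabolites must be metabolite objects", call. = FALSE)
  }
  for (r in reactions) {
    if (!inherits(r, "reaction")) stop("all reactions must be reaction objects", call. = FALSE)
  }
  mids <- vapply(metabolites, `[[`, character(1), "id")
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(mids)) {
    stop(sprintf("duplicate metabolite id: %s", mids[duplicated(mids)][1L]), call. = FALSE)
  }
  if (anyDuplicated(rids)) {
    stop(sprintf("duplicate reaction id: %s", rids[duplicated(rids)][1L]), call. = FALSE)
  }
  for (r in reactions) {
    ref <- union(names(r$substrates), names(r$products))
    missing <- setdiff(ref, mids)
    if (length(missing) > 0L) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(metabolites = stats::setNames(metabolites, mids),
         reactions = stats::setNames(reactions, rids)),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  next_ <- sum(vapply(x$metabolites, `[[`, logical(1), "is_external"))
  nrev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat(sprintf("<metabolic_network> %d metabolites (%d external), %d reactions (%d reversible)\n",
              length(x$metabolites), next_, length(x$reactions), nrev))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param net A [metabolic_network()].
#' @return Numeric matrix, rows named by metabolite ids, columns by reaction
#'   ids; entry is the net production coefficient (products minus substrates).
#' @export
stoich_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- names(net$metabolites)
  rids <- names(net$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in net$reactions) {
    S[names(r$substrates), r$id] <- S[names(r$substrates), r$id] - r$substrates
    S[names(r$products), r$id] <- S[names(r$products), r$id] + r$products
  }
  S
}

#' Default cofactor list
#'
#' Common currency metabolites stripped before cycle detection in
#' core-model-like networks. User-overridable everywhere it is used.
#'
#' @return Character vector of metabolite ids.
#' @export
default_cofactors <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa", "pi",
    "h2o", "h", "co2")
}

#' Remove cofactors from a network
#'
#' Deletes the given metabolites from every substrate/product map and drops
#' reactions left with empty substrate and product sets, mirroring the
#' preprocessing step of graph-based autocatalytic cycle identification.
#'
#' @param net A [metabolic_network()].
#' @param cofactor_ids Character vector of metabolite ids to remove; must be
#'   a subset of the network's metabolites.
#' @return A new `metabolic_network` without the named metabolites.
#' @export
strip_cofactors <- function(net, cofactor_ids) {
  stopifnot(inherits(net, "metabolic_network"))
  cofactor_ids <- as.character(cofactor_ids)
  unknown <- setdiff(cofactor_ids, names(net$metabolites))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown metabolite id(s) in cofactor_ids: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep_m <- net$metabolites[setdiff(names(net$metabolites), cofactor_ids)]
  new_r <- list()
  for (r in net$reactions) {
    subs <- r$substrates[setdiff(names(r$substrates), cofactor_ids)]
    prods <- r$products[setdiff(names(r$products), cofactor_ids)]
    if (length(subs) == 0L && length(prods) == 0L) next
    new_r[[length(new_r) + 1L]] <- reaction(r$id, subs, prods, r$reversible)
  }
  metabolic_network(unname(keep_m), new_r)
}

#' Multiplicity-weighted net reaction vector
#'
#' Computes the total reaction vector r* = sum_l i_l * V_rl, the sum of the
#' network's stoichiometric columns weighted by positive integer
#' multiplicities. This is the quantity whose non-negativity on cycle
#' intermediates (with a strict gain somewhere) certifies autocatalysis.
#'
#' @param net A [metabolic_network()].
#' @param multiplicities Named numeric vector (names are reaction ids,
#'   values positive integers).
#' @return Named numeric vector over all network metabolites.
#' @export
#' @examples
#' # one extra malate per glyoxylate-shunt traversal
#' net <- autocat_example("glyoxylate")
#' net_reaction_vector(net, c(mal_to_icit = 1, icl_mas = 1))
net_reaction_vector <- function(net, multiplicities) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(multiplicities) == 0L) stop("multiplicities must be non-empty", call. = FALSE)
  rid <- names(multiplicities)
  if (is.null(rid) || any(!nzchar(rid))) {
    stop("multiplicities must be named by reaction id", call. = FALSE)
  }
  unknown <- setdiff(rid, names(net$reactions))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown reaction id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  m <- as.numeric(multiplicities)
  if (any(!is.finite(m)) || any(m <= 0) || any(abs(m - round(m)) > 1e-9)) {
    stop("multiplicities must be positive integers", call. = FALSE)
  }
  S <- stoich_matrix(net)
  drop(S[, rid, drop = FALSE] %*% round(m))
}

# ---- I/O ---------------------------------------------------------------

#' Load a metabolic network from file
#'
#' Supported formats:
#' \describe{
#'   \item{json}{Schema written by [write_network()]: top-level `metabolites`
#'     (id, name, is_cofactor, is_external) and `reactions` (id, substrates,
#'     products as id -> coefficient maps, reversible).}
#'   \item{tsv}{One reaction per line: `id <TAB> substrates <TAB> products`,
#'     sides as `+`-separated terms with optional `2*` coefficient prefixes
#'     (e.g. `icl_mas<TAB>icit + accoa<TAB>2*mal`). Metabolites are declared
#'     implicitly; ids listed on an optional header line
#'     `#external: id1,id2` are marked external, `#cofactors:` likewise.}
#'   \item{sbml}{SBML level-3 core stoichiometry (kinetics ignored);
#'     `boundaryCondition` species become external metabolites.}
#' }
#'
#' @param path Path to the file.
#' @param format One of `"json"`, `"tsv"`, `"sbml"`; default guesses from the
#'   file extension.
#' @return A [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop(sprintf("cannot guess format from extension '.%s'", ext),
                          call. = FALSE))
  }
  switch(format,
         json = load_network_json(path),
         tsv = load_network_tsv(path),
         sbml = read_sbml_network(path))
}

load_network_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop(sprintf("malformed JSON in %s: %s",
                                                 path, conditionMessage(e)),
                                         call. = FALSE))
  mets <- lapply(x$metabolites, function(m) {
    if (is.null(m$id)) stop(sprintf("metabolite record without 'id' in %s", path), call. = FALSE)
    metabolite(m$id, name = m$name %||% m$id,
               is_cofactor = isTRUE(m$is_cofactor),
               is_external = isTRUE(m$is_external))
  })
  rxns <- lapply(x$reactions, function(r) {
    if (is.null(r$id)) stop(sprintf("reaction record without 'id' in %s", path), call. = FALSE)
    reaction(r$id,
             substrates = unlist_coeffs(r$substrates),
             products = unlist_coeffs(r$products),
             reversible = isTRUE(r$reversible))
  })
  metabolic_network(mets, rxns)
}

unlist_coeffs <- function(x) {
  if (is.null(x) || length(x) == 0L) return(numeric())
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

parse_side <- function(s, rid) {
  s <- trimws(s)
  if (!nzchar(s)) return(numeric())
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
  out <- numeric()
  add <- function(id, coef) {
    prev <- if (id %in% names(out)) out[[id]] else 0
    out[[id]] <<- prev + coef
  }
  for (t in terms) {
    if (grepl("*", t, fixed = TRUE)) {
      parts <- trimws(strsplit(t, "*", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[1L])))) {
        stop(sprintf("reaction '%s': cannot parse term '%s'", rid, t), call. = FALSE)
      }
      add(parts[2L], as.numeric(parts[1L]))
    } else {
      add(t, 1)
    }
  }
  out
}

load_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  external <- character()
  cofactors <- character()
  body <- character()
  for (ln in lines) {
    if (startsWith(ln, "#external:")) {
      external <- trimws(strsplit(sub("^#external:", "", ln), ",")[[1L]])
    } else if (startsWith(ln, "#cofactors:")) {
      cofactors <- trimws(strsplit(sub("^#cofactors:", "", ln), ",")[[1L]])
    } else if (!startsWith(ln, "#")) {
      body <- c(body, ln)
    }
  }
  rxns <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed TSV reaction line (need 3 tab-separated fields): '%s'", ln),
           call. = FALSE)
    }
    rev <- length(f) >= 4L && trimws(f[4L]) %in% c("reversible", "true", "TRUE", "1")
    reaction(trimws(f[1L]), parse_side(f[2L], f[1L]), parse_side(f[3L], f[1L]),
             reversible = rev)
  })
  mids <- sort(unique(unlist(lapply(rxns, function(r) union(names(r$substrates), names(r$products))))))
  mets <- lapply(mids, function(id) {
    metabolite(id, is_cofactor = id %in% cofactors, is_external = id %in% external)
  })
  metabolic_network(mets, rxns)
}

#' Write a metabolic network to JSON
#'
#' Inverse of [load_network()] for the JSON format: `load_network(write_network(net))`
#' reproduces `net` exactly.
#'
#' @param net A [metabolic_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  x <- list(
    metabolites = lapply(unname(net$metabolites), function(m) {
      list(id = m$id, name = m$name, is_cofactor = m$is_cofactor,
           is_external = m$is_external)
    }),
    reactions = lapply(unname(net$reactions), function(r) {
      list(id = r$id,
           substrates = as.list(r$substrates),
           products = as.list(r$products),
           reversible = r$reversible)
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged example networks
#'
#' Small lumped encodings of the autocatalytic cycles of central carbon
#' metabolism used throughout the package documentation and tests:
#' \describe{
#'   \item{glyoxylate}{Glyoxylate shunt lumped to two reactions: malate (plus
#'     an external acetyl-CoA) to isocitrate, and isocitrate cleavage plus
#'     malate synthase (second acetyl-CoA) to two malates.}
#'   \item{pts}{Glucose assimilation by the phosphotransferase system fuelled
#'     by pep, with lower glycolysis lumped to g6p -> 2 pep.}
#'   \item{glycolysis_atp}{ATP autocatalysis in glycolysis: a priming lump
#'     investing 2 ATP per glucose and a payoff lump returning 2 ATP per
#'     triose phosphate.}
#'   \item{cbb}{Carbon-fixation (Calvin-Benson-Bassham) lump: 5 five-carbon
#'     units + 5 CO2 -> 6 five-carbon units.}
#' }
#'
#' @param name One of `"glyoxylate"`, `"pts"`, `"glycolysis_atp"`, `"cbb"`.
#' @param path_only If `TRUE` return the path of the packaged JSON file
#'   instead of the loaded network.
#' @return A [metabolic_network()], or a file path.
#' @export
#' @examples
#' autocat_example("pts")
autocat_example <- function(name = c("glyoxylate", "pts", "glycolysis_atp", "cbb"),
                            path_only = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "autocat",
                      mustWork = TRUE)
  if (path_only) return(path)
  load_network(path, "json")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
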