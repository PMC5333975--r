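#' Read an SBML model as a metabolic network
#'
#' Minimal SBML level-3 core reader: species ids, `boundaryCondition`
#' (mapped to external metabolites), reactions with their
#' `speciesReference` stoichiometries and the `reversible` flag. Kinetic
#' laws, compartments, units and annotations are ignored.
#'
#' @param path Path to an SBML (XML) file.
#' @return A [metabolic_network()].
#' @export
read_sbml_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("malformed SBML in %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(species) == 0L) stop(sprintf("no species found in %s", path), call. = FALSE)
  mets <- lapply(species, function(sp) {
    id <- xml2::xml_attr(sp, "id")
    if (is.na(id)) stop(sprintf("species without id in %s", path), call. = FALSE)
    metabolite(id,
               name = xml2::xml_attr(sp, "name") %na% id,
               is_external = identical(xml2::xml_attr(sp, "boundaryCondition"), "true"))
  })
  rxnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rxnodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    if (is.na(id)) stop(sprintf("reaction without id in %s", path), call. = FALSE)
    side <- function(xpath) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      if (length(refs) == 0L) return(numeric())
      ids <- xml2::xml_attr(refs, "species")
      st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      st[is.na(st)] <- 1
      stats::setNames(st, ids)
    }
    reaction(id,
             substrates = side("./s:listOfReactants/s:speciesReference"),
             products = side("./s:listOfProducts/s:speciesReference"),
             reversible = identical(xml2::xml_attr(rx, "reversible"), "true"))
  })
  metabolic_network(mets, rxns)
}

`%na%` <- function(a, b) if (is.na(a)) b else a
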