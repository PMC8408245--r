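# Lightweight SBML Level 3 (+fbc) reader and writer built on xml2.
#
# Covers the subset needed for constraint-based models: species (id, name,
# compartment), reactions with stoichiometries and reversibility, flux
# bounds through fbc parameters (with a COBRA-style Level 2 kinetic-law
# fallback), the active fbc objective, mass-action kinetic laws on export,
# and provenance notes so reduced models keep their original reaction ids.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Read an SBML model
#'
#' Parses SBML Level 3 (fbc flux bounds and objective honoured) or Level 2
#' (bounds from COBRA-style kinetic-law parameters). Missing bounds default
#' to `[0, Inf)` for irreversible and `(-Inf, Inf)` for reversible reactions,
#' with a warning; reversibility is preserved so the model can be split
#' afterwards.
#'
#' @param path SBML file.
#' @return a `network_model` (pre-split: reversible flags and negative lower
#'   bounds retained).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), xml2::xml_attr(sp_nodes, "id")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"))

  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) rlang::abort("no reactions found; not a valid SBML model?")
  side_of <- function(node, tag) {
    refs <- xml2::xml_find_all(
      node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
    if (length(refs) == 0L) return(stats::setNames(numeric(0), character(0)))
    st <- xml2::xml_attr(refs, "stoichiometry")
    st[is.na(st)] <- "1"
    stats::setNames(as.numeric(st), xml2::xml_attr(refs, "species"))
  }
  bound_of <- function(node, which) {
    ref <- xml2::xml_attr(node, paste0(which, "FluxBound"))  # fbc attribute
    if (!is.na(ref) && ref %in% names(pval)) return(pval[[ref]])
    kl <- xml2::xml_find_first(
      node, sprintf(".//*[local-name()='parameter'][@id='%s_BOUND']",
                    toupper(which)))
    if (!inherits(kl, "xml_missing")) return(as.numeric(xml2::xml_attr(kl, "value")))
    NA_real_
  }

  n <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  reversible <- is.na(rev_attr) | rev_attr == "true"
  lb <- ub <- rep(NA_real_, n)
  subs <- vector("list", n); prods <- vector("list", n)
  prov <- vector("list", n)
  for (i in seq_len(n)) {
    subs[[i]] <- side_of(rx_nodes[[i]], "listOfReactants")
    prods[[i]] <- side_of(rx_nodes[[i]], "listOfProducts")
    lb[i] <- bound_of(rx_nodes[[i]], "lower")
    ub[i] <- bound_of(rx_nodes[[i]], "upper")
    note <- xml2::xml_find_first(rx_nodes[[i]], ".//*[local-name()='notes']")
    prov[[i]] <- if (!inherits(note, "xml_missing")) {
      txt <- xml2::xml_text(note)
      m <- regmatches(txt, regexpr("provenance:[^\n]*", txt))
      if (length(m)) trimws(strsplit(sub("provenance:", "", m), ",")[[1]]) else ids[i]
    } else ids[i]
  }
  if (anyNA(lb) || anyNA(ub)) {
    rlang::warn("missing flux bounds; using defaults (0/Inf irreversible, -Inf/Inf reversible)")
    lb[is.na(lb)] <- ifelse(reversible[is.na(lb)], -Inf, 0)
    ub[is.na(ub)] <- Inf
  }

  obj_node <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  objective <- if (!inherits(obj_node, "xml_missing")) {
    xml2::xml_attr(obj_node, "reaction")
  } else NULL

  rxn <- tibble::tibble(id = ids, substrates = subs, products = prods,
                        lb = lb, ub = ub, reversible = reversible,
                        provenance = prov)
  build_complexes(rxn, species = species, objective = objective)
}

sbml_escape <- function(x) gsub("&", "&amp;", x)

#' Write an SBML Level 3 model
#'
#' Serializes a model with fbc flux bounds and objective; provenance
#' (contributing original reaction ids) is written to each reaction's notes,
#' and, when kinetics are given, mass-action kinetic laws
#' `k * prod(substrates^stoichiometry)` are attached with the (rescaled)
#' constants as local parameters.
#'
#' @param model a `network_model`.
#' @param path output file.
#' @param kinetics optional named numeric rate constants.
#' @return the path, invisibly.
#' @export
write_sbml <- function(model, path, kinetics = NULL) {
  stopifnot(inherits(model, "network_model"))
  comp <- unique(model$species$compartment)
  comp[is.na(comp) | comp == ""] <- "c"
  comp <- unique(comp)
  sp_comp <- model$species$compartment
  sp_comp[is.na(sp_comp) | sp_comp == ""] <- "c"

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="false">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', comp),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  lines <- c(lines, sprintf(
    '      <species id="%s" name="%s" compartment="%s" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    model$species$id, sbml_escape(model$species$name), sp_comp),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  rxn <- model$reactions
  lines <- c(lines,
    sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>', rxn$id, fmt17(rxn$lb)),
    sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>', rxn$id,
            ifelse(is.finite(rxn$ub), fmt17(rxn$ub), "INF")),
    '    </listOfParameters>',
    '    <listOfReactions>')

  for (i in seq_len(nrow(rxn))) {
    sub <- model$complexes$composition[[rxn$substrate[i]]]
    prod <- model$complexes$composition[[rxn$product[i]]]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      rxn$id[i], tolower(as.character(rxn$reversible[i])), rxn$id[i], rxn$id[i]))
    prov <- paste(rxn$provenance[[i]], collapse = ",")
    lines <- c(lines,
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>provenance: %s</p>', sbml_escape(prov)),
      '        </body></notes>')
    if (length(sub)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                names(sub), fmt17(unname(sub))),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                names(prod), fmt17(unname(prod))),
        '        </listOfProducts>')
    }
    if (!is.null(kinetics) && rxn$id[i] %in% names(kinetics)) {
      terms <- if (length(sub)) {
        paste0(vapply(seq_along(sub), function(s) {
          if (sub[[s]] == 1) sprintf('<ci>%s</ci>', names(sub)[s])
          else sprintf('<apply><power/><ci>%s</ci><cn>%s</cn></apply>',
                       names(sub)[s], fmt17(unname(sub[[s]])))
        }, ""), collapse = "")
      } else ""
      lines <- c(lines,
        '        <kineticLaw>',
        sprintf('          <math xmlns="%s"><apply><times/><ci>k</ci>%s</apply></math>', MATHML_NS, terms),
        '          <listOfLocalParameters>',
        sprintf('            <localParameter id="k" value="%s"/>', fmt17(unname(kinetics[[rxn$id[i]]]))),
        '          </listOfLocalParameters>',
        '        </kineticLaw>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.na(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', model$objective),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  # parse back immediately so malformed output fails loudly at write time
  xml2::read_xml(path)
  invisible(path)
}
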