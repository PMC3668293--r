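#' SBML Level 3 export
#'
#' Writes the assembled network as SBML L3V2 with explicit MathML kinetic
#' laws (amounts in particle numbers, `hasOnlySubstanceUnits = true`, time
#' in minutes), so third-party simulators reproduce the rate laws without
#' SBO shortcut semantics. Boundary species carry the boundary-condition
#' flag. A private annotation records the rate-law family and constants;
#' [read_sbml()] uses it to round-trip this package's own exports.
#'
#' @param model An [new_model()] object.
#' @param path Output file path.
#' @param model_id SBML model id.
#' @return Invisibly, the path.
#' @export
write_sbml <- function(model, path, model_id = "insox_model") {
  ok <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", model$species$name)
  if (!all(ok)) {
    stop("invalid SBML identifiers: ",
         paste(model$species$name[!ok], collapse = ", "), call. = FALSE)
  }
  esc <- function(x) gsub("&", "&amp;", x)
  ln <- character()
  push <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
       'level="3" version="2">')
  push('  <model id="', model_id, '" substanceUnits="item" timeUnits="minute">')
  push('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments))) {
    push('      <compartment id="', model$compartments$name[i],
         '" size="', format(model$compartments$volume[i], digits = 17),
         '" spatialDimensions="3" constant="true"/>')
  }
  push('    </listOfCompartments>')
  push('    <listOfSpecies>')
  for (i in seq_len(nrow(model$species))) {
    push('      <species id="', model$species$name[i],
         '" compartment="', model$species$compartment[i],
         '" initialAmount="', format(model$species$amount[i], digits = 17),
         '" hasOnlySubstanceUnits="true" boundaryCondition="',
         tolower(model$species$boundary[i]), '" constant="false">')
    push('        <annotation><insox:species ',
         'xmlns:insox="https://example.org/insox" scale="',
         model$species$scale[i], '"/></annotation>')
    push('      </species>')
  }
  push('    </listOfSpecies>')
  push('    <listOfReactions>')
  for (r in model$reactions) {
    push('      <reaction id="', r$id, '" reversible="false">')
    # collapse repeated names into stoichiometry but keep declaration order,
    # so a round-tripped model rebuilds the identical state/flux layout
    collapse <- function(x) {
      r <- rle(x)
      data.frame(species = r$values, stoich = r$lengths,
                 stringsAsFactors = FALSE)
    }
    if (length(r$reactants)) {
      push('        <listOfReactants>')
      tab <- collapse(r$reactants)
      for (q in seq_len(nrow(tab))) {
        push('          <speciesReference species="', tab$species[q],
             '" stoichiometry="', tab$stoich[q], '" constant="true"/>')
      }
      push('        </listOfReactants>')
    }
    if (length(r$products)) {
      push('        <listOfProducts>')
      tab <- collapse(r$products)
      for (q in seq_len(nrow(tab))) {
        push('          <speciesReference species="', tab$species[q],
             '" stoichiometry="', tab$stoich[q], '" constant="true"/>')
      }
      push('        </listOfProducts>')
    }
    if (length(r$modifiers)) {
      push('        <listOfModifiers>')
      for (nm in r$modifiers) {
        push('          <modifierSpeciesReference species="', nm, '"/>')
      }
      push('        </listOfModifiers>')
    }
    cst <- r$law$constants
    cst_attr <- paste(vapply(names(cst), function(nm) {
      paste0(nm, '="', format(cst[[nm]], digits = 17), '"')
    }, character(1)), collapse = " ")
    push('        <kineticLaw>')
    push('          <annotation><insox:law ',
         'xmlns:insox="https://example.org/insox" kind="', r$law$kind,
         '" ', esc(cst_attr), '/></annotation>')
    push('          <math xmlns="http://www.w3.org/1998/Math/MathML">')
    push(.law_mathml(r, indent = "            "))
    push('          </math>')
    push('          <listOfLocalParameters>')
    for (nm in names(cst)) {
      push('            <localParameter id="', nm, '" value="',
           format(cst[[nm]], digits = 17), '"/>')
    }
    push('          </listOfLocalParameters>')
    push('        </kineticLaw>')
    push('      </reaction>')
  }
  push('    </listOfReactions>')
  push('  </model>')
  push('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

# MathML for one reaction's rate law (particle-number semantics)
.law_mathml <- function(r, indent = "") {
  ci <- function(x) paste0("<ci> ", x, " </ci>")
  ap <- function(op, ...) {
    paste0("<apply><", op, "/>", paste0(...), "</apply>")
  }
  reac <- paste0(vapply(r$reactants, ci, character(1)), collapse = "")
  msum <- if (length(r$modifiers) > 1) {
    ap("plus", paste0(vapply(r$modifiers, ci, character(1)), collapse = ""))
  } else if (length(r$modifiers) == 1) {
    ci(r$modifiers)
  } else ""
  body <- switch(r$law$kind,
    zero_order = ci("k"),
    mass_action = ap("times", ci("k"), reac),
    catalytic = ap("times", ci("k"), msum, reac),
    synthesis = ap("times", ci("k"), msum),
    offset_mass_action = ap("times", ci("k"), reac,
      ap("max", "<cn> 0 </cn>", ap("minus", msum, ci("offset")))),
    michaelis_menten = ap("divide",
      ap("times", ci("kcat"), msum, ci(r$reactants[1])),
      ap("plus", ci("Km"), ci(r$reactants[1]))),
    transcription = ap("plus", ci("k_basal"),
                       ap("times", ci("k_stim"), msum)))
  paste0(indent, body)
}

#' Read back an SBML file written by [write_sbml()]
#'
#' Import is limited to round-tripping this package's own exports: rate
#' laws are reconstructed from the embedded annotation, not from arbitrary
#' MathML.
#'
#' @param path SBML file path.
#' @return An [new_model()] object.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          i = "https://example.org/insox")
  comp_nodes <- xml2::xml_find_all(doc, ".//s:compartment", ns)
  compartments <- data.frame(
    name = xml2::xml_attr(comp_nodes, "id"),
    volume = as.numeric(xml2::xml_attr(comp_nodes, "size")),
    stringsAsFactors = FALSE)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  scale <- vapply(sp_nodes, function(n) {
    a <- xml2::xml_find_first(n, ".//i:species", ns)
    if (inherits(a, "xml_missing")) 1 else as.numeric(xml2::xml_attr(a, "scale"))
  }, numeric(1))
  species <- species_table(
    name = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    amount = as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    scale = scale)
  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- lapply(rx_nodes, function(n) {
    expand <- function(xpath) {
      refs <- xml2::xml_find_all(n, xpath, ns)
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      rep(sp, times = st)
    }
    law_node <- xml2::xml_find_first(n, ".//i:law", ns)
    if (inherits(law_node, "xml_missing")) {
      stop("reaction ", xml2::xml_attr(n, "id"),
           " lacks the round-trip annotation", call. = FALSE)
    }
    attrs <- xml2::xml_attrs(law_node)
    kind <- attrs[["kind"]]
    keep <- setdiff(names(attrs)[!grepl("^xmlns", names(attrs))], "kind")
    cst <- as.list(as.numeric(attrs[keep]))
    names(cst) <- keep
    reaction(
      id = xml2::xml_attr(n, "id"),
      reactants = expand(".//s:listOfReactants/s:speciesReference"),
      products = expand(".//s:listOfProducts/s:speciesReference"),
      modifiers = xml2::xml_attr(
        xml2::xml_find_all(n, ".//s:modifierSpeciesReference", ns),
        "species"),
      law = rate_law(kind, cst))
  })
  new_model(species, reactions, compartments)
}

#' Evaluate an exported kinetic law's MathML at a state
#'
#' Independent evaluator for the MathML written by [write_sbml()] (times,
#' plus, minus, divide, max, ci, cn), resolving `ci` symbols against the
#' reaction's local parameters first and the state second. Used to verify
#' that the exported math reproduces [evaluate_rate()].
#'
#' @param path SBML file.
#' @param reaction_id Reaction id.
#' @param state Named species-amount vector.
#' @return Flux value.
#' @export
sbml_evaluate_kinetic_law <- function(path, reaction_id, state) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          m = "http://www.w3.org/1998/Math/MathML")
  rx <- xml2::xml_find_first(
    doc, paste0(".//s:reaction[@id='", reaction_id, "']"), ns)
  if (inherits(rx, "xml_missing")) {
    stop("no reaction ", reaction_id, call. = FALSE)
  }
  lp <- xml2::xml_find_all(rx, ".//s:localParameter", ns)
  params <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                            xml2::xml_attr(lp, "id"))
  env <- c(as.list(params), as.list(state))
  math <- xml2::xml_find_first(rx, ".//m:math", ns)
  top <- xml2::xml_find_first(math, "./*")
  eval_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "ci") {
      sym <- trimws(xml2::xml_text(node))
      if (is.null(env[[sym]])) stop("unbound symbol ", sym, call. = FALSE)
      return(as.numeric(env[[sym]]))
    }
    if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
    if (nm == "apply") {
      kids <- xml2::xml_find_all(node, "./*")
      op <- xml2::xml_name(kids[[1]])
      args <- vapply(kids[-1], eval_node, numeric(1))
      return(switch(op,
        times = prod(args),
        plus = sum(args),
        minus = if (length(args) == 1) -args else args[1] - args[2],
        divide = args[1] / args[2],
        max = max(args),
        stop("unsupported MathML operator ", op, call. = FALSE)))
    }
    stop("unsupported MathML node ", nm, call. = FALSE)
  }
  eval_node(top)
}
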