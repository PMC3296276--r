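# Minimal SBML Level 3 Version 1 export/import for mass-action
# networks with timed parameter events.  Covers exactly the constructs
# an ad_model uses: amount-only species in a single compartment,
# global parameters, reactions whose kineticLaw is a MathML product of
# one rate parameter and species factors, and events triggered by
# (time >= t) whose assignments set or scale one parameter.  Anything
# outside that vocabulary is rejected with a named diagnostic rather
# than silently dropped.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a model to SBML (Level 3 Version 1)
#'
#' Mass-action kinetic laws are written as explicit MathML products
#' (rate parameter times each reactant/modifier factor, with the
#' combinatoric divisor for stoichiometries of two); timed events
#' carry a (time >= fire_time) trigger and a single parameter
#' assignment.  The export is lossless for any valid \code{ad_model}:
#' [import_sbml()] reads it back to an equal network.
#'
#' @param model A validated \code{ad_model}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [import_sbml()]
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "ad_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    sprintf('  <model id="%s" name="%s" extentUnits="item" timeUnits="day">',
            gsub("[^A-Za-z0-9_]", "_", model$name), esc(model$name)),
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (sp in model$species) {
    out <- c(out, sprintf(
      paste0('      <species id="%s" name="%s" compartment="cell" ',
             'initialAmount="%d" hasOnlySubstanceUnits="true" ',
             'boundaryCondition="false" constant="false"/>'),
      sp$id, esc(sp$display_name), sp$initial_count))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (pp in model$parameters) {
    out <- c(out, sprintf(
      '      <parameter id="%s" name="%s" value="%s" constant="false"/>',
      pp$id, esc(pp$description), num(pp$value)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (rx in model$reactions) {
    out <- c(out, sprintf('      <reaction id="%s" reversible="false">',
                          rx$id))
    if (length(rx$reactants)) {
      out <- c(out, '        <listOfReactants>')
      for (i in seq_along(rx$reactants)) {
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
          names(rx$reactants)[i], rx$reactants[[i]]))
      }
      out <- c(out, '        </listOfReactants>')
    }
    if (length(rx$products)) {
      out <- c(out, '        <listOfProducts>')
      for (i in seq_along(rx$products)) {
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
          names(rx$products)[i], rx$products[[i]]))
      }
      out <- c(out, '        </listOfProducts>')
    }
    if (length(rx$modifiers)) {
      out <- c(out, '        <listOfModifiers>')
      for (m in rx$modifiers) {
        out <- c(out, sprintf(
          '          <modifierSpeciesReference species="%s"/>', m))
      }
      out <- c(out, '        </listOfModifiers>')
    }
    # kinetic law as a flat MathML product: k * factors; a reactant
    # with stoichiometry m contributes m <ci> factors and a 1/m!
    # constant, mirroring the combinatoric propensity up to the
    # falling-factorial correction applied by the simulator
    factors <- sprintf('<ci> %s </ci>', rx$rate_parameter)
    div <- 1
    for (i in seq_along(rx$reactants)) {
      s <- names(rx$reactants)[i]; m <- rx$reactants[[i]]
      factors <- c(factors, rep(sprintf('<ci> %s </ci>', s), m))
      div <- div * factorial(m)
    }
    for (m in rx$modifiers) {
      factors <- c(factors, sprintf('<ci> %s </ci>', m))
    }
    if (div > 1) {
      factors <- c(factors, sprintf('<cn> %s </cn>', num(1 / div)))
    }
    out <- c(out,
      '        <kineticLaw>',
      sprintf('          <math xmlns="%s">', MATHML_NS),
      '            <apply><times/>',
      paste0('              ', factors),
      '            </apply>',
      '          </math>',
      '        </kineticLaw>',
      '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (length(model$events)) {
    out <- c(out, '    <listOfEvents>')
    for (k in seq_along(model$events)) {
      ev <- model$events[[k]]
      assign_math <- if (ev$action == "set_value") {
        sprintf('<cn> %s </cn>', num(ev$operand))
      } else {
        sprintf('<apply><times/><cn> %s </cn><ci> %s </ci></apply>',
                num(ev$operand), ev$parameter_id)
      }
      out <- c(out,
        sprintf('      <event id="ev%d" useValuesFromTriggerTime="true">', k),
        '        <trigger initialValue="true" persistent="true">',
        sprintf('          <math xmlns="%s">', MATHML_NS),
        '            <apply><geq/>',
        '              <csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time"> t </csymbol>',
        sprintf('              <cn> %s </cn>', num(ev$fire_time)),
        '            </apply>',
        '          </math>',
        '        </trigger>',
        '        <listOfEventAssignments>',
        sprintf('          <eventAssignment variable="%s">', ev$parameter_id),
        sprintf('            <math xmlns="%s">', MATHML_NS),
        paste0('              ', assign_math),
        '            </math>',
        '          </eventAssignment>',
        '        </listOfEventAssignments>',
        '      </event>')
    }
    out <- c(out, '    </listOfEvents>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

# collect <ci> identifiers of a flat MathML <apply><times/> product;
# errors via the supplied reject() on anything else
parse_product <- function(math_node, reject) {
  kids <- xml2::xml_children(math_node)
  if (length(kids) != 1L) reject("kineticLaw math must hold one expression")
  apply_node <- kids[[1]]
  if (xml2::xml_name(apply_node) != "apply") {
    if (xml2::xml_name(apply_node) == "ci") {
      return(list(ids = trimws(xml2::xml_text(apply_node)), const = 1))
    }
    reject(paste0("unsupported kineticLaw element <",
                  xml2::xml_name(apply_node), ">"))
  }
  terms <- xml2::xml_children(apply_node)
  if (xml2::xml_name(terms[[1]]) != "times") {
    reject(paste0("unsupported kineticLaw operator <",
                  xml2::xml_name(terms[[1]]), ">"))
  }
  ids <- character(); const <- 1
  for (tn in terms[-1]) {
    nm <- xml2::xml_name(tn)
    if (nm == "ci") ids <- c(ids, trimws(xml2::xml_text(tn)))
    else if (nm == "cn") const <- const * as.numeric(xml2::xml_text(tn))
    else reject(paste0("unsupported kineticLaw factor <", nm, ">"))
  }
  list(ids = ids, const = const)
}

#' Import an SBML mass-action model
#'
#' Reads the SBML subset written by [export_sbml()]: species with
#' integer initial amounts, global parameters, irreversible reactions
#' with product-form mass-action kinetic laws, and time-triggered
#' single-parameter events.  Unsupported constructs (rules, function
#' definitions, assignment math beyond a constant or constant-times-
#' parameter, non-time triggers) raise an error naming the construct.
#'
#' @param path Path to an SBML file.
#' @param horizon Simulation horizon in days for the resulting model
#'   (SBML does not encode one); default 12.
#' @return A validated \code{ad_model}.
#' @export
import_sbml <- function(path, horizon = 12) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, m = MATHML_NS)
  reject <- function(msg) stop("unsupported SBML construct: ", msg,
                               call. = FALSE)
  for (bad in c("listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints", "listOfInitialAssignments")) {
    if (length(xml2::xml_find_all(doc, paste0("//s:", bad), ns))) {
      reject(bad)
    }
  }
  model_node <- xml2::xml_find_first(doc, "//s:model", ns)
  name <- xml2::xml_attr(model_node, "name")
  if (is.na(name)) name <- xml2::xml_attr(model_node, "id")

  species <- lapply(xml2::xml_find_all(doc, "//s:species", ns), function(n) {
    amt <- as.numeric(xml2::xml_attr(n, "initialAmount"))
    if (is.na(amt)) reject(paste0("species '", xml2::xml_attr(n, "id"),
                                  "' without initialAmount"))
    nm <- xml2::xml_attr(n, "name")
    ad_species(xml2::xml_attr(n, "id"),
               if (is.na(nm)) xml2::xml_attr(n, "id") else nm,
               amt)
  })
  parameters <- lapply(xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter",
                                          ns), function(n) {
    desc <- xml2::xml_attr(n, "name")
    ad_parameter(xml2::xml_attr(n, "id"),
                 as.numeric(xml2::xml_attr(n, "value")),
                 if (is.na(desc)) "" else desc)
  })
  par_ids <- vapply(parameters, `[[`, "", "id")
  sp_ids <- vapply(species, `[[`, "", "id")

  reactions <- lapply(xml2::xml_find_all(doc, "//s:reaction", ns), function(n) {
    id <- xml2::xml_attr(n, "id")
    ref <- function(xp) {
      nodes <- xml2::xml_find_all(n, xp, ns)
      if (!length(nodes)) return(integer())
      st <- as.integer(round(as.numeric(
        xml2::xml_attr(nodes, "stoichiometry"))))
      st[is.na(st)] <- 1L
      setNames(st, xml2::xml_attr(nodes, "species"))
    }
    reactants <- ref("./s:listOfReactants/s:speciesReference")
    products <- ref("./s:listOfProducts/s:speciesReference")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(n, "./s:listOfModifiers/s:modifierSpeciesReference",
                         ns), "species")
    math <- xml2::xml_find_first(n, "./s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing")) {
      reject(paste0("reaction '", id, "' without kineticLaw"))
    }
    pr <- parse_product(math, reject)
    k_id <- intersect(pr$ids, par_ids)
    if (length(k_id) != 1L) {
      reject(paste0("reaction '", id,
                    "' kineticLaw must reference exactly one parameter"))
    }
    sp_factors <- pr$ids[pr$ids %in% sp_ids]
    # the species factors must match reactants (with multiplicity) plus
    # modifiers -- i.e. a plain mass-action product
    expected <- c(rep(names(reactants), times = reactants), modifiers)
    if (!identical(sort(sp_factors), sort(expected))) {
      reject(paste0("reaction '", id,
                    "' kineticLaw is not mass action in its reactants",
                    " and modifiers"))
    }
    ad_reaction(id, reactants, products, modifiers, k_id,
                kinetics = if (length(modifiers)) "modifier_mass_action"
                           else "mass_action")
  })

  events <- lapply(xml2::xml_find_all(doc, "//s:event", ns), function(n) {
    trig <- xml2::xml_find_first(
      n, "./s:trigger/m:math/m:apply", ns)
    if (inherits(trig, "xml_missing")) reject("event without trigger math")
    kids <- xml2::xml_children(trig)
    if (xml2::xml_name(kids[[1]]) != "geq" ||
        xml2::xml_name(kids[[2]]) != "csymbol" ||
        !grepl("time", xml2::xml_attr(kids[[2]], "definitionURL"))) {
      reject("event trigger is not (time >= t0)")
    }
    fire_time <- as.numeric(xml2::xml_text(kids[[3]]))
    ea <- xml2::xml_find_all(n, "./s:listOfEventAssignments/s:eventAssignment",
                             ns)
    if (length(ea) != 1L) reject("event must carry exactly one assignment")
    var <- xml2::xml_attr(ea[[1]], "variable")
    if (!var %in% par_ids) reject(paste0("event assignment to non-parameter '",
                                         var, "'"))
    expr <- xml2::xml_child(xml2::xml_find_first(ea[[1]], "./m:math", ns))
    nm <- xml2::xml_name(expr)
    if (nm == "cn") {
      timed_event(fire_time, var, "set_value",
                  as.numeric(xml2::xml_text(expr)))
    } else if (nm == "apply") {
      terms <- xml2::xml_children(expr)
      ok <- length(terms) == 3L && xml2::xml_name(terms[[1]]) == "times" &&
        xml2::xml_name(terms[[2]]) == "cn" &&
        xml2::xml_name(terms[[3]]) == "ci" &&
        trimws(xml2::xml_text(terms[[3]])) == var
    if (!ok) reject("event assignment math is not constant or scale-self")
      timed_event(fire_time, var, "multiply",
                  as.numeric(xml2::xml_text(terms[[2]])))
    } else {
      reject(paste0("event assignment element <", nm, ">"))
    }
  })

  model_definition(name, species, reactions, parameters, events, horizon)
}
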