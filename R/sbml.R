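# SBML Level 3 Version 1 export/import for the mass-action model subset
# used here: single compartment of size 1, species in amounts, kinetic
# laws that are plain products of one rate parameter, the modifiers and
# (optionally) the substrate. Inhibitor-to-reaction coupling and moiety
# metadata travel in a package-namespace annotation so that models
# round-trip. Constructs outside this subset raise an explicit
# unsupported-feature error on import.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
HN_NS <- "https://hybridnet.invalid/sbml-annotation"

#' Write an ODE model as SBML L3V1
#' @param m ode_model
#' @param path output file
#' @param model_id SBML model id
#' @export
write_sbml <- function(m, path, model_id = "model") {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "1")
  mod <- xml2::xml_add_child(doc, "model", id = model_id)

  ann <- xml2::xml_add_child(mod, "annotation")
  hn <- xml2::xml_add_child(ann, "hybridnet")
  xml2::xml_set_attr(hn, "xmlns", HN_NS)
  xml2::xml_set_attr(hn, "signal",
                     if (is.na(m$signal)) "" else m$signal)
  xml2::xml_set_attr(hn, "constants", paste(m$constants, collapse = ","))
  xml2::xml_set_attr(hn, "synth_deg",
                     paste(m$options$synth_deg, collapse = ","))
  for (nm in names(m$inhibitors)) {
    ih <- xml2::xml_add_child(hn, "inhibitor", name = nm)
    xml2::xml_set_attr(ih, "reactions",
                       paste(m$inhibitors[[nm]]$reactions, collapse = ","))
  }

  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = "1",
                      constant = "true")
  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(m$species))) {
    xml2::xml_add_child(ls, "species",
                        id = m$species$id[i], compartment = "cell",
                        initialAmount = format(m$species$initial[i],
                                               digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_len(nrow(m$parameters))) {
    v <- m$parameters$value[i]
    xml2::xml_add_child(lp, "parameter", id = m$parameters$id[i],
                        value = if (is.na(v)) "NaN" else format(v, digits = 17),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in m$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = paste0("r", r$id),
                              name = r$name, reversible = "false")
    if (!is.na(r$substrate)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      xml2::xml_add_child(lre, "speciesReference", species = r$substrate,
                          stoichiometry = "1", constant = "true")
    }
    if (!is.na(r$product)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      xml2::xml_add_child(lpr, "speciesReference", species = r$product,
                          stoichiometry = "1", constant = "true")
    }
    state_mods <- r$modifiers[r$modifiers %in% m$species$id]
    if (length(state_mods)) {
      lmo <- xml2::xml_add_child(rx, "listOfModifiers")
      for (mo in state_mods)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = mo)
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    factors <- c(r$param, r$modifiers,
                 if (!is.na(r$substrate)) r$substrate)
    if (length(factors) == 1L) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML L3V1 file into an ODE model
#'
#' Only the mass-action subset written by [write_sbml()] is supported:
#' irreversible reactions with at most one reactant and one product, unit
#' stoichiometry, and kinetic laws that are products of identifiers.
#' @param path SBML file
#' @return ode_model
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, m = MATHML_NS, h = HN_NS)
  unsupported <- function(what) stop("unsupported SBML feature: ", what)
  if (length(xml2::xml_find_all(doc, "//s:listOfRules", ns)) ||
      length(xml2::xml_find_all(doc, "//s:listOfEvents", ns)) ||
      length(xml2::xml_find_all(doc, "//s:listOfFunctionDefinitions", ns)))
    unsupported("rules/events/function definitions")

  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  species <- data.frame(
    id = sp_ids,
    initial = as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_vals <- suppressWarnings(as.numeric(xml2::xml_attr(par_nodes, "value")))

  hn <- xml2::xml_find_first(doc, "//h:hybridnet", ns)
  sig <- NA_character_; consts <- character(0); synth <- character(0)
  inhibitors <- list()
  if (!inherits(hn, "xml_missing")) {
    s <- xml2::xml_attr(hn, "signal")
    if (!is.na(s) && nzchar(s)) sig <- s
    cs <- xml2::xml_attr(hn, "constants")
    if (!is.na(cs) && nzchar(cs)) consts <- strsplit(cs, ",")[[1]]
    sd <- xml2::xml_attr(hn, "synth_deg")
    if (!is.na(sd) && nzchar(sd)) synth <- strsplit(sd, ",")[[1]]
    for (ih in xml2::xml_find_all(hn, "h:inhibitor", ns)) {
      rxs <- xml2::xml_attr(ih, "reactions")
      inhibitors[[xml2::xml_attr(ih, "name")]] <-
        list(param = paste0(xml2::xml_attr(ih, "name"), "_strength"),
             reactions = if (nzchar(rxs)) as.integer(strsplit(rxs, ",")[[1]])
                         else integer(0))
    }
  }

  rx_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    rx <- rx_nodes[[i]]
    if (identical(xml2::xml_attr(rx, "reversible"), "true"))
      unsupported("reversible reaction")
    reac <- xml2::xml_find_all(rx, "s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rx, "s:listOfProducts/s:speciesReference", ns)
    if (length(reac) > 1 || length(prod) > 1)
      unsupported("non-unary stoichiometry")
    for (sr in c(reac, prod)) {
      st <- xml2::xml_attr(sr, "stoichiometry")
      if (!is.na(st) && as.numeric(st) != 1)
        unsupported("stoichiometry != 1")
    }
    mods <- xml2::xml_attr(
      xml2::xml_find_all(rx, "s:listOfModifiers/s:modifierSpeciesReference",
                         ns), "species")
    math <- xml2::xml_find_first(rx, "s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing")) unsupported("reaction without kinetic law")
    top <- xml2::xml_find_first(math, "m:apply|m:ci", ns)
    cis <- character(0)
    if (xml2::xml_name(top) == "ci") {
      cis <- trimws(xml2::xml_text(top))
    } else {
      op <- xml2::xml_find_first(top, "*[1]")
      if (xml2::xml_name(op) != "times")
        unsupported(paste0("kinetic-law operator '", xml2::xml_name(op), "'"))
      kids <- xml2::xml_children(top)[-1]
      if (!all(xml2::xml_name(kids) == "ci"))
        unsupported("non-identifier factor in kinetic law")
      cis <- trimws(xml2::xml_text(kids))
    }
    # constant species and inputs also appear as parameter factors in the
    # law; the rate constant is the remaining parameter identifier
    param <- setdiff(intersect(cis, par_ids), c(consts, sig))
    if (length(param) != 1)
      unsupported("kinetic law without exactly one rate parameter")
    substrate <- if (length(reac)) xml2::xml_attr(reac[[1]], "species")
                 else NA_character_
    product <- if (length(prod)) xml2::xml_attr(prod[[1]], "species")
               else NA_character_
    modifiers <- setdiff(cis, c(param, substrate))
    reactions[[i]] <- list(id = i, name = xml2::xml_attr(rx, "name"),
                           substrate = substrate, product = product,
                           modifiers = modifiers, param = param,
                           origin = "sbml")
  }

  kind <- rep("kinetic", length(par_ids))
  kind[par_ids %in% consts] <- "constant"
  if (!is.na(sig)) kind[par_ids == sig] <- "input"
  params <- data.frame(id = par_ids, value = par_vals,
                       lower = ifelse(kind == "input", 0, 1e-5),
                       upper = ifelse(kind == "input", Inf, 1e3),
                       kind = kind, stringsAsFactors = FALSE)

  # reconstruct form/pool metadata from initial amounts (inactive pools
  # start full) and from the activation/deactivation reaction structure
  pool_of <- stats::setNames(rep(NA_character_, nrow(species)), species$id)
  for (r in reactions) {
    if (!is.na(r$substrate) && !is.na(r$product)) {
      if (species$initial[match(r$substrate, species$id)] > 0)
        pool_of[r$product] <- r$substrate
      else if (!is.na(pool_of[r$substrate]) || TRUE) {
        # deactivations point active -> pool; fill the active side too
        if (species$initial[match(r$product, species$id)] > 0)
          pool_of[r$substrate] <- r$product
      }
    }
  }
  form <- ifelse(species$initial > 0, "inactive", "active")
  pool <- ifelse(form == "inactive", species$id, pool_of[species$id])
  pool[is.na(pool)] <- species$id[is.na(pool)]
  species2 <- data.frame(id = species$id, form = form, pool = pool,
                         initial = species$initial, stringsAsFactors = FALSE)

  structure(list(species = species2, reactions = reactions,
                 parameters = params, inhibitors = inhibitors,
                 n_core_reactions = length(reactions),
                 signal = sig, constants = consts,
                 options = translate_options(signal = sig,
                                             constants = consts,
                                             synth_deg = synth)),
            class = "ode_model")
}
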