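# Reading and writing models. Two dialects: SBML Level 3 + FBC v2 (the
# interchange subset the pipeline needs: species, compartments, bounds,
# gene-product associations, active objective) and a compact JSON dialect
# convenient for fixtures. Subsystem/kind/molecular weight travel in SBML
# notes; both dialects round-trip field-by-field through read/write.

#' Read a metabolic model
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"sbml"} or \code{"json"}.
#' @return a \linkS4class{MetabolicModel}.
#' @export
readMetabolicModel <- function(path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  model <- if (dialect == "sbml") .readSBML(path) else .readJSONModel(path)
  validateModel(model)
  model
}

#' Write a metabolic model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output path.
#' @param dialect \code{"auto"}, \code{"sbml"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeMetabolicModel <- function(model, path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (dialect == "sbml") .writeSBML(model, path) else .writeJSONModel(model, path)
  invisible(path)
}

# ---- JSON dialect ----------------------------------------------------------

.readJSONModel <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  model <- emptyModel(compartments = as.character(unlist(j$compartments)))
  for (m in j$metabolites) {
    model <- addMetabolite(model, m$id, name = m$name %||% m$id,
                           compartment = m$compartment,
                           formula = m$formula %||% NA_character_,
                           mw = m$mw %||% NA_real_)
  }
  for (r in j$reactions) {
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st)) stop("reaction with empty stoichiometry: ", r$id)
    model <- addReaction(model, r$id, st,
                         lb = as.numeric(r$lower_bound %||% 0),
                         ub = as.numeric(r$upper_bound %||% 1000),
                         gpr = r$gene_reaction_rule %||% "",
                         subsystem = r$subsystem %||% "",
                         kind = r$kind %||% .inferKind(r$id, st, model))
  }
  if (!is.null(j$objective)) model@objective <- j$objective
  model
}

.writeJSONModel <- function(model, path) {
  met <- model@metabolites
  mets <- lapply(seq_len(nrow(met)), function(i) {
    x <- list(id = met$id[i], name = met$name[i], compartment = met$compartment[i])
    if (!is.na(met$formula[i])) x$formula <- met$formula[i]
    if (!is.na(met$mw[i])) x$mw <- met$mw[i]
    x
  })
  rxn <- model@reactions
  S <- model@stoichiometry
  rxns <- lapply(seq_len(nrow(rxn)), function(i) {
    col <- S[, i]
    nz <- which(col != 0)
    list(id = rxn$id[i], metabolites = as.list(setNames(col[nz], met$id[nz])),
         lower_bound = rxn$lb[i], upper_bound = rxn$ub[i],
         gene_reaction_rule = rxn$gpr[i], subsystem = rxn$subsystem[i],
         kind = rxn$kind[i])
  })
  out <- list(compartments = as.list(model@compartments), metabolites = mets,
              reactions = rxns, objective = model@objective)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.inferKind <- function(id, stoich, model) {
  if (length(stoich) == 1) return("exchange")
  if (grepl("biomass", id, ignore.case = TRUE)) return("biomass")
  comps <- unique(model@metabolites$compartment[match(names(stoich), model@metabolites$id)])
  if (length(comps) > 1) "transport" else "enzymatic"
}

# ---- SBML L3 + FBC subset --------------------------------------------------

.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "algaeGEM_model",
                             "fbc:strict" = "false")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (c_ in model@compartments) {
    xml2::xml_add_child(loc, "compartment", id = .sid(c_), name = c_,
                        constant = "true")
  }
  met <- model@metabolites
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(los, "species",
      id = paste0("M_", .sid(met$id[i])), name = met$name[i],
      compartment = .sid(met$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(met$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[i])
    }
    notes <- character(0)
    notes <- c(notes, paste0("ORIGINAL_ID: ", met$id[i]))
    if (!is.na(met$mw[i])) notes <- c(notes, paste0("MW: ", format(met$mw[i], digits = 15)))
    .addNotes(sp, notes)
  }
  rxn <- model@reactions
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  addPar <- function(id, value) {
    xml2::xml_add_child(lop, "parameter", id = id,
                        value = format(value, digits = 17), constant = "true")
    id
  }
  genes <- model@genes
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  S <- model@stoichiometry
  for (i in seq_len(nrow(rxn))) {
    rid <- paste0("R_", .sid(rxn$id[i]))
    lbp <- addPar(paste0(rid, "_lb"), rxn$lb[i])
    ubp <- addPar(paste0(rid, "_ub"), rxn$ub[i])
    rx <- xml2::xml_add_child(lor, "reaction", id = rid, name = rxn$id[i],
      reversible = if (rxn$lb[i] < 0) "true" else "false", fast = "false")
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound", lbp)
    xml2::xml_set_attr(rx, "fbc:upperFluxBound", ubp)
    .addNotes(rx, c(paste0("ORIGINAL_ID: ", rxn$id[i]),
                    paste0("SUBSYSTEM: ", rxn$subsystem[i]),
                    paste0("KIND: ", rxn$kind[i])))
    col <- S[, i]; nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in reac) xml2::xml_add_child(lr, "speciesReference",
        species = paste0("M_", .sid(met$id[k])),
        stoichiometry = format(-col[k], digits = 15), constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in prod) xml2::xml_add_child(lp, "speciesReference",
        species = paste0("M_", .sid(met$id[k])),
        stoichiometry = format(col[k], digits = 15), constant = "true")
    }
    rule <- parseGPR(rxn$gpr[i])
    if (!is.null(rule)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .writeGPA(gpa, rule)
    }
  }
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      gp <- xml2::xml_add_child(logp, "fbc:geneProduct")
      xml2::xml_set_attr(gp, "fbc:id", paste0("G_", .sid(g)))
      xml2::xml_set_attr(gp, "fbc:label", g)
    }
  }
  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives")
  xml2::xml_set_attr(loo, "fbc:activeObjective", "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective")
  xml2::xml_set_attr(ob, "fbc:id", "obj")
  xml2::xml_set_attr(ob, "fbc:type", "maximize")
  if (nzchar(model@objective)) {
    lof <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    fo <- xml2::xml_add_child(lof, "fbc:fluxObjective")
    xml2::xml_set_attr(fo, "fbc:reaction", paste0("R_", .sid(model@objective)))
    xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  }
  xml2::write_xml(doc, path)
}

.writeGPA <- function(node, rule) {
  if (is.character(rule)) {
    ref <- xml2::xml_add_child(node, "fbc:geneProductRef")
    xml2::xml_set_attr(ref, "fbc:geneProduct", paste0("G_", .sid(rule)))
    return(invisible())
  }
  inner <- xml2::xml_add_child(node, paste0("fbc:", rule$op))
  for (a in rule$args) .writeGPA(inner, a)
}

.addNotes <- function(node, lines) {
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
  for (l in lines) xml2::xml_add_child(body, "p", l)
}

# xml_ns_strip() does not make fbc-prefixed elements visible to plain XPath,
# so fbc containers are located by scanning child names.
.childrenByName <- function(node, name) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) == name]
}

.childByName <- function(node, name) {
  hits <- .childrenByName(node, name)
  if (length(hits)) hits[[1]] else NULL
}

.attrNS <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^[^:]+:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

.noteField <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//p")
  for (p in ps) {
    txt <- xml2::xml_text(p)
    if (startsWith(txt, paste0(key, ": "))) {
      return(sub(paste0("^", key, ": "), "", txt))
    }
  }
  NA_character_
}

.readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML parse error: no <model> element")
  comps <- xml2::xml_find_all(mdl, "./listOfCompartments/compartment")
  cids <- vapply(comps, function(x) {
    nm <- xml2::xml_attr(x, "name")
    if (!is.na(nm)) nm else xml2::xml_attr(x, "id")
  }, character(1))
  cid_by_sid <- setNames(cids, vapply(comps, xml2::xml_attr, character(1), attr = "id"))
  model <- emptyModel(compartments = if (length(cids)) cids else "c")
  # gene labels
  logp <- .childByName(mdl, "listOfGeneProducts")
  gps <- if (is.null(logp)) list() else .childrenByName(logp, "geneProduct")
  glabel <- setNames(
    vapply(gps, function(g) {
      lb <- .attrNS(g, "label")
      if (is.na(lb)) .attrNS(g, "id") else lb
    }, character(1)),
    vapply(gps, function(g) .attrNS(g, "id"), character(1)))
  # parameters (flux bounds)
  pars <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  pvals <- setNames(as.numeric(vapply(pars, xml2::xml_attr, character(1), attr = "value")),
                    vapply(pars, xml2::xml_attr, character(1), attr = "id"))
  sp_nodes <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
  sid2id <- character(0)
  for (s in sp_nodes) {
    sid <- xml2::xml_attr(s, "id")
    orig <- .noteField(s, "ORIGINAL_ID")
    id <- if (!is.na(orig)) orig else sub("^M_", "", sid)
    mw <- suppressWarnings(as.numeric(.noteField(s, "MW")))
    csid <- xml2::xml_attr(s, "compartment")
    comp <- if (!is.na(csid) && csid %in% names(cid_by_sid)) cid_by_sid[[csid]] else csid
    model <- addMetabolite(model, id,
                           name = xml2::xml_attr(s, "name") %|na|% id,
                           compartment = comp %|na|% model@compartments[1],
                           formula = .attrNS(s, "chemicalFormula"),
                           mw = mw)
    sid2id[sid] <- id
  }
  rx_nodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
  for (rx in rx_nodes) {
    rid_s <- xml2::xml_attr(rx, "id")
    orig <- .noteField(rx, "ORIGINAL_ID")
    id <- if (!is.na(orig)) orig else sub("^R_", "", rid_s)
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% names(sid2id)) stop("unknown metabolite reference '", sid,
                                        "' in reaction ", id)
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
      st[sid2id[[sid]]] <- (st[sid2id[[sid]]] %|na0|% 0) - coef
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% names(sid2id)) stop("unknown metabolite reference '", sid,
                                        "' in reaction ", id)
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
      st[sid2id[[sid]]] <- (st[sid2id[[sid]]] %|na0|% 0) + coef
    }
    lbp <- .attrNS(rx, "lowerFluxBound"); ubp <- .attrNS(rx, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else
      if (identical(xml2::xml_attr(rx, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
    gpa <- .childByName(rx, "geneProductAssociation")
    gpr <- if (is.null(gpa)) "" else
      deparseGPR(.readGPA(xml2::xml_children(gpa)[[1]], glabel))
    subsystem <- .noteField(rx, "SUBSYSTEM") %|na|% ""
    kind <- .noteField(rx, "KIND")
    if (is.na(kind)) kind <- .inferKind(id, st, model)
    model <- addReaction(model, id, st, lb = lb, ub = ub, gpr = gpr,
                         subsystem = subsystem, kind = kind)
  }
  loo <- .childByName(mdl, "listOfObjectives")
  fo <- NULL
  if (!is.null(loo)) {
    ob <- .childByName(loo, "objective")
    if (!is.null(ob)) {
      lof <- .childByName(ob, "listOfFluxObjectives")
      if (!is.null(lof)) fo <- .childByName(lof, "fluxObjective")
    }
  }
  if (!is.null(fo)) {
    orid <- .attrNS(fo, "reaction")
    hit <- model@reactions$id[paste0("R_", .sid(model@reactions$id)) == orid]
    if (length(hit) == 1) model@objective <- hit else {
      plain <- sub("^R_", "", orid)
      if (plain %in% model@reactions$id) model@objective <- plain
    }
  }
  model
}

.readGPA <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- .attrNS(node, "geneProduct")
    g <- if (gid %in% names(glabel)) glabel[[gid]] else sub("^G_", "", gid)
    return(g)
  }
  if (nm %in% c("and", "or")) {
    return(list(op = nm,
                args = lapply(xml2::xml_children(node), .readGPA, glabel = glabel)))
  }
  stop("SBML parse error: unexpected element <", nm, "> in gene association")
}

`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
`%|na0|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
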