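# Construction and in-place editing of MetabolicModel objects. All editing
# helpers return a new (validated) model; the stoichiometric matrix is kept
# sparse and in registration with the metabolite/reaction tables.

.emptyMetTable <- function() {
  data.frame(id = character(0), name = character(0), compartment = character(0),
             formula = character(0), mw = numeric(0), stringsAsFactors = FALSE)
}

.emptyRxnTable <- function() {
  data.frame(id = character(0), lb = numeric(0), ub = numeric(0),
             gpr = character(0), subsystem = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Create an empty metabolic model
#'
#' @param compartments ordered character vector of compartment ids.
#' @return a \linkS4class{MetabolicModel} with no metabolites or reactions.
#' @export
emptyModel <- function(compartments = "c") {
  new("MetabolicModel",
      metabolites = .emptyMetTable(),
      reactions = .emptyRxnTable(),
      stoichiometry = Matrix::Matrix(0, 0, 0, sparse = TRUE,
                                     dimnames = list(character(0), character(0))),
      compartments = compartments,
      objective = "",
      genes = character(0))
}

#' Add a metabolite
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id metabolite id (unique).
#' @param name display name.
#' @param compartment compartment id (added to the compartment list if new).
#' @param formula chemical formula or \code{NA}.
#' @param mw molecular weight in g mol-1 or \code{NA}.
#' @return the extended model.
#' @export
addMetabolite <- function(model, id, name = id, compartment = model@compartments[1],
                          formula = NA_character_, mw = NA_real_) {
  if (id %in% model@metabolites$id) return(model)
  if (!compartment %in% model@compartments) {
    model@compartments <- c(model@compartments, compartment)
  }
  model@metabolites <- rbind(model@metabolites, data.frame(
    id = id, name = name, compartment = compartment,
    formula = as.character(formula), mw = as.numeric(mw), stringsAsFactors = FALSE))
  S <- model@stoichiometry
  model@stoichiometry <- rbind(S, Matrix::Matrix(0, 1, ncol(S), sparse = TRUE))
  rownames(model@stoichiometry) <- model@metabolites$id
  model
}

#' Add a reaction
#'
#' Metabolites referenced by \code{stoich} that are absent from the model are
#' created on the fly in the model's first compartment (pass them through
#' \code{\link{addMetabolite}} first for full control).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id reaction id (unique).
#' @param stoich named numeric, metabolite id -> signed coefficient.
#' @param lb,ub flux bounds, mmol g-1 DW h-1.
#' @param gpr GPR rule text ("" for none).
#' @param subsystem subsystem label.
#' @param kind one of \code{enzymatic}, \code{transport}, \code{exchange},
#'   \code{biomass}, \code{demand}.
#' @return the extended model.
#' @export
addReaction <- function(model, id, stoich, lb = 0, ub = 1000, gpr = "",
                        subsystem = "", kind = "enzymatic") {
  stopifnot(length(stoich) > 0, !is.null(names(stoich)))
  if (id %in% model@reactions$id) stop("duplicate reaction id: ", id)
  for (m in setdiff(names(stoich), model@metabolites$id)) {
    model <- addMetabolite(model, m)
  }
  model@reactions <- rbind(model@reactions, data.frame(
    id = id, lb = lb, ub = ub, gpr = gpr, subsystem = subsystem, kind = kind,
    stringsAsFactors = FALSE))
  S <- model@stoichiometry
  col <- Matrix::Matrix(0, nrow(S), 1, sparse = TRUE)
  col[match(names(stoich), model@metabolites$id), 1] <- unname(stoich)
  model@stoichiometry <- cbind(S, col)
  colnames(model@stoichiometry) <- model@reactions$id
  g <- gprGenes(parseGPR(gpr))
  model@genes <- union(model@genes, g)
  model
}

#' Remove reactions (and optionally orphaned metabolites)
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param ids reaction ids to drop.
#' @param dropOrphans drop metabolites no longer used by any reaction.
#' @return the reduced model.
#' @export
removeReactions <- function(model, ids, dropOrphans = TRUE) {
  keep <- !model@reactions$id %in% ids
  model@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(model@reactions) <- NULL
  model@stoichiometry <- model@stoichiometry[, keep, drop = FALSE]
  if (dropOrphans && nrow(model@metabolites)) {
    used <- Matrix::rowSums(abs(model@stoichiometry) > 0) > 0
    model@metabolites <- model@metabolites[used, , drop = FALSE]
    rownames(model@metabolites) <- NULL
    model@stoichiometry <- model@stoichiometry[used, , drop = FALSE]
  }
  if (nzchar(model@objective) && !model@objective %in% model@reactions$id) {
    model@objective <- ""
  }
  model
}

#' Set flux bounds of one or more reactions
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param ids reaction ids.
#' @param lb,ub new bounds (recycled); \code{NA} leaves a bound untouched.
#' @return the model with updated bounds.
#' @export
setBounds <- function(model, ids, lb = NA, ub = NA) {
  ix <- match(ids, model@reactions$id)
  if (anyNA(ix)) stop("unknown reaction id(s): ", paste(ids[is.na(ix)], collapse = ", "))
  lb <- rep_len(lb, length(ids)); ub <- rep_len(ub, length(ids))
  sel <- !is.na(lb); model@reactions$lb[ix[sel]] <- lb[sel]
  sel <- !is.na(ub); model@reactions$ub[ix[sel]] <- ub[sel]
  model
}

#' Validate a model
#'
#' Runs the class validity checks and errors with the collected messages.
#' @param model a \linkS4class{MetabolicModel}.
#' @return the model, invisibly, if valid.
#' @export
validateModel <- function(model) {
  methods::validObject(model)
  invisible(model)
}

# ---- accessors -------------------------------------------------------------

#' Accessors for MetabolicModel
#'
#' @param object a \linkS4class{MetabolicModel}.
#' @param value replacement value.
#' @param ... unused.
#' @name MetabolicModel-accessors
NULL

#' @rdname MetabolicModel-accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object, ...) object@reactions)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object, ...) object@metabolites)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object, ...) object@stoichiometry)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("compartmentIds", "MetabolicModel", function(object, ...) object@compartments)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(object, ...) object@objective)

#' @rdname MetabolicModel-accessors
#' @export
setReplaceMethod("objectiveReaction", "MetabolicModel", function(object, value) {
  if (!value %in% object@reactions$id) stop("objective reaction not in model: ", value)
  object@objective <- value
  object
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("modelGenes", "MetabolicModel", function(object, ...) object@genes)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("nReactions", "MetabolicModel", function(object) nrow(object@reactions))

#' @rdname MetabolicModel-accessors
#' @export
setMethod("nMetabolites", "MetabolicModel", function(object) nrow(object@metabolites))

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites,",
      length(object@genes), "genes\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  kinds <- table(object@reactions$kind)
  if (length(kinds)) {
    cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  }
  rev <- sum(object@reactions$lb < 0 & object@reactions$ub > 0)
  cat("  reversible:", rev, " objective:",
      if (nzchar(object@objective)) object@objective else "<unset>", "\n")
})

#' @rdname result-accessors
#' @export
setMethod("fluxes", "FluxResult", function(object, ...) object@fluxes)

#' @rdname result-accessors
#' @export
setMethod("objectiveValue", "FluxResult", function(object, ...) object@objective)

#' @rdname result-accessors
#' @export
setMethod("solverStatus", "FluxResult", function(object, ...) object@status)

#' @rdname result-accessors
#' @export
setMethod("fluxes", "FluxSample", function(object, ...) object@samples)

setMethod("show", "FluxResult", function(object) {
  cat("FluxResult: objective =", format(object@objective, digits = 6),
      "(", object@status, ")\n")
})

setMethod("show", "FluxSample", function(object) {
  cat("FluxSample:", nrow(object@samples), "samples x", ncol(object@samples),
      "reactions (thinning", object@thinning, ", seed", object@seed, ")\n")
})
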