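#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t
NULL

#' Constraint-based metabolic model
#'
#' Central container for a stoichiometric metabolic network. Metabolites and
#' reactions are kept as data frames in registration with a sparse
#' stoichiometric matrix (metabolites x reactions). Flux bounds are in
#' mmol g-1 DW h-1; metabolite molecular weights (column \code{mw}, g mol-1)
#' are optional but required for biomass and enzyme-pool arithmetic.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula}, \code{mw}.
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{gpr} (boolean rule text over gene ids), \code{subsystem},
#'   \code{kind} (one of \code{enzymatic}, \code{transport}, \code{exchange},
#'   \code{biomass}, \code{demand}).
#' @slot stoichiometry sparse \code{dgCMatrix}, rows = metabolite ids,
#'   columns = reaction ids, signed coefficients.
#' @slot compartments ordered character vector of compartment ids (at most
#'   eight in the algal pipeline: cytoplasm, chloroplast, lysosome/vacuole,
#'   mitochondrion, thylakoid/plastid, peroxisome, endoplasmic reticulum,
#'   extracellular).
#' @slot objective id of the objective (usually biomass) reaction.
#' @slot genes character vector registry of all gene ids referenced by GPRs.
#'
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    compartments = "character",
    objective = "character",
    genes = "character"
  )
)

.REACTION_KINDS <- c("enzymatic", "transport", "exchange", "biomass", "demand")

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment", "formula", "mw")
  need_rxn <- c("id", "lb", "ub", "gpr", "subsystem", "kind")
  if (!all(need_met %in% names(met))) {
    msgs <- c(msgs, "metabolites must have columns id, name, compartment, formula, mw")
  }
  if (!all(need_rxn %in% names(rxn))) {
    msgs <- c(msgs, "reactions must have columns id, lb, ub, gpr, subsystem, kind")
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (!identical(dim(S), c(nrow(met), nrow(rxn)))) {
    msgs <- c(msgs, "stoichiometry dimensions do not match metabolite/reaction tables")
  } else {
    if (nrow(met) && !identical(rownames(S), met$id)) {
      msgs <- c(msgs, "stoichiometry rownames != metabolite ids")
    }
    if (nrow(rxn) && !identical(colnames(S), rxn$id)) {
      msgs <- c(msgs, "stoichiometry colnames != reaction ids")
    }
  }
  if (any(rxn$lb > rxn$ub + 1e-12)) msgs <- c(msgs, "reaction with lb > ub")
  if (!all(rxn$kind %in% .REACTION_KINDS)) {
    msgs <- c(msgs, sprintf("unknown reaction kind(s): %s",
                            paste(setdiff(rxn$kind, .REACTION_KINDS), collapse = ", ")))
  }
  bad_mw <- !is.na(met$mw) & met$mw <= 0
  if (any(bad_mw)) msgs <- c(msgs, "metabolite mw must be > 0 when present")
  if (any(!met$compartment %in% object@compartments)) {
    msgs <- c(msgs, "metabolite compartment not in compartment list")
  }
  if (length(object@objective) == 1 && nzchar(object@objective) &&
      !object@objective %in% rxn$id) {
    msgs <- c(msgs, sprintf("objective reaction '%s' not in model", object@objective))
  }
  if (nrow(rxn) && length(msgs) == 0) {
    nz <- Matrix::colSums(abs(S) > 0)
    if (any(nz == 0)) {
      msgs <- c(msgs, sprintf("reaction(s) with empty stoichiometry: %s",
                              paste(rxn$id[nz == 0], collapse = ", ")))
    }
    is_ex <- rxn$kind == "exchange"
    if (any(is_ex) && any(nz[is_ex] != 1)) {
      msgs <- c(msgs, "exchange reactions must touch exactly one metabolite")
    }
    gset <- unique(unlist(lapply(rxn$gpr, function(g) gprGenes(parseGPR(g)))))
    if (length(gset) && !all(gset %in% object@genes)) {
      msgs <- c(msgs, "GPR references gene(s) absent from the gene registry")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Growth condition
#'
#' A named set of exchange-bound overrides plus the biomass reaction that the
#' condition optimizes. The four standard conditions of the algal pipeline are
#' \code{auto_100}, \code{auto_3k}, \code{mixo} and \code{hetero}.
#'
#' @slot name condition name.
#' @slot overrides named list, exchange reaction id -> numeric c(lb, ub).
#' @slot biomass id of the condition's biomass reaction.
#' @export
setClass("GrowthCondition",
  representation(name = "character", overrides = "list", biomass = "character")
)

#' Replicated multi-compartment model
#'
#' A base model expanded so that each reaction is instantiated once per
#' assigned compartment (instance id \code{parent__compartment}) over
#' compartment-specific metabolite pools, optionally augmented with candidate
#' 1:1 carrier transports between pools of a shared metabolite.
#'
#' @slot model the replicated \linkS4class{MetabolicModel}.
#' @slot provenance data.frame with columns \code{instance}, \code{parent},
#'   \code{compartment}.
#' @slot transports character vector of candidate transport reaction ids.
#' @export
setClass("ReplicatedModel",
  representation(model = "MetabolicModel", provenance = "data.frame",
                 transports = "character")
)

#' Result of the minimal-additions compartmentalization MILP
#'
#' @slot model pruned \linkS4class{MetabolicModel}.
#' @slot kept,removed instance ids retained / removed by the MILP.
#' @slot keptTransports retained candidate transports.
#' @slot objective optimal number of retained removable reactions.
#' @slot status solver status string.
#' @export
setClass("CompartmentalizationResult",
  representation(model = "MetabolicModel", kept = "character",
                 removed = "character", keptTransports = "character",
                 objective = "numeric", status = "character")
)

#' Report of thermodynamically-infeasible-cycle elimination
#'
#' @slot model model after removal (removed directions closed).
#' @slot ticReactions reactions (directions) able to carry flux with all
#'   exchanges closed.
#' @slot removed minimal removal set (direction ids).
#' @slot certificates list of cycle supports found during the hitting-set
#'   iterations.
#' @slot status \code{"optimal"} or \code{"no_valid_removal"}.
#' @export
setClass("TicReport",
  representation(model = "MetabolicModel", ticReactions = "character",
                 removed = "character", certificates = "list",
                 status = "character")
)

#' Condition-specific biomass reaction
#'
#' Precursor coefficients in mmol g-1 DW (consumed, stored negative) plus
#' byproducts (polymerization water) produced, normalized so that the
#' molecular-weight-weighted sum of consumed precursors equals 1 g g-1 DW.
#'
#' @slot name biomass reaction name (e.g. \code{biomass_auto_100}).
#' @slot coefficients named numeric, metabolite id -> signed coefficient
#'   (negative = consumed).
#' @slot mw named numeric, metabolite id -> molecular weight used (g mol-1),
#'   residue weights for polymer monomers.
#' @export
setClass("BiomassReaction",
  representation(name = "character", coefficients = "numeric", mw = "numeric")
)

#' Enzyme-constrained model (GECKO-style)
#'
#' @slot model augmented \linkS4class{MetabolicModel} with enzyme
#'   pseudo-metabolites, usage (draw) reactions and the protein-pool exchange.
#' @slot pool total protein pool bound, g protein g-1 DW.
#' @slot enzymes data.frame with columns \code{reaction} (constrained
#'   instance), \code{protein}, \code{kcat_per_s}, \code{kda}.
#' @export
setClass("ECModel",
  representation(model = "MetabolicModel", pool = "numeric",
                 enzymes = "data.frame")
)

#' Flux solution
#'
#' @slot objective objective value (h-1 when the objective is growth).
#' @slot fluxes named numeric flux vector (mmol g-1 DW h-1).
#' @slot status solver status string.
#' @export
setClass("FluxResult",
  representation(objective = "numeric", fluxes = "numeric", status = "character")
)

#' Flux sample
#'
#' @slot samples numeric matrix n_samples x n_reactions (named columns).
#' @slot seed RNG seed used for the chain.
#' @slot thinning thinning constant (chain steps per kept sample).
#' @export
setClass("FluxSample",
  representation(samples = "matrix", seed = "numeric", thinning = "numeric")
)
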