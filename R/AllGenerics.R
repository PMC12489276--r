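#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichiometry", function(object, ...) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("compartmentIds", function(object, ...) standardGeneric("compartmentIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveReaction", function(object, ...) standardGeneric("objectiveReaction"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveReaction<-", function(object, value) standardGeneric("objectiveReaction<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("modelGenes", function(object, ...) standardGeneric("modelGenes"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' Flux vector / objective accessors
#' @param object a \linkS4class{FluxResult} or \linkS4class{FluxSample}.
#' @param ... unused.
#' @rdname result-accessors
#' @export
setGeneric("fluxes", function(object, ...) standardGeneric("fluxes"))

#' @rdname result-accessors
#' @export
setGeneric("objectiveValue", function(object, ...) standardGeneric("objectiveValue"))

#' @rdname result-accessors
#' @export
setGeneric("solverStatus", function(object, ...) standardGeneric("solverStatus"))
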