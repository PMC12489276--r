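# Reproduction of the published whole-model analyses. The curated algal GEMs
# (iCO1515 and relatives) are distributed by their authors and are not
# bundled here; point `reproduceBenchmark()` at a local copy (SBML) to rerun
# the growth, essentiality, activity-partition and target-screening analyses
# on it.

#' Rerun the flux analyses on a published genome-scale model
#'
#' Loads an SBML model, applies the four standard growth conditions (the
#' model must carry the standard media exchanges or a bound override list
#' must be supplied per condition), and recomputes: FBA growth rates,
#' essential gene and reaction counts under photoautotrophic low light,
#' essential genes common to all conditions, the active-reaction condition
#' partition, and the growth-correlated gene count.
#'
#' @param modelPath path to the model SBML/JSON file.
#' @param conditions optional named list of \linkS4class{GrowthCondition}
#'   objects (names \code{auto_100}, \code{auto_3k}, \code{mixo},
#'   \code{hetero}); by default built with \code{\link{standardCondition}}.
#' @param nIncrements growth increments for target screening (default 100).
#' @return list with \code{growth} (named numeric, h-1),
#'   \code{essentialGenes}, \code{essentialReactions} (counts, auto_100),
#'   \code{commonEssentialGenes}, \code{partition} (see
#'   \code{\link{conditionPartition}}), and \code{correlatedGenes} (count).
#' @export
reproduceBenchmark <- function(modelPath, conditions = NULL, nIncrements = 100) {
  model <- readMetabolicModel(modelPath)
  condNames <- c("auto_100", "auto_3k", "mixo", "hetero")
  if (is.null(conditions)) {
    conditions <- lapply(condNames, function(nm) standardCondition(model, nm))
    names(conditions) <- condNames
  }
  growth <- vapply(conditions, function(cd) objectiveValue(fba(model, cd)),
                   numeric(1))
  essG <- essentiality(model, conditions$auto_100, target = "gene")
  essR <- essentiality(model, conditions$auto_100, target = "reaction")
  essAll <- Reduce(intersect, lapply(conditions, function(cd) {
    essentiality(model, cd, target = "gene")
  }))
  act <- lapply(conditions[c("auto_100", "mixo", "hetero")], function(cd) {
    callActiveReactions(model, cd)
  })
  part <- conditionPartition(act$auto_100, act$mixo, act$hetero)
  targ <- growthCorrelatedTargets(model, conditions$auto_100,
                                  nIncrements = nIncrements)
  list(growth = growth,
       essentialGenes = length(essG),
       essentialReactions = length(essR),
       commonEssentialGenes = length(essAll),
       partition = part,
       correlatedGenes = length(targ$genes))
}
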