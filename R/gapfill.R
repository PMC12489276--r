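# MILP gap-filling: add the minimum-cardinality subset of a universal
# reaction pool that makes biomass producible at a flux floor.

#' Gap-fill a model against a universal reaction pool
#'
#' Merges the candidate pool into the model, attaches a binary retention
#' indicator to each candidate (flux coupled by big-M) and minimizes the
#' (optionally weighted) number of retained candidates subject to steady
#' state and biomass flux >= \code{eps}. Ties are broken towards the
#' lexicographically smallest added-id set.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param pool a \linkS4class{MetabolicModel} whose reactions are the
#'   candidates (ids must be disjoint from the model's).
#' @param biomass biomass reaction id in \code{model}.
#' @param eps biomass flux floor (default 1e-3).
#' @param bigM big-M flux cap (default 1000).
#' @param penalty optional named numeric per-candidate weight (default 1).
#' @return character vector of added candidate ids (empty if the model is
#'   already feasible).
#' @export
gapfillMILP <- function(model, pool, biomass, eps = 1e-3, bigM = 1000,
                        penalty = NULL) {
  if (!biomass %in% model@reactions$id) stop("biomass reaction not in model: ", biomass)
  overlap <- intersect(pool@reactions$id, model@reactions$id)
  if (length(overlap)) {
    stop("pool ids must be disjoint from model ids: ", paste(overlap, collapse = ", "))
  }
  # already feasible without additions?
  base <- setBounds(model, biomass, lb = eps)
  if (.modelLP(base, setNames(1, biomass), maximize = TRUE)$status == "optimal") {
    return(character(0))
  }
  merged <- model
  pmet <- pool@metabolites
  for (i in seq_len(nrow(pmet))) {
    merged <- addMetabolite(merged, pmet$id[i], name = pmet$name[i],
                            compartment = pmet$compartment[i],
                            formula = pmet$formula[i], mw = pmet$mw[i])
  }
  pS <- pool@stoichiometry
  prxn <- pool@reactions
  for (i in seq_len(nrow(prxn))) {
    col <- pS[, i]; nz <- which(col != 0)
    merged <- addReaction(merged, prxn$id[i], setNames(col[nz], pmet$id[nz]),
                          lb = prxn$lb[i], ub = prxn$ub[i], gpr = prxn$gpr[i],
                          subsystem = prxn$subsystem[i], kind = prxn$kind[i])
  }
  merged <- setBounds(merged, biomass, lb = eps)
  cand <- sort(prxn$id)
  # feasibility with the whole pool
  pre <- .modelLP(merged, setNames(1, biomass), maximize = TRUE)
  if (pre$status != "optimal") {
    bad <- .probeBiomassPrecursors(merged, biomass, eps)
    stop("biomass infeasible even with the entire pool; unproducible precursor(s): ",
         paste(bad, collapse = ", "))
  }
  rxn <- merged@reactions
  n <- nrow(rxn); k <- length(cand)
  cix <- match(cand, rxn$id)
  S <- as.matrix(merged@stoichiometry)
  nv <- n + k
  A <- cbind(S, matrix(0, nrow(S), k))
  rlb <- rep(0, nrow(S)); rub <- rep(0, nrow(S))
  cup <- matrix(0, k, nv); cdn <- matrix(0, k, nv)
  for (t in seq_len(k)) {
    cup[t, cix[t]] <- 1; cup[t, n + t] <- -bigM
    cdn[t, cix[t]] <- 1; cdn[t, n + t] <- bigM
  }
  A <- rbind(A, cup, cdn)
  rlb <- c(rlb, rep(-Inf, k), rep(0, k))
  rub <- c(rub, rep(0, k), rep(Inf, k))
  w <- rep(1, k)
  if (!is.null(penalty)) {
    hit <- cand %in% names(penalty)
    w[hit] <- penalty[cand[hit]]
  }
  obj <- c(rep(0, n), w + 1e-6 * seq_len(k) / k)
  vlb <- c(pmax(rxn$lb, -bigM), rep(0, k))
  vub <- c(pmin(rxn$ub, bigM), rep(1, k))
  sol <- solveProblem(obj, A, rlb, rub, vlb, vub,
                      integer = c(rep(FALSE, n), rep(TRUE, k)))
  if (sol$status != "optimal") stop("gap-filling MILP failed: ", sol$status)
  cand[sol$x[n + seq_len(k)] > 0.5]
}

# per-precursor demand probe on the biomass reaction's substrates
.probeBiomassPrecursors <- function(model, biomass, eps) {
  col <- model@stoichiometry[, match(biomass, model@reactions$id)]
  prec <- names(which(col < 0))
  bad <- character(0)
  model <- setBounds(model, biomass, lb = 0)
  for (p in prec) {
    did <- paste0(".probe_", p)
    probe <- addReaction(model, did, setNames(-1, p), lb = 0, ub = 1000,
                         kind = "demand")
    sol <- .modelLP(probe, setNames(1, did), maximize = TRUE)
    if (sol$status != "optimal" || sol$objective < eps) bad <- c(bad, p)
  }
  bad
}
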