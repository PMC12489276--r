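# Thermodynamically infeasible cycles (TICs): internal loops that can carry
# flux with every boundary reaction closed. Identification is a per-direction
# LP sweep with unit caps; removal is a lazy hitting-set MILP that finds the
# minimum-cardinality set of directions whose closure makes the internal
# network flux-free while biomass production survives.

.isBoundaryKind <- function(kind) kind %in% c("exchange", "demand")

# close boundary reactions and cap internal fluxes at [-cap, cap]
.closedBounds <- function(model, cap = 1) {
  rxn <- model@reactions
  lb <- rxn$lb; ub <- rxn$ub
  boundary <- .isBoundaryKind(rxn$kind)
  lb[boundary] <- 0; ub[boundary] <- 0
  lb <- pmax(lb, -cap); ub <- pmin(ub, cap)
  lb <- pmin(lb, ub)  # guard reactions with forced positive flux
  list(lb = lb, ub = ub)
}

#' Find all reactions that can participate in a TIC
#'
#' With all exchange (and demand) bounds closed and internal fluxes capped at
#' +-1, every reaction whose maximal absolute flux exceeds \code{tol} is part
#' of some thermodynamically infeasible cycle. Implemented as a per-reaction
#' LP sweep; reactions already seen carrying flux in a previous optimum are
#' marked without re-solving.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tol detection tolerance on LP optima (default 1e-6).
#' @return character vector of reaction ids.
#' @export
findTicReactions <- function(model, tol = 1e-6) {
  rxn <- model@reactions
  if (!nrow(rxn)) return(character(0))
  cb <- .closedBounds(model)
  internal <- which(!.isBoundaryKind(rxn$kind))
  status <- setNames(rep(NA, nrow(rxn)), rxn$id)  # TRUE in TIC, FALSE not
  fixed <- as.list(setNames(Map(c, cb$lb, cb$ub), rxn$id))
  for (i in internal) {
    id <- rxn$id[i]
    if (!is.na(status[id])) next
    inTic <- FALSE
    for (sense in c(TRUE, FALSE)) {
      sol <- .modelLP(model, setNames(1, id), maximize = sense, fixed = fixed)
      if (sol$status == "optimal" && abs(sol$objective) > tol) {
        hot <- names(sol$x)[abs(sol$x) > tol]
        status[hot] <- TRUE
        inTic <- TRUE
        break
      }
    }
    if (!inTic && is.na(status[id])) status[id] <- FALSE
  }
  names(status)[which(status %in% TRUE)]
}

#' Certify that a model is free of TICs
#'
#' Splits reversible reactions internally, closes all boundary reactions,
#' caps each direction at 1 and maximizes total internal flux: the model is
#' TIC-free iff the optimum is zero (every direction's feasible range is
#' [0, 0]).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tol absolute tolerance on the LP optimum (default 1e-6).
#' @return list with \code{ticFree} (logical) and \code{maxInternalFlux}
#'   (the witness total flux).
#' @export
certifyTicFree <- function(model, tol = 1e-6) {
  if (!nrow(model@reactions)) return(list(ticFree = TRUE, maxInternalFlux = 0))
  sm <- splitReversible(model)$model
  rxn <- sm@reactions
  cb <- .closedBounds(sm)
  internal <- rxn$id[!.isBoundaryKind(rxn$kind)]
  if (!length(internal)) return(list(ticFree = TRUE, maxInternalFlux = 0))
  fixed <- as.list(setNames(Map(c, cb$lb, cb$ub), rxn$id))
  sol <- .modelLP(sm, setNames(rep(1, length(internal)), internal),
                  maximize = TRUE, fixed = fixed)
  val <- if (sol$status == "optimal") sol$objective else Inf
  list(ticFree = is.finite(val) && val <= tol, maxInternalFlux = val)
}

#' Remove a minimal set of reaction directions to eliminate all TICs
#'
#' Iterative hitting-set MILP. Reversible reactions are first split into
#' direction pairs, and the set of TIC-capable directions is identified. An
#' inner LP (boundaries closed, retained TIC directions capped at 1) searches
#' for a remaining cycle; its support adds a covering cut. The master MILP
#' minimizes the number of removed directions subject to all cuts plus an
#' embedded flux block forcing biomass flux >= \code{eps} to survive the
#' removal. Terminates when the inner LP proves no cycle remains; the removal
#' set is minimum-cardinality over the accumulated cuts. Removing one
#' direction of a reversible reaction converts it to irreversible rather than
#' deleting it.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param biomass biomass reaction id (must be FBA-feasible beforehand).
#' @param eps biomass flux floor, mmol g-1 DW h-1 (default 1e-3).
#' @param tol LP detection tolerance (default 1e-6).
#' @param bigM big-M used in the biomass survival block (default 1000).
#' @param wholeReaction remove whole reactions instead of single directions.
#' @return a \linkS4class{TicReport}; status \code{"no_valid_removal"} when
#'   every hitting set kills biomass production.
#' @export
minimalTicRemoval <- function(model, biomass, eps = 1e-3, tol = 1e-6,
                              bigM = 1000, wholeReaction = FALSE) {
  if (!biomass %in% model@reactions$id) stop("biomass reaction not in model: ", biomass)
  split <- splitReversible(model)
  sm <- split$model
  map <- split$mapping
  bm <- biomass
  if (!bm %in% sm@reactions$id) {
    f <- map$fwd[match(biomass, map$parent)]
    bm <- if (!is.na(f)) f else map$bwd[match(biomass, map$parent)]
  }
  tic <- findTicReactions(sm, tol = tol)
  tic <- sort(tic)
  if (wholeReaction) {
    # group directions of one parent: removing any direction removes both
    parent_of <- function(id) {
      hit <- map$parent[match(id, map$fwd)]
      hit2 <- map$parent[match(id, map$bwd)]
      ifelse(!is.na(hit), hit, ifelse(!is.na(hit2), hit2, id))
    }
  }
  if (!length(tic)) {
    return(new("TicReport", model = model, ticReactions = character(0),
               removed = character(0), certificates = list(),
               status = "optimal"))
  }
  rxn <- sm@reactions
  n <- nrow(rxn)
  k <- length(tic)
  tix <- match(tic, rxn$id)
  cb <- .closedBounds(sm)
  cuts <- list()
  removed <- character(0)
  repeat {
    # inner LP: any circulation among retained TIC directions?
    fixed <- as.list(setNames(Map(c, cb$lb, cb$ub), rxn$id))
    for (id in removed) fixed[[id]] <- c(0, 0)
    sol <- .modelLP(sm, setNames(rep(1, k), tic), maximize = TRUE, fixed = fixed)
    if (sol$status == "optimal" && sol$objective <= tol) break
    if (sol$status != "optimal") {
      stop("internal error: closed-network LP not optimal (", sol$status, ")")
    }
    support <- tic[sol$x[tic] > tol]
    if (wholeReaction) {
      par <- unique(vapply(support, parent_of, character(1)))
      support <- tic[vapply(tic, parent_of, character(1)) %in% par]
    }
    cuts[[length(cuts) + 1L]] <- support
    # master MILP: min #removed s.t. every cut hit, biomass still feasible
    nv <- n + k
    S <- as.matrix(sm@stoichiometry)
    A <- cbind(S, matrix(0, nrow(S), k))
    rlb <- rep(0, nrow(S)); rub <- rep(0, nrow(S))
    # w_i <= M (1 - z_i)  =>  w_i + M z_i <= M   for TIC directions
    cup <- matrix(0, k, nv)
    for (t in seq_len(k)) {
      cup[t, tix[t]] <- 1; cup[t, n + t] <- bigM
    }
    A <- rbind(A, cup)
    rlb <- c(rlb, rep(-Inf, k)); rub <- c(rub, rep(bigM, k))
    for (cut in cuts) {
      row <- numeric(nv)
      row[n + match(cut, tic)] <- 1
      A <- rbind(A, row)
      rlb <- c(rlb, 1); rub <- c(rub, Inf)
    }
    if (wholeReaction) {
      # tie fwd/bwd removal indicators of one parent together
      pv <- vapply(tic, parent_of, character(1))
      for (p in unique(pv[duplicated(pv)])) {
        ii <- which(pv == p)
        for (t in ii[-1]) {
          row <- numeric(nv)
          row[n + ii[1]] <- 1; row[n + t] <- -1
          A <- rbind(A, row)
          rlb <- c(rlb, 0); rub <- c(rub, 0)
        }
      }
    }
    wlb <- pmax(rxn$lb, -bigM); wub <- pmin(rxn$ub, bigM)
    wlb[match(bm, rxn$id)] <- eps
    obj <- c(rep(0, n), rep(1, k))
    msol <- solveProblem(obj, A, rlb, rub, c(wlb, rep(0, k)), c(wub, rep(1, k)),
                         integer = c(rep(FALSE, n), rep(TRUE, k)))
    if (msol$status != "optimal") {
      return(new("TicReport", model = model, ticReactions = tic,
                 removed = character(0), certificates = cuts,
                 status = "no_valid_removal"))
    }
    removed <- tic[msol$x[n + seq_len(k)] > 0.5]
  }
  out <- model
  for (id in removed) {
    i <- match(id, map$fwd)
    j <- match(id, map$bwd)
    if (!is.na(i)) {
      out <- setBounds(out, map$parent[i], ub = 0)
    } else if (!is.na(j)) {
      out <- setBounds(out, map$parent[j], lb = 0)
    } else if (wholeReaction) {
      out <- removeReactions(out, id)
    } else {
      out <- setBounds(out, id, lb = 0, ub = 0)
    }
  }
  new("TicReport", model = out, ticReactions = tic, removed = sort(removed),
      certificates = cuts, status = "optimal")
}

setMethod("show", "TicReport", function(object) {
  cat("TicReport (", object@status, "): ", length(object@ticReactions),
      " TIC direction(s), ", length(object@removed), " removed in ",
      length(object@certificates), " iteration(s)\n", sep = "")
})
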