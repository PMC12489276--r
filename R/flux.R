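# Downstream flux analyses: FBA, pFBA, FVA, active-reaction calling with the
# split-direction exclusion rule, condition partitioning, gene/reaction
# essentiality and growth-correlation target screening.

.asModel <- function(model) {
  if (is(model, "ECModel")) model@model else model
}

.conditioned <- function(model, cond) {
  model <- .asModel(model)
  if (!is.null(cond)) model <- applyCondition(model, cond)
  if (!nzchar(model@objective)) stop("model has no objective reaction set")
  model
}

#' Flux balance analysis
#'
#' Maximizes the objective (biomass) flux subject to steady state and bounds.
#'
#' @param model a \linkS4class{MetabolicModel} or \linkS4class{ECModel}.
#' @param cond optional \linkS4class{GrowthCondition} applied first.
#' @return a \linkS4class{FluxResult}; growth objectives are in h-1.
#' @export
fba <- function(model, cond = NULL) {
  model <- .conditioned(model, cond)
  sol <- .modelLP(model, setNames(1, model@objective), maximize = TRUE)
  if (sol$status != "optimal") {
    return(new("FluxResult", objective = 0, fluxes = numeric(0), status = sol$status))
  }
  new("FluxResult", objective = sol$objective, fluxes = sol$x, status = sol$status)
}

#' Parsimonious FBA
#'
#' Fixes the objective at \code{fraction} of its FBA optimum and minimizes
#' total absolute flux, yielding a minimal-enzyme-usage flux distribution.
#'
#' @param model a \linkS4class{MetabolicModel} or \linkS4class{ECModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param fraction fraction of the FBA optimum to fix (default 1).
#' @param growth optional explicit growth value to fix instead of
#'   \code{fraction} x optimum.
#' @return a \linkS4class{FluxResult} whose objective is the fixed growth.
#' @export
pfba <- function(model, cond = NULL, fraction = 1, growth = NULL) {
  model <- .conditioned(model, cond)
  if (is.null(growth)) {
    opt <- fba(model)
    if (opt@status != "optimal") return(opt)
    growth <- fraction * opt@objective
  }
  rxn <- model@reactions
  n <- nrow(rxn)
  lb <- rxn$lb; ub <- rxn$ub
  oi <- match(model@objective, rxn$id)
  lb[oi] <- growth; ub[oi] <- growth
  # variables [v, t]; minimize sum t with -t <= v <= t
  S <- as.matrix(model@stoichiometry)
  m <- nrow(S)
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), -diag(n)),
             cbind(diag(n), diag(n)))
  rlb <- c(rep(0, m), rep(-Inf, n), rep(0, n))
  rub <- c(rep(0, m), rep(0, n), rep(Inf, n))
  tmax <- pmax(abs(lb), abs(ub))
  sol <- solveProblem(c(rep(0, n), rep(1, n)), A, rlb, rub,
                      c(lb, rep(0, n)), c(ub, tmax))
  if (sol$status != "optimal") {
    return(new("FluxResult", objective = 0, fluxes = numeric(0), status = sol$status))
  }
  v <- sol$x[seq_len(n)]
  names(v) <- rxn$id
  new("FluxResult", objective = growth, fluxes = v, status = "optimal")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux with the objective held at
#' \code{fractionOfOptimum} of its FBA optimum (0 = full feasible space
#' under the condition bounds).
#'
#' @param model a \linkS4class{MetabolicModel} or \linkS4class{ECModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param fractionOfOptimum growth fraction to maintain (default 1).
#' @param reactions reaction ids to analyze (default all).
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max}.
#' @export
fva <- function(model, cond = NULL, fractionOfOptimum = 1, reactions = NULL) {
  model <- .conditioned(model, cond)
  fixed <- list()
  if (fractionOfOptimum > 0) {
    opt <- fba(model)
    if (opt@status != "optimal") stop("FVA: model infeasible (", opt@status, ")")
    oi <- match(model@objective, model@reactions$id)
    fixed[[model@objective]] <- c(fractionOfOptimum * opt@objective,
                                  model@reactions$ub[oi])
  }
  ids <- if (is.null(reactions)) model@reactions$id else reactions
  res <- data.frame(reaction = ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    lo <- .modelLP(model, setNames(1, ids[j]), maximize = FALSE, fixed = fixed)
    hi <- .modelLP(model, setNames(1, ids[j]), maximize = TRUE, fixed = fixed)
    res$min[j] <- if (lo$status == "optimal") lo$objective else NA_real_
    res$max[j] <- if (hi$status == "optimal") hi$objective else NA_real_
  }
  res
}

#' Call active reactions under a condition
#'
#' Splits reversible reactions, computes each direction's maximal flux over
#' the condition's feasible space, and calls a direction active when its
#' maximum exceeds \code{tol}. Direction pairs whose forward and backward
#' maxima coincide (within relative \code{tol}) are excluded as likely
#' thermodynamically infeasible cycling, and results are reported at the
#' parent-reaction level.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param fractionOfOptimum growth fraction maintained during FVA (default 0:
#'   the full feasible space).
#' @param tol activity/equality tolerance (default 1e-6).
#' @return character vector of active parent reaction ids.
#' @export
callActiveReactions <- function(model, cond = NULL, fractionOfOptimum = 0,
                                tol = 1e-6) {
  model <- .conditioned(model, cond)
  split <- splitReversible(model)
  sm <- split$model
  map <- split$mapping
  rng <- fva(sm, fractionOfOptimum = fractionOfOptimum)
  mx <- setNames(rng$max, rng$reaction)
  active_dir <- names(mx)[mx > tol]
  excluded <- character(0)
  for (i in seq_len(nrow(map))) {
    f <- map$fwd[i]; b <- map$bwd[i]
    if (is.na(f) || !f %in% names(mx) || !b %in% names(mx)) next
    if (abs(mx[[f]] - mx[[b]]) <= tol * max(1, abs(mx[[f]]))) {
      excluded <- c(excluded, f, b)
    }
  }
  active_dir <- setdiff(active_dir, excluded)
  parents <- active_dir
  for (i in seq_len(nrow(map))) {
    parents[parents %in% c(map$fwd[i], map$bwd[i])] <- map$parent[i]
  }
  sort(unique(parents))
}

#' Partition active reactions across three growth conditions
#'
#' Exclusive-intersection (UpSet-style) counts for photoautotrophic,
#' mixotrophic and heterotrophic active sets: two-set classes exclude
#' members of the third set.
#'
#' @param auto,mixo,hetero character vectors of active reaction ids.
#' @return data.frame with columns \code{class} and \code{count}, plus the
#'   member sets in attribute \code{"sets"}.
#' @export
conditionPartition <- function(auto, mixo, hetero) {
  sets <- list(
    auto_only = setdiff(auto, union(mixo, hetero)),
    mixo_only = setdiff(mixo, union(auto, hetero)),
    hetero_only = setdiff(hetero, union(auto, mixo)),
    auto_mixo = setdiff(intersect(auto, mixo), hetero),
    auto_hetero = setdiff(intersect(auto, hetero), mixo),
    mixo_hetero = setdiff(intersect(mixo, hetero), auto),
    all = Reduce(intersect, list(auto, mixo, hetero))
  )
  out <- data.frame(class = names(sets),
                    count = vapply(sets, length, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sets") <- sets
  out
}

#' Gene or reaction essentiality by single knockouts
#'
#' A gene knockout disables every reaction whose GPR evaluates false without
#' it; a reaction knockout closes that reaction. The knockout is essential
#' when the resulting optimum drops below \code{thresholdFrac} of the
#' wild-type optimum.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param target \code{"gene"} or \code{"reaction"}.
#' @param thresholdFrac essentiality threshold as a fraction of wild-type
#'   growth (default 0.01).
#' @return character vector of essential gene or reaction ids.
#' @export
essentiality <- function(model, cond = NULL, target = c("gene", "reaction"),
                         thresholdFrac = 0.01) {
  target <- match.arg(target)
  model <- .conditioned(model, cond)
  wt <- fba(model)
  if (wt@status != "optimal" || wt@objective <= 0) {
    stop("wild-type model does not grow; essentiality undefined")
  }
  thr <- thresholdFrac * wt@objective
  rxn <- model@reactions
  rules <- lapply(rxn$gpr, parseGPR)
  essential <- character(0)
  if (target == "gene") {
    for (g in model@genes) {
      off <- which(vapply(rules, function(r) !evalGPR(r, knocked = g), logical(1)))
      if (!length(off)) next
      fixed <- as.list(setNames(rep(list(c(0, 0)), length(off)), rxn$id[off]))
      sol <- .modelLP(model, setNames(1, model@objective), maximize = TRUE,
                      fixed = fixed)
      if (sol$status != "optimal" || sol$objective < thr) essential <- c(essential, g)
    }
  } else {
    for (id in rxn$id) {
      sol <- .modelLP(model, setNames(1, model@objective), maximize = TRUE,
                      fixed = setNames(list(c(0, 0)), id))
      if (sol$status != "optimal" || sol$objective < thr) essential <- c(essential, id)
    }
  }
  essential
}

#' Screen genes whose reaction fluxes correlate with growth
#'
#' Divides the maximal growth rate into \code{nIncrements} uniform steps,
#' computes a pFBA flux distribution at each fixed growth, and selects
#' reactions whose absolute flux (so that scaling uptakes count as positively
#' associated) has Pearson correlation > \code{rMin} with growth and
#' an adjusted p-value < \code{alpha} (t transform with n-2 degrees of
#' freedom). The unique gene set of the selected reactions is returned.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param nIncrements number of growth increments (default 100).
#' @param rMin correlation threshold (default 0.8).
#' @param alpha adjusted significance threshold (default 0.01).
#' @param mtc multiple-testing correction: \code{"BH"} (default) or
#'   \code{"bonferroni"}.
#' @return list with \code{genes} (unique gene ids), \code{reactions}
#'   (selected reaction ids) and \code{table} (per-reaction r, p, p_adj;
#'   zero-variance series are reported with NA r and skipped).
#' @export
growthCorrelatedTargets <- function(model, cond = NULL, nIncrements = 100,
                                    rMin = 0.8, alpha = 0.01,
                                    mtc = c("BH", "bonferroni")) {
  mtc <- match.arg(mtc)
  model <- .conditioned(model, cond)
  opt <- fba(model)
  if (opt@status != "optimal" || opt@objective <= 0) {
    stop("model must have a positive FBA optimum for target screening")
  }
  mu <- opt@objective * seq_len(nIncrements) / nIncrements
  flux <- matrix(NA_real_, nIncrements, nrow(model@reactions),
                 dimnames = list(NULL, model@reactions$id))
  for (i in seq_along(mu)) {
    p <- pfba(model, growth = mu[i])
    if (p@status != "optimal") stop("pFBA infeasible at growth ", mu[i])
    flux[i, ] <- p@fluxes[colnames(flux)]
  }
  n <- nIncrements
  flux <- abs(flux)  # magnitudes, so scaling uptakes (negative) correlate positively
  rvec <- rep(NA_real_, ncol(flux)); pvec <- rep(NA_real_, ncol(flux))
  for (j in seq_len(ncol(flux))) {
    if (stats::sd(flux[, j]) < 1e-12) next
    r <- stats::cor(mu, flux[, j])
    rvec[j] <- r
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    pvec[j] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  padj <- rep(NA_real_, length(pvec))
  ok <- !is.na(pvec)
  padj[ok] <- stats::p.adjust(pvec[ok], method = mtc)
  sel <- which(!is.na(rvec) & rvec > rMin & padj < alpha)
  rids <- colnames(flux)[sel]
  genes <- unique(unlist(lapply(
    model@reactions$gpr[match(rids, model@reactions$id)],
    function(g) gprGenes(parseGPR(g)))))
  list(genes = genes %||% character(0), reactions = rids,
       table = data.frame(reaction = colnames(flux), r = rvec, p = pvec,
                          p_adj = padj, stringsAsFactors = FALSE))
}

#' Compare sampled fluxes between paired (homologous) reactions
#'
#' Welch two-sample t-test per pair with Bonferroni adjustment over the
#' number of pairs; pairs with zero variance on both sides are flagged
#' (\code{NA} p-value).
#'
#' @param samplesA,samplesB \linkS4class{FluxSample} objects (or matrices)
#'   drawn with the same number of samples.
#' @param pairs data.frame with columns \code{reactionA}, \code{reactionB}.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return data.frame (reactionA, reactionB, meanA, meanB, t, p, p_adj,
#'   higher_in, significant).
#' @export
compareHomologFluxes <- function(samplesA, samplesB, pairs, alpha = 0.05) {
  A <- if (is(samplesA, "FluxSample")) samplesA@samples else samplesA
  B <- if (is(samplesB, "FluxSample")) samplesB@samples else samplesB
  if (nrow(A) != nrow(B)) stop("samples must have the same number of rows")
  m <- nrow(pairs)
  out <- data.frame(reactionA = pairs$reactionA, reactionB = pairs$reactionB,
                    meanA = NA_real_, meanB = NA_real_, t = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    higher_in = NA_character_, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- A[, pairs$reactionA[i]]; b <- B[, pairs$reactionB[i]]
    out$meanA[i] <- mean(a); out$meanB[i] <- mean(b)
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) next
    tt <- stats::t.test(a, b)
    out$t[i] <- unname(tt$statistic)
    out$p[i] <- tt$p.value
    out$higher_in[i] <- if (out$meanA[i] >= out$meanB[i]) "A" else "B"
  }
  ok <- !is.na(out$p)
  out$p_adj[ok] <- pmin(out$p[ok] * m, 1)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}
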