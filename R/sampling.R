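# Flux sampling with an artificial-centering hit-and-run chain. Warmup
# points are the FVA vertex solutions (per-reaction min/max optimizers), the
# chain walks in their affine hull (which is the null space of S), and every
# `thinning`-th state is kept. The C++ chain uses R's RNG, so a fixed seed
# gives a bit-identical sample matrix.

#' Sample flux distributions from the feasible polytope
#'
#' @param model a \linkS4class{MetabolicModel} or \linkS4class{ECModel}.
#' @param cond optional \linkS4class{GrowthCondition}.
#' @param n number of kept samples (default 5000).
#' @param thinning chain steps per kept sample (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param fractionOfOptimum optional growth fraction fixed during sampling
#'   (default 0: the full feasible polytope under the condition bounds).
#' @return a \linkS4class{FluxSample} (samples matrix n x reactions).
#' @export
sampleFluxes <- function(model, cond = NULL, n = 5000, thinning = 1000, seed,
                         fractionOfOptimum = 0) {
  if (missing(seed)) stop("a seed is required for reproducible sampling")
  model <- .asModel(model)
  if (!is.null(cond)) model <- applyCondition(model, cond)
  rxn <- model@reactions
  lb <- rxn$lb; ub <- rxn$ub
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("sampling requires a bounded polytope; tighten the infinite bounds on: ",
         paste(rxn$id[!is.finite(lb) | !is.finite(ub)], collapse = ", "))
  }
  fixed <- list()
  if (fractionOfOptimum > 0) {
    opt <- fba(model)
    if (opt@status != "optimal") stop("sampling: model infeasible")
    oi <- match(model@objective, rxn$id)
    fixed[[model@objective]] <- c(fractionOfOptimum * opt@objective, ub[oi])
    lb[oi] <- fractionOfOptimum * opt@objective
  }
  # warmup: optimizer of min/max for each reaction
  W <- matrix(NA_real_, nrow(rxn), 0)
  for (id in rxn$id) {
    for (mx in c(FALSE, TRUE)) {
      sol <- .modelLP(model, setNames(1, id), maximize = mx, fixed = fixed)
      if (sol$status != "optimal") {
        stop("sampling warmup LP not optimal for ", id, " (", sol$status, ")")
      }
      W <- cbind(W, sol$x)
    }
  }
  x0 <- rowMeans(W)
  set.seed(seed)
  out <- .achrChain(W, x0, lb, ub, as.integer(n), as.integer(thinning))
  colnames(out) <- rxn$id
  new("FluxSample", samples = out, seed = seed, thinning = thinning)
}

#' Audit a flux sample against the model constraints
#'
#' Checks that every sampled row satisfies steady state and the bounds within
#' \code{tol}.
#'
#' @param sample a \linkS4class{FluxSample}.
#' @param model the model it was drawn from (condition applied).
#' @param cond optional \linkS4class{GrowthCondition} applied to the model.
#' @param tol tolerance (default 1e-6).
#' @return TRUE invisibly; errors with the worst violation otherwise.
#' @export
auditFluxSample <- function(sample, model, cond = NULL, tol = 1e-6) {
  model <- .asModel(model)
  if (!is.null(cond)) model <- applyCondition(model, cond)
  X <- sample@samples[, model@reactions$id, drop = FALSE]
  S <- as.matrix(model@stoichiometry)
  resid <- max(abs(S %*% t(X)))
  lbv <- max(0, max(sweep(-X, 2, model@reactions$lb, `+`)))  # lb - x
  ubv <- max(0, max(sweep(X, 2, model@reactions$ub, `-`)))
  if (resid > tol || lbv > tol || ubv > tol) {
    stop(sprintf("flux sample violates constraints: |Sv|=%.2e, lb=%.2e, ub=%.2e",
                 resid, lbv, ubv))
  }
  invisible(TRUE)
}
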