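# Single entry point to the LP/MILP solver (HiGHS, reached through
# scipy.optimize via reticulate). Every optimization in the package -- FBA,
# pFBA, FVA, the compartmentalization and TIC MILPs, gap-filling -- assembles
# its matrices in R and hands them to solveProblem().

.algae_env <- new.env(parent = emptyenv())

.scipyOpt <- function() {
  if (is.null(.algae_env$sp)) {
    py <- Sys.getenv("RETICULATE_PYTHON", unset = "")
    if (!nzchar(py) && !reticulate::py_available(initialize = FALSE)) {
      exe <- Sys.which("python")
      if (nzchar(exe)) try(reticulate::use_python(exe, required = FALSE), silent = TRUE)
    }
    .algae_env$sp <- reticulate::import("scipy.optimize", delay_load = FALSE)
    .algae_env$np <- reticulate::import("numpy", delay_load = FALSE)
    reticulate::py_run_string(
      "import warnings; warnings.filterwarnings('ignore', message='Unrecognized options')")
  }
  .algae_env$sp
}

.SOLVER_STATUS <- c("optimal", "iteration_limit", "infeasible", "unbounded", "numerical")

#' Solve a linear or mixed-integer linear program
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to
#' \code{rowlb <= A x <= rowub} and \code{lb <= x <= ub}, with selected
#' variables integral. Backed by HiGHS (\code{scipy.optimize.milp}).
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (may be \code{NULL} for box-only problems).
#' @param rowlb,rowub row bounds (equalities: \code{rowlb == rowub}).
#' @param lb,ub variable bounds (\code{-Inf}/\code{Inf} allowed).
#' @param integer logical vector marking integer variables (default none).
#' @param maximize maximize instead of minimize.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, ...), \code{objective} and the solution vector
#'   \code{x} (\code{NULL} unless optimal).
#' @export
solveProblem <- function(obj, A = NULL, rowlb = numeric(0), rowub = numeric(0),
                         lb, ub, integer = NULL, maximize = FALSE) {
  sp <- .scipyOpt()
  np <- .algae_env$np
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (is.null(integer)) integer <- rep(FALSE, n)
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  cons <- list()
  if (!is.null(A) && nrow(A) > 0) {
    Ad <- as.matrix(A)
    cons <- list(sp$LinearConstraint(Ad, lb = np$asarray(as.numeric(rowlb)),
                                     ub = np$asarray(as.numeric(rowub))))
  }
  bnds <- sp$Bounds(lb = np$asarray(as.numeric(lb)), ub = np$asarray(as.numeric(ub)))
  # tight integrality/feasibility tolerances: big-M couplings with demand
  # floors around 1e-3 must not admit fractional "integral" indicators
  opts <- list(mip_feasibility_tolerance = 1e-9,
               primal_feasibility_tolerance = 1e-9)
  res <- suppressWarnings(
    sp$milp(c = np$asarray(cvec), constraints = cons, bounds = bnds,
            integrality = np$asarray(as.integer(integer)),
            options = opts))
  status <- .SOLVER_STATUS[res$status + 1L]
  if (identical(status, "optimal")) {
    x <- as.numeric(res$x)
    list(status = status, objective = if (maximize) -res$fun else res$fun, x = x)
  } else {
    list(status = status, objective = NA_real_, x = NULL)
  }
}

# Assemble and solve the steady-state LP for a model: optimize `obj` (named
# sparse objective over reaction ids) subject to S v = 0 and the model bounds.
# `fixed` is a named list id -> c(lb, ub) of temporary bound overrides.
.modelLP <- function(model, obj, maximize = TRUE, fixed = list(),
                     extraA = NULL, extraLb = numeric(0), extraUb = numeric(0)) {
  rxn <- model@reactions
  n <- nrow(rxn)
  lb <- rxn$lb; ub <- rxn$ub
  if (length(fixed)) {
    ix <- match(names(fixed), rxn$id)
    if (anyNA(ix)) stop("unknown reaction id(s): ",
                        paste(names(fixed)[is.na(ix)], collapse = ", "))
    for (k in seq_along(ix)) {
      lb[ix[k]] <- fixed[[k]][1]; ub[ix[k]] <- fixed[[k]][2]
    }
  }
  cvec <- numeric(n)
  cvec[match(names(obj), rxn$id)] <- unname(obj)
  S <- as.matrix(model@stoichiometry)
  m <- nrow(S)
  A <- S; rlb <- rep(0, m); rub <- rep(0, m)
  if (!is.null(extraA)) {
    A <- rbind(A, extraA); rlb <- c(rlb, extraLb); rub <- c(rub, extraUb)
  }
  sol <- solveProblem(cvec, A, rlb, rub, lb, ub, maximize = maximize)
  if (!is.null(sol$x)) names(sol$x) <- rxn$id
  sol
}
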