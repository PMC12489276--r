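# GECKO-style enzyme constraints: each constrained reaction consumes its
# enzyme pseudo-metabolite at 1/kcat (kcat in h-1) per unit flux; enzymes are
# drawn from a shared protein pool at their molecular weight in kDa
# (= g mmol-1), and the pool exchange is bounded by the measured total
# protein content P (g protein g-1 DW). Saturation/abundance factors are
# collapsed into P.

#' Apply enzyme constraints to an irreversible model
#'
#' Isozymes (top-level OR in the GPR) become parallel reaction copies
#' (\code{id__iso<k>}), each drawing its own enzyme; enzyme complexes (AND)
#' consume every subunit at flux/kcat with the pair-specific kcat applied per
#' subunit. Reactions without any kcat entry are left unconstrained, as are
#' subunits lacking a kcat.
#'
#' @param model a \linkS4class{MetabolicModel} with all \code{lb >= 0}
#'   (run \code{\link{splitReversible}} first).
#' @param kcats data.frame with columns \code{reaction}, \code{protein},
#'   \code{kcat_per_s} (turnover numbers in s-1, converted x3600 to h-1).
#' @param mws named numeric, protein id -> molecular weight in kDa.
#' @param pool total protein pool P, g protein g-1 DW.
#' @return an \linkS4class{ECModel}.
#' @export
applyEnzymeConstraints <- function(model, kcats, mws, pool) {
  stopifnot(all(c("reaction", "protein", "kcat_per_s") %in% names(kcats)))
  if (any(model@reactions$lb < 0)) {
    stop("model must be irreversible (all lb >= 0); run splitReversible() first")
  }
  if (any(kcats$kcat_per_s <= 0)) {
    bad <- kcats[kcats$kcat_per_s <= 0, ]
    stop("kcat must be > 0; offending pair(s): ",
         paste(paste(bad$reaction, bad$protein, sep = "/"), collapse = ", "))
  }
  need <- setdiff(unique(kcats$protein), names(mws))
  if (length(need)) {
    stop("missing molecular weight (kDa) for protein(s): ", paste(need, collapse = ", "))
  }
  out <- model
  out <- addMetabolite(out, "prot_pool", name = "protein pool",
                       compartment = out@compartments[1])
  used <- character(0)
  enz <- list()
  for (r in unique(kcats$reaction)) {
    if (!r %in% out@reactions$id) {
      stop("kcat table references unknown reaction: ", r)
    }
    kc <- kcats[kcats$reaction == r, , drop = FALSE]
    i <- match(r, out@reactions$id)
    rule <- parseGPR(out@reactions$gpr[i])
    alts <- .isozymeAlternatives(rule, kc$protein)
    col <- out@stoichiometry[, i]
    nz <- which(col != 0)
    st0 <- setNames(col[nz], out@metabolites$id[nz])
    rrow <- out@reactions[i, ]
    copies <- if (length(alts) > 1) paste0(r, "__iso", seq_along(alts)) else r
    if (length(alts) > 1) out <- removeReactions(out, r, dropOrphans = FALSE)
    for (a in seq_along(alts)) {
      st <- st0
      members <- intersect(alts[[a]], kc$protein)
      for (p in members) {
        kcat_h <- 3600 * kc$kcat_per_s[match(p, kc$protein)]
        pm <- paste0("prot_", p)
        if (!pm %in% out@metabolites$id) {
          out <- addMetabolite(out, pm, name = paste("enzyme", p),
                               compartment = out@compartments[1])
        }
        st[pm] <- (if (pm %in% names(st)) st[[pm]] else 0) - 1 / kcat_h
        used <- union(used, p)
        enz[[paste(copies[a], p)]] <- data.frame(
          reaction = copies[a], protein = p,
          kcat_per_s = kc$kcat_per_s[match(p, kc$protein)],
          kda = mws[[p]], stringsAsFactors = FALSE)
      }
      if (length(alts) > 1) {
        out <- addReaction(out, copies[a], st, lb = rrow$lb, ub = rrow$ub,
                           gpr = paste(alts[[a]], collapse = " and "),
                           subsystem = rrow$subsystem, kind = rrow$kind)
      } else if (length(members)) {
        out <- .replaceStoich(out, r, st)
      }
    }
  }
  for (p in used) {
    out <- addReaction(out, paste0("draw_prot_", p),
                       setNames(c(-mws[[p]], 1), c("prot_pool", paste0("prot_", p))),
                       lb = 0, ub = 1000, kind = "demand", subsystem = "enzyme")
  }
  out <- addReaction(out, "EX_prot_pool", setNames(1, "prot_pool"),
                     lb = 0, ub = pool, kind = "exchange", subsystem = "enzyme")
  enzdf <- if (length(enz)) do.call(rbind, enz) else
    data.frame(reaction = character(0), protein = character(0),
               kcat_per_s = numeric(0), kda = numeric(0))
  rownames(enzdf) <- NULL
  new("ECModel", model = out, pool = pool, enzymes = enzdf)
}

# top-level OR branches are isozyme alternatives; each branch contributes its
# full gene set (complex). No GPR: every listed protein is its own isozyme.
.isozymeAlternatives <- function(rule, proteins) {
  if (is.null(rule)) return(as.list(unique(proteins)))
  if (is.character(rule)) return(list(rule))
  if (rule$op == "or") {
    return(lapply(rule$args, function(a) gprGenes(a)))
  }
  list(gprGenes(rule))
}

.replaceStoich <- function(model, id, stoich) {
  i <- match(id, model@reactions$id)
  for (m in setdiff(names(stoich), model@metabolites$id)) {
    model <- addMetabolite(model, m)
  }
  col <- numeric(nrow(model@metabolites))
  col[match(names(stoich), model@metabolites$id)] <- unname(stoich)
  model@stoichiometry[, i] <- col
  model
}

#' Protein-pool bound of an enzyme-constrained model
#' @param ec an \linkS4class{ECModel}.
#' @return pool bound P in g protein g-1 DW.
#' @export
proteinPool <- function(ec) ec@pool

#' Set the protein-pool bound
#' @param ec an \linkS4class{ECModel}.
#' @param pool new bound (g protein g-1 DW; \code{Inf} lifts the constraint).
#' @return the updated \linkS4class{ECModel}.
#' @export
setProteinPool <- function(ec, pool) {
  ec@pool <- pool
  ec@model <- setBounds(ec@model, "EX_prot_pool", ub = min(pool, 1e9))
  ec
}

setMethod("show", "ECModel", function(object) {
  cat("ECModel:", nrow(object@enzymes), "reaction-enzyme couplings, pool =",
      object@pool, "g protein g-1 DW\n")
})
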