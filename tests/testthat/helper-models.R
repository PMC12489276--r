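# Toy model builders shared across the test files. All are constructed in
# code; closed-form optima are stated next to each builder.

# uptake (<=10) -> transport -> biomass consuming 2 substrate per unit:
# FBA optimum 5.
chainModel <- function() {
  m <- emptyModel(c("c", "e"))
  m <- addReaction(m, "EX_s", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "T", c(s_e = -1, s = 1), gpr = "g_t")
  m <- addReaction(m, "BM", c(s = -2), kind = "biomass")
  objectiveReaction(m) <- "BM"
  m
}

# two equivalent parallel branches feeding biomass; optimum 10.
twoBranchModel <- function() {
  m <- emptyModel(c("c", "e"))
  m <- addReaction(m, "EX_s", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "A1", c(s_e = -1, p = 1), gpr = "ga")
  m <- addReaction(m, "A2", c(s_e = -1, p = 1), gpr = "gb")
  m <- addReaction(m, "BM", c(p = -1), kind = "biomass")
  objectiveReaction(m) <- "BM"
  m
}

# 1-D segment: src -> x -> sink, both capped at [0, 10]; the feasible set is
# the segment v_src = v_snk in [0, 10].
segmentModel <- function() {
  m <- emptyModel("c")
  m <- addReaction(m, "SRC", c(x = 1), lb = 0, ub = 10, kind = "demand")
  m <- addReaction(m, "SNK", c(x = -1), lb = 0, ub = 10, kind = "demand")
  m
}

# canonical internal 2-cycle A<->B plus a biomass route through R1.
twoCycleModel <- function() {
  m <- emptyModel(c("c", "e"))
  m <- addReaction(m, "EX_a", c(a_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "T", c(a_e = -1, a = 1))
  m <- addReaction(m, "R1", c(a = -1, b = 1))
  m <- addReaction(m, "R2", c(b = -1, a = 1))
  m <- addReaction(m, "BM", c(b = -1), kind = "biomass")
  objectiveReaction(m) <- "BM"
  m
}

# brute-force minimum retained-set size for a compartmentalization instance:
# enumerate retained subsets by increasing cardinality, require parent
# coverage, check joint demand feasibility by LP.
bruteForceMinimalRetained <- function(repm, precursors, eps = 1e-3,
                                      fixedKeep = character(0)) {
  model <- repm@model
  demands <- character(0)
  for (i in seq_len(nrow(precursors))) {
    pool <- paste0(precursors$metabolite[i], "__", precursors$compartment[i])
    did <- paste0("DM_", pool)
    if (!did %in% reactions(model)$id) {
      model <- addReaction(model, did, setNames(-1, pool), lb = eps, ub = 1000,
                           kind = "demand")
      demands <- c(demands, did)
    }
  }
  removable <- sort(setdiff(union(repm@provenance$instance, repm@transports),
                            fixedKeep))
  k <- length(removable)
  prov <- repm@provenance
  parents <- unique(prov$parent)
  feasibleWith <- function(keep) {
    closed <- setdiff(removable, keep)
    fixed <- as.list(setNames(rep(list(c(0, 0)), length(closed)), closed))
    sol <- algaeGEM:::.modelLP(model, setNames(1, reactions(model)$id[1]),
                               maximize = TRUE, fixed = fixed)
    sol$status == "optimal"
  }
  for (size in 0:k) {
    if (size == 0) {
      if (coversParents(character(0), prov, fixedKeep) &&
          feasibleWith(character(0))) return(0)
      next
    }
    combs <- utils::combn(removable, size, simplify = FALSE)
    for (keep in combs) {
      if (!coversParents(keep, prov, fixedKeep)) next
      if (feasibleWith(keep)) return(size)
    }
  }
  Inf
}

coversParents <- function(keep, prov, fixedKeep) {
  for (p in unique(prov$parent)) {
    inst <- prov$instance[prov$parent == p]
    if (!any(inst %in% c(keep, fixedKeep))) return(FALSE)
  }
  TRUE
}

# brute-force minimum number of removed directions that makes the split model
# TIC-free while biomass stays feasible; Inf when no subset works.
bruteForceTicRemoval <- function(model, biomass, eps = 1e-3, tol = 1e-6) {
  split <- splitReversible(model)
  sm <- split$model
  bm <- biomass
  if (!bm %in% reactions(sm)$id) {
    map <- split$mapping
    f <- map$fwd[match(biomass, map$parent)]
    bm <- if (!is.na(f)) f else map$bwd[match(biomass, map$parent)]
  }
  tic <- sort(findTicReactions(sm, tol = tol))
  if (!length(tic)) return(0)
  rxn <- reactions(sm)
  cb <- algaeGEM:::.closedBounds(sm)
  internal <- rxn$id[!rxn$kind %in% c("exchange", "demand")]
  for (size in 0:length(tic)) {
    combs <- if (size == 0) list(character(0)) else
      utils::combn(tic, size, simplify = FALSE)
    for (rem in combs) {
      closedFix <- as.list(setNames(Map(c, cb$lb, cb$ub), rxn$id))
      for (id in rem) closedFix[[id]] <- c(0, 0)
      loop <- algaeGEM:::.modelLP(sm, setNames(rep(1, length(tic)), tic),
                                  maximize = TRUE, fixed = closedFix)
      if (!(loop$status == "optimal" && loop$objective <= tol)) next
      openFix <- as.list(setNames(rep(list(c(0, 0)), length(rem)), rem))
      openFix[[bm]] <- c(eps, rxn$ub[match(bm, rxn$id)])
      grow <- algaeGEM:::.modelLP(sm, setNames(1, bm), maximize = TRUE,
                                  fixed = openFix)
      if (grow$status == "optimal") return(size)
    }
  }
  Inf
}
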