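# Synthetic fixtures: a hand-designed compartmentalization toy (two
# replicable reactions, three compartments, five shared metabolites with a
# unique minimal pruning), seeded localization profiles with planted truth,
# and random pathway models with planted cycles and gaps. All generators are
# pure functions of their arguments and seed.

#' The two-reaction / three-compartment compartmentalization toy
#'
#' An uncompartmentalized network with reactions \code{R1: a -> b + d} and
#' \code{R2: b -> c + f} over five shared metabolites, replicable into
#' compartments C1-C3. Substrate \code{a} is natively supplied in C1 and C2
#' and \code{b} in C3 (non-removable supply reactions), and the designated
#' precursors demand \code{c,d,f} in C1, \code{b,d} in C2 and \code{c,f} in
#' C3. Under these requirements the unique minimal solution retains
#' \code{R1} in C1 and C2 and \code{R2} in C1 and C3 -- i.e. removes one
#' instance of R2 from C2 and one instance of R1 from C3 -- and prunes all
#' fifteen candidate transports.
#'
#' @return list with \code{model} (base \linkS4class{MetabolicModel}),
#'   \code{assignment} (reaction -> compartments), \code{precursors}
#'   (data.frame metabolite/compartment), \code{fixedKeep} (supply instance
#'   ids) and \code{expectedRemovedInstances}.
#' @export
makeTwoReactionToy <- function() {
  m <- emptyModel("c")
  for (x in c("a", "b", "c", "d", "f")) m <- addMetabolite(m, x)
  m <- addReaction(m, "R1", c(a = -1, b = 1, d = 1), gpr = "gR1")
  m <- addReaction(m, "R2", c(b = -1, c = 1, f = 1), gpr = "gR2")
  m <- addReaction(m, "U_a", c(a = 1), kind = "demand", subsystem = "supply")
  m <- addReaction(m, "U_b", c(b = 1), kind = "demand", subsystem = "supply")
  assignment <- list(R1 = c("C1", "C2", "C3"), R2 = c("C1", "C2", "C3"),
                     U_a = c("C1", "C2"), U_b = "C3")
  precursors <- data.frame(
    metabolite = c("c", "d", "f", "b", "d", "c", "f"),
    compartment = c("C1", "C1", "C1", "C2", "C2", "C3", "C3"),
    stringsAsFactors = FALSE)
  list(model = m, assignment = assignment, precursors = precursors,
       fixedKeep = c("U_a__C1", "U_a__C2", "U_b__C3"),
       expectedRemovedInstances = c("R1__C3", "R2__C2"))
}

#' Simulate per-tool protein localization profiles with planted truth
#'
#' Each tool reports, per protein, a probability vector
#' \code{(1 - eta) * e_true + eta * w} where \code{w} is an independent
#' uniform random point on the compartment simplex. The true compartment
#' therefore always holds at least \code{1 - eta} of the mass, and the
#' consensus recovers the planted assignment whenever \code{1 - eta} clears
#' the retention threshold.
#'
#' @param trueAssignment named character vector, protein -> true compartment.
#' @param compartments compartment universe.
#' @param nTools number of simulated tools (default 5).
#' @param eta noise level in [0, 1).
#' @param seed RNG seed.
#' @return data.frame (protein, tool, compartment, probability).
#' @export
simulateLocalizationProfiles <- function(trueAssignment, compartments,
                                         nTools = 5, eta = 0.2, seed = 1) {
  stopifnot(eta >= 0, eta < 1, all(trueAssignment %in% compartments))
  set.seed(seed)
  k <- length(compartments)
  rows <- vector("list", length(trueAssignment) * nTools)
  ix <- 0L
  for (p in names(trueAssignment)) {
    for (t in seq_len(nTools)) {
      w <- -log(runif(k))          # Dirichlet(1) via normalized exponentials
      w <- w / sum(w)
      prob <- eta * w
      ti <- match(trueAssignment[[p]], compartments)
      prob[ti] <- prob[ti] + (1 - eta)
      ix <- ix + 1L
      rows[[ix]] <- data.frame(protein = p, tool = paste0("tool", t),
                               compartment = compartments, probability = prob,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random pathway model with planted cycles and gaps
#'
#' Generates a linear uptake -> chain -> biomass backbone (guaranteed
#' acyclic, hence TIC-free) and plants: \code{nTics} internal cycles of
#' length \code{ticLength} on fresh metabolites branching off the chain, and
#' \code{nGaps} chain reactions moved out of the model into a universal pool.
#' Construction records name the planted reactions so oracles can verify
#' detection exactly.
#'
#' @param nChain backbone length (default 6 internal reactions).
#' @param nTics number of planted internal cycles (default 1).
#' @param ticLength reactions per planted cycle (>= 2, default 3).
#' @param nGaps number of backbone reactions moved to the pool (default 0).
#' @param seed RNG seed.
#' @return list with \code{model}, \code{pool} (universal pool model,
#'   possibly empty), \code{biomass} (reaction id), \code{ticReactions}
#'   (list of planted cycle id sets) and \code{gapReactions}.
#' @export
makeRandomModel <- function(nChain = 6, nTics = 1, ticLength = 3, nGaps = 0,
                            seed = 1) {
  stopifnot(nChain >= 2, ticLength >= 2, nGaps < nChain)
  set.seed(seed)
  m <- emptyModel(c("c", "e"))
  m <- addMetabolite(m, "s_e", compartment = "e")
  mets <- paste0("m", seq_len(nChain))
  m <- addReaction(m, "EX_s", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "UP", c(s_e = -1, m1 = 1), gpr = "g_up")
  chain_ids <- character(0)
  for (i in seq_len(nChain - 1)) {
    id <- paste0("C", i)
    st <- setNames(c(-1, 1), c(mets[i], mets[i + 1]))
    m <- addReaction(m, id, st, gpr = paste0("g", i))
    chain_ids <- c(chain_ids, id)
  }
  m <- addReaction(m, "BIOMASS", setNames(-1, mets[nChain]), kind = "biomass")
  m@objective <- "BIOMASS"
  tics <- list()
  for (t in seq_len(nTics)) {
    anchor <- mets[sample.int(nChain, 1)]
    loopmets <- c(anchor, paste0("t", t, "_", seq_len(ticLength - 1)))
    ids <- character(ticLength)
    for (j in seq_len(ticLength)) {
      from <- loopmets[j]
      to <- loopmets[if (j == ticLength) 1 else j + 1]
      ids[j] <- paste0("TIC", t, "_", j)
      m <- addReaction(m, ids[j], setNames(c(-1, 1), c(from, to)),
                       gpr = paste0("g_tic", t))
    }
    tics[[t]] <- ids
  }
  pool <- emptyModel(c("c", "e"))
  gaps <- character(0)
  if (nGaps > 0) {
    gaps <- sample(chain_ids, nGaps)
    S <- m@stoichiometry
    for (g in gaps) {
      col <- S[, g]
      nz <- which(col != 0)
      st <- setNames(col[nz], m@metabolites$id[nz])
      pool <- addReaction(pool, paste0("pool_", g), st)
    }
    # decoy pool reactions that do not bridge the gap
    for (d in 1:2) {
      pool <- addReaction(pool, paste0("pool_decoy", d),
                          setNames(c(-1, 1), c(paste0("x", d), paste0("y", d))))
    }
    m <- removeReactions(m, gaps, dropOrphans = FALSE)
  }
  list(model = m, pool = pool, biomass = "BIOMASS",
       ticReactions = tics, gapReactions = gaps)
}

#' Random compartmentalization instance with brute-force-checkable size
#'
#' Builds a small uncompartmentalized chain, assigns each internal reaction
#' to a random subset of compartments, supplies the chain substrate in one
#' compartment and demands the end product in another, so the MILP must pick
#' instances and transports. The number of removable elements stays small
#' enough for exhaustive verification.
#'
#' @param nReactions chain length (2-4 recommended).
#' @param nCompartments number of compartments (default 2).
#' @param seed RNG seed.
#' @return list with \code{replicated} (a \linkS4class{ReplicatedModel} with
#'   transport candidates), \code{precursors} and \code{fixedKeep}.
#' @export
makeRandomCompartmentToy <- function(nReactions = 3, nCompartments = 2, seed = 1) {
  set.seed(seed)
  comps <- paste0("C", seq_len(nCompartments))
  m <- emptyModel("c")
  mets <- paste0("m", seq_len(nReactions + 1))
  ids <- character(nReactions)
  for (i in seq_len(nReactions)) {
    ids[i] <- paste0("R", i)
    m <- addReaction(m, ids[i], setNames(c(-1, 1), c(mets[i], mets[i + 1])))
  }
  m <- addReaction(m, "U", setNames(1, mets[1]), kind = "demand")
  assignment <- c(
    setNames(lapply(ids, function(id) {
      sort(sample(comps, sample(1:min(2, nCompartments), 1)))
    }), ids),
    list(U = sample(comps, 1)))
  demand_comp <- sample(assignment[[ids[nReactions]]], 1)
  list(replicated = enumerateTransportCandidates(
         replicateByAssignment(m, assignment)),
       precursors = data.frame(metabolite = mets[nReactions + 1],
                               compartment = demand_comp,
                               stringsAsFactors = FALSE),
       fixedKeep = paste0("U__", assignment$U))
}
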