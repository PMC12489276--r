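test_that("replication instantiates reactions per assigned compartment", {
  toy <- makeTwoReactionToy()
  rep_ <- replicateByAssignment(toy$model, toy$assignment)
  prov <- rep_@provenance
  # the two replicable reactions give 2 x 3 instances
  expect_identical(sum(prov$parent %in% c("R1", "R2")), 6L)
  expect_true(all(c("R1__C1", "R1__C2", "R1__C3", "R2__C1", "R2__C2", "R2__C3")
                  %in% prov$instance))
  # pools are compartment-specific and disjoint
  expect_true(all(c("a__C1", "a__C2", "a__C3", "b__C3") %in%
                  metabolites(rep_@model)$id))
  # single-compartment assignment: isomorphic to the input
  m <- chainModel()
  a1 <- list(T = "c", BM = "c")
  r1 <- replicateByAssignment(m, a1)
  expect_identical(nReactions(r1@model), nReactions(m))
  expect_identical(sort(r1@provenance$parent), c("BM", "T"))
  # exchange reactions attach to the extracellular pool
  expect_true("s_e__e" %in% metabolites(r1@model)$id)
  # unknown reaction in the assignment and uncovered reactions error
  expect_error(replicateByAssignment(m, c(a1, list(ghost = "c"))), "unknown")
  expect_error(replicateByAssignment(m, list(T = "c")), "missing")
})

test_that("transport candidate counts follow choose(k, 2) per shared metabolite", {
  toy <- makeTwoReactionToy()
  rep_ <- enumerateTransportCandidates(
    replicateByAssignment(toy$model, toy$assignment))
  # five shared metabolites in three compartments each: 5 * C(3,2) = 15
  expect_identical(length(rep_@transports), 15L)
  # all transports conserve their metabolite with -1/+1 coefficients
  S <- stoichiometry(rep_@model)
  for (t in rep_@transports) {
    col <- S[, t]
    expect_identical(sort(as.numeric(col[col != 0])), c(-1, 1))
  }
  # a metabolite confined to one compartment gets no transport
  m <- chainModel()
  r1 <- enumerateTransportCandidates(
    replicateByAssignment(m, list(T = "c", BM = "c")))
  expect_identical(grep("^T_s__", r1@transports, value = TRUE), character(0))
})

test_that("the two-reaction toy prunes to the published minimal solution", {
  toy <- makeTwoReactionToy()
  rep_ <- enumerateTransportCandidates(
    replicateByAssignment(toy$model, toy$assignment))
  res <- pruneMinimal(rep_, precursors = toy$precursors,
                      fixedKeep = toy$fixedKeep)
  expect_identical(res@status, "optimal")
  # one R1 instance leaves C3 and one R2 instance leaves C2
  expect_setequal(intersect(res@removed, rep_@provenance$instance),
                  toy$expectedRemovedInstances)
  # the redundant transports are pruned entirely
  expect_identical(res@keptTransports, character(0))
  expect_identical(res@objective, 4)
})

test_that("a self-sufficient compartment sheds all foreign instances and transports", {
  m <- emptyModel("c")
  m <- addReaction(m, "U", c(a = 1), kind = "demand")
  m <- addReaction(m, "R", c(a = -1, b = 1))
  rep_ <- enumerateTransportCandidates(replicateByAssignment(
    m, list(U = "C1", R = c("C1", "C2"))))
  res <- pruneMinimal(rep_, precursors = data.frame(metabolite = "b",
                                                    compartment = "C1"),
                      fixedKeep = "U__C1")
  expect_identical(sort(setdiff(reactions(res@model)$id, "U__C1")), "R__C1")
  expect_identical(res@objective, 1)
})

test_that("MILP objective equals exhaustive enumeration on random instances", {
  agree <- 0L
  for (seed in 1:10) {
    toy <- makeRandomCompartmentToy(nReactions = sample(2:3, 1),
                                    nCompartments = 2, seed = seed)
    res <- pruneMinimal(toy$replicated, precursors = toy$precursors,
                        fixedKeep = toy$fixedKeep)
    bf <- bruteForceMinimalRetained(toy$replicated, toy$precursors,
                                    fixedKeep = toy$fixedKeep)
    expect_equal(res@objective, as.numeric(bf), info = paste("seed", seed))
    agree <- agree + 1L
  }
  expect_identical(agree, 10L)
})

test_that("the pruned model certifies feasibility and pruning is idempotent", {
  toy <- makeTwoReactionToy()
  rep_ <- enumerateTransportCandidates(
    replicateByAssignment(toy$model, toy$assignment))
  res <- pruneMinimal(rep_, precursors = toy$precursors, fixedKeep = toy$fixedKeep)
  # feasibility certificate: demands reach eps on the pruned model
  m2 <- res@model
  for (i in seq_len(nrow(toy$precursors))) {
    pool <- paste0(toy$precursors$metabolite[i], "__", toy$precursors$compartment[i])
    m2 <- addReaction(m2, paste0("DM_", pool), setNames(-1, pool),
                      lb = 1e-3, ub = 1000, kind = "demand")
  }
  sol <- algaeGEM:::.modelLP(m2, setNames(1, reactions(m2)$id[1]), maximize = TRUE)
  expect_identical(sol$status, "optimal")
  # idempotence: pruning the pruned model removes nothing
  prov2 <- rep_@provenance[rep_@provenance$instance %in% reactions(res@model)$id, ]
  rep2 <- new("ReplicatedModel", model = res@model, provenance = prov2,
              transports = res@keptTransports)
  res2 <- pruneMinimal(rep2, precursors = toy$precursors, fixedKeep = toy$fixedKeep)
  expect_identical(res2@removed, character(0))
})

test_that("growing fixedKeep never decreases the MILP objective", {
  toy <- makeTwoReactionToy()
  rep_ <- enumerateTransportCandidates(
    replicateByAssignment(toy$model, toy$assignment))
  base <- pruneMinimal(rep_, precursors = toy$precursors, fixedKeep = toy$fixedKeep)
  forced <- pruneMinimal(rep_, precursors = toy$precursors,
                         fixedKeep = c(toy$fixedKeep, "R1__C3"))
  # forcing a previously-removed instance keeps the count at least as large
  expect_gte(forced@objective + 1, base@objective)
  expect_true("R1__C3" %in% reactions(forced@model)$id)
})

test_that("unproducible precursors are reported before the MILP", {
  m <- emptyModel("c")
  m <- addReaction(m, "U", c(a = 1), kind = "demand")
  m <- addReaction(m, "R", c(a = -1, b = 1))
  rep_ <- enumerateTransportCandidates(replicateByAssignment(
    m, list(U = "C1", R = "C1")))
  expect_error(
    pruneMinimal(rep_, precursors = data.frame(metabolite = "ghost",
                                               compartment = "C1")),
    "ghost")
})
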