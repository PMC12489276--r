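test_that("model construction enforces the structural invariants", {
  m <- chainModel()
  expect_s4_class(m, "MetabolicModel")
  expect_identical(nReactions(m), 3L)
  expect_identical(nMetabolites(m), 2L)
  expect_error(addReaction(m, "BM", c(s = -1)), "duplicate")
  # exchange reactions must touch exactly one metabolite
  bad <- addReaction(m, "EX_bad", c(s_e = -1, s = 1), kind = "exchange")
  expect_error(validateModel(bad), "exactly one metabolite")
  # lb > ub rejected
  bad2 <- setBounds(m, "T", lb = 5, ub = 1)
  expect_error(validateModel(bad2), "lb > ub")
  # objective must exist
  m2 <- m
  expect_error(objectiveReaction(m2) <- "nope", "not in model")
})

test_that("splitReversible produces irreversible pairs preserving semantics", {
  m <- chainModel()
  m <- setBounds(m, "T", lb = -10, ub = 10)
  sp <- splitReversible(m)
  expect_true(all(reactions(sp$model)$lb >= 0))
  tfwd <- reactions(sp$model)[reactions(sp$model)$id == "T__fwd", ]
  tbwd <- reactions(sp$model)[reactions(sp$model)$id == "T__bwd", ]
  expect_equal(c(tfwd$lb, tfwd$ub), c(0, 10))
  expect_equal(c(tbwd$lb, tbwd$ub), c(0, 10))
  # backward stoichiometry negated
  expect_equal(stoichiometry(sp$model)[, "T__bwd"],
               -stoichiometry(sp$model)[, "T__fwd"])
  # already-irreversible model: unchanged, empty mapping
  m3 <- segmentModel()
  sp3 <- splitReversible(m3)
  expect_identical(reactions(sp3$model), reactions(m3))
  expect_identical(nrow(sp3$mapping), 0L)
})

test_that("split reaction count follows n_irrev + 2 n_rev on a model with 196 reversible reactions", {
  # chain of 2516 reactions over 2517 metabolites, 196 reversible as in the
  # curated algal model's reaction table
  n <- 2516L; nrev <- 196L
  mets <- paste0("m", seq_len(n + 1))
  ids <- paste0("r", seq_len(n))
  S <- Matrix::sparseMatrix(
    i = c(seq_len(n), seq_len(n) + 1L),
    j = c(seq_len(n), seq_len(n)),
    x = c(rep(-1, n), rep(1, n)),
    dims = c(n + 1, n), dimnames = list(mets, ids))
  lb <- rep(0, n); lb[seq_len(nrev)] <- -1000
  model <- new("MetabolicModel",
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             formula = NA_character_, mw = NA_real_,
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = ids, lb = lb, ub = 1000, gpr = "",
                           subsystem = "", kind = "enzymatic",
                           stringsAsFactors = FALSE),
    stoichiometry = methods::as(S, "CsparseMatrix"),
    compartments = "c", objective = "", genes = character(0))
  sp <- splitReversible(model)
  expect_identical(nReactions(sp$model), n + nrev)  # 2712
  expect_identical(nrow(sp$mapping), nrev)
})

test_that("split-then-merge reproduces feasible fluxes and optima on random LPs", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- emptyModel(c("c", "e"))
    m <- addReaction(m, "EX", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
    m <- addReaction(m, "T", c(s_e = -1, m1 = 1), lb = -5, ub = 10)
    nmid <- sample(2:4, 1)
    for (i in seq_len(nmid)) {
      rev <- runif(1) < 0.5
      m <- addReaction(m, paste0("R", i),
                       setNames(c(-1, 1), c(paste0("m", i), paste0("m", i + 1))),
                       lb = if (rev) -runif(1, 1, 10) else 0, ub = runif(1, 5, 15))
    }
    m <- addReaction(m, "BM", setNames(-1, paste0("m", nmid + 1)), kind = "biomass")
    objectiveReaction(m) <- "BM"
    base <- fba(m)
    sp <- splitReversible(m)
    split_opt <- fba(sp$model)
    expect_equal(objectiveValue(split_opt), objectiveValue(base), tolerance = 1e-8)
    if (split_opt@status == "optimal" && nrow(sp$mapping)) {
      merged <- mergeSplitFluxes(fluxes(split_opt), sp$mapping)
      S <- stoichiometry(m)
      expect_lt(max(abs(as.numeric(S %*% merged[colnames(S)]))), 1e-8)
    }
  }
})

test_that("standard growth conditions set the published media bounds", {
  m <- attachMedia(chainModel())
  for (nm in c("auto_100", "auto_3k", "mixo", "hetero")) {
    m <- addReaction(m, paste0("biomass_", nm), c(s = -1), kind = "biomass")
  }
  hetero <- standardCondition(m, "hetero")
  mh <- applyCondition(m, hetero)
  rx <- reactions(mh)
  expect_equal(rx$lb[rx$id == "EX_photon_e"], 0)     # no light
  expect_equal(rx$lb[rx$id == "EX_ac_e"], -2)        # acetate uptake <= 2
  expect_equal(rx$lb[rx$id == "EX_co2_e"], 0)        # CO2 closed
  expect_identical(objectiveReaction(mh), "biomass_hetero")
  # the eight nutrient uptakes at capacity 10
  for (b in c("h2o", "h", "pi", "nh4", "so4", "fe2", "mg2", "o2")) {
    expect_equal(rx$lb[rx$id == paste0("EX_", b, "_e")], -10, info = b)
  }
  a3k <- standardCondition(m, "auto_3k")
  m3 <- applyCondition(m, a3k)
  expect_equal(reactions(m3)$lb[reactions(m3)$id == "EX_photon_e"], -3000)
  mx <- applyCondition(m, standardCondition(m, "mixo"))
  expect_equal(reactions(mx)$lb[reactions(mx)$id == "EX_photon_e"], -100)
  expect_equal(reactions(mx)$lb[reactions(mx)$id == "EX_ac_e"], -2)
  # idempotence
  expect_identical(reactions(applyCondition(mh, hetero)), reactions(mh))
  # missing exchange -> configuration error naming the culprits
  expect_error(applyCondition(chainModel(),
                              growthCondition("x", "BM", list(EX_nope = c(0, 1)))),
               "EX_nope")
})
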