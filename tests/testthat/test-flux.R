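test_that("FBA solves the closed-form chain and reports blocked growth as zero", {
  m <- chainModel()  # uptake <= 10, biomass needs 2 substrate -> growth 5
  res <- fba(m)
  expect_identical(solverStatus(res), "optimal")
  expect_equal(objectiveValue(res), 5)
  # steady state and bounds hold on the flux vector
  v <- fluxes(res)
  expect_lt(max(abs(as.numeric(stoichiometry(m) %*% v[reactions(m)$id]))), 1e-6)
  expect_true(all(v >= reactions(m)$lb - 1e-6 & v <= reactions(m)$ub + 1e-6))
  # blocked precursor -> growth 0
  blocked <- setBounds(m, "T", lb = 0, ub = 0)
  expect_equal(objectiveValue(fba(blocked)), 0)
})

test_that("pFBA fixes growth and shuts down futile long routes", {
  # direct route (1 reaction) vs detour (2 reactions) to the same product
  m <- emptyModel(c("c", "e"))
  m <- addReaction(m, "EX_s", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "direct", c(s_e = -1, p = 1))
  m <- addReaction(m, "d1", c(s_e = -1, q = 1))
  m <- addReaction(m, "d2", c(q = -1, p = 1))
  m <- addReaction(m, "BM", c(p = -1), kind = "biomass")
  objectiveReaction(m) <- "BM"
  res <- pfba(m)
  expect_equal(objectiveValue(res), objectiveValue(fba(m)), tolerance = 1e-9)
  expect_lt(fluxes(res)[["d1"]], 1e-9)
  expect_lt(fluxes(res)[["d2"]], 1e-9)
  expect_equal(fluxes(res)[["direct"]], 10, tolerance = 1e-6)
  # total |v| of pFBA never exceeds that of the FBA solution
  expect_lte(sum(abs(fluxes(res))), sum(abs(fluxes(fba(m)))) + 1e-6)
})

test_that("FVA brackets the FBA solution and resolves branch symmetry", {
  m <- chainModel()
  rng <- fva(m, fractionOfOptimum = 1)
  sol <- fluxes(fba(m))
  for (i in seq_len(nrow(rng))) {
    expect_lte(rng$min[i], sol[[rng$reaction[i]]] + 1e-6)
    expect_gte(rng$max[i], sol[[rng$reaction[i]]] - 1e-6)
  }
  # a single essential chain at fraction 1 has point ranges
  expect_true(all(abs(rng$max - rng$min) < 1e-6))
  # two equivalent branches: each spans [0, v_tot]
  m2 <- twoBranchModel()
  rng2 <- fva(m2, fractionOfOptimum = 1)
  for (id in c("A1", "A2")) {
    expect_equal(rng2$min[rng2$reaction == id], 0, tolerance = 1e-6)
    expect_equal(rng2$max[rng2$reaction == id], 10, tolerance = 1e-6)
  }
  # fraction 0 relaxes to the bound-constrained ranges
  rng0 <- fva(m, fractionOfOptimum = 0)
  expect_equal(rng0$min[rng0$reaction == "BM"], 0, tolerance = 1e-6)
  expect_equal(rng0$max[rng0$reaction == "BM"], 5, tolerance = 1e-6)
})

test_that("active-reaction calling excludes balanced split pairs", {
  # an irreversible used reaction is active; a pure internal 2-cycle (equal
  # forward/backward maxima) is excluded
  m <- twoCycleModel()
  m <- setBounds(m, "R2", lb = -1000)  # make R2 reversible: R2 bwd == R1 fwd cycle
  act <- callActiveReactions(m)
  expect_true(all(c("T", "BM") %in% act))
  # the exchange splits into uptake/export directions that cancel with equal
  # maxima (take up 10, re-export 10) and is excluded by the rule
  expect_false("EX_a" %in% act)
  # unequal maxima on a split pair keep the parent active
  m2 <- chainModel()
  m2 <- setBounds(m2, "T", lb = -3, ub = 10)
  act2 <- callActiveReactions(m2)
  expect_true("T" %in% act2)
})

test_that("condition partitioning produces the seven exclusive classes", {
  p <- conditionPartition(auto = c("a", "b"), mixo = c("b", "c"), hetero = "c")
  counts <- setNames(p$count, p$class)
  expect_equal(counts[["auto_only"]], 1)   # {a}
  expect_equal(counts[["auto_mixo"]], 1)   # {b}
  expect_equal(counts[["mixo_hetero"]], 1) # {c}
  expect_equal(counts[["all"]], 0)
  expect_equal(sum(counts), length(unique(c("a", "b", "c"))))
  # identical sets put all mass in the triple intersection
  p2 <- conditionPartition(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(setNames(p2$count, p2$class)[["all"]], 2)
  expect_equal(sum(p2$count), 2)
})

test_that("essentiality respects GPR boolean structure", {
  m <- chainModel()
  expect_setequal(essentiality(m, target = "reaction"),
                  c("EX_s", "T", "BM"))  # single path: everything essential
  expect_identical(essentiality(m, target = "gene"), "g_t")
  # isozyme pair: neither gene essential, the reaction route is
  m2 <- twoBranchModel()
  expect_identical(essentiality(m2, target = "gene"), character(0))
  # complex: both subunits essential
  m3 <- chainModel()
  m3@reactions$gpr[m3@reactions$id == "T"] <- "s1 and s2"
  m3@genes <- c("s1", "s2")
  expect_setequal(essentiality(m3, target = "gene"), c("s1", "s2"))
})

test_that("growth-correlation screening selects proportional reactions only", {
  # single chain: every reaction flux is proportional to growth (r = 1)
  m <- chainModel()
  res <- growthCorrelatedTargets(m, nIncrements = 25)
  expect_setequal(res$reactions, reactions(m)$id)
  expect_identical(res$genes, "g_t")
  expect_true(all(abs(res$table$r[!is.na(res$table$r)] - 1) < 1e-6 |
                  abs(res$table$r[!is.na(res$table$r)] + 1) < 1e-6))
  # a constant-flux maintenance reaction has zero variance and is skipped
  m2 <- chainModel()
  m2 <- addReaction(m2, "maint", c(s = -0.001), lb = 0.5, ub = 0.5,
                    kind = "demand")
  res2 <- growthCorrelatedTargets(m2, nIncrements = 25)
  expect_false("maint" %in% res2$reactions)
  expect_true(is.na(res2$table$r[res2$table$reaction == "maint"]))
  # screening at r_min = 0 and alpha = 1 degenerates to "varies with growth"
  res3 <- growthCorrelatedTargets(m2, nIncrements = 25, rMin = 0, alpha = 1)
  expect_setequal(res3$reactions, setdiff(reactions(m2)$id, "maint"))
})

test_that("correlation statistics match an independent recomputation", {
  # a branch active only above half-maximal growth: screen at 40 increments
  # and recompute Pearson r and its t-test p-value from the raw flux series
  m <- emptyModel(c("c", "e"))
  m <- addReaction(m, "EX_s", c(s_e = -1), lb = -10, ub = 1000, kind = "exchange")
  m <- addReaction(m, "cheap", c(s_e = -1, p = 1), ub = 5, gpr = "g_cheap")
  m <- addReaction(m, "costly", c(s_e = -2, p = 1), gpr = "g_costly")
  m <- addReaction(m, "BM", c(p = -1), kind = "biomass")
  objectiveReaction(m) <- "BM"
  n <- 40
  res <- growthCorrelatedTargets(m, nIncrements = n, mtc = "bonferroni")
  mu_max <- objectiveValue(fba(m))
  mu <- mu_max * seq_len(n) / n
  flux <- vapply(mu, function(g) fluxes(pfba(m, growth = g))[["costly"]],
                 numeric(1))
  r_ref <- cor(mu, flux)
  t_ref <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
  p_ref <- 2 * pt(-abs(t_ref), df = n - 2)
  row <- res$table[res$table$reaction == "costly", ]
  expect_equal(row$r, r_ref, tolerance = 1e-9)
  expect_equal(row$p, p_ref, tolerance = 1e-9)
  # the costly branch only activates above cheap's cap: 0 < r < 1
  expect_gt(row$r, 0)
  expect_lt(row$r, 0.999)
  # gene selection is consistent with the recomputed statistics
  m_tests <- sum(!is.na(res$table$p))
  sel_ref <- r_ref > 0.8 && min(p_ref * m_tests, 1) < 0.01
  expect_identical("g_costly" %in% res$genes, sel_ref)
})
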