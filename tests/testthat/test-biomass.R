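writeFasta <- function(records, path, wrap = 60) {
  con <- file(path, "w")
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    s <- records[[nm]]
    starts <- seq(1, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  close(con)
}

test_that("monomer fractions derive from genome and proteome composition", {
  g <- withr::local_tempfile(fileext = ".fa")
  p <- withr::local_tempfile(fileext = ".fa")
  writeFasta(c(chr1 = "ATGC"), g)
  writeFasta(c(p1 = "GGG"), p)
  mf <- monomerFractionsFromGenome(g, p)
  expect_equal(unname(mf$dna), rep(0.25, 4))          # uniform base content
  expect_equal(mf$protein[["G"]], 1)                  # glycine-only proteome
  expect_equal(sum(mf$protein), 1)
  expect_equal(sum(mf$rna), 1)
  # strand symmetry: an A-only coding strand pairs with T on the complement
  writeFasta(c(chr1 = "AAAA"), g)
  mf2 <- monomerFractionsFromGenome(g, p)
  expect_equal(mf2$dna[["dATP"]], 0.5)
  expect_equal(mf2$dna[["dTTP"]], 0.5)
  expect_equal(mf2$dna[["dGTP"]], 0)
  expect_equal(mf2$dna[["dCTP"]], 0)
  # the coding-strand transcript is all-A -> ATP fraction 1
  expect_equal(mf2$rna[["ATP"]], 1)
  # empty inputs error
  e <- withr::local_tempfile(fileext = ".fa")
  writeLines(">empty", e)
  expect_error(monomerFractionsFromGenome(e, p), "empty")
})

test_that("monomer fractions are invariant to line wrapping and case", {
  g1 <- withr::local_tempfile(fileext = ".fa")
  g2 <- withr::local_tempfile(fileext = ".fa")
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  seq_g <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  seq_p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 200,
                        replace = TRUE), collapse = "")
  writeFasta(setNames(list(seq_g), "g"), g1, wrap = 60)
  writeFasta(setNames(list(tolower(seq_g)), "g"), g2, wrap = 7)
  writeFasta(setNames(list(seq_p), "p"), p1, wrap = 60)
  writeFasta(setNames(list(tolower(seq_p)), "p"), p2, wrap = 11)
  expect_equal(monomerFractionsFromGenome(g1, p1),
               monomerFractionsFromGenome(g2, p2))
})

test_that("biomass coefficients respect the 1 g g-1 DW closure", {
  # pure glycine protein: coeff = 1000 / (75.07 - 18.02)
  br <- buildBiomassReaction(c(protein = 1), monomers = list(protein = c(G = 1)))
  expect_equal(unname(-br@coefficients[["G"]]), 1000 / (75.07 - 18.02),
               tolerance = 1e-12)
  expect_equal(unname(-br@coefficients[["G"]]), 17.53, tolerance = 1e-3)
  expect_equal(biomassMass(br), 1000, tolerance = 1e-9)
  # polymerization water released stoichiometrically
  expect_equal(br@coefficients[["h2o"]], -sum(br@coefficients[["G"]]))
  # uniform dNTPs: four equal coefficients, MW-weighted sum = 1000 mg
  brd <- buildBiomassReaction(c(dna = 1),
                              monomers = list(dna = c(dATP = .25, dCTP = .25,
                                                      dGTP = .25, dTTP = .25)))
  cons <- -brd@coefficients[brd@coefficients < 0]
  expect_equal(length(unique(round(cons, 12))), 1L)
  expect_equal(biomassMass(brd), 1000, tolerance = 1e-9)
  # class vector not summing to 1 is rescaled before computing coefficients
  br98 <- buildBiomassReaction(c(protein = 0.49, dna = 0.49),
                               monomers = list(protein = c(G = 1),
                                               dna = c(dATP = 1)))
  expect_equal(biomassMass(br98), 1000, tolerance = 1e-9)
  # missing molecular weight errors with the culprit named
  expect_error(buildBiomassReaction(c(protein = 1),
                                    monomers = list(protein = c(Xx = 1))),
               "Xx")
})

test_that("mass closure holds for random mixed compositions", {
  set.seed(31)
  for (i in 1:10) {
    f <- runif(4)
    comp <- setNames(f / sum(f), c("protein", "dna", "rna", "carbohydrate"))
    aa <- runif(20); aa <- aa / sum(aa)
    names(aa) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    dn <- runif(4); dn <- dn / sum(dn); names(dn) <- c("dATP", "dCTP", "dGTP", "dTTP")
    rn <- runif(4); rn <- rn / sum(rn); names(rn) <- c("ATP", "CTP", "GTP", "UTP")
    mw <- c(standardMonomerWeights(), starch_unit = 162.14, sucrose = 342.3)
    br <- buildBiomassReaction(
      comp, monomers = list(protein = aa, dna = dn, rna = rn),
      mwTable = mw,
      precursorMasses = list(carbohydrate = c(starch_unit = 0.7, sucrose = 0.3)))
    expect_equal(biomassMass(br), 1000, tolerance = 1e-6)
  }
})

test_that("media attachment creates exactly eleven exchanges, idempotently", {
  m <- attachMedia(chainModel())
  ex <- reactions(m)[reactions(m)$kind == "exchange", ]
  media_ex <- grep("^EX_(h2o|h|pi|nh4|so4|fe2|mg2|o2|photon|ac|co2)_e$",
                   ex$id, value = TRUE)
  expect_identical(length(media_ex), 11L)
  # second call adds nothing
  m2 <- attachMedia(m)
  expect_identical(reactions(m2), reactions(m))
  # an existing exchange for one of the media metabolites is reused
  m3 <- emptyModel(c("c", "e"))
  m3 <- addMetabolite(m3, "o2_e", compartment = "e")
  m3 <- addReaction(m3, "EX_o2_e", c(o2_e = -1), lb = -5, ub = 5, kind = "exchange")
  m3 <- attachMedia(m3)
  expect_identical(sum(reactions(m3)$id == "EX_o2_e"), 1L)
  expect_equal(reactions(m3)$lb[reactions(m3)$id == "EX_o2_e"], -5)
})

test_that("four condition-specific biomass reactions coexist and are selectable", {
  m <- attachMedia(chainModel())
  mono <- list(protein = c(G = 0.6, A = 0.4))
  for (nm in c("auto_100", "auto_3k", "mixo", "hetero")) {
    br <- buildBiomassReaction(c(protein = 1), monomers = mono,
                               name = paste0("biomass_", nm))
    m <- addBiomassReaction(m, br)
  }
  expect_identical(sum(reactions(m)$kind == "biomass"), 5L)  # 4 + chain's BM
  for (nm in c("auto_100", "mixo")) {
    mc <- applyCondition(m, standardCondition(m, nm))
    expect_identical(objectiveReaction(mc), paste0("biomass_", nm))
  }
})
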