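test_that("consensus aggregation averages tools with renormalization", {
  # two confident tools disagreeing -> 50/50
  p <- data.frame(protein = "p1", tool = c("t1", "t2"),
                  compartment = c("cyto", "chloro"), probability = c(1, 1))
  cons <- aggregateToolPredictions(p)
  expect_equal(setNames(cons$probability, cons$compartment),
               c(cyto = 0.5, chloro = 0.5))
  # single tool passes through unchanged
  p1 <- data.frame(protein = "p", tool = "t1",
                   compartment = c("mito", "cyto"), probability = c(0.7, 0.3))
  c1 <- aggregateToolPredictions(p1)
  expect_equal(setNames(c1$probability, c1$compartment),
               c(mito = 0.7, cyto = 0.3))
  # three tools, missing compartments count as zero: c = 8/15, m = 7/15
  p3 <- rbind(
    data.frame(protein = "p", tool = "t1", compartment = c("c", "m"),
               probability = c(0.6, 0.4)),
    data.frame(protein = "p", tool = "t2", compartment = "c", probability = 1),
    data.frame(protein = "p", tool = "t3", compartment = "m", probability = 1))
  c3 <- aggregateToolPredictions(p3)
  expect_equal(setNames(c3$probability, c3$compartment),
               c(c = 8 / 15, m = 7 / 15), tolerance = 1e-12)
  # per-tool renormalization before averaging
  p4 <- data.frame(protein = "p", tool = c("t1", "t1"),
                   compartment = c("c", "m"), probability = c(0.3, 0.3))
  c4 <- aggregateToolPredictions(p4)
  expect_equal(sum(c4$probability), 1, tolerance = 1e-12)
  # all-zero protein flagged unlocalized and excluded
  p5 <- rbind(p1, data.frame(protein = "dead", tool = "t1",
                             compartment = "c", probability = 0))
  c5 <- aggregateToolPredictions(p5)
  expect_identical(attr(c5, "unlocalized"), "dead")
  expect_false("dead" %in% c5$protein)
})

test_that("reaction votes are normalized by GPR gene count and sum to 1", {
  m <- emptyModel("x")
  m <- addReaction(m, "R_or", c(a = -1, b = 1), gpr = "g1 or g2")
  m <- addReaction(m, "R_one", c(b = -1, c = 1), gpr = "g3")
  m <- addReaction(m, "R_four", c(c = -1, d = 1), gpr = "g4 and g5 and g6 and g7")
  m <- addReaction(m, "R_nogpr", c(d = -1, e = 1))
  cons <- data.frame(
    protein = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    compartment = c("cyto", "mito", "chloro", "cyto", "cyto", "cyto", "mito"),
    probability = 1, stringsAsFactors = FALSE)
  v <- voteReactions(m, cons)
  getv <- function(r) setNames(v$vote[v$reaction == r], v$compartment[v$reaction == r])
  expect_equal(getv("R_or"), c(cyto = 0.5, mito = 0.5))
  expect_equal(getv("R_one"), c(chloro = 1))
  expect_equal(getv("R_four"), c(cyto = 0.75, mito = 0.25))
  expect_false("R_nogpr" %in% v$reaction)
  # conservation: per-reaction votes sum to 1
  sums <- tapply(v$vote, v$reaction, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("threshold assignment retains compartments above 25% with fallbacks", {
  v <- data.frame(reaction = "R",
                  compartment = c("chloro", "cyto", "mito"),
                  vote = c(0.5, 0.3, 0.2))
  expect_setequal(assignReactionCompartments(v)$R, c("chloro", "cyto"))
  # strict inequality at the boundary
  v2 <- data.frame(reaction = "R", compartment = c("cyto", "mito", "chloro"),
                   vote = c(0.25, 0.25, 0.5))
  expect_identical(assignReactionCompartments(v2)$R, "chloro")
  # degenerate flat vote: lexicographic argmax
  v3 <- data.frame(reaction = "R", compartment = paste0("k", 5:1),
                   vote = rep(0.2, 5))
  expect_identical(assignReactionCompartments(v3)$R, "k1")
  # fixed assignments override; no-GPR reactions fall back to default
  a <- assignReactionCompartments(v, fixed = list(R = "perox"),
                                  reactions = c("R", "R_free"), default = "cyto")
  expect_identical(a$R, "perox")
  expect_identical(a$R_free, "cyto")
  expect_error(
    assignReactionCompartments(v, fixed = list(R = "nowhere"),
                               compartments = c("chloro", "cyto", "mito")),
    "nowhere")
})

test_that("raising the threshold never adds a compartment (monotonicity)", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    vt <- runif(k); vt <- vt / sum(vt)
    v <- data.frame(reaction = "R", compartment = paste0("c", seq_len(k)), vote = vt)
    lo <- assignReactionCompartments(v, threshold = 0.15)$R
    hi <- assignReactionCompartments(v, threshold = 0.35)$R
    expect_true(all(hi %in% lo))
  }
})

test_that("planted compartments are recovered at moderate noise", {
  comps <- c("cyto", "chloro", "mito", "perox", "er")
  set.seed(99)
  truth <- setNames(sample(comps, 50, replace = TRUE), paste0("prot", 1:50))
  prof <- simulateLocalizationProfiles(truth, comps, nTools = 5, eta = 0.2,
                                       seed = 123)
  cons <- aggregateToolPredictions(prof)
  m <- emptyModel("cyto")
  for (i in seq_along(truth)) {
    m <- addReaction(m, paste0("R", i),
                     setNames(c(-1, 1), paste0(c("a", "b"), i)),
                     gpr = names(truth)[i])
  }
  asn <- assignReactionCompartments(voteReactions(m, cons), threshold = 0.25)
  hit <- vapply(seq_along(truth),
                function(i) identical(asn[[paste0("R", i)]], unname(truth[i])),
                logical(1))
  expect_true(all(hit))
})

test_that("a mitochondrial pathway block lands entirely in the mitochondrion", {
  # nine reactions whose 22 associated proteins are all consensus-localized
  # to the mitochondrion: the assignment must place all nine there
  set.seed(5)
  nprot <- 22
  prots <- paste0("tca_p", seq_len(nprot))
  truth <- setNames(rep("mito", nprot), prots)
  prof <- simulateLocalizationProfiles(truth,
                                       c("cyto", "chloro", "mito", "perox"),
                                       nTools = 5, eta = 0.15, seed = 17)
  cons <- aggregateToolPredictions(prof)
  m <- emptyModel("cyto")
  sizes <- c(3, 2, 3, 2, 3, 2, 3, 2, 2)  # 22 proteins over 9 reactions
  start <- cumsum(c(1, head(sizes, -1)))
  for (i in 1:9) {
    gs <- prots[seq(start[i], length.out = sizes[i])]
    m <- addReaction(m, paste0("TCA", i),
                     setNames(c(-1, 1), paste0(c("s", "p"), i)),
                     gpr = paste(gs, collapse = " and "))
  }
  asn <- assignReactionCompartments(voteReactions(m, cons), threshold = 0.25)
  for (i in 1:9) expect_identical(asn[[paste0("TCA", i)]], "mito")
})

test_that("localization tables read with alias mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ttool\tcompartment\tprobability",
               "p1\tt1\tplastid\t0.9",
               "p1\tt1\tcyto\t0.1"), f)
  tab <- readLocalizationTable(f, aliases = c(plastid = "chloroplast"))
  expect_identical(tab$compartment, c("chloroplast", "cyto"))
  writeLines(c("protein_id\ttool\tcompartment\tprobability",
               "p1\tt1\tcyto\t1.7"), f)
  expect_error(readLocalizationTable(f), "0, 1")
})
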