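# Masking, score transfer, placement classification, monophyly and the
# four-analysis experiment driver

test_that("masking is idempotent and leaves other cells untouched", {
  set.seed(51)
  m <- randomMorphMatrix(6, 10, missingFrac = 0.2)
  once <- maskPartition(m, c("t1", "t2"), 3:5)
  twice <- maskPartition(once, c("t1", "t2"), 3:5)
  expect_identical(once@cells, twice@cells)
  expect_identical(once@cells[c("t3","t4","t5","t6"), ],
                   m@cells[c("t3","t4","t5","t6"), ])
  expect_identical(once@cells[, setdiff(1:10, 3:5)],
                   m@cells[, setdiff(1:10, 3:5)])
  expect_error(maskPartition(m, "nope", 1:2), "nope")
  expect_error(maskPartition(m, "t1", 99), "99")
})

test_that("an empty mask is the identity", {
  set.seed(52)
  m <- randomMorphMatrix(5, 8)
  expect_identical(maskPartition(m, taxa(m), integer(0))@cells, m@cells)
})

test_that("score transfer takes donor unions, flags conflicts, and
          respects the force flag", {
  tok <- rbind(d1 = c("0", "0", "?"),
               d2 = c("1", "0", "?"),
               r  = c("?", "?", "?"),
               x  = c("1", "1", "1"))
  m <- morphMatrix(tok)
  out <- transferScores(m, c("d1", "d2"), "r", 1:3)
  expect_equal(stateSet(out, "r", 1), c(0L, 1L))   # conflict -> polymorphism
  expect_equal(stateSet(out, "r", 2), 0L)
  expect_true(is.na(stateSet(out, "r", 3)))        # no donor data
  expect_equal(attr(out, "conflicts")$charId, 1L)
  # recipient already scored: error without force
  m2 <- morphMatrix(rbind(d1 = "0", r = "1"))
  expect_error(transferScores(m2, "d1", "r", 1L), "force")
  expect_warning(out2 <- transferScores(m2, "d1", "r", 1L, force = TRUE),
                 "overwriting")
  expect_equal(stateSet(out2, "r", 1), 0L)
  expect_error(transferScores(m, "d1", "ghost", 1:2), "ghost")
})

test_that("transfer then mask equals mask alone on the recipient", {
  set.seed(53)
  m <- randomMorphMatrix(6, 10, missingFrac = 0.3)
  part <- 2:5
  cells <- m@cells; cells["t3", part] <- 0L
  m@cells <- cells                                  # recipient unscored
  tm <- transferScores(m, c("t1", "t2"), "t3", part)
  expect_identical(maskPartition(tm, "t3", part)@cells,
                   maskPartition(m, "t3", part)@cells)
})

test_that("placement classification works on hand-built trees", {
  anchors <- list(gavialoids = c("G1", "G2"), crown = c("B1", "B2"),
                  hylaeochampsids = c("H1", "H2"))
  crown <- ape::read.tree(
    text = "(O,((H1,H2),((G1,G2),(B1,(B2,(F1,F2))))));")
  basal <- ape::read.tree(
    text = "(O,(((F1,F2),(H1,H2)),((G1,G2),(B1,B2))));")
  expect_equal(classifyPlacement(crown, c("F1", "F2"), anchors),
               "crown_crocodylian")
  expect_equal(classifyPlacement(basal, c("F1", "F2"), anchors),
               "basal_eusuchian")
  # a polytomy collapsing the crown group blocks the determination
  poly <- ape::read.tree(
    text = "(O,((H1,H2),((G1,G2),(B1,B2),(F1,F2))));")
  expect_equal(classifyPlacement(poly, c("F1", "F2"), anchors),
               "unresolved")
  expect_error(classifyPlacement(crown, c("F1", "FX"), anchors), "FX")
})

test_that("placement is invariant to rerooting along the outgroup edge", {
  anchors <- list(gavialoids = c("G1", "G2"), crown = c("B1", "B2"),
                  hylaeochampsids = c("H1", "H2"))
  crown <- ape::read.tree(
    text = "(O,((H1,H2),((G1,G2),(B1,(B2,(F1,F2))))));")
  rr <- ape::root(ape::unroot(crown), outgroup = "O",
                  resolve.root = TRUE)
  expect_equal(classifyPlacement(rr, c("F1", "F2"), anchors),
               "crown_crocodylian")
})

test_that("monophyly classification matches cherry/grade intuition and
          the brute-force convexity oracle", {
  tr <- ape::read.tree(text = "(o,(a,(b,(c,(d,e)))));")
  expect_equal(monophylyStatus(tr, c("d", "e")), "monophyletic")
  expect_equal(monophylyStatus(tr, c("a", "b")), "paraphyletic")
  expect_equal(monophylyStatus(tr, c("a", "c")), "polyphyletic")

  set.seed(54)
  for (i in 1:8) {
    tr <- ape::root(ape::rtree(8, br = NULL), outgroup = "t1",
                    resolve.root = TRUE)
    tips <- setdiff(tr$tip.label, "t1")
    for (j in 1:12) {
      ts <- sample(tips, sample(2:4, 1))
      expect_equal(monophylyStatus(tr, ts), bruteMonophyly(tr, ts),
                   info = paste(ape::write.tree(tr),
                                paste(ts, collapse = ",")))
    }
  }
})

test_that("the experiment driver reports a placement flip on a planted
          conflict and is the identity under an empty mask", {
  sc <- makeConflictScenario(seed = 60)
  m <- sc$matrix; tr <- sc$truth
  rep <- runExperiment(
    m, outgroup = tr$outgroup, partition = "postcranial",
    maskTaxa = tr$focal, focal = tr$focal, anchors = tr$anchors,
    cladeTests = list(focal = tr$focal),
    config = searchConfig(nReplicates = 6, hold = 20, earlyStop = NULL),
    seed = 60)
  expect_setequal(names(rep@analyses), c("full", "masked"))
  expect_equal(rep@analyses$masked$placement, "basal_eusuchian")
  expect_true(rep@analyses$full$placement != rep@analyses$masked$placement)
  expect_equal(rep@analyses$full$cladeStatus$focal, "monophyletic")
  expect_true(all(rep@comparisons$rf > 0))

  # empty partition: masked analysis must match the full one exactly
  rep0 <- runExperiment(
    m, outgroup = tr$outgroup, partition = integer(0),
    maskTaxa = tr$focal,
    config = searchConfig(nReplicates = 4, hold = 10, earlyStop = NULL),
    seed = 61)
  expect_equal(rep0@analyses$full$bestLength,
               rep0@analyses$masked$bestLength)
  expect_equal(rep0@comparisons$rf, 0L)
})

test_that("control and transfer variants drop and fill taxa as configured", {
  sc <- makeConflictScenario(seed = 62, missingFraction = 0)
  m <- sc$matrix; tr <- sc$truth
  # make one focal taxon postcranium-free so it can act as recipient
  m2 <- maskPartition(m, "Focal_1", "postcranial")
  rep <- runExperiment(
    m2, outgroup = tr$outgroup, partition = "postcranial",
    maskTaxa = tr$focal, controlDrop = c("Focal_2", "Focal_3"),
    donors = c("Focal_2", "Focal_3"), recipients = "Focal_1",
    config = searchConfig(nReplicates = 3, hold = 5, earlyStop = NULL),
    seed = 63)
  expect_setequal(names(rep@analyses),
                  c("control", "full", "masked", "transferred"))
  expect_false(any(c("Focal_2", "Focal_3") %in%
                     taxa_of(rep@analyses$control$trees)))
  expect_false(any(c("Focal_2", "Focal_3") %in%
                     taxa_of(rep@analyses$transferred$trees)))
  expect_true("Focal_1" %in% taxa_of(rep@analyses$transferred$trees))
})
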