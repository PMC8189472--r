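# Simulator ground truth, determinism, and recovery properties

test_that("simulation is deterministic and matrices round-trip", {
  a <- makeConflictScenario(seed = 71)
  b <- makeConflictScenario(seed = 71)
  expect_identical(a$matrix@cells, b$matrix@cells)
  expect_identical(a$truth$charPartition, b$truth$charPartition)
  m2 <- readTNT(text = writeTNT(a$matrix))
  expect_identical(m2@cells, a$matrix@cells)
  expect_true(validObject(a$matrix))
})

test_that("a fully missing taxon has an all-missing row", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  p <- simulationParams(tr, nChars = c(all = 20L),
                        missingFraction = c(a = 1, b = 0, c = 0, d = 0),
                        seed = 72)
  sim <- simulateMatrix(p)
  expect_true(all(sim$matrix@cells["a", ] == 0L))
  expect_true(any(sim$matrix@cells["b", ] != 0L))
})

test_that("missingness can be restricted to one partition", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  p <- simulationParams(tr, nChars = c(post = 10L, cran = 10L),
                        missingFraction = c(a = 1, b = 0, c = 0, d = 0),
                        missingPartition = "post", seed = 73)
  sim <- simulateMatrix(p)
  expect_true(all(sim$matrix@cells["a", 1:10] == 0L))
  expect_true(all(sim$matrix@cells["a", 11:20] != 0L))
})

test_that("expected changes grow with tree length", {
  base <- ape::read.tree(text = "((a,b),(c,d));")
  nRep <- 600L
  countChanges <- function(scale) {
    tr <- base
    tr$edge.length <- rep(scale / nrow(base$edge), nrow(base$edge))
    p <- simulationParams(tr, nChars = c(all = nRep),
                          homoplasyRate = c(all = 1), seed = 74)
    sim <- simulateMatrix(p)
    # observed parsimony steps lower-bound the realised changes; with a
    # 4-taxon star-like count just use state variety per character
    mean(vapply(seq_len(nChar(sim$matrix)), function(k) {
      s <- sim$matrix@cells[, k]
      length(unique(s)) - 1L
    }, integer(1)))
  }
  lo <- countChanges(0.3)
  hi <- countChanges(3)
  expect_gt(hi, lo)
})

test_that("zero homoplasy and no missingness recover the generating
          topology exactly with CI 1", {
  for (seed in 75:77) {
    sc <- makeConflictScenario(seed = seed, homoplasyRate = 0,
                               conflict = FALSE)
    m <- sc$matrix
    ts <- heuristicSearch(m, searchConfig(nReplicates = 4, hold = 10,
                                          earlyStop = NULL, seed = seed),
                          outgroup = sc$truth$outgroup)
    cons <- strictConsensus(ts)
    expect_equal(rfDistance(cons, sc$truth$trees$base), 0L)
    expect_equal(ensembleIndices(ts, m)$CI, 1)
  }
})

test_that("planted markers are recovered as unambiguous synapomorphies
          with no false negatives", {
  sc <- makeConflictScenario(seed = 78, homoplasyRate = 0,
                             conflict = FALSE)
  m <- sc$matrix
  ts <- heuristicSearch(m, searchConfig(nReplicates = 4, hold = 10,
                                        earlyStop = NULL, seed = 78),
                        outgroup = sc$truth$outgroup)
  focal <- sc$truth$focal
  focalStem <- vapply(sc$truth$markers, function(mk)
    setequal(mk$clade, focal), logical(1))
  ids <- vapply(sc$truth$markers[focalStem], function(mk)
    mk$charId, integer(1))
  if (length(ids)) {
    rec <- unambiguousSynapomorphies(ts, m, focal)
    expect_true(all(ids %in% rec$charId[rec$status == "unambiguous"]))
  }
  # markers of a backbone clade, likewise
  crocs <- grep("^Croc_", taxa(m), value = TRUE)
  cladeIds <- vapply(sc$truth$markers, function(mk)
    setequal(mk$clade, crocs), logical(1))
  ids2 <- vapply(sc$truth$markers[cladeIds], function(mk)
    mk$charId, integer(1))
  rec2 <- unambiguousSynapomorphies(ts, m, crocs)
  expect_true(all(ids2 %in% rec2$charId[rec2$status == "unambiguous"]))
  expect_true(length(ids2) >= 1)
})

test_that("the conflict generator plants the documented structure", {
  sc <- makeConflictScenario(seed = 79)
  m <- sc$matrix
  expect_equal(nChar(m), 65L)
  expect_equal(length(partitions(m)$postcranial), 25L)
  expect_equal(length(partitions(m)$cranial), 40L)
  expect_equal(classifyPlacement(sc$truth$trees$base, sc$truth$focal,
                                 sc$truth$anchors), "crown_crocodylian")
  expect_equal(classifyPlacement(sc$truth$trees$conflict, sc$truth$focal,
                                 sc$truth$anchors), "basal_eusuchian")
  # generated matrices satisfy container invariants
  expect_true(validObject(m))
})
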