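# Fitch scoring against the Sankoff oracle, step bounds, and indices

test_that("constant and all-missing characters need zero steps", {
  tok <- cbind(rep("1", 5), c("?", "?", "?", "?", "?"),
               c("0", "1", "0", "1", "0"))
  rownames(tok) <- paste0("t", 1:5)
  m <- morphMatrix(tok)
  tr <- ape::rtree(5, tip.label = paste0("t", 1:5), br = NULL)
  sc <- fitchLength(tr, m)
  expect_equal(sc@perChar[1], 0L)
  expect_equal(sc@perChar[2], 0L)
  expect_true(sc@perChar[3] >= 1L)
})

test_that("fitchLength equals the Sankoff uniform-cost oracle", {
  set.seed(11)
  for (i in 1:60) {
    m <- randomMorphMatrix(6, 8, nStates = 3, missingFrac = 0.1,
                           polyFrac = 0.05)
    tr <- ape::rtree(6, tip.label = sample(taxa(m)), br = NULL)
    expect_equal(fitchLength(tr, m)@totalSteps, sankoffOracle(tr, m))
  }
})

test_that("fitch length is invariant to root placement", {
  set.seed(12)
  m <- randomMorphMatrix(8, 15)
  tr <- ape::rtree(8, tip.label = taxa(m), br = NULL)
  L <- fitchLength(tr, m)@totalSteps
  for (og in taxa(m)[2:5]) {
    rer <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(fitchLength(rer, m)@totalSteps, L)
  }
})

test_that("masking cells never increases the length of a fixed tree", {
  set.seed(13)
  for (i in 1:10) {
    m <- randomMorphMatrix(7, 12, missingFrac = 0.05)
    tr <- ape::rtree(7, tip.label = taxa(m), br = NULL)
    L <- fitchLength(tr, m)@totalSteps
    m2 <- maskPartition(m, sample(taxa(m), 3), sample(12, 5))
    expect_lte(fitchLength(tr, m2)@totalSteps, L)
  }
})

test_that("minSteps follows the distinct-state count over resolutions", {
  tok <- rbind(a = c("0", "?", "0", "[01]"),
               b = c("1", "?", "1", "[01]"),
               c = c("1", "?", "2", "0"),
               d = c("0", "?", "2", "1"))
  m <- morphMatrix(tok)
  expect_equal(minSteps(m, 1), 1L)   # binary, both states
  expect_equal(minSteps(m, 2), 0L)   # entirely missing
  expect_equal(minSteps(m, 3), 2L)   # three states
  # polymorphisms resolve to cover {0,1} with... 0 and 1 both needed by
  # the fixed cells; polymorphic cells hit either -> still 1
  expect_equal(minSteps(m, 4), 1L)
})

test_that("maxSteps is n minus the top state frequency, and matches
          exhaustive maximisation over 6-taxon topologies", {
  tok <- rbind(a = "0", b = "0", c = "1", d = "1")
  m <- morphMatrix(tok)
  expect_equal(maxSteps(m, 1), 2L)
  expect_equal(maxSteps(morphMatrix(rbind(a = "0", b = "0", c = "0")), 1), 0L)

  set.seed(14)
  labels <- paste0("t", 1:6)
  topos <- allTopologies(labels)
  for (i in 1:12) {
    m <- randomMorphMatrix(6, 1, nStates = 3, missingFrac = 0.15,
                           polyFrac = 0.1, labels = labels)
    if (all(m@cells == 0L)) next
    brute <- max(vapply(topos, function(tr)
      sankoffOracleChar(tr, m, 1L), numeric(1)))
    expect_equal(maxSteps(m, 1), brute)
  }
})

test_that("m_i <= s_i <= g_i on every scored tree", {
  set.seed(15)
  for (i in 1:10) {
    m <- randomMorphMatrix(7, 10, missingFrac = 0.2, polyFrac = 0.1)
    tr <- ape::rtree(7, tip.label = taxa(m), br = NULL)
    sc <- fitchLength(tr, m)
    expect_true(all(sc@minSteps <= sc@perChar))
    expect_true(all(sc@perChar <= sc@maxSteps))
  }
})

test_that("ensemble indices: CI = 1 without homoplasy and hand equality", {
  # zero-homoplasy: characters are clade markers of the scoring tree
  tr <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  tok <- cbind(c("0", "0", "1", "1", "1"), c("0", "0", "0", "1", "1"))
  rownames(tok) <- c("a", "b", "c", "d", "e")
  m <- morphMatrix(tok)
  ei <- ensembleIndices(tr, m)
  expect_equal(ei$CI, 1)

  set.seed(16)
  m <- randomMorphMatrix(6, 9, missingFrac = 0.1)
  tr <- ape::rtree(6, tip.label = taxa(m), br = NULL)
  sc <- fitchLength(tr, m)
  S <- sum(vapply(seq_len(nChar(m)), function(k)
    sankoffOracleChar(tr, m, k), numeric(1)))
  topos <- allTopologies(taxa(m))
  g <- vapply(seq_len(nChar(m)), function(k)
    max(vapply(topos, sankoffOracleChar, numeric(1), m = m, charId = k)),
    numeric(1))
  mins <- vapply(seq_len(nChar(m)), function(k)
    min(vapply(topos, sankoffOracleChar, numeric(1), m = m, charId = k)),
    numeric(1))
  ei <- ensembleIndices(tr, m)
  expect_equal(ei$S, S)
  expect_equal(ei$CI, sum(mins) / S)
  expect_equal(ei$RI, (sum(g) - S) / (sum(g) - sum(mins)))
})

test_that("uninformative characters can be excluded from the indices", {
  tok <- rbind(a = c("0", "0"), b = c("0", "1"), c = c("1", "0"),
               d = c("1", "0"), e = c("1", "1"))
  m <- morphMatrix(tok)
  tr <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  incl <- ensembleIndices(tr, m, includeUninformative = TRUE)
  excl <- ensembleIndices(tr, m, includeUninformative = FALSE)
  expect_true(is.list(excl))
  expect_lte(excl$S, incl$S)
})

test_that("per-character scores export as a m/s/g table", {
  set.seed(17)
  m <- randomMorphMatrix(6, 8)
  tr <- ape::rtree(6, tip.label = taxa(m), br = NULL)
  sc <- fitchLength(tr, m)
  df <- writeScores(sc)
  expect_equal(names(df), c("charId", "m", "s", "g"))
  expect_equal(sum(df$s), sc@totalSteps)
  f <- tempfile(fileext = ".csv")
  writeScores(sc, f)
  expect_equal(read.csv(f)$g, df$g)
})
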