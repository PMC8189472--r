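# Strict consensus, RF distance, bootstrap and Bremer support

test_that("consensus of one tree is that tree", {
  tr <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  cons <- strictConsensus(list(tr))
  expect_equal(rfDistance(cons, tr), 0L)
})

test_that("consensus of all 5-taxon topologies is the star tree", {
  labels <- letters[1:5]
  topos <- allTopologies(labels)
  expect_equal(length(topos), 15L)
  cons <- strictConsensus(topos)
  expect_equal(cons$Nnode, 1L)
})

test_that("one NNI produces exactly one polytomy, matching bipartition
          intersection", {
  t1 <- ape::read.tree(text = "(a,(b,((c,d),(e,f))));")
  t2 <- ape::read.tree(text = "(a,(b,((c,e),(d,f))));")
  cons <- strictConsensus(list(t1, t2))
  # shared splits by hand: {c,d,e,f} only among the non-trivial ones
  expect_equal(sort(MorphoMask:::splitKeys(cons)),
               sort(intersect(MorphoMask:::splitKeys(t1),
                              MorphoMask:::splitKeys(t2))))
  expect_error(strictConsensus(list(t1, ape::drop.tip(t2, "a"))), "a")
})

test_that("strict consensus matches ape's consensus on random tree sets", {
  set.seed(31)
  labels <- paste0("t", 1:8)
  for (i in 1:6) {
    trees <- lapply(1:4, function(j) {
      tr <- ape::rtree(8, tip.label = sample(labels), br = NULL)
      ape::root(tr, outgroup = "t1", resolve.root = TRUE)
    })
    mine <- strictConsensus(trees)
    apecons <- ape::consensus(trees, p = 1, rooted = TRUE)
    expect_equal(sort(MorphoMask:::cladeKeys(mine, includeRoot = TRUE)),
                 sort(MorphoMask:::cladeKeys(apecons, includeRoot = TRUE)))
  }
})

test_that("RF distance: identity, NNI neighbours, and phangorn equality", {
  t1 <- ape::read.tree(text = "(a,(b,((c,d),(e,f))));")
  expect_equal(rfDistance(t1, t1), 0L)
  # one NNI across the (c,d)|(e,f) edge: d trades places with (e,f)
  t2 <- ape::read.tree(text = "(a,(b,((c,(e,f)),d)));")
  expect_equal(rfDistance(t1, t2), 2L)
  skip_if_not_installed("phangorn")
  set.seed(32)
  for (i in 1:20) {
    labels <- paste0("t", 1:10)
    a <- ape::rtree(10, tip.label = sample(labels), br = NULL)
    b <- ape::rtree(10, tip.label = sample(labels), br = NULL)
    expect_equal(rfDistance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a),
                                              ape::unroot(b))))
  }
})

test_that("bootstrap frequencies are deterministic, bounded, and high
          for clean clades", {
  set.seed(33)
  # zero-homoplasy matrix with several characters per clade
  tr <- ape::read.tree(text = "(o,(a,(b,(c,(d,e)))));")
  clades <- list(c("a","b","c","d","e"), c("b","c","d","e"),
                 c("c","d","e"), c("d","e"))
  tok <- do.call(cbind, lapply(clades, function(cl)
    matrix(ifelse(tr$tip.label %in% cl, "1", "0"), ncol = 1)))
  tok <- tok[, rep(1:4, each = 8)]
  rownames(tok) <- tr$tip.label
  m <- morphMatrix(tok)
  cfg <- searchConfig(nReplicates = 3, earlyStop = NULL)
  bs1 <- bootstrapSupport(m, nBoot = 40, config = cfg, outgroup = "o",
                          clades = clades, seed = 4)
  bs2 <- bootstrapSupport(m, nBoot = 40, config = cfg, outgroup = "o",
                          clades = clades, seed = 4)
  expect_identical(bs1, bs2)
  expect_true(all(bs1$bootstrap >= 0 & bs1$bootstrap <= 100))
  expect_true(all(bs1$bootstrap >= 95))
})

test_that("Bremer decay matches exhaustive enumeration on small instances", {
  set.seed(34)
  for (i in 1:5) {
    m <- randomMorphMatrix(6, 12, missingFrac = 0.05)
    mpts <- heuristicSearch(m, searchConfig(nReplicates = 5, hold = 30,
                                            seed = i))
    maxExtra <- 3L
    bd <- bremerSupport(m, mpts, maxExtra = maxExtra)
    # oracle: score all topologies, find for each consensus clade the
    # cheapest tree lacking it
    topos <- allTopologies(taxa(m))
    lens <- vapply(topos, sankoffOracle, numeric(1), m = m)
    L <- min(lens)
    expect_equal(L, bestLength(mpts))
    cons <- strictConsensus(mpts)
    og <- mpTrees(mpts)[[1]]$edge[1, 2]
    ogLab <- mpTrees(mpts)[[1]]$tip.label[og]
    keys <- MorphoMask:::cladeKeys(cons)
    oracle <- vapply(keys, function(k) {
      tipset <- strsplit(k, "\r", fixed = TRUE)[[1]]
      lacking <- vapply(seq_along(topos), function(j) {
        rooted <- ape::root(topos[[j]], outgroup = ogLab,
                            resolve.root = TRUE)
        !(k %in% MorphoMask:::cladeKeys(rooted, includeRoot = TRUE))
      }, logical(1))
      if (!any(lacking)) Inf else min(lens[lacking]) - L
    }, numeric(1))
    cmp <- ifelse(oracle > maxExtra, Inf, oracle)
    got <- setNames(bd$bremer, NULL)
    expect_equal(got, setNames(cmp, NULL))
  }
})

test_that("clades with no support decay immediately", {
  # two characters in direct conflict: consensus keeps only what both
  # agree on
  tok <- rbind(o = c("0","0"), a = c("1","1"), b = c("1","0"),
               c = c("0","1"), d = c("0","0"))
  m <- morphMatrix(tok)
  mpts <- heuristicSearch(m, searchConfig(nReplicates = 6, hold = 30,
                                          seed = 2), outgroup = "o")
  bd <- bremerSupport(m, mpts, maxExtra = 2L)
  # consensus clades survive at L by definition, so decay is >= 1
  expect_true(all(bd$bremer >= 1))
})

test_that("support annotation lands on the right consensus nodes", {
  tr <- ape::read.tree(text = "(o,(a,(b,(c,d))));")
  boot <- data.frame(clade = c("c,d", "b,c,d"), bootstrap = c(98, 76))
  brem <- data.frame(clade = "c,d", bremer = Inf)
  ann <- annotateSupport(tr, boot, brem)
  expect_equal(length(ann$node.label), tr$Nnode)
  sets <- MorphoMask:::nodeTipSets(ann)
  nTip <- 5L
  for (v in (nTip + 1L):(nTip + ann$Nnode)) {
    key <- paste(sort(ann$tip.label[sets[[v]]]), collapse = ",")
    lab <- ann$node.label[v - nTip]
    if (key == "c,d") expect_equal(lab, "98/>max")
    if (key == "b,c,d") expect_equal(lab, "76/-")
  }
  nwk <- ape::write.tree(ann)
  expect_match(nwk, "98/>max", fixed = TRUE)
})
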