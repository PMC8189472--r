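# Independent oracles used throughout the suite.  These deliberately
# avoid the package's own scoring/search/consensus code paths: Sankoff
# dynamic programming written directly on ape trees, exhaustive
# topology enumeration by stepwise addition, and brute-force labelling
# enumeration for reconstruction sets.

ORACLE_INF <- 1e9

taxa_of <- function(ts) mpTrees(ts)[[1]]$tip.label

# random token matrix (and MorphMatrix) with controllable missing and
# polymorphic fractions
randomTokens <- function(nTaxa, nCharacters, nStates = 3L,
                         missingFrac = 0.1, polyFrac = 0.05,
                         labels = paste0("t", seq_len(nTaxa))) {
  tok <- matrix(as.character(sample(0:(nStates - 1L),
                                    nTaxa * nCharacters, TRUE)),
                nTaxa, nCharacters, dimnames = list(labels, NULL))
  nCells <- length(tok)
  miss <- sample(nCells, round(missingFrac * nCells))
  tok[miss] <- sample(c("?", "-"), length(miss), TRUE)
  free <- setdiff(seq_len(nCells), miss)
  poly <- sample(free, round(polyFrac * nCells))
  for (i in poly) {
    st <- sort(sample(0:(nStates - 1L), 2L))
    tok[i] <- paste0("[", st[1L], st[2L], "]")
  }
  tok
}

randomMorphMatrix <- function(nTaxa, nCharacters, ...) {
  morphMatrix(randomTokens(nTaxa, nCharacters, ...))
}

# state-set list per tip for one character (missing = full alphabet)
oracleTipSets <- function(m, charId, labels) {
  alph <- sort(unique(unlist(lapply(taxa(m), function(tx) {
    s <- stateSet(m, tx, charId)
    if (anyNA(s)) NULL else s
  }))))
  if (!length(alph)) alph <- 0L
  lapply(labels, function(tx) {
    s <- stateSet(m, tx, charId)
    if (anyNA(s)) alph else s
  })
}

# Sankoff uniform-cost minimum steps for one character on a tree
sankoffOracleChar <- function(tree, m, charId) {
  labels <- tree$tip.label
  tips <- oracleTipSets(m, charId, labels)
  alph <- sort(unique(unlist(tips)))
  k <- length(alph)
  nTip <- length(labels)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  cost <- matrix(0, nTip + tree$Nnode, k)
  for (i in seq_len(nTip))
    cost[i, ] <- ifelse(alph %in% tips[[i]], 0, ORACLE_INF)
  for (p in unique(po[, 1L])) {
    acc <- rep(0, k)
    for (ch in po[po[, 1L] == p, 2L]) {
      cc <- cost[ch, ]
      acc <- acc + vapply(seq_len(k), function(s)
        min(cc + (seq_len(k) != s)), numeric(1))
    }
    cost[p, ] <- acc
  }
  min(cost[nTip + 1L, ])
}

sankoffOracle <- function(tree, m) {
  sum(vapply(seq_len(nChar(m)), function(k)
    sankoffOracleChar(tree, m, k), numeric(1)))
}

# all unrooted topologies over the given labels (rooted at the first
# label for phylo representation), by recursive edge insertion
allTopologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);",
                                        labels[1], labels[2], labels[3]))
  trees <- list(base)
  for (i in seq(4L, length.out = n - 3L)) {
    nxt <- list()
    for (tr in trees)
      for (e in seq_len(nrow(tr$edge)))
        nxt[[length(nxt) + 1L]] <- insertTipOracle(tr, e, labels[i])
    trees <- nxt
  }
  trees
}

# insert a new tip into edge e of an (unrooted, trifurcating-root)
# phylo by direct edge-matrix surgery
insertTipOracle <- function(tr, e, label) {
  nTip <- length(tr$tip.label)
  edge <- tr$edge
  # renumber: tips 1..nTip+1 (new tip = nTip+1), internals shift by 1
  edge[edge > nTip] <- edge[edge > nTip] + 1L
  newTip <- nTip + 1L
  newNode <- max(edge) + 1L
  target <- edge[e, ]
  edge <- edge[-e, , drop = FALSE]
  edge <- rbind(edge,
                c(target[1L], newNode),
                c(newNode, target[2L]),
                c(newNode, newTip))
  out <- list(edge = edge, Nnode = tr$Nnode + 1L,
              tip.label = c(tr$tip.label, label))
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

# exhaustive minimum length over all topologies
bruteOptimum <- function(m) {
  trees <- allTopologies(taxa(m))
  lens <- vapply(trees, sankoffOracle, numeric(1), m = m)
  list(length = min(lens), trees = trees[lens == min(lens)], all = lens)
}

# all internal labellings of a rooted binary tree achieving minimum
# cost for one character; returns per-node optimal state sets
bruteMPRsets <- function(tree, m, charId) {
  labels <- tree$tip.label
  tips <- oracleTipSets(m, charId, labels)
  alph <- sort(unique(unlist(tips)))
  nTip <- length(labels)
  nInt <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  grid <- expand.grid(rep(list(alph), nInt))
  best <- Inf
  sets <- vector("list", nTip + nInt)
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    stateOf <- function(v) assign[v - nTip]
    # leaves pick their cheapest member given the parent state
    cost <- 0
    for (i in seq_len(nrow(po))) {
      p <- po[i, 1L]; ch <- po[i, 2L]
      ps <- stateOf(p)
      cost <- cost + if (ch <= nTip) as.integer(!(ps %in% tips[[ch]]))
      else as.integer(stateOf(ch) != ps)
    }
    if (cost < best) {
      best <- cost
      sets <- vector("list", nTip + nInt)
    }
    if (cost == best) {
      for (v in seq_len(nInt))
        sets[[nTip + v]] <- union(sets[[nTip + v]], assign[v])
    }
  }
  for (i in seq_len(nTip)) sets[[i]] <- tips[[i]]
  list(minCost = best, sets = lapply(sets, sort))
}

# brute-force monophyly classification: rooted-clade test via ape,
# then convexity via the minimum number of changes of the membership
# character on the subtree spanned by the MRCA clade (1 change iff the
# set and its complement occupy disjoint parts of that subtree)
bruteMonophyly <- function(tree, tipset) {
  if (ape::is.monophyletic(tree, tipset)) return("monophyletic")
  anc <- ape::getMRCA(tree, tipset)
  sub <- ape::extract.clade(tree, anc)
  tok <- matrix(ifelse(sub$tip.label %in% tipset, "1", "0"),
                ncol = 1, dimnames = list(sub$tip.label, NULL))
  m <- morphMatrix(tok)
  steps <- sankoffOracleChar(sub, m, 1L)
  if (steps == 1) "paraphyletic" else "polyphyletic"
}
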