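# Exact most-parsimonious-reconstruction (MPR) machinery for unordered
# characters: per-node MPR state sets via a uniform-cost dynamic
# program (down + outside passes), and branch-change queries via the
# same program with node-state clamps.  Feasible exactly because
# characters carry few states.

.INF <- 1e9

# leaf cost rows: 0 for each member state of the cell's set (missing =
# full alphabet), INF otherwise
leafCosts <- function(bitsRow, nStates) {
  t(vapply(bitsRow, function(b) {
    ifelse(bitwAnd(b, bitwShiftL(1L, seq_len(nStates) - 1L)) != 0L, 0, .INF)
  }, numeric(nStates)))
}

# downpass costs for one character on a rooted tree; clamps is a list
# node-id -> logical allowed vector
sankoffDown <- function(tree, leafCost, nStates, clamps = list()) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  cost <- matrix(0, nNode, nStates)
  cost[seq_len(nTip), ] <- leafCost
  for (nm in names(clamps)) {
    v <- as.integer(nm)
    if (v <= nTip) cost[v, !clamps[[nm]]] <- .INF
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(po[, 2L], po[, 1L])
  for (p in unique(po[, 1L])) {            # postorder parent order
    acc <- rep(0, nStates)
    for (ch in kids[[as.character(p)]]) {
      cc <- cost[ch, ]
      acc <- acc + pmin(cc, min(cc) + 1)
    }
    cl <- clamps[[as.character(p)]]
    if (!is.null(cl)) acc[!cl] <- .INF
    cost[p, ] <- acc
  }
  cost
}

rootNodeOf <- function(tree) length(tree$tip.label) + 1L

# minimum tree length for one character under optional clamps
clampedMin <- function(tree, leafCost, nStates, clamps = list()) {
  cost <- sankoffDown(tree, leafCost, nStates, clamps)
  min(cost[rootNodeOf(tree), ])
}

#' MPR state sets for one character
#'
#' For every node, the exact set of states attainable in at least one
#' most-parsimonious reconstruction of the character on the tree
#' (uniform-cost inside/outside dynamic program).  Leaves keep their
#' observed sets, with missing cells treated as the full alphabet.
#'
#' @param tree rooted binary `phylo` whose tips occur in `m`
#' @param m a [MorphMatrix-class]
#' @param charId 1-based character id
#' @return list of integer state vectors, indexed by node id (tips
#'   first, then internal nodes ape-style)
#' @export
mprStateSets <- function(tree, m, charId) {
  stopifnot(is(m, "MorphMatrix"))
  alph <- alphabetBits(m)[charId]
  nStates <- if (alph == 0L) 1L else max(bitsToStates(alph)) + 1L
  bits <- tipBits(m, tree$tip.label)[, charId]
  lc <- leafCosts(bits, nStates)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  down <- sankoffDown(tree, lc, nStates)
  root <- rootNodeOf(tree)
  S <- min(down[root, ])

  # outside costs: out[v, s] = min cost of the whole tree minus
  # subtree(v), given v = s (includes the edge above v)
  out <- matrix(0, nNode, nStates)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  kids <- split(pre[, 2L], pre[, 1L])
  out[root, ] <- 0
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1L]; v <- pre[i, 2L]
    sib <- setdiff(kids[[as.character(p)]], v)
    base <- out[p, ]                       # cost above p given p = e
    for (b in sib) {
      cc <- down[b, ]
      base <- base + pmin(cc, min(cc) + 1)
    }
    # out[v, s] = min_e(base[e] + (e != s))
    out[v, ] <- pmin(base, min(base) + 1)
  }
  sets <- vector("list", nNode)
  for (v in seq_len(nNode)) {
    tot <- down[v, ] + out[v, ]
    sets[[v]] <- which(tot == S) - 1L
  }
  for (v in seq_len(nTip))
    sets[[v]] <- if (bits[v] == 0L) 0:(nStates - 1L) else
      bitsToStates(bits[v])
  sets
}

#' Render a character change in superscript notation
#'
#' @param charId 1-based character id
#' @param state derived state
#' @return e.g. `"C151^1"`
#' @export
synapoNotation <- function(charId, state) paste0("C", charId, "^", state)

#' Unambiguous synapomorphies of a clade
#'
#' Enumerates every (character, derived state) pair whose change is
#' placed on the clade's stem branch by most-parsimonious
#' reconstructions, across all supplied trees.  A change is
#' `unambiguous` when every MPR of every tree containing the clade
#' asserts it (the clade node is fixed to the derived state and the
#' stem's parent can never hold it), `ambiguous` when some but not all
#' MPRs do.
#'
#' @param trees a [TreeSet-class] or list of rooted `phylo` trees
#' @param m a [MorphMatrix-class]
#' @param clade character vector of tip labels defining the clade
#' @return data.frame with columns `charId`, `derivedState`, `status`,
#'   `nTreesSupporting`, `label`; ordered by `charId`
#' @export
unambiguousSynapomorphies <- function(trees, m, clade) {
  tr <- if (is(trees, "TreeSet")) mpTrees(trees) else trees
  key <- cladeKeyOf(clade)
  holds <- if (length(clade) == 1L)
    vapply(tr, function(t) clade %in% t$tip.label, logical(1))
  else
    vapply(tr, function(t) key %in% cladeKeys(t, includeRoot = TRUE),
           logical(1))
  if (!any(holds)) stop("clade not present in any supplied tree")
  trIn <- tr[holds]

  recs <- list()
  alph <- alphabetBits(m)
  for (k in seq_len(nChar(m))) {
    if (alph[k] == 0L) next
    states <- bitsToStates(alph[k])
    nStates <- max(states) + 1L
    existsCount <- setNames(integer(length(states)), states)
    allCount <- setNames(integer(length(states)), states)
    for (t in trIn) {
      bits <- tipBits(m, t$tip.label)[, k]
      lc <- leafCosts(bits, nStates)
      sChar <- clampedMin(t, lc, nStates)
      nodeId <- cladeNodeId(t, clade)
      parentId <- t$edge[t$edge[, 2L] == nodeId, 1L]
      if (!length(parentId)) next            # clade node is the root
      for (d in states) {
        allow <- rep(FALSE, nStates); allow[d + 1L] <- TRUE
        clampD <- list(allow)
        names(clampD) <- nodeId
        clampNotD <- list(!allow)
        names(clampNotD) <- parentId
        ex <- clampedMin(t, lc, nStates,
                         c(clampD, clampNotD)) == sChar
        if (ex) {
          existsCount[as.character(d)] <- existsCount[as.character(d)] + 1L
          # all MPRs assert the change iff no MPR violates it
          clampCNotD <- list(!allow); names(clampCNotD) <- nodeId
          clampPD <- list(allow); names(clampPD) <- parentId
          viol <- clampedMin(t, lc, nStates, clampCNotD) == sChar ||
            clampedMin(t, lc, nStates, clampPD) == sChar
          if (!viol) allCount[as.character(d)] <- allCount[as.character(d)] + 1L
        }
      }
    }
    for (d in states) {
      dd <- as.character(d)
      if (existsCount[dd] > 0L) {
        status <- if (allCount[dd] == length(trIn) && all(holds))
          "unambiguous" else "ambiguous"
        recs[[length(recs) + 1L]] <- data.frame(
          charId = k, derivedState = d, status = status,
          nTreesSupporting = unname(existsCount[dd]),
          label = synapoNotation(k, d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs))
    return(data.frame(charId = integer(0), derivedState = integer(0),
                      status = character(0), nTreesSupporting = integer(0),
                      label = character(0)))
  out <- do.call(rbind, recs)
  out[order(out$charId, out$derivedState), , drop = FALSE]
}

# node id whose tip set equals the clade (tip id for singletons)
cladeNodeId <- function(tree, clade) {
  idx <- match(clade, tree$tip.label)
  if (anyNA(idx)) stop("clade tips missing from tree: ",
                       paste(clade[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  sets <- nodeTipSets(tree)
  nTip <- length(tree$tip.label)
  target <- sort(idx)
  for (v in (nTip + 1L):(nTip + tree$Nnode))
    if (identical(sets[[v]], target)) return(v)
  stop("clade is not present in the tree")
}
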