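# Internal helpers: state-set bitmask encoding and light phylo plumbing.
# States are small non-negative integers (0-based, matching the matrix
# files); a cell is an integer bitmask with bit s set for state s and
# 0 meaning MISSING.

.MAX_STATES <- 16L

statesToBits <- function(states) {
  if (length(states) == 0L) return(0L)
  if (any(states < 0L | states >= .MAX_STATES))
    stop("states must lie in 0..", .MAX_STATES - 1L)
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

bitsToStates <- function(bits) {
  which(bitwAnd(bits, bitwShiftL(1L, 0:(.MAX_STATES - 1L))) != 0L) - 1L
}

# render a bitmask as a matrix token: "?", "1", "[01]"
bitsToToken <- function(bits) {
  if (bits == 0L) return("?")
  st <- bitsToStates(bits)
  if (length(st) == 1L) as.character(st) else
    paste0("[", paste(st, collapse = ""), "]")
}

# ape-style rooted phylo from an edge matrix produced by the kernel
newPhylo <- function(edge, tipLabels) {
  tr <- list(edge = edge, Nnode = nrow(edge) + 1L - length(tipLabels),
             tip.label = tipLabels)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# per-internal-node tip index sets, postorder accumulation (handles
# polytomies); returns list indexed by node id - nTip
nodeTipSets <- function(tree) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  sets <- vector("list", nTip + nNode)
  for (i in seq_len(nTip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# clade keys: one string per internal node, sorted tip labels
cladeKeys <- function(tree, includeRoot = FALSE) {
  nTip <- length(tree$tip.label)
  sets <- nodeTipSets(tree)
  rootNode <- nTip + 1L
  ids <- (nTip + 1L):(nTip + tree$Nnode)
  if (!includeRoot) ids <- setdiff(ids, rootNode)
  keys <- vapply(ids, function(v)
    paste(sort(tree$tip.label[sets[[v]]]), collapse = "\r"), character(1))
  names(keys) <- ids
  keys
}

cladeKeyOf <- function(tipLabels) paste(sort(tipLabels), collapse = "\r")

# unrooted non-trivial splits, normalised to exclude the side holding
# the alphabetically first tip label
splitKeys <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  nTip <- length(labs)
  sets <- nodeTipSets(tree)
  out <- character(0)
  for (v in (nTip + 1L):(nTip + tree$Nnode)) {
    side <- labs[sets[[v]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= nTip - 2L)
      out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

# canonical topology key (unrooted identity)
topologyKey <- function(tree) paste(sort(splitKeys(tree)), collapse = "\n")

# smallest clade (node id) containing the given tips on a rooted tree
mrcaNode <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tips not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  sets <- nodeTipSets(tree)
  nTip <- length(tree$tip.label)
  cand <- which(vapply(sets, function(s) all(idx %in% s), logical(1)))
  cand <- cand[cand > nTip]
  cand[which.min(lengths(sets[cand]))]
}
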