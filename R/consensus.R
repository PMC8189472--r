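# Strict consensus, Robinson-Foulds distance, bootstrap clade
# frequencies and Bremer (decay) support.

#' Strict consensus of a tree set
#'
#' Returns the rooted tree containing exactly the clades present in
#' every input tree, with polytomies where the trees disagree.  All
#' trees must share one leaf set and rooting (searches root on the
#' configured outgroup).
#'
#' @param trees a [TreeSet-class] or list of `phylo` trees
#' @return a `phylo`, possibly polytomous
#' @export
strictConsensus <- function(trees) {
  tr <- if (is(trees, "TreeSet")) mpTrees(trees) else trees
  if (!length(tr)) stop("no trees supplied")
  labs <- sort(tr[[1L]]$tip.label)
  for (t in tr[-1L]) {
    if (!identical(sort(t$tip.label), labs)) {
      miss <- c(setdiff(labs, t$tip.label), setdiff(t$tip.label, labs))
      stop("trees differ in their leaf sets: ",
           paste(unique(miss), collapse = ", "))
    }
  }
  shared <- Reduce(intersect, lapply(tr, cladeKeys))
  buildFromClades(tr[[1L]]$tip.label, shared)
}

# assemble a rooted (possibly polytomous) phylo from nested clade keys
buildFromClades <- function(tipLabels, keys) {
  nTip <- length(tipLabels)
  sets <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  sets <- unique(sets[order(lengths(sets), decreasing = TRUE)])
  sets <- Filter(function(s) length(s) < nTip, sets)
  nodeSets <- c(list(tipLabels), sets)       # node 1 = root (all tips)
  nNode <- length(nodeSets)
  parent <- integer(nNode)                   # index into nodeSets
  for (i in seq_len(nNode)[-1L]) {
    cand <- which(vapply(seq_len(nNode), function(j)
      j != i && length(nodeSets[[j]]) > length(nodeSets[[i]]) &&
        all(nodeSets[[i]] %in% nodeSets[[j]]), logical(1)))
    parent[i] <- cand[which.min(lengths(nodeSets)[cand])]
  }
  tipParent <- vapply(tipLabels, function(tp) {
    cand <- which(vapply(nodeSets, function(s) tp %in% s, logical(1)))
    cand[which.min(lengths(nodeSets)[cand])]
  }, integer(1))
  edge <- rbind(
    cbind(nTip + tipParent, seq_len(nTip)),
    if (nNode > 1L) cbind(nTip + parent[-1L], nTip + seq_len(nNode)[-1L]))
  tr <- list(edge = edge, Nnode = nNode, tip.label = tipLabels)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies; 0 iff the trees are topologically identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set
#' @return integer
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- splitKeys(t1); s2 <- splitKeys(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Bootstrap clade frequencies
#'
#' For each pseudoreplicate, characters are resampled with replacement
#' to the original count (implemented as integer weights), a reduced
#' heuristic search is run, and the strict consensus taken; clades are
#' scored by the percentage of pseudoreplicate consensuses containing
#' them.  Seeded and reproducible.
#'
#' @param m a [MorphMatrix-class]
#' @param nBoot number of pseudoreplicates
#' @param config per-pseudoreplicate [searchConfig()] (default 10
#'   addition sequences with TBR)
#' @param outgroup rooting taxon
#' @param clades optional list of clade tip-label vectors to score; by
#'   default the clades of the reference search consensus
#' @param seed integer seed
#' @return data.frame with columns `clade` (tip labels pasted with
#'   commas) and `bootstrap` (percentage in 0..100)
#' @export
bootstrapSupport <- function(m, nBoot = 100L,
                             config = searchConfig(nReplicates = 10L,
                                                   earlyStop = NULL),
                             outgroup = taxa(m)[1L], clades = NULL,
                             seed = 1L) {
  stopifnot(is(m, "MorphMatrix"))
  set.seed(seed)
  if (is.null(clades)) {
    ref <- heuristicSearch(m, config, outgroup = outgroup)
    cons <- strictConsensus(ref)
    keys <- cladeKeys(cons)
    clades <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  }
  keys <- vapply(clades, cladeKeyOf, character(1))
  hits <- numeric(length(keys))
  for (b in seq_len(nBoot)) {
    w <- tabulate(sample.int(nChar(m), replace = TRUE), nChar(m))
    ts <- heuristicSearch(m, config, outgroup = outgroup,
                          weights = as.integer(w))
    ck <- cladeKeys(strictConsensus(ts))
    hits <- hits + (keys %in% ck)
  }
  data.frame(
    clade = vapply(clades, function(s) paste(sort(s), collapse = ","),
                   character(1)),
    bootstrap = 100 * hits / nBoot,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bremer (decay) support
#'
#' For each clade of the strict consensus of `mpts`, the smallest
#' number of extra steps d such that some tree of length at most
#' L + d lacks the clade, found by a suboptimal-retention search that
#' expands the TBR neighbourhoods of pooled trees while keeping every
#' distinct topology within `maxExtra` steps of the optimum.  Clades
#' still present in every retained tree are reported as `Inf`
#' (printed "> maxExtra").
#'
#' @param m a [MorphMatrix-class]
#' @param mpts a [TreeSet-class] from a completed search
#' @param maxExtra largest decay value resolved (default 5)
#' @param maxPool cap on retained suboptimal trees
#' @param maxExpand cap on neighbourhood expansions
#' @return data.frame with columns `clade`, `bremer`
#' @export
bremerSupport <- function(m, mpts, maxExtra = 5L, maxPool = 5000L,
                          maxExpand = 200L) {
  stopifnot(is(m, "MorphMatrix"), is(mpts, "TreeSet"))
  if (maxExtra < 1L) stop("maxExtra must be at least 1")
  labs <- mpTrees(mpts)[[1L]]$tip.label
  bits <- tipBits(m, labs)
  edges <- lapply(mpTrees(mpts), function(t) t$edge)
  og <- mpTrees(mpts)[[1L]]$edge[1L, 2L]   # first child of the root
  res <- retain_pool_cpp(edges, length(labs), bits,
                         rep(1L, nChar(m)), as.integer(maxExtra),
                         as.integer(maxPool), as.integer(maxExpand),
                         as.integer(og))
  poolTrees <- lapply(res$trees, newPhylo, tipLabels = labs)
  lens <- res$lengths
  L <- res$bestLength
  cons <- strictConsensus(mpts)
  keys <- cladeKeys(cons)
  poolKeys <- lapply(poolTrees, cladeKeys)
  bremer <- vapply(keys, function(k) {
    lacking <- lens[!vapply(poolKeys, function(ck) k %in% ck, logical(1))]
    if (!length(lacking)) Inf else min(lacking) - L
  }, numeric(1))
  data.frame(
    clade = vapply(keys, function(k)
      paste(strsplit(k, "\r", fixed = TRUE)[[1L]], collapse = ","),
      character(1)),
    bremer = bremer, row.names = NULL, stringsAsFactors = FALSE)
}
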