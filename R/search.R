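# Heuristic most-parsimonious-tree search: random addition sequences,
# NNI/SPR/TBR hill climbing (compiled kernel), hold-k retention, and
# pooling/deduplication of equally best trees across replicates.

.swapModes <- c(nni = 0L, spr = 1L, tbr = 2L)

#' Search configuration
#'
#' Desk-scale defaults: 50 random-addition replicates with an early
#' stop once 20 consecutive replicates fail to improve or add new
#' trees, TBR swapping, holding 10 trees per replicate.  A full
#' 1000-replicate protocol is obtained by raising `nReplicates` and
#' disabling the early stop.
#'
#' @param nReplicates number of random addition sequence replicates
#' @param hold equally shortest trees retained per replicate
#' @param swap branch-swapping neighbourhood: "nni", "spr" or "tbr"
#' @param maxPool cap on pooled equally best trees across replicates
#' @param earlyStop stop after this many replicates without improvement
#'   (NULL disables)
#' @param seed optional integer seed applied before drawing addition
#'   orders
#' @return a list of class `SearchConfig`
#' @export
searchConfig <- function(nReplicates = 50L, hold = 10L, swap = "tbr",
                         maxPool = 500L, earlyStop = 20L, seed = NULL) {
  swap <- match.arg(swap, names(.swapModes))
  stopifnot(nReplicates >= 1L, hold >= 1L, maxPool >= 1L)
  structure(list(nReplicates = as.integer(nReplicates),
                 hold = as.integer(hold), swap = swap,
                 maxPool = as.integer(maxPool),
                 earlyStop = if (is.null(earlyStop)) NULL else
                   as.integer(earlyStop),
                 seed = seed),
            class = "SearchConfig")
}

#' Random addition sequence starting tree
#'
#' Builds a tree by stepwise addition: taxa are inserted in a random
#' (seeded) order, each at the attachment edge of minimum incremental
#' Fitch length, ties broken by lowest edge index.  The result is
#' rooted on the outgroup.
#'
#' @param m a [MorphMatrix-class] with at least 3 taxa
#' @param outgroup taxon label used to root the tree (default first
#'   taxon)
#' @param order optional explicit taxon order (labels); when `NULL` a
#'   random permutation is drawn from R's RNG
#' @param weights optional integer character weights
#' @return a rooted binary `phylo`
#' @export
randomAdditionTree <- function(m, outgroup = taxa(m)[1L], order = NULL,
                               weights = NULL) {
  stopifnot(is(m, "MorphMatrix"))
  if (nTaxa(m) < 3L) stop("need at least 3 taxa")
  if (is.null(weights)) weights <- rep(1L, nChar(m))
  labs <- taxa(m)
  if (is.null(order)) order <- sample.int(nTaxa(m))
  else order <- match(order, labs)
  bits <- tipBits(m, labs)
  edge <- addition_tree_cpp(bits, as.integer(weights),
                            as.integer(order),
                            match(outgroup, labs))
  newPhylo(edge, labs)
}

#' Branch swapping from a starting tree
#'
#' Hill-climbs the NNI/SPR/TBR neighbourhood of `tree` by
#' first-improvement with deterministic move ordering, restarting after
#' every improvement, then collects up to `hold` equally shortest
#' trees by plateau exploration.  The returned best length never
#' exceeds the starting length.
#'
#' @param tree starting binary `phylo`
#' @param m a [MorphMatrix-class]
#' @param hold number of equally shortest trees to retain
#' @param swap "nni", "spr" or "tbr"
#' @param outgroup taxon used to root the returned trees
#' @param weights optional integer character weights
#' @return a [TreeSet-class]
#' @export
tbrSwap <- function(tree, m, hold = 10L, swap = "tbr",
                    outgroup = tree$tip.label[1L], weights = NULL) {
  stopifnot(inherits(tree, "phylo"), is(m, "MorphMatrix"))
  checkBinary(tree)
  swap <- match.arg(swap, names(.swapModes))
  if (is.null(weights)) weights <- rep(1L, nChar(m))
  labs <- tree$tip.label
  bits <- tipBits(m, labs)
  res <- swap_from_cpp(tree$edge, length(labs), bits, as.integer(weights),
                       .swapModes[[swap]], as.integer(hold),
                       match(outgroup, labs))
  new("TreeSet",
      trees = lapply(res$trees, newPhylo, tipLabels = labs),
      bestLength = res$bestLength,
      replicateBest = as.integer(res$replicateBest))
}

#' Heuristic search for most-parsimonious trees
#'
#' Runs `nReplicates` random-addition-plus-branch-swapping replicates,
#' pooling and deduplicating the equally best trees (by unrooted
#' topology) up to `maxPool`.  Fully reproducible given `seed`.
#'
#' @param m a [MorphMatrix-class] with at least 4 taxa
#' @param config a [searchConfig()] list
#' @param outgroup taxon label used to root reported trees
#' @param weights optional integer character weights (bootstrap
#'   resampling weights)
#' @param keepTaxa optional subset of taxa to analyse (default all)
#' @return a [TreeSet-class]
#' @export
heuristicSearch <- function(m, config = searchConfig(),
                            outgroup = NULL, weights = NULL,
                            keepTaxa = NULL) {
  stopifnot(is(m, "MorphMatrix"))
  if (!is.null(keepTaxa)) m <- dropTaxa(m, setdiff(taxa(m), keepTaxa))
  labs <- taxa(m)
  if (is.null(outgroup)) outgroup <- labs[1L]
  if (length(labs) < 4L) stop("need at least 4 taxa to search")
  if (!outgroup %in% labs) stop("outgroup '", outgroup, "' not in matrix")
  if (is.null(weights)) weights <- rep(1L, nChar(m))
  if (!is.null(config$seed)) set.seed(config$seed)
  bits <- tipBits(m, labs)
  og <- match(outgroup, labs)

  n <- length(labs)
  chunk <- 5L
  done <- 0L
  sinceImprove <- 0L
  best <- Inf
  pool <- list()           # topologyKey -> phylo
  repBest <- integer(0)
  while (done < config$nReplicates) {
    k <- min(chunk, config$nReplicates - done)
    orders <- t(vapply(seq_len(k), function(i) sample.int(n),
                       integer(n)))
    res <- search_cpp(bits, as.integer(weights), orders,
                      .swapModes[[config$swap]], config$hold,
                      config$maxPool, og)
    repBest <- c(repBest, as.integer(res$replicateBest))
    improved <- FALSE
    if (res$bestLength < best) {
      best <- res$bestLength
      pool <- list()
      improved <- TRUE
    }
    if (res$bestLength == best) {
      for (ed in res$trees) {
        if (length(pool) >= config$maxPool) break
        tr <- newPhylo(ed, labs)
        key <- topologyKey(tr)
        if (is.null(pool[[key]])) {
          pool[[key]] <- tr
          improved <- TRUE
        }
      }
    }
    done <- done + k
    sinceImprove <- if (improved) 0L else sinceImprove + k
    if (!is.null(config$earlyStop) && sinceImprove >= config$earlyStop)
      break
  }
  new("TreeSet", trees = unname(pool), bestLength = best,
      replicateBest = repBest)
}

#' Drop taxa from a matrix
#'
#' @param m a [MorphMatrix-class]
#' @param drop taxon labels to remove
#' @return the reduced [MorphMatrix-class]
#' @export
dropTaxa <- function(m, drop) {
  stopifnot(is(m, "MorphMatrix"))
  bad <- setdiff(drop, taxa(m))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  keep <- setdiff(taxa(m), drop)
  new("MorphMatrix", cells = m@cells[keep, , drop = FALSE],
      partitions = m@partitions)
}
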