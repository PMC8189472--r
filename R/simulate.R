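# Mk-style matrix simulation with known ground truth: characters
# evolve on a specified topology with a per-branch change probability
# (scaled by branch length and a per-partition homoplasy multiplier);
# planted marker characters change exactly once, on the stem of a
# named clade, so they are guaranteed homoplasy-free synapomorphies.
# Fossil-like missingness masks cells per taxon.  A two-topology
# conflict mode lets one partition carry signal for a different
# placement of a focal clade, emulating a cranial-vs-postcranial
# signal conflict.

#' Simulation parameters
#'
#' @param tree generating topology (`phylo`) with branch lengths in
#'   expected changes
#' @param nChars named integer vector: characters per partition
#' @param nStates number of states characters may visit (2 or 3)
#' @param homoplasyRate named multiplier per partition applied to
#'   branch lengths when evolving noise characters (0 = no extra
#'   changes beyond planted markers)
#' @param missingFraction per-taxon probability that a cell is masked;
#'   scalar or named vector (elevated values emulate fragmentary
#'   fossils)
#' @param missingPartition optional partition name: restrict
#'   missingness to that partition's characters
#' @param conflictTree optional second topology over the same leaves
#' @param conflictPartitions partitions whose characters evolve on
#'   `conflictTree`
#' @param markers named list (by partition) of tip-label vectors; one
#'   marker character is planted per entry on the clade's stem
#' @param seed integer seed
#' @return a list of class `SimulationParams`
#' @export
simulationParams <- function(tree, nChars, nStates = 2L,
                             homoplasyRate = NULL, missingFraction = 0,
                             missingPartition = NULL,
                             conflictTree = NULL,
                             conflictPartitions = character(0),
                             markers = list(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(nChars)))
  if (is.null(homoplasyRate))
    homoplasyRate <- setNames(rep(1, length(nChars)), names(nChars))
  if (!is.null(conflictTree)) {
    if (!setequal(tree$tip.label, conflictTree$tip.label))
      stop("conflictTree must share the leaf set of tree")
    if (length(tree$tip.label) < 4L)
      stop("conflict scenarios need at least 4 leaves")
  }
  if (any(missingFraction < 0 | missingFraction > 1))
    stop("missingFraction must lie in [0, 1]")
  structure(list(tree = tree, nChars = nChars, nStates = as.integer(nStates),
                 homoplasyRate = homoplasyRate,
                 missingFraction = missingFraction,
                 missingPartition = missingPartition,
                 conflictTree = conflictTree,
                 conflictPartitions = conflictPartitions,
                 markers = markers, seed = seed),
            class = "SimulationParams")
}

# evolve one character on a tree: root state 0, per-edge change
# probability 1 - exp(-branch length * rate), uniform new state
evolveChar <- function(tree, rate, nStates) {
  nTip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")
  state <- integer(nTip + tree$Nnode)
  bl <- pre$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(pre$edge))
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1L]; v <- pre$edge[i, 2L]
    s <- state[p]
    if (runif(1) < 1 - exp(-bl[i] * rate)) {
      s <- sample(setdiff(0:(nStates - 1L), s), 1L)
    }
    state[v] <- s
  }
  state[seq_len(nTip)]
}

# marker character: derived state 1 on the clade, 0 elsewhere
markerChar <- function(tipLabels, clade) {
  as.integer(tipLabels %in% clade)
}

#' Simulate a character matrix with ground truth
#'
#' @param params a [simulationParams()] object
#' @return list with elements `matrix` (a [MorphMatrix-class]) and
#'   `truth` (generating trees, per-character partition and topology,
#'   planted markers, masked-cell record)
#' @export
simulateMatrix <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!is.null(params$seed)) set.seed(params$seed)
  labs <- params$tree$tip.label
  nTip <- length(labs)
  cols <- list()
  charPartition <- character(0)
  charTree <- character(0)
  markerRec <- list()
  for (p in names(params$nChars)) {
    gen <- if (p %in% params$conflictPartitions && !is.null(params$conflictTree))
      params$conflictTree else params$tree
    genName <- if (p %in% params$conflictPartitions && !is.null(params$conflictTree))
      "conflict" else "base"
    mk <- params$markers[[p]]
    nMk <- length(mk)
    if (nMk > params$nChars[[p]])
      stop("more markers than characters in partition ", p)
    if (nMk) {
      genKeys <- cladeKeys(gen, includeRoot = TRUE)
      for (i in seq_len(nMk)) {
        if (!cladeKeyOf(mk[[i]]) %in% genKeys)
          warning("marker clade not present in the generating topology ",
                  "of partition ", p)
        cols[[length(cols) + 1L]] <- markerChar(labs, mk[[i]])
        markerRec[[length(markerRec) + 1L]] <-
          list(partition = p, clade = mk[[i]],
               charId = length(cols))
      }
    }
    for (i in seq_len(params$nChars[[p]] - nMk))
      cols[[length(cols) + 1L]] <-
        evolveChar(gen, params$homoplasyRate[[p]], params$nStates)
    charPartition <- c(charPartition, rep(p, params$nChars[[p]]))
    charTree <- c(charTree, rep(genName, params$nChars[[p]]))
  }
  states <- do.call(cbind, cols)
  rownames(states) <- labs

  # missingness
  mf <- params$missingFraction
  if (length(mf) == 1L && is.null(names(mf)))
    mf <- setNames(rep(mf, nTip), labs)
  eligible <- if (is.null(params$missingPartition))
    seq_len(ncol(states)) else
    which(charPartition == params$missingPartition)
  masked <- matrix(FALSE, nTip, ncol(states), dimnames = list(labs, NULL))
  for (tx in labs) {
    f <- if (tx %in% names(mf)) mf[[tx]] else 0
    if (f > 0)
      masked[tx, eligible] <- runif(length(eligible)) < f
  }
  tokens <- matrix(as.character(states), nTip, ncol(states),
                   dimnames = list(labs, NULL))
  tokens[masked] <- "?"

  parts <- split(seq_along(charPartition), charPartition)
  mm <- morphMatrix(tokens, partitions = parts[unique(charPartition)])
  list(matrix = mm,
       truth = list(trees = list(base = params$tree,
                                 conflict = params$conflictTree),
                    charPartition = charPartition,
                    charTree = charTree,
                    markers = markerRec,
                    masked = masked))
}

# ladder ((A,B),C),D... newick fragment for a label vector
.ladder <- function(labs) {
  if (length(labs) == 1L) return(labs)
  out <- sprintf("(%s,%s)", labs[1L], labs[2L])
  for (l in labs[-(1:2)]) out <- sprintf("(%s,%s)", out, l)
  out
}

#' Build a two-partition signal-conflict scenario
#'
#' Constructs a base topology in which a focal clade attaches inside
#' the crown group (sister to the Brevirostres-like anchors) and a
#' conflict topology in which the same clade attaches basally (sister
#' to the hylaeochampsid-like anchors).  "Postcranial" characters
#' evolve on the base tree and carry `signal["postcranial"]` marker
#' characters for the crown attachment; "cranial" characters evolve on
#' the conflict tree and carry `signal["cranial"]` markers for the
#' basal attachment.  Both partitions also receive one marker per
#' clade shared by the two topologies, so each partition alone can
#' resolve the backbone; remaining characters are noise evolved at
#' `homoplasyRate`.  With `conflict = FALSE` the cranial markers move
#' to the base topology (negative control: no conflicting signal).
#'
#' @param nTaxa total number of taxa (>= 12)
#' @param focalSize number of focal-clade taxa (>= 2)
#' @param signal named vector: focal-attachment marker counts per
#'   partition, default `c(postcranial = 12, cranial = 6)`
#' @param nChars named vector of partition sizes, default
#'   `c(postcranial = 25, cranial = 40)`
#' @param conflict logical; `FALSE` gives the negative control
#' @param homoplasyRate expected number of changes per noise character
#'   over the whole tree (Poisson-like; values above ~1 produce
#'   appreciable homoplasy)
#' @param missingFraction per-taxon missingness (default 0)
#' @param seed integer seed
#' @return list with `matrix`, `truth` (as [simulateMatrix()], plus
#'   `focal`, `anchors`, `outgroup` and the expected placements)
#' @export
makeConflictScenario <- function(nTaxa = 16L, focalSize = 3L,
                                 signal = c(postcranial = 12L, cranial = 6L),
                                 nChars = c(postcranial = 25L, cranial = 40L),
                                 conflict = TRUE, homoplasyRate = 1,
                                 missingFraction = 0, seed = NULL) {
  if (focalSize < 2L) stop("focalSize must be at least 2")
  nCroc <- nTaxa - 7L - focalSize
  if (nCroc < 2L) stop("nTaxa too small for the anchor structure")
  focal <- paste0("Focal_", seq_len(focalSize))
  crocs <- paste0("Croc_", seq_len(nCroc))
  hylaeo <- c("Hylaeo_1", "Hylaeo_2")
  gavial <- c("Gavialoid_1", "Gavialoid_2")
  og <- "Outgroup"

  crown <- sprintf(
    "(%s,(Borealosuchus,(Planocraniid,(%s,%s))))",
    .ladder(gavial), .ladder(crocs), .ladder(focal))
  baseNwk <- sprintf("(%s,(%s,%s));", og, .ladder(hylaeo), crown)
  crownNoF <- sprintf(
    "(%s,(Borealosuchus,(Planocraniid,%s)))",
    .ladder(gavial), .ladder(crocs))
  confNwk <- sprintf("(%s,((%s,%s),%s));", og, .ladder(focal),
                     .ladder(hylaeo), crownNoF)
  base <- ape::read.tree(text = baseNwk)
  conf <- ape::read.tree(text = confNwk)
  # total tree length 1: homoplasyRate is then the expected number of
  # changes per noise character over the whole tree
  base$edge.length <- rep(1 / nrow(base$edge), nrow(base$edge))
  conf$edge.length <- rep(1 / nrow(conf$edge), nrow(conf$edge))

  crownAttach <- c(crocs, focal)            # base-only clade
  basalAttach <- c(focal, hylaeo)           # conflict-only clade
  sharedKeys <- intersect(cladeKeys(base), cladeKeys(conf))
  sharedClades <- lapply(sharedKeys, function(k)
    strsplit(k, "\r", fixed = TRUE)[[1L]])
  baseClades <- lapply(cladeKeys(base), function(k)
    strsplit(k, "\r", fixed = TRUE)[[1L]])

  # backbone markers cycled over clades, at least two deep where the
  # slot budget allows, so that a partition alone resolves its
  # generating backbone and no single homoplastic noise character can
  # tie a backbone clade; leftovers become evolved noise characters
  fillMarkers <- function(n, clades) {
    if (n <= 0L) return(list())
    clades[rep(seq_along(clades), length.out = min(n, 2L * length(clades)))]
  }
  postMk <- c(rep(list(crownAttach), signal[["postcranial"]]),
              fillMarkers(nChars[["postcranial"]] - signal[["postcranial"]],
                          baseClades))
  cranialFocal <- if (conflict) basalAttach else crownAttach
  cranMk <- c(rep(list(cranialFocal), signal[["cranial"]]),
              fillMarkers(nChars[["cranial"]] - signal[["cranial"]],
                          sharedClades))

  params <- simulationParams(
    tree = base, nChars = nChars, nStates = 2L,
    homoplasyRate = c(postcranial = homoplasyRate,
                      cranial = homoplasyRate),
    missingFraction = missingFraction,
    conflictTree = if (conflict) conf else NULL,
    conflictPartitions = if (conflict) "cranial" else character(0),
    markers = list(postcranial = postMk, cranial = cranMk),
    seed = seed)
  sim <- simulateMatrix(params)
  sim$truth$focal <- focal
  sim$truth$outgroup <- og
  sim$truth$anchors <- list(gavialoids = gavial,
                            crown = c("Borealosuchus", "Planocraniid",
                                      crocs),
                            hylaeochampsids = hylaeo)
  sim$truth$expectedPlacement <- list(
    full = "crown_crocodylian",
    masked = if (conflict) "basal_eusuchian" else "crown_crocodylian")
  sim
}
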