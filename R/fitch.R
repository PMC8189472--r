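# Fitch scoring of trees against a MorphMatrix, plus per-character
# minimum/maximum step bounds and the ensemble CI/RI built from them.

# bitmask rows for the kernel: tree-tip order, missing expanded to the
# character's observed alphabet (a character with no observed state at
# all becomes a constant, contributing zero steps)
tipBits <- function(m, tipLabels) {
  miss <- setdiff(tipLabels, taxa(m))
  if (length(miss))
    stop("tree leaf absent from matrix: ", paste(miss, collapse = ", "))
  bits <- m@cells[tipLabels, , drop = FALSE]
  alph <- alphabetBits(m)
  alph[alph == 0L] <- 1L
  for (k in seq_len(ncol(bits))) {
    z <- bits[, k] == 0L
    if (any(z)) bits[z, k] <- alph[k]
  }
  bits
}

checkBinary <- function(tree) {
  tab <- tabulate(tree$edge[, 1L])
  nTip <- length(tree$tip.label)
  kids <- tab[tab > 0L]
  if (any(kids > 3L) || sum(kids == 3L) > 1L)
    stop("tree must be binary (a single trifurcation at the root of an ",
         "unrooted tree is allowed)")
  invisible(TRUE)
}

#' Fitch parsimony length of a tree
#'
#' Exact minimum number of state changes of each unordered, equally
#' weighted character on the given topology (Fitch downpass with
#' missing cells initialised to the full observed alphabet and
#' polymorphic cells to their state set).  The result is independent of
#' where the tree is rooted.
#'
#' @param tree a binary `phylo` whose tips occur in `m`
#' @param m a [MorphMatrix-class]
#' @param weights optional non-negative integer character weights
#'   (used internally by the bootstrap); default all 1
#' @return a [ParsimonyScores-class]; its `totalSteps` is the tree
#'   length
#' @export
fitchLength <- function(tree, m, weights = NULL) {
  stopifnot(inherits(tree, "phylo"), is(m, "MorphMatrix"))
  checkBinary(tree)
  if (is.null(weights)) weights <- rep(1L, nChar(m))
  bits <- tipBits(m, tree$tip.label)
  res <- fitch_counts_cpp(tree$edge, length(tree$tip.label), bits,
                          as.integer(weights))
  # min/max bounds refer to the taxa actually scored on this tree
  msub <- if (setequal(tree$tip.label, taxa(m))) m else
    new("MorphMatrix", cells = m@cells[tree$tip.label, , drop = FALSE],
        partitions = m@partitions)
  new("ParsimonyScores",
      totalSteps = res$total,
      perChar = as.integer(res$perChar),
      minSteps = minSteps(msub) * as.integer(weights),
      maxSteps = maxSteps(msub) * as.integer(weights))
}

#' Per-character minimum possible steps
#'
#' The fewest changes any topology can require: the size of the
#' smallest state set hitting every scored cell, minus one (so
#' polymorphic cells are resolved in whichever way minimises the
#' count).  Missing cells are ignored; an unscored character needs 0
#' steps.
#'
#' @param m a [MorphMatrix-class]
#' @param charId 1-based character id(s); default all
#' @return integer vector
#' @export
minSteps <- function(m, charId = seq_len(nChar(m))) {
  stopifnot(is(m, "MorphMatrix"))
  vapply(charId, function(k) {
    cells <- m@cells[, k]
    cells <- cells[cells != 0L]
    if (!length(cells)) return(0L)
    alph <- bitsToStates(Reduce(bitwOr, cells))
    for (size in seq_along(alph)) {
      combos <- utils::combn(alph, size, simplify = FALSE)
      for (a in combos) {
        mask <- statesToBits(a)
        if (all(bitwAnd(cells, mask) != 0L)) return(size - 1L)
      }
    }
    length(alph) - 1L
  }, integer(1))
}

#' Per-character maximum parsimony steps
#'
#' The largest length any topology can force for an unordered
#' character: number of scored taxa minus the count of the most
#' frequent state, with polymorphic cells resolved to that state when
#' they contain it.
#'
#' @inheritParams minSteps
#' @return integer vector
#' @export
maxSteps <- function(m, charId = seq_len(nChar(m))) {
  stopifnot(is(m, "MorphMatrix"))
  vapply(charId, function(k) {
    cells <- m@cells[, k]
    cells <- cells[cells != 0L]
    if (!length(cells)) return(0L)
    alph <- bitsToStates(Reduce(bitwOr, cells))
    freq <- vapply(alph, function(s)
      sum(bitwAnd(cells, statesToBits(s)) != 0L), integer(1))
    length(cells) - max(freq)
  }, integer(1))
}

#' Ensemble consistency and retention indices
#'
#' CI = sum(m_i)/S and RI = (sum(g_i) - S)/(sum(g_i) - sum(m_i)),
#' computed over all characters by default (the TNT/PAUP* ensemble
#' convention, which includes parsimony-uninformative characters);
#' `includeUninformative = FALSE` restricts all three sums to
#' characters that can show homoplasy (m_i < g_i).
#'
#' @param trees a [TreeSet-class] of equally parsimonious trees, or a
#'   single `phylo`
#' @param m a [MorphMatrix-class]
#' @param includeUninformative include invariant/uninformative
#'   characters in the sums (default TRUE)
#' @return list with `S`, `CI`, `RI` (full precision) and `CI2`, `RI2`
#'   rounded to two decimals
#' @export
ensembleIndices <- function(trees, m, includeUninformative = TRUE) {
  tr <- if (is(trees, "TreeSet")) mpTrees(trees) else list(trees)
  scores <- fitchLength(tr[[1L]], m)
  lens <- vapply(tr, function(t) fitchLength(t, m)@totalSteps, numeric(1))
  if (length(unique(lens)) != 1L)
    warning("trees in the set differ in length; indices use the first tree")
  keep <- if (includeUninformative) rep(TRUE, nChar(m)) else
    scores@minSteps < scores@maxSteps
  S <- sum(scores@perChar[keep])
  sm <- sum(scores@minSteps[keep])
  sg <- sum(scores@maxSteps[keep])
  CI <- if (S > 0) sm / S else NA_real_
  RI <- if (sg > sm) (sg - S) / (sg - sm) else NA_real_
  list(S = S, CI = CI, RI = RI,
       CI2 = round(CI, 2L), RI2 = round(RI, 2L))
}
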