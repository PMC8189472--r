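# The masking/transfer experiment layer: build matrix variants, run
# the battery of searches, classify the focal clade's placement, test
# monophyly, and compare topologies across analyses.

#' Mask a character partition in selected taxa
#'
#' Sets every cell (taxon in `maskTaxa`, character in the partition) to
#' missing, leaving everything else untouched.  Idempotent.
#'
#' @param m a [MorphMatrix-class]
#' @param maskTaxa taxon labels to mask
#' @param partition partition name (looked up in `partitions(m)`) or an
#'   integer vector of 1-based character ids
#' @return the masked [MorphMatrix-class]
#' @export
maskPartition <- function(m, maskTaxa, partition) {
  stopifnot(is(m, "MorphMatrix"))
  ids <- resolvePartition(m, partition)
  bad <- setdiff(maskTaxa, taxa(m))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  cells <- m@cells
  cells[maskTaxa, ids] <- 0L
  new("MorphMatrix", cells = cells, partitions = m@partitions)
}

resolvePartition <- function(m, partition) {
  if (is.character(partition) && length(partition) == 1L) {
    if (!partition %in% names(partitions(m)))
      stop("matrix has no partition named '", partition, "'")
    return(partitions(m)[[partition]])
  }
  ids <- as.integer(partition)
  bad <- ids[!ids %in% seq_len(nChar(m))]
  if (length(bad)) stop("character ids outside 1..n_chars: ",
                        paste(bad, collapse = ", "))
  ids
}

#' Transfer partition scores from donor taxa to a recipient
#'
#' The recipient receives, per partition character, the union of the
#' donors' non-missing state sets; conflicting donor states become
#' polymorphisms and are reported in the `conflicts` attribute.  By
#' default the recipient's partition cells must be missing (the
#' experiment assumes a taxon with unknown data for the partition);
#' use `force = TRUE` to overwrite scored cells.
#'
#' @param m a [MorphMatrix-class]
#' @param donors donor taxon labels, scored for at least one partition
#'   character
#' @param recipient recipient taxon label
#' @param partition partition name or character id vector
#' @param force overwrite non-missing recipient cells
#' @param dropDonors remove the donors from the returned matrix
#' @return the modified [MorphMatrix-class], with a `conflicts`
#'   data.frame attribute
#' @export
transferScores <- function(m, donors, recipient, partition,
                           force = FALSE, dropDonors = FALSE) {
  stopifnot(is(m, "MorphMatrix"))
  ids <- resolvePartition(m, partition)
  bad <- setdiff(c(donors, recipient), taxa(m))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  cells <- m@cells
  if (length(ids) && all(cells[donors, ids, drop = FALSE] == 0L))
    stop("donors carry no scores in the partition")
  scored <- cells[recipient, ids] != 0L
  if (any(scored)) {
    if (!force)
      stop("recipient '", recipient, "' already scored for partition ",
           "character(s) ", paste(ids[scored], collapse = ", "),
           "; use force = TRUE to overwrite")
    warning("overwriting ", sum(scored), " scored recipient cell(s)")
  }
  conflicts <- list()
  for (k in ids) {
    dbits <- cells[donors, as.character(k)]
    dbits <- dbits[dbits != 0L]
    if (!length(dbits)) next
    u <- Reduce(bitwOr, dbits)
    if (length(unique(dbits)) > 1L)
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        charId = k, states = bitsToToken(u), stringsAsFactors = FALSE)
    cells[recipient, as.character(k)] <- u
  }
  out <- new("MorphMatrix", cells = cells, partitions = m@partitions)
  if (dropDonors) out <- dropTaxa(out, donors)
  attr(out, "conflicts") <- if (length(conflicts))
    do.call(rbind, conflicts) else
    data.frame(charId = integer(0), states = character(0))
  out
}

#' Classify the phylogenetic placement of a focal clade
#'
#' Decides whether the focal taxa fall inside the crown group
#' (`crown_crocodylian`): the smallest clade containing the focal taxa
#' and the crown (Brevirostres-side) anchors excludes every gavialoid
#' anchor; or outside it (`basal_eusuchian`): the smallest clade
#' containing the focal taxa and the hylaeochampsid anchors excludes
#' every crown-lineage anchor, or the focal taxa attach wholly outside
#' the clade spanned by the crown-lineage anchors.  Polytomies that
#' prevent either determination yield `unresolved`.
#'
#' @param tree rooted (consensus) `phylo`
#' @param focal tip labels of the focal group
#' @param anchors named list with elements `gavialoids`, `crown`
#'   (Borealosuchus/planocraniid/Brevirostres anchors) and
#'   `hylaeochampsids`
#' @return one of `"crown_crocodylian"`, `"basal_eusuchian"`,
#'   `"unresolved"`
#' @export
classifyPlacement <- function(tree, focal, anchors) {
  need <- c("gavialoids", "crown", "hylaeochampsids")
  if (!all(need %in% names(anchors)))
    stop("anchors must name: ", paste(need, collapse = ", "))
  all_anchors <- unlist(anchors[need], use.names = FALSE)
  missing <- setdiff(c(focal, all_anchors), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  sets <- nodeTipSets(tree)
  labs <- tree$tip.label
  spanned <- function(tips) {
    v <- mrcaNode(tree, tips)
    labs[sets[[v]]]
  }
  crocodylian <- c(anchors$gavialoids, anchors$crown)

  crownSpan <- spanned(c(focal, anchors$crown))
  if (!any(anchors$gavialoids %in% crownSpan))
    return("crown_crocodylian")
  basalSpan <- spanned(c(focal, anchors$hylaeochampsids))
  if (!any(crocodylian %in% basalSpan))
    return("basal_eusuchian")
  crocSpan <- spanned(crocodylian)
  if (!any(focal %in% crocSpan))
    return("basal_eusuchian")
  "unresolved"
}

#' Monophyly status of a tip set
#'
#' `monophyletic` when the smallest clade containing the tips equals
#' them exactly; otherwise `paraphyletic` when, within that smallest
#' clade, the tip set and its complement occupy disjoint parts of the
#' tree (the standard convexity criterion: their Steiner subtrees share
#' no internal node), and `polyphyletic` otherwise.
#'
#' @param tree rooted `phylo`
#' @param tipset at least two tip labels
#' @return `"monophyletic"`, `"paraphyletic"` or `"polyphyletic"`
#' @export
monophylyStatus <- function(tree, tipset) {
  if (length(tipset) < 2L) stop("tipset must contain at least two tips")
  missing <- setdiff(tipset, tree$tip.label)
  if (length(missing)) stop("tips absent from tree: ",
                            paste(missing, collapse = ", "))
  sets <- nodeTipSets(tree)
  labs <- tree$tip.label
  v <- mrcaNode(tree, tipset)
  cladeTips <- labs[sets[[v]]]
  if (setequal(cladeTips, tipset)) return("monophyletic")
  comp <- setdiff(cladeTips, tipset)
  if (steinerDisjoint(tree, tipset, comp, v))
    "paraphyletic" else "polyphyletic"
}

# do the Steiner subtrees of sets A and B (within the clade rooted at
# `top`) share an internal vertex?
steinerDisjoint <- function(tree, A, B, top) {
  nTip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- nodeTipSets(tree)
  kids <- split(po[, 2L], po[, 1L])
  inClade <- function(v) v == top || all(sets[[v]] %in% sets[[top]])
  # an internal node of the clade lies on the Steiner tree of X iff
  # at least two of its incident directions (children subtrees, plus
  # the up direction within the clade) contain X tips
  steiner <- function(X) {
    xt <- match(X, tree$tip.label)
    below <- integer(nTip + tree$Nnode)
    below[xt] <- 1L
    for (i in seq_len(nrow(po)))
      below[po[i, 1L]] <- below[po[i, 1L]] + below[po[i, 2L]]
    res <- logical(nTip + tree$Nnode)
    for (p in unique(po[, 1L])) {
      if (!inClade(p)) next
      dirs <- sum(vapply(kids[[as.character(p)]], function(ch)
        below[ch] > 0L, logical(1)))
      if (p != top && length(xt) - below[p] > 0L) dirs <- dirs + 1L
      res[p] <- dirs >= 2L
    }
    res
  }
  !any(steiner(A) & steiner(B))
}

#' Run the full masking/transfer experiment
#'
#' Executes up to four analyses on variants of a base matrix:
#' \describe{
#'   \item{control}{the base matrix minus `controlDrop` taxa}
#'   \item{full}{the base matrix as given}
#'   \item{masked}{`maskPartition(m, maskTaxa, partition)`}
#'   \item{transferred}{partition scores of `donors` transferred to
#'     `recipients`, donors dropped}
#' }
#' Each analysis yields the best length, the strict consensus, CI/RI,
#' the focal placement classification (when `focal`/`anchors` are
#' given) and monophyly statuses for `cladeTests`; consensuses are
#' compared pairwise by Robinson-Foulds distance on shared leaves.
#'
#' @param m base [MorphMatrix-class]
#' @param outgroup rooting taxon
#' @param partition partition name or id vector under test
#' @param maskTaxa taxa whose partition cells are masked in the
#'   `masked` analysis (typically the focal clade)
#' @param controlDrop taxa removed for the `control` analysis (NULL
#'   skips it)
#' @param donors,recipients transfer settings (NULL skips the
#'   `transferred` analysis); scores are transferred to every
#'   recipient
#' @param focal focal clade tip labels for placement classification
#' @param anchors anchor sets for [classifyPlacement()]
#' @param cladeTests named list of tip-label vectors whose monophyly
#'   status is reported per analysis
#' @param config [searchConfig()] used for every search
#' @param seed integer; per-analysis seeds are derived from it
#' @return an [ExperimentReport-class]
#' @export
runExperiment <- function(m, outgroup, partition, maskTaxa,
                          controlDrop = NULL, donors = NULL,
                          recipients = NULL, focal = NULL, anchors = NULL,
                          cladeTests = list(),
                          config = searchConfig(nReplicates = 10L),
                          seed = 1L) {
  stopifnot(is(m, "MorphMatrix"))
  variants <- list(full = m)
  if (!is.null(controlDrop))
    variants$control <- dropTaxa(m, controlDrop)
  variants$masked <- maskPartition(m, maskTaxa, partition)
  if (!is.null(donors) && !is.null(recipients)) {
    tm <- m
    for (r in recipients)
      tm <- transferScores(tm, donors, r, partition, force = TRUE)
    variants$transferred <- dropTaxa(tm, setdiff(donors, recipients))
  }
  variants <- variants[intersect(c("control", "full", "masked",
                                   "transferred"), names(variants))]

  analyses <- list()
  for (i in seq_along(variants)) {
    nm <- names(variants)[i]
    mv <- variants[[i]]
    cfg <- config
    cfg$seed <- seed + i
    ts <- heuristicSearch(mv, cfg, outgroup = outgroup)
    cons <- strictConsensus(ts)
    idx <- ensembleIndices(ts, mv)
    placement <- NULL
    if (!is.null(focal) && !is.null(anchors)) {
      foc <- intersect(focal, taxa(mv))
      placement <- if (length(foc) >= 1L)
        classifyPlacement(cons, foc, anchors) else NA_character_
    }
    statuses <- lapply(cladeTests, function(tips) {
      tips <- intersect(tips, taxa(mv))
      if (length(tips) < 2L) return(NA_character_)
      monophylyStatus(cons, tips)
    })
    analyses[[nm]] <- list(trees = ts, bestLength = bestLength(ts),
                           consensus = cons, indices = idx,
                           placement = placement,
                           cladeStatus = statuses)
  }

  cmp <- list()
  nms <- names(analyses)
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    a <- analyses[[i]]$consensus; b <- analyses[[j]]$consensus
    shared <- intersect(a$tip.label, b$tip.label)
    if (length(shared) < 4L) next
    ra <- restrictTree(a, shared); rb <- restrictTree(b, shared)
    cmp[[length(cmp) + 1L]] <- data.frame(
      a = nms[i], b = nms[j], sharedTips = length(shared),
      rf = rfDistance(ra, rb), stringsAsFactors = FALSE)
  }
  comparisons <- if (length(cmp)) do.call(rbind, cmp) else
    data.frame(a = character(0), b = character(0),
               sharedTips = integer(0), rf = integer(0))

  new("ExperimentReport", analyses = analyses, comparisons = comparisons,
      config = list(outgroup = outgroup, partition = partition,
                    maskTaxa = maskTaxa, controlDrop = controlDrop,
                    donors = donors, recipients = recipients,
                    focal = focal, anchors = anchors, seed = seed,
                    search = unclass(config)))
}

# restrict a (possibly polytomous) rooted tree to a tip subset
restrictTree <- function(tree, tips) {
  drop <- setdiff(tree$tip.label, tips)
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}
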