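#' Morphological character matrix with state-set cells
#'
#' An S4 container for a taxa-by-characters grid of discrete unordered
#' character states.  Each cell is a set of integer states (singleton
#' for a normal score, larger for polymorphisms) or missing; internally
#' cells are integer bitmasks with 0 meaning missing, so scoring stays
#' cheap.  Character ids are 1-based throughout the user-facing
#' interface.  Named character partitions (e.g. \code{postcranial},
#' \code{dermal}, \code{cranial}) travel with the matrix.
#'
#' @slot cells integer matrix (taxa x characters) of state bitmasks;
#'   0 encodes a missing cell.  Row names are taxon labels, column
#'   names the 1-based character ids.
#' @slot partitions named list of integer vectors of 1-based character
#'   ids.
#' @seealso [readTNT()], [morphMatrix()], [maskPartition()]
#' @export
setClass("MorphMatrix",
         representation(cells = "matrix", partitions = "list"))

setValidity("MorphMatrix", function(object) {
  cells <- object@cells
  msgs <- character(0)
  if (!is.integer(cells)) msgs <- c(msgs, "cells must be an integer matrix")
  if (is.null(rownames(cells)) || anyDuplicated(rownames(cells)))
    msgs <- c(msgs, "taxon labels must be present and unique")
  if (any(cells < 0L, na.rm = TRUE) || anyNA(cells))
    msgs <- c(msgs, "cells must be non-negative bitmasks (0 = missing)")
  if (!identical(colnames(cells), as.character(seq_len(ncol(cells)))))
    msgs <- c(msgs, "character ids must be consecutive from 1")
  p <- object@partitions
  if (length(p)) {
    if (is.null(names(p)) || any(names(p) == ""))
      msgs <- c(msgs, "partitions must be named")
    bad <- unlist(p)[!unlist(p) %in% seq_len(ncol(cells))]
    if (length(bad))
      msgs <- c(msgs, paste("partition members outside 1..n_chars:",
                            paste(unique(bad), collapse = ", ")))
    canon <- intersect(c("postcranial", "dermal", "cranial"), names(p))
    if (length(canon) > 1L) {
      ids <- unlist(p[canon])
      if (anyDuplicated(ids))
        msgs <- c(msgs, "postcranial/dermal/cranial partitions overlap")
      if (length(canon) == 3L && length(ids) != ncol(cells))
        msgs <- c(msgs,
                  "postcranial+dermal+cranial must cover all characters")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of equally parsimonious trees
#'
#' Holds the deduplicated most-parsimonious trees returned by a search,
#' all of the same Fitch length.  Trees are `ape::phylo` objects rooted
#' on the designated outgroup.
#'
#' @slot trees list of `phylo` objects
#' @slot bestLength numeric(1), the common tree length in steps
#' @slot replicateBest integer vector of per-replicate best lengths
#' @export
setClass("TreeSet",
         representation(trees = "list", bestLength = "numeric",
                        replicateBest = "integer"))

setValidity("TreeSet", function(object) {
  if (!length(object@trees)) return("TreeSet must hold at least one tree")
  if (!all(vapply(object@trees, inherits, logical(1), "phylo")))
    return("all trees must be phylo objects")
  TRUE
})

#' Per-character parsimony scores and ensemble indices
#'
#' @slot totalSteps numeric(1) observed tree length S
#' @slot perChar integer per-character observed steps s_i
#' @slot minSteps integer per-character minimum steps m_i
#' @slot maxSteps integer per-character maximum steps g_i
#' @export
setClass("ParsimonyScores",
         representation(totalSteps = "numeric", perChar = "integer",
                        minSteps = "integer", maxSteps = "integer"))

setValidity("ParsimonyScores", function(object) {
  n <- length(object@perChar)
  if (length(object@minSteps) != n || length(object@maxSteps) != n)
    return("per-character vectors must have equal length")
  if (any(object@minSteps > object@perChar) ||
      any(object@perChar > object@maxSteps))
    return("m_i <= s_i <= g_i violated")
  TRUE
})

#' Report of a masking/transfer partition experiment
#'
#' @slot analyses named list, one entry per analysis (e.g. control,
#'   full, masked, transferred), each holding the search result,
#'   consensus, indices, placement and clade-status table
#' @slot comparisons data.frame of pairwise consensus comparisons
#' @slot config the configuration the experiment was run with
#' @export
setClass("ExperimentReport",
         representation(analyses = "list", comparisons = "data.frame",
                        config = "list"))
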