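# Small report exporters: per-character score tables and
# support-annotated consensus trees.

#' Write per-character parsimony scores as CSV
#'
#' Columns: `charId`, `m` (minimum steps), `s` (observed steps),
#' `g` (maximum steps).
#'
#' @param scores a [ParsimonyScores-class]
#' @param file output path; `NULL` returns the data.frame
#' @return the data.frame, invisibly when written
#' @export
writeScores <- function(scores, file = NULL) {
  stopifnot(is(scores, "ParsimonyScores"))
  df <- data.frame(charId = seq_along(scores@perChar),
                   m = scores@minSteps, s = scores@perChar,
                   g = scores@maxSteps)
  if (is.null(file)) return(df)
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Annotate a consensus tree with support values
#'
#' Attaches `bootstrap/bremer` labels to the internal nodes of a
#' (consensus) tree, keyed by clade, suitable for Newick export with
#' `ape::write.tree`.  Missing values render as `-`; infinite Bremer
#' values (clades surviving the whole retention search) as `>max`.
#'
#' @param tree rooted `phylo` (e.g. from [strictConsensus()])
#' @param bootstrap data.frame from [bootstrapSupport()] (optional)
#' @param bremer data.frame from [bremerSupport()] (optional)
#' @return the tree with `node.label` set
#' @export
annotateSupport <- function(tree, bootstrap = NULL, bremer = NULL) {
  nTip <- length(tree$tip.label)
  sets <- nodeTipSets(tree)
  fmt <- function(tbl, col, key) {
    if (is.null(tbl)) return("-")
    hit <- match(key, tbl$clade)
    if (is.na(hit)) return("-")
    v <- tbl[[col]][hit]
    if (is.infinite(v)) ">max" else format(v)
  }
  labs <- vapply((nTip + 1L):(nTip + tree$Nnode), function(v) {
    key <- paste(sort(tree$tip.label[sets[[v]]]), collapse = ",")
    paste0(fmt(bootstrap, "bootstrap", key), "/",
           fmt(bremer, "bremer", key))
  }, character(1))
  tree$node.label <- labs
  tree
}
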