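# YAML experiment configuration: load, validate (reporting every
# violation, not just the first), and run.  All randomness flows from
# the single top-level seed.

#' Read and validate an experiment configuration
#'
#' The YAML file names the matrix file, outgroup, partition under
#' test, taxon sets (mask set, optional control drops, donors and
#' recipients), optional focal/anchor sets for placement
#' classification, clade tests, and the search budget.  Every
#' validation problem is collected and reported at once.
#'
#' @param path YAML file path
#' @return validated config list (with the matrix loaded into
#'   `$matrix`)
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  need <- c("matrix", "outgroup", "partition", "mask_taxa")
  for (f in need)
    if (is.null(cfg[[f]])) errs <- c(errs, paste0("missing field: ", f))
  if (!is.null(cfg$matrix) && !file.exists(cfg$matrix))
    errs <- c(errs, paste0("matrix file not found: ", cfg$matrix))
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  parts <- if (!is.null(cfg$partitions))
    lapply(cfg$partitions, function(v) as.integer(unlist(v)))
  else defaultPartitions()
  m <- readTNT(cfg$matrix, partitions = list())
  parts <- lapply(parts, function(v) v[v <= nChar(m)])
  partitions(m) <- parts

  errs <- character(0)
  for (tx in c(cfg$outgroup, unlist(cfg$mask_taxa), unlist(cfg$control_drop),
               unlist(cfg$donors), unlist(cfg$recipients),
               unlist(cfg$focal), unlist(cfg$anchors)))
    if (!tx %in% taxa(m))
      errs <- c(errs, paste0("taxon not in matrix: ", tx))
  if (is.character(cfg$partition) && !cfg$partition %in% names(parts))
    errs <- c(errs, paste0("unknown partition: ", cfg$partition))
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(unique(errs), collapse = "\n  "))
  cfg$matrix <- m
  cfg
}

#' Run the experiment described by a configuration file
#'
#' @param config path to a YAML file, or a list from [readRunConfig()]
#' @param outDir optional directory to write Newick consensuses, a CSV
#'   comparison table and a JSON report into
#' @param dryRun validate only; returns `TRUE` without searching
#' @return an [ExperimentReport-class] (or `TRUE` for a dry run)
#' @export
runExperimentFromConfig <- function(config, outDir = NULL, dryRun = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (dryRun) return(TRUE)
  sc <- searchConfig(
    nReplicates = if (is.null(cfg$replicates)) 10L else cfg$replicates,
    hold = if (is.null(cfg$hold)) 10L else cfg$hold,
    swap = if (is.null(cfg$swap)) "tbr" else cfg$swap)
  rep <- runExperiment(
    cfg$matrix, outgroup = cfg$outgroup, partition = cfg$partition,
    maskTaxa = unlist(cfg$mask_taxa), controlDrop = unlist(cfg$control_drop),
    donors = unlist(cfg$donors), recipients = unlist(cfg$recipients),
    focal = unlist(cfg$focal),
    anchors = if (is.null(cfg$anchors)) NULL else
      lapply(cfg$anchors, unlist),
    cladeTests = if (is.null(cfg$clade_tests)) list() else
      lapply(cfg$clade_tests, unlist),
    config = sc,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  if (!is.null(outDir)) writeExperimentReport(rep, outDir)
  rep
}

#' Write an experiment report to disk
#'
#' One Newick consensus per analysis, a CSV of pairwise consensus
#' comparisons, and a JSON summary with lengths, indices, placements
#' and clade statuses.
#'
#' @param report an [ExperimentReport-class]
#' @param outDir output directory (created if needed)
#' @return `outDir`, invisibly
#' @export
writeExperimentReport <- function(report, outDir) {
  stopifnot(is(report, "ExperimentReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  for (nm in names(report@analyses)) {
    a <- report@analyses[[nm]]
    ape::write.tree(a$consensus,
                    file.path(outDir, paste0("consensus_", nm, ".nwk")))
    summary[[nm]] <- list(bestLength = a$bestLength,
                          nTrees = length(mpTrees(a$trees)),
                          CI = a$indices$CI, RI = a$indices$RI,
                          placement = a$placement,
                          cladeStatus = a$cladeStatus)
  }
  write.csv(report@comparisons, file.path(outDir, "comparisons.csv"),
            row.names = FALSE)
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' Write a tree set as Newick, one tree per line
#'
#' @param trees a [TreeSet-class] or list of `phylo`
#' @param file output path
#' @export
writeTrees <- function(trees, file) {
  tr <- if (is(trees, "TreeSet")) mpTrees(trees) else trees
  class(tr) <- "multiPhylo"
  ape::write.tree(tr, file)
  invisible(file)
}
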