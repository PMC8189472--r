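#' @describeIn MorphMatrix-accessors taxon labels
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @describeIn MorphMatrix-accessors number of taxa
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @describeIn MorphMatrix-accessors number of characters
#' @export
setGeneric("nChar", function(x) standardGeneric("nChar"))

#' @describeIn MorphMatrix-accessors named list of character partitions
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @describeIn MorphMatrix-accessors replace the partition list
#' @export
setGeneric("partitions<-", function(x, value) standardGeneric("partitions<-"))

#' Accessors for MorphMatrix objects
#'
#' @param x a [MorphMatrix-class] object
#' @param value replacement partition list
#' @param taxon taxon label
#' @param charId 1-based character id
#' @name MorphMatrix-accessors
#' @aliases taxa nTaxa nChar partitions partitions<-
NULL

#' @rdname MorphMatrix-accessors
#' @export
setMethod("taxa", "MorphMatrix", function(x) rownames(x@cells))

#' @rdname MorphMatrix-accessors
#' @export
setMethod("nTaxa", "MorphMatrix", function(x) nrow(x@cells))

#' @rdname MorphMatrix-accessors
#' @export
setMethod("nChar", "MorphMatrix", function(x) ncol(x@cells))

#' @rdname MorphMatrix-accessors
#' @export
setMethod("partitions", "MorphMatrix", function(x) x@partitions)

#' @rdname MorphMatrix-accessors
#' @export
setMethod("partitions<-", "MorphMatrix", function(x, value) {
  x@partitions <- value
  validObject(x)
  x
})

#' State set of one matrix cell
#'
#' Returns the integer states scored for a taxon at a character, or
#' `NA` when the cell is missing.
#'
#' @inheritParams MorphMatrix-accessors
#' @return integer vector of states, or `NA_integer_` for missing
#' @export
stateSet <- function(x, taxon, charId) {
  stopifnot(is(x, "MorphMatrix"))
  if (!taxon %in% taxa(x)) stop("unknown taxon: ", taxon)
  b <- x@cells[taxon, as.character(charId)]
  if (b == 0L) NA_integer_ else bitsToStates(b)
}

#' Per-character observed state alphabets
#'
#' @param x a [MorphMatrix-class]
#' @return integer vector of alphabet bitmasks, one per character
#' @keywords internal
alphabetBits <- function(x) {
  b <- rep(0L, ncol(x@cells))
  for (i in seq_len(nrow(x@cells))) b <- bitwOr(b, x@cells[i, ])
  b
}

#' @describeIn TreeSet-accessors trees in the set
#' @export
setGeneric("mpTrees", function(x) standardGeneric("mpTrees"))

#' @describeIn TreeSet-accessors common tree length
#' @export
setGeneric("bestLength", function(x) standardGeneric("bestLength"))

#' Accessors for TreeSet objects
#'
#' @param x a [TreeSet-class]
#' @name TreeSet-accessors
#' @aliases mpTrees bestLength
NULL

#' @rdname TreeSet-accessors
#' @export
setMethod("mpTrees", "TreeSet", function(x) x@trees)

#' @rdname TreeSet-accessors
#' @export
setMethod("bestLength", "TreeSet", function(x) x@bestLength)

#' Consistency and retention index accessors
#'
#' `ci()` is the ensemble consistency index sum(m_i)/S; `ri()` the
#' ensemble retention index (sum(g_i) - S)/(sum(g_i) - sum(m_i)).
#' `ri()` is `NA` when sum(g) equals sum(m) (no retainable variation).
#'
#' @param x a [ParsimonyScores-class]
#' @export
ci <- function(x) {
  stopifnot(is(x, "ParsimonyScores"))
  sum(x@minSteps) / x@totalSteps
}

#' @rdname ci
#' @export
ri <- function(x) {
  stopifnot(is(x, "ParsimonyScores"))
  sg <- sum(x@maxSteps); sm <- sum(x@minSteps)
  if (sg == sm) return(NA_real_)
  (sg - x@totalSteps) / (sg - sm)
}

setMethod("show", "MorphMatrix", function(object) {
  cat("MorphMatrix:", nTaxa(object), "taxa x", nChar(object), "characters\n")
  miss <- mean(object@cells == 0L)
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if (length(object@partitions)) {
    sizes <- vapply(object@partitions, length, integer(1))
    cat("  partitions:",
        paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "TreeSet", function(object) {
  cat("TreeSet:", length(object@trees), "tree(s) of length",
      object@bestLength, "\n")
  invisible(object)
})

setMethod("show", "ParsimonyScores", function(object) {
  cat("ParsimonyScores: S =", object@totalSteps,
      sprintf("| CI = %.4f | RI = %s\n", ci(object),
              ifelse(is.na(ri(object)), "NA", sprintf("%.4f", ri(object)))))
  invisible(object)
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport with analyses:",
      paste(names(object@analyses), collapse = ", "), "\n")
  for (nm in names(object@analyses)) {
    a <- object@analyses[[nm]]
    cat(sprintf("  %-12s length %s, %d MPT(s), placement: %s\n", nm,
                format(a$bestLength), length(mpTrees(a$trees)),
                if (is.null(a$placement)) "-" else a$placement))
  }
  if (nrow(object@comparisons)) {
    cat("  consensus comparisons (RF):\n")
    print(object@comparisons, row.names = FALSE)
  }
  invisible(object)
})
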