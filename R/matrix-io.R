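# TNT-dialect (and minimal NEXUS) matrix reading and writing.  The
# reader accepts bare "nchar ntaxa" blocks as well as full xread files
# with trailing commands; '?' and '-' both map to missing, bracketed
# tokens like [01] to polymorphic state sets.

#' Build a MorphMatrix from token strings
#'
#' @param tokens character matrix (taxa x characters) of single-cell
#'   tokens: a digit, `"?"` or `"-"` for missing, or a bracketed
#'   polymorphism such as `"[01]"`.  Row names are taxon labels.
#' @param partitions optional named list of 1-based character id
#'   vectors.
#' @return a [MorphMatrix-class]
#' @export
#' @examples
#' m <- morphMatrix(matrix(c("0", "1", "0", "?"), 2, 2,
#'                         dimnames = list(c("A", "B"), NULL)))
#' nChar(m)
morphMatrix <- function(tokens, partitions = list()) {
  stopifnot(is.matrix(tokens), is.character(tokens))
  cells <- matrix(0L, nrow(tokens), ncol(tokens),
                  dimnames = list(rownames(tokens),
                                  as.character(seq_len(ncol(tokens)))))
  for (i in seq_len(nrow(tokens))) {
    cells[i, ] <- vapply(tokens[i, ], parseToken, integer(1),
                         USE.NAMES = FALSE)
  }
  new("MorphMatrix", cells = cells, partitions = partitions)
}

parseToken <- function(tok) {
  if (tok %in% c("?", "-")) return(0L)
  if (grepl("^[0-9]$", tok)) return(statesToBits(as.integer(tok)))
  if (grepl("^\\[[0-9]+\\]$", tok)) {
    digits <- as.integer(strsplit(gsub("\\[|\\]", "", tok), "")[[1L]])
    return(statesToBits(digits))
  }
  stop("unknown state token: '", tok, "'")
}

# split a row's state string into per-character tokens
tokenizeStates <- function(s) {
  s <- gsub("\\s", "", s)
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[" || ch == "(") {
      close <- if (ch == "[") "]" else ")"
      j <- i + 1L
      while (j <= n && substr(s, j, j) != close) j <- j + 1L
      if (j > n) stop("unterminated polymorphism token in '", s, "'")
      out <- c(out, paste0("[", substr(s, i + 1L, j - 1L), "]"))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Read a TNT-dialect character matrix
#'
#' Parses an `xread`-style block: an optional `xread` keyword and
#' quoted title, a dimensions line (`nchar ntaxa`), then one row per
#' taxon.  `?` and `-` are both read as missing; `[01]`-style tokens
#' become polymorphic state sets.  Trailing commands are tolerated and
#' ignored with a warning, except `ccode` lines declaring ordered
#' (additive) or differentially weighted characters, which are an
#' error: the engine supports unordered, equally weighted characters
#' only.  Taxon-label whitespace is normalised to underscores.
#'
#' @param file path to a matrix file, or `NULL` when `text` is given
#' @param text the file content as a single string (alternative input)
#' @param partitions optional partition list attached to the result,
#'   e.g. [defaultPartitions()]
#' @return a [MorphMatrix-class]
#' @export
readTNT <- function(file = NULL, text = NULL, partitions = list()) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "\n")
  # drop the leading xread (and optional quoted title)
  m <- regexpr("(?i)xread", text, perl = TRUE)
  if (m > 0) {
    text <- substr(text, m + attr(m, "match.length"), nchar(text))
    tm <- regexpr("^\\s*'[^']*'", text, perl = TRUE)
    if (tm > 0) text <- substr(text, tm + attr(tm, "match.length"),
                               nchar(text))
  }
  semi <- regexpr(";", text, fixed = TRUE)
  trailing <- ""
  if (semi > 0) {
    trailing <- substr(text, semi + 1L, nchar(text))
    text <- substr(text, 1L, semi - 1L)
  }
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  if (length(toks) < 2L || anyNA(suppressWarnings(as.integer(toks[1:2]))))
    stop("expected a dimensions line 'nchar ntaxa' at the top of the block")
  nc <- as.integer(toks[1L]); nt <- as.integer(toks[2L])

  lines <- strsplit(text, "\n")[[1L]]
  # locate the line holding the dimensions, rows start after it
  dimLine <- which(grepl("^\\s*\\d+\\s+\\d+\\s*$", lines))[1L]
  if (is.na(dimLine)) {
    # dimensions may share a line with the first row; re-split by tokens
    stop("could not locate the dimensions line")
  }
  rows <- lines[-seq_len(dimLine)]
  rows <- rows[!grepl("^\\s*$", rows)]

  labels <- character(0)
  tokens <- list()
  cur <- NULL
  isStateTok <- function(x) grepl("^[0-9?\\-]+$|^\\[[0-9]+\\]$|^\\([0-9]+\\)$",
                                  gsub("\\[[0-9]+\\]|\\([0-9]+\\)", "0", x))
  for (ln in rows) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 2L)
      stop("cannot parse matrix row: '", ln, "'")
    # state tokens run from the end of the line; everything before is
    # the (possibly multi-word) taxon label, normalised to underscores
    nState <- 0L
    while (nState < length(toks) - 1L &&
           isStateTok(toks[length(toks) - nState])) nState <- nState + 1L
    if (nState == 0L) {
      # no clean trailing state run: take the first token as the label
      # so malformed state strings surface as token errors, not label
      # confusion
      nm <- toks[1L]
      st <- tokenizeStates(paste(toks[-1L], collapse = ""))
    } else {
      nm <- paste(toks[seq_len(length(toks) - nState)], collapse = "_")
      st <- tokenizeStates(paste(toks[seq(length(toks) - nState + 1L,
                                          length.out = nState)],
                                 collapse = ""))
    }
    if (!is.null(cur) && nm == cur) {            # continuation block
      tokens[[cur]] <- c(tokens[[cur]], st)
    } else if (nm %in% labels) {                 # interleaved repeat
      tokens[[nm]] <- c(tokens[[nm]], st)
      cur <- nm
    } else {
      labels <- c(labels, nm)
      tokens[[nm]] <- st
      cur <- nm
    }
  }
  if (length(labels) != nt)
    stop("header declares ", nt, " taxa but ", length(labels),
         " rows were found")
  bad <- labels[vapply(tokens[labels], length, integer(1)) != nc]
  if (length(bad))
    stop("character count mismatch (expected ", nc, ") for taxon: ",
         paste(bad, collapse = ", "))
  tokmat <- do.call(rbind, tokens[labels])
  rownames(tokmat) <- labels

  checkTrailingCommands(trailing)

  mm <- tryCatch(morphMatrix(tokmat, partitions),
                 error = function(e) stop(conditionMessage(e), call. = FALSE))
  mm
}

checkTrailingCommands <- function(trailing) {
  if (!nzchar(trimws(trailing))) return(invisible())
  cmds <- strsplit(trailing, ";")[[1L]]
  for (cmd in cmds) {
    cmd <- trimws(cmd)
    if (!nzchar(cmd)) next
    word <- tolower(strsplit(cmd, "\\s+")[[1L]][1L])
    if (word == "ccode") {
      if (grepl("\\+", cmd))
        stop("unsupported setting: ccode declares ordered (additive) ",
             "characters; only unordered characters are supported")
      if (grepl("/\\s*([02-9]|1[0-9])", cmd))
        stop("unsupported setting: ccode declares differential character ",
             "weights; only equal weights are supported")
      next
    }
    if (word %in% c("proc", "procedure", "cnames", "comments", "nstates",
                    "taxname", "mxram", "xread")) next
    warning("ignoring unrecognised trailing command: '",
            substr(cmd, 1L, 30L), "'")
  }
  invisible()
}

#' Write a MorphMatrix as a TNT xread block
#'
#' @param x a [MorphMatrix-class]
#' @param file optional path; when `NULL` the text is returned
#' @param title quoted title placed after `xread`
#' @return the text, invisibly when written to a file
#' @export
writeTNT <- function(x, file = NULL, title = "exported matrix") {
  stopifnot(is(x, "MorphMatrix"))
  rows <- vapply(seq_len(nTaxa(x)), function(i) {
    paste0(format(taxa(x)[i], width = max(nchar(taxa(x))) + 2L), " ",
           paste(vapply(x@cells[i, ], bitsToToken, character(1)),
                 collapse = ""))
  }, character(1))
  txt <- paste0("xread\n'", title, "'\n", nChar(x), " ", nTaxa(x), "\n",
                paste(rows, collapse = "\n"), "\n;\nproc /;\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a minimal NEXUS CHARACTERS/DATA block
#'
#' Supports `DIMENSIONS NTAX NCHAR`, `FORMAT` with `MISSING=?` and
#' `GAP=-`, and a non-interleaved `MATRIX` of token rows.  Anything
#' beyond this subset (assumptions blocks, step matrices) is rejected.
#'
#' @inheritParams readTNT
#' @return a [MorphMatrix-class]
#' @export
readNexusMatrix <- function(file = NULL, text = NULL, partitions = list()) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "\n")
  if (!grepl("(?i)#nexus", text, perl = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  text <- gsub("\\[[^]]*\\]", " ", text)   # strip NEXUS comments
  nt <- as.integer(sub("(?si).*ntax\\s*=\\s*(\\d+).*", "\\1", text,
                       perl = TRUE))
  nc <- as.integer(sub("(?si).*nchar\\s*=\\s*(\\d+).*", "\\1", text,
                       perl = TRUE))
  if (is.na(nt) || is.na(nc)) stop("DIMENSIONS NTAX/NCHAR not found")
  mm <- regmatches(text, regexec("(?is)matrix(.*?);", text, perl = TRUE))[[1L]]
  if (length(mm) < 2L) stop("MATRIX block not found")
  body <- paste0(nc, " ", nt, "\n", mm[2L])
  readTNT(text = body, partitions = partitions)
}

#' Default character partitions of the allodaposuchid matrix layout
#'
#' Postcranial characters 1-37 and 189, dermal-shield characters 38-46,
#' 183 and 184, and the remaining 140 cranial characters, matching the
#' composition of the 189-character eusuchian matrix the experiment
#' layer was designed around.
#'
#' @param nChars total character count (189 for the canonical layout)
#' @return named list of integer vectors
#' @export
defaultPartitions <- function(nChars = 189L) {
  post <- c(1:37, 189L)
  derm <- c(38:46, 183L, 184L)
  post <- post[post <= nChars]
  derm <- derm[derm <= nChars]
  list(postcranial = post, dermal = derm,
       cranial = setdiff(seq_len(nChars), c(post, derm)))
}

#' Cell-wise difference between two matrices
#'
#' @param a,b [MorphMatrix-class] objects over the same taxa (by label)
#'   and the same character count
#' @return data.frame with columns `taxon`, `charId`, `stateA`,
#'   `stateB` (token rendering); zero rows iff the matrices are equal
#' @export
diffMatrices <- function(a, b) {
  stopifnot(is(a, "MorphMatrix"), is(b, "MorphMatrix"))
  if (!setequal(taxa(a), taxa(b))) {
    onlyA <- setdiff(taxa(a), taxa(b)); onlyB <- setdiff(taxa(b), taxa(a))
    stop("taxon sets differ; only in a: ",
         paste(onlyA, collapse = ", "), "; only in b: ",
         paste(onlyB, collapse = ", "))
  }
  if (nChar(a) != nChar(b)) stop("character counts differ")
  bb <- b@cells[taxa(a), , drop = FALSE]
  idx <- which(a@cells != bb, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(taxon = character(0), charId = integer(0),
                      stateA = character(0), stateB = character(0)))
  data.frame(
    taxon = taxa(a)[idx[, 1L]],
    charId = idx[, 2L],
    stateA = vapply(a@cells[idx], bitsToToken, character(1)),
    stateB = vapply(bb[idx], bitsToToken, character(1)),
    stringsAsFactors = FALSE)
}
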