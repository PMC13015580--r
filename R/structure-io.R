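# Parsing and annotation of dot-bracket secondary structures. All coordinates
# are 1-based; an unpaired position has partner NA in the pair table.

#' Construct a Duplex
#'
#' Builds a validated [Duplex-class] from a sequence and its dot-bracket
#' structure. DNA input is tolerated: \code{T} is silently mapped to \code{U};
#' any other character outside \code{A,C,G,U,N} is mapped to \code{N} with a
#' warning. Case is ignored.
#'
#' @param id Identifier string.
#' @param sequence Nucleotide sequence.
#' @param dotBracket Structure string over \code{(, ), .} of the same length.
#' @return A \code{Duplex}.
#' @examples
#' duplex("d1", "GCAAGC", "((..))")
#' @export
duplex <- function(id, sequence, dotBracket) {
  sequence <- toupper(sequence)
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(bases %in% RNA_ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " character(s) outside {A,C,G,U,N} in '", id,
            "' mapped to N")
    bases[bad] <- "N"
    sequence <- paste(bases, collapse = "")
  }
  new("Duplex", id = as.character(id), sequence = sequence,
      dotBracket = dotBracket)
}

#' Parse dot-bracket notation into a pair table
#'
#' Converts a nested Vienna dot-bracket string into a pair table: an integer
#' vector \code{pt} with \code{pt[i]} the 1-based partner of position
#' \code{i}, or \code{NA} when unpaired. The table is an involution
#' (\code{pt[pt[i]] == i}) and free of crossing pairs by construction.
#'
#' @param db Dot-bracket string over \code{(, ), .}. Pseudoknot dialects
#'   (\code{[]}, \code{{}}, letters) are rejected with an error rather than
#'   silently dropped.
#' @return Integer vector of partners with \code{NA} for unpaired positions.
#' @examples
#' parseDotBracket("((..))")  # 6 5 NA NA 2 1
#' @export
parseDotBracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (any(ch %in% c("[", "]", "{", "}", "<", ">") | grepl("[A-Za-z]", ch))) {
    stop("unsupported dot-bracket dialect (pseudoknot brackets?): only '(', ')', '.' are accepted")
  }
  if (!all(ch %in% c("(", ")", "."))) {
    stop("dot-bracket contains unsupported characters")
  }
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      top <- top + 1L
      stack[top] <- i
    } else if (ch[i] == ")") {
      if (top == 0L) stop("unbalanced dot-bracket string: unmatched ')' at position ", i)
      j <- stack[top]
      top <- top - 1L
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (top > 0L) stop("unbalanced dot-bracket string: ", top, " unmatched '('")
  pt
}

#' Render a pair table back to dot-bracket
#'
#' Inverse of [parseDotBracket()] for nested tables.
#'
#' @param pt Integer pair table (NA = unpaired).
#' @return Dot-bracket string.
#' @export
pairTableToDotBracket <- function(pt) {
  ch <- rep(".", length(pt))
  paired <- which(!is.na(pt))
  ch[paired[pt[paired] > paired]] <- "("
  ch[paired[pt[paired] < paired]] <- ")"
  paste(ch, collapse = "")
}

#' Base-pair validity (Watson-Crick and wobble)
#'
#' \code{TRUE} exactly for the canonical Watson-Crick pairs A:U and G:C and
#' the wobble pair G:U, in either orientation. Any pairing involving \code{N}
#' is invalid.
#'
#' @param b1,b2 Single bases in \code{A,C,G,U,N} (vectorized).
#' @return Logical vector.
#' @examples
#' isValidPair("A", "U")  # TRUE
#' isValidPair("A", "C")  # FALSE (the A:C mismatch ADAR favours is not a pair)
#' @export
isValidPair <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  key %in% c("AU", "CG", "GU")
}

#' Pairing-energy estimate for a base pair
#'
#' A fixed lookup mimicking nearest-neighbor stability ordering
#' (G:C stronger than A:U stronger than G:U): G:C = -3, A:U = -2, G:U = -1,
#' anything else 0, in arbitrary units. Downstream features consume
#' \code{energy / 3} so scaled values lie in \code{[-1, 0]}.
#'
#' @inheritParams isValidPair
#' @return Numeric vector of energies (<= 0).
#' @export
pairEnergy <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  e <- c(AU = -2, CG = -3, GU = -1)[key]
  e[is.na(e)] <- 0
  unname(e)
}

#' Annotate stem-loop geometry and pairing energies
#'
#' Computes the four per-position tracks of [StructureAnnotation-class] for a
#' duplex. A helix is a maximal run of stacked pairs
#' \code{(i, j), (i+1, j-1), ...}; bulges break helices. A loop is a maximal
#' contiguous unpaired run on the strand. The junction distance of position
#' \code{i} is the smallest \code{k >= 1} such that position \code{i - k} or
#' \code{i + k} has the opposite pairing status; when the structure is uniform
#' it is the duplex length \code{L}.
#'
#' @param dup A [Duplex-class].
#' @param pt Pair table from [parseDotBracket()] on \code{dup}'s structure.
#' @return A \code{StructureAnnotation}.
#' @examples
#' d <- duplex("d", "GCAAGC", "((..))")
#' annotateStructure(d, parseDotBracket(d@dotBracket))
#' @export
annotateStructure <- function(dup, pt) {
  stopifnot(is(dup, "Duplex"))
  L <- length(dup)
  if (length(pt) != L) stop("pair table length does not match the duplex")
  bases <- strsplit(dup@sequence, "", fixed = TRUE)[[1L]]
  paired <- !is.na(pt)

  # helix id: pair (i, j) with i < j extends the helix of (i-1, j+1)
  stem <- integer(L)
  if (any(paired)) {
    opens <- which(paired & pt > seq_len(L))
    helixId <- integer(L)
    hid <- 0L
    for (i in opens) {
      j <- pt[i]
      if (i > 1L && !is.na(pt[i - 1L]) && pt[i - 1L] == j + 1L) {
        helixId[i] <- helixId[i - 1L]
      } else {
        hid <- hid + 1L
        helixId[i] <- hid
      }
      helixId[j] <- helixId[i]
    }
    sizes <- tabulate(helixId[opens], nbins = max(1L, hid))
    stem[paired] <- sizes[helixId[paired]]
  }

  # unpaired runs
  loop <- integer(L)
  r <- rle(paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) loop[starts[k]:ends[k]] <- r$lengths[k]
  }

  # distance to nearest pairing-status flip
  dj <- rep(L, L)
  if (length(unique(paired)) > 1L) {
    flipLeft <- rep(NA_integer_, L)   # nearest flip at or before i (boundary index)
    last <- NA_integer_
    for (i in seq_len(L)) {
      if (i > 1L && paired[i] != paired[i - 1L]) last <- i
      flipLeft[i] <- last
    }
    flipRight <- rep(NA_integer_, L)
    nxt <- NA_integer_
    for (i in L:1L) {
      if (i < L && paired[i] != paired[i + 1L]) nxt <- i
      flipRight[i] <- nxt
    }
    dl <- ifelse(is.na(flipLeft), L, seq_len(L) - flipLeft + 1L)
    dr <- ifelse(is.na(flipRight), L, flipRight - seq_len(L) + 1L)
    dj <- pmin(dl, dr)
  }

  en <- numeric(L)
  en[paired] <- pairEnergy(bases[paired], bases[pt[paired]])

  new("StructureAnnotation",
      stemLength = as.integer(stem), loopLength = as.integer(loop),
      distToJunction = as.integer(dj), pairEnergy = en)
}

#' Read and write Vienna dot-bracket files
#'
#' One record per duplex: a \code{>id} header line, the sequence line, and the
#' structure line. A trailing free-energy suffix in parentheses on the
#' structure line (as printed by MFE folding tools) is tolerated and stripped.
#' \code{readFastaFile} reads plain sequence FASTA via Biostrings.
#'
#' @param path File path.
#' @return \code{readDotBracketFile}: named list of [Duplex-class] objects.
#' @export
readDotBracketFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' records in ", path)
  out <- vector("list", length(heads))
  ids <- character(length(heads))
  for (k in seq_along(heads)) {
    i <- heads[k]
    if (i + 2L > length(lines)) stop("truncated record at ", lines[i])
    id <- sub("^>\\s*", "", lines[i])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    seqline <- trimws(lines[i + 1L])
    structline <- trimws(lines[i + 2L])
    # strip energy suffix like "(((...))) (-12.30)"
    structline <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", structline)
    out[[k]] <- duplex(id, seqline, structline)
    ids[k] <- id
  }
  names(out) <- ids
  out
}

#' @rdname readDotBracketFile
#' @param duplexes List of [Duplex-class] objects.
#' @export
writeDotBracketFile <- function(duplexes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in duplexes) {
    writeLines(c(paste0(">", d@id), d@sequence, d@dotBracket), con)
  }
  invisible(path)
}

#' @rdname readDotBracketFile
#' @export
readFastaFile <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA files")
  }
  xs <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
}

#' Fold sequences with an external MFE tool (optional hook)
#'
#' Convenience wrapper for users without precomputed structures: pipes
#' sequences through an external minimum-free-energy folding executable
#' (\code{RNAfold}-compatible interface) and returns duplexes. Never required
#' by the package itself, which consumes dot-bracket input.
#'
#' @param sequences Named character vector of RNA sequences.
#' @param folder Name/path of the folding executable.
#' @return Named list of [Duplex-class] objects.
#' @export
foldWithExternalTool <- function(sequences, folder = "RNAfold") {
  if (Sys.which(folder) == "") stop("external folding tool '", folder, "' not found on PATH")
  input <- paste0(">", names(sequences), "\n", unname(sequences), collapse = "\n")
  out <- system2(folder, args = "--noPS", input = input, stdout = TRUE)
  tf <- tempfile(); writeLines(out, tf); on.exit(unlink(tf))
  readDotBracketFile(tf)
}
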