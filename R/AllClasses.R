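#' @import methods
NULL

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Duplex: one dsRNA substrate
#'
#' A \code{Duplex} holds one double-stranded RNA substrate: an identifier, the
#' nucleotide sequence over \code{A,C,G,U,N} (DNA \code{T} is mapped to
#' \code{U} on ingest) and its secondary structure in Vienna dot-bracket
#' notation. Sequence and structure must have equal length and the brackets
#' must be balanced; pseudoknot dialects (square/curly brackets) are rejected.
#'
#' @slot id character(1) identifier.
#' @slot sequence character(1) RNA sequence.
#' @slot dotBracket character(1) structure string over \code{(, ), .}.
#'
#' @seealso [duplex()], [parseDotBracket()], [annotateStructure()]
#' @export
setClass("Duplex", representation(
  id = "character",
  sequence = "character",
  dotBracket = "character"
))

setValidity("Duplex", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id)) {
    msg <- c(msg, "'id' must be a single non-empty string")
  }
  if (length(object@sequence) != 1L || length(object@dotBracket) != 1L) {
    msg <- c(msg, "'sequence' and 'dotBracket' must be single strings")
  } else {
    if (nchar(object@sequence) != nchar(object@dotBracket)) {
      msg <- c(msg, "sequence and dot-bracket lengths differ")
    }
    if (nchar(object@sequence) < 1L) msg <- c(msg, "empty duplex")
    bases <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
    if (!all(bases %in% RNA_ALPHABET)) {
      msg <- c(msg, "sequence contains characters outside {A,C,G,U,N}")
    }
    db <- strsplit(object@dotBracket, "", fixed = TRUE)[[1L]]
    if (!all(db %in% c("(", ")", "."))) {
      msg <- c(msg, "dot-bracket contains unsupported characters")
    } else {
      depth <- cumsum(ifelse(db == "(", 1L, ifelse(db == ")", -1L, 0L)))
      if (any(depth < 0L) || depth[length(depth)] != 0L) {
        msg <- c(msg, "unbalanced dot-bracket string")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Duplex Length of the duplex in nucleotides.
#' @param x A \code{Duplex}.
#' @export
setMethod("length", "Duplex", function(x) nchar(x@sequence))

setMethod("show", "Duplex", function(object) {
  n <- nchar(object@sequence)
  pt <- parseDotBracket(object@dotBracket)
  cat("Duplex '", object@id, "': ", n, " nt, ",
      sum(!is.na(pt)) %/% 2L, " base pairs\n", sep = "")
  if (n <= 70L) {
    cat("  ", object@sequence, "\n  ", object@dotBracket, "\n", sep = "")
  } else {
    cat("  ", substr(object@sequence, 1L, 60L), "...\n  ",
        substr(object@dotBracket, 1L, 60L), "...\n", sep = "")
  }
})

#' Per-position structural annotation of a duplex
#'
#' Four per-position tracks derived from a pair table: the number of pairs in
#' the maximal helix containing the position (\code{stemLength}, 0 when
#' unpaired), the length of the maximal contiguous unpaired run containing the
#' position (\code{loopLength}, 0 when paired), the distance in nucleotides to
#' the nearest position with the opposite pairing status
#' (\code{distToJunction}, equal to the duplex length when the structure is
#' uniform), and a nearest-neighbor-style pairing energy estimate
#' (\code{pairEnergy}, negative for paired positions, 0 otherwise).
#'
#' @slot stemLength integer vector.
#' @slot loopLength integer vector.
#' @slot distToJunction integer vector.
#' @slot pairEnergy numeric vector.
#' @seealso [annotateStructure()]
#' @export
setClass("StructureAnnotation", representation(
  stemLength = "integer",
  loopLength = "integer",
  distToJunction = "integer",
  pairEnergy = "numeric"
))

setValidity("StructureAnnotation", function(object) {
  n <- length(object@stemLength)
  if (length(object@loopLength) != n || length(object@distToJunction) != n ||
      length(object@pairEnergy) != n) {
    return("annotation tracks have unequal lengths")
  }
  if (any(object@stemLength < 0L) || any(object@loopLength < 0L)) {
    return("negative stem/loop length")
  }
  if (any((object@stemLength > 0L) == (object@loopLength > 0L))) {
    return("each position must be exactly one of paired (stem) or unpaired (loop)")
  }
  if (any(object@pairEnergy > 0)) return("pair energies must be <= 0")
  TRUE
})

setMethod("show", "StructureAnnotation", function(object) {
  cat("StructureAnnotation over", length(object@stemLength), "positions;",
      sum(object@stemLength > 0L), "paired,",
      sum(object@loopLength > 0L), "unpaired\n")
})

#' Position-centric graph for one candidate adenosine
#'
#' One \code{SiteGraph} encodes a whole duplex as a nucleotide graph whose
#' features are centred on a single candidate adenosine (the target). Nodes
#' are nucleotides; directed edges encode backbone adjacency and base pairs
#' (both directions stored). The feature layout is frozen; see
#' [buildBaselineGraph()] and [buildBioawareGraph()] for the column order.
#'
#' @slot duplexId character(1) parent duplex.
#' @slot nodeFeatures numeric matrix, L x 8 (baseline) or L x 22 (bio-aware).
#' @slot edgeSrc,edgeDst integer vectors of directed edge endpoints (1-based).
#' @slot edgeType character vector: \code{"BACKBONE"}, \code{"WC_PAIR"},
#'   \code{"WOBBLE_PAIR"} (bio-aware) or \code{"PAIR"} (baseline, untyped).
#' @slot edgeScalars numeric matrix, E x 10 (see [buildBioawareGraph()]);
#'   zero-column matrix for baseline graphs.
#' @slot targetIndex integer(1), 1-based position of the candidate adenosine.
#' @slot label character(1): \code{"edited"}, \code{"non_edited"} or
#'   \code{NA_character_}.
#' @slot sequence character(1), retained for the CNN sequence branch.
#' @slot featureSet character(1): \code{"baseline"} or \code{"bioaware"}.
#' @export
setClass("SiteGraph", representation(
  duplexId = "character",
  nodeFeatures = "matrix",
  edgeSrc = "integer",
  edgeDst = "integer",
  edgeType = "character",
  edgeScalars = "matrix",
  targetIndex = "integer",
  label = "character",
  sequence = "character",
  featureSet = "character"
))

setValidity("SiteGraph", function(object) {
  msg <- character()
  L <- nrow(object@nodeFeatures)
  E <- length(object@edgeSrc)
  if (length(object@edgeDst) != E || length(object@edgeType) != E) {
    msg <- c(msg, "edge vectors have unequal lengths")
  }
  if (!object@featureSet %in% c("baseline", "bioaware")) {
    msg <- c(msg, "featureSet must be 'baseline' or 'bioaware'")
  }
  d <- ncol(object@nodeFeatures)
  if (object@featureSet == "baseline" && d != 8L) {
    msg <- c(msg, "baseline graphs need 8 node-feature columns")
  }
  if (object@featureSet == "bioaware" && d != 22L) {
    msg <- c(msg, "bio-aware graphs need 22 node-feature columns")
  }
  if (object@targetIndex < 1L || object@targetIndex > L) {
    msg <- c(msg, "target index out of range")
  }
  if (E > 0L && (any(object@edgeSrc < 1L) || any(object@edgeSrc > L) ||
                 any(object@edgeDst < 1L) || any(object@edgeDst > L))) {
    msg <- c(msg, "edge endpoint out of range")
  }
  if (!is.na(object@label) && !object@label %in% c("edited", "non_edited")) {
    msg <- c(msg, "label must be 'edited', 'non_edited' or NA")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteGraph", function(object) {
  cat("SiteGraph (", object@featureSet, ") on duplex '", object@duplexId,
      "': ", nrow(object@nodeFeatures), " nodes, ",
      length(object@edgeSrc), " directed edges, target at position ",
      object@targetIndex, if (!is.na(object@label)) paste0(" [", object@label, "]"),
      "\n", sep = "")
})

#' Accessors for SiteGraph
#'
#' @param x A \code{SiteGraph}.
#' @return \code{targetIndex} returns the 1-based candidate position,
#'   \code{siteLabel} the class label (or NA), \code{nodeFeatures} the node
#'   feature matrix, \code{edgeTable} a data.frame of directed edges with
#'   their scalar attributes.
#' @export
targetIndex <- function(x) x@targetIndex

#' @rdname targetIndex
#' @export
siteLabel <- function(x) x@label

#' @rdname targetIndex
#' @export
nodeFeatures <- function(x) x@nodeFeatures

#' @rdname targetIndex
#' @export
edgeTable <- function(x) {
  df <- data.frame(src = x@edgeSrc, dst = x@edgeDst, type = x@edgeType,
                   stringsAsFactors = FALSE)
  if (ncol(x@edgeScalars) > 0L) df <- cbind(df, as.data.frame(x@edgeScalars))
  df
}

#' Result of the F1-optimized threshold/checkpoint search
#'
#' @slot table data.frame with columns epoch, threshold, accuracy, f1,
#'   precision, recall, specificity (one row per epoch x threshold).
#' @slot bestEpoch,bestThreshold,bestF1 the selected operating point
#'   (ties broken by earliest epoch, then lowest threshold).
#' @seealso [selectCheckpoint()], [thresholdGrid()]
#' @export
setClass("ThresholdSearchResult", representation(
  table = "data.frame",
  bestEpoch = "integer",
  bestThreshold = "numeric",
  bestF1 = "numeric"
))

setValidity("ThresholdSearchResult", function(object) {
  need <- c("epoch", "threshold", "accuracy", "f1", "precision", "recall",
            "specificity")
  if (!all(need %in% names(object@table))) {
    return("table missing required metric columns")
  }
  if (nrow(object@table) > 0L &&
      object@bestF1 < max(object@table$f1) - 1e-12) {
    return("bestF1 is not the maximum of the table")
  }
  TRUE
})

setMethod("show", "ThresholdSearchResult", function(object) {
  cat("ThresholdSearchResult:", nrow(object@table), "epoch x threshold rows\n")
  cat(sprintf("  best: epoch %d, threshold %.3f, F1 = %.4f\n",
              object@bestEpoch, object@bestThreshold, object@bestF1))
  cat("  (validation-tuned operating point; treat metrics as validation",
      "estimates, not unbiased test performance)\n")
})

#' Position x base preference matrix from perturbation analyses
#'
#' Mean change in model prediction when a base (or base-pair combination) is
#' substituted at each offset around the target adenosine. When
#' \code{centered}, each offset row has been mean-centred so values express
#' relative preferences.
#'
#' @slot values numeric matrix, offsets x bases.
#' @slot offsets integer vector of offsets relative to the target.
#' @slot bases character vector of substituted bases (columns).
#' @slot centered logical(1).
#' @slot nSites integer(1), number of sites aggregated.
#' @seealso [sequenceMutagenesis()], [structureCoupledMutagenesis()],
#'   [pairInteractionScan()], [centerByPosition()]
#' @export
setClass("PreferenceMatrix", representation(
  values = "matrix",
  offsets = "integer",
  bases = "character",
  centered = "logical",
  nSites = "integer"
))

setValidity("PreferenceMatrix", function(object) {
  if (nrow(object@values) != length(object@offsets) ||
      ncol(object@values) != length(object@bases)) {
    return("values dimensions do not match offsets/bases")
  }
  if (isTRUE(object@centered)) {
    rm_ <- rowMeans(object@values)
    if (any(abs(rm_) > 1e-9)) return("centered matrix has non-zero row means")
  }
  TRUE
})

setMethod("show", "PreferenceMatrix", function(object) {
  cat("PreferenceMatrix: ", length(object@offsets), " offsets x ",
      length(object@bases), " bases over ", object@nSites, " sites",
      if (object@centered) " (position-centered)", "\n", sep = "")
  m <- object@values
  dimnames(m) <- list(object@offsets, object@bases)
  print(round(m, 4))
})

#' @rdname PreferenceMatrix-class
#' @param x A \code{PreferenceMatrix}.
#' @export
preferenceValues <- function(x) {
  m <- x@values
  dimnames(m) <- list(x@offsets, x@bases)
  m
}
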