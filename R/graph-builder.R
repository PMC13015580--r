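# Position-centric graph construction. Feature column layouts are frozen:
#
# baseline node features (8):
#   1-5  one-hot base (A, C, G, U, N)
#   6    pairing-status flag
#   7    signed relative distance to target, (i - target) / L
#   8    target-site indicator
#
# bio-aware node features (22): baseline 8, then
#   9-13  one-hot 5' neighbor (boundary -> N)
#   14-18 one-hot 3' neighbor (boundary -> N)
#   19    stem length   (clipped at 50, scaled to [0, 1])
#   20    loop length   (clipped at 50, scaled to [0, 1])
#   21    distance to junction (clipped at 50, scaled to [0, 1])
#   22    pair energy / 3      (in [-1, 0])
#
# edge scalars (10, bio-aware):
#   1 is_pair flag, 2 |src-dst|/L, 3 stem(src), 4 stem(dst), 5 loop(src),
#   6 loop(dst), 7 distToJunction (min over endpoints), 8 pair energy / 3,
#   9 relDist(src), 10 relDist(dst)   [lengths clipped at 50, scaled]

LENGTH_CLIP <- 50

.clipScale <- function(x) pmin(x, LENGTH_CLIP) / LENGTH_CLIP

.baseOneHot <- function(bases) {
  m <- matrix(0, length(bases), 5L)
  m[cbind(seq_along(bases), match(bases, RNA_ALPHABET))] <- 1
  m
}

.duplexEdges <- function(pt) {
  L <- length(pt)
  bbSrc <- c(seq_len(L - 1L), 2L:L)
  bbDst <- c(2L:L, seq_len(L - 1L))
  opens <- which(!is.na(pt) & pt > seq_len(L))
  prSrc <- c(opens, pt[opens])
  prDst <- c(pt[opens], opens)
  list(src = c(bbSrc, prSrc), dst = c(bbDst, prDst),
       isPair = c(rep(FALSE, length(bbSrc)), rep(TRUE, length(prSrc))))
}

.checkTarget <- function(dup, target) {
  L <- length(dup)
  if (target < 1L || target > L) stop("target position ", target, " out of range 1..", L)
  b <- substr(dup@sequence, target, target)
  if (b != "A") stop("target position ", target, " is '", b, "', not an adenosine")
}

#' Build the baseline 8-dimensional site graph
#'
#' Encodes a duplex as a directed graph centred on one candidate adenosine.
#' Nodes carry the knowledge-poor baseline features (one-hot base, pairing
#' flag, signed relative distance to the target, target indicator); edges are
#' backbone adjacencies plus base pairs, untyped (\code{"PAIR"}) and without
#' scalar attributes.
#'
#' @param dup A [Duplex-class].
#' @param pt Pair table from [parseDotBracket()].
#' @param target 1-based position of the candidate adenosine.
#' @param label Optional class label (\code{"edited"} / \code{"non_edited"}).
#' @return A [SiteGraph-class].
#' @examples
#' d <- duplex("d", "GCAAGC", "((..))")
#' g <- buildBaselineGraph(d, parseDotBracket(d@dotBracket), target = 4)
#' @export
buildBaselineGraph <- function(dup, pt, target, label = NA_character_) {
  stopifnot(is(dup, "Duplex"))
  L <- length(dup)
  if (length(pt) != L) stop("pair table length does not match the duplex")
  target <- as.integer(target)
  .checkTarget(dup, target)
  bases <- strsplit(dup@sequence, "", fixed = TRUE)[[1L]]
  X <- cbind(.baseOneHot(bases),
             as.numeric(!is.na(pt)),
             (seq_len(L) - target) / L,
             as.numeric(seq_len(L) == target))
  e <- .duplexEdges(pt)
  new("SiteGraph", duplexId = dup@id, nodeFeatures = X,
      edgeSrc = as.integer(e$src), edgeDst = as.integer(e$dst),
      edgeType = ifelse(e$isPair, "PAIR", "BACKBONE"),
      edgeScalars = matrix(numeric(0), length(e$src), 0L),
      targetIndex = target, label = as.character(label),
      sequence = dup@sequence, featureSet = "baseline")
}

#' Build the bio-aware 22-dimensional site graph
#'
#' Extends [buildBaselineGraph()] with neighbor one-hots, stem-loop geometry
#' and pairing-energy node features, typed pair edges
#' (\code{WC_PAIR} / \code{WOBBLE_PAIR} by [isValidPair()]) and the 10 scalar
#' edge attributes listed in the package's frozen layout. A structure pairing
#' two bases that fail [isValidPair()] (possible in noncanonical MFE output)
#' is kept as \code{WC_PAIR} with energy 0 and a message is emitted.
#'
#' @inheritParams buildBaselineGraph
#' @param ann [StructureAnnotation-class] from [annotateStructure()].
#' @return A [SiteGraph-class].
#' @export
buildBioawareGraph <- function(dup, pt, ann, target, label = NA_character_) {
  stopifnot(is(dup, "Duplex"), is(ann, "StructureAnnotation"))
  L <- length(dup)
  if (length(pt) != L || length(ann@stemLength) != L) {
    stop("pair table / annotation length does not match the duplex")
  }
  target <- as.integer(target)
  .checkTarget(dup, target)
  bases <- strsplit(dup@sequence, "", fixed = TRUE)[[1L]]
  prev <- c("N", bases[-L])
  nxt <- c(bases[-1L], "N")
  X <- cbind(.baseOneHot(bases),
             as.numeric(!is.na(pt)),
             (seq_len(L) - target) / L,
             as.numeric(seq_len(L) == target),
             .baseOneHot(prev),
             .baseOneHot(nxt),
             .clipScale(ann@stemLength),
             .clipScale(ann@loopLength),
             .clipScale(ann@distToJunction),
             ann@pairEnergy / 3)
  e <- .duplexEdges(pt)
  type <- rep("BACKBONE", length(e$src))
  if (any(e$isPair)) {
    pi_ <- which(e$isPair)
    valid <- isValidPair(bases[e$src[pi_]], bases[e$dst[pi_]])
    wob <- paste0(pmin(bases[e$src[pi_]], bases[e$dst[pi_]]),
                  pmax(bases[e$src[pi_]], bases[e$dst[pi_]])) == "GU"
    type[pi_] <- ifelse(valid & wob, "WOBBLE_PAIR", "WC_PAIR")
    if (any(!valid)) {
      message(sum(!valid) %/% 2L, " noncanonical pair(s) in '", dup@id,
              "' kept as WC_PAIR with energy 0")
    }
  }
  en <- numeric(length(e$src))
  en[e$isPair] <- pairEnergy(bases[e$src[e$isPair]], bases[e$dst[e$isPair]])
  relDist <- (seq_len(L) - target) / L
  S <- cbind(as.numeric(e$isPair),
             abs(e$src - e$dst) / L,
             .clipScale(ann@stemLength[e$src]),
             .clipScale(ann@stemLength[e$dst]),
             .clipScale(ann@loopLength[e$src]),
             .clipScale(ann@loopLength[e$dst]),
             .clipScale(pmin(ann@distToJunction[e$src], ann@distToJunction[e$dst])),
             en / 3,
             relDist[e$src],
             relDist[e$dst])
  new("SiteGraph", duplexId = dup@id, nodeFeatures = X,
      edgeSrc = as.integer(e$src), edgeDst = as.integer(e$dst),
      edgeType = type, edgeScalars = S,
      targetIndex = target, label = as.character(label),
      sequence = dup@sequence, featureSet = "bioaware")
}

#' One site graph per candidate adenosine of a duplex
#'
#' Builds position-centric graphs for a list of candidate positions. All
#' graphs share the duplex topology; only the target flag, relative-distance
#' features and (bio-aware) nothing else differ between candidates.
#'
#' @inheritParams buildBioawareGraph
#' @param targets Integer vector of candidate adenosine positions (1-based).
#' @param featureSet \code{"baseline"} or \code{"bioaware"}.
#' @param labels Optional character vector of labels, recycled if length 1.
#' @return List of [SiteGraph-class] objects (empty list for no candidates).
#' @export
graphsForDuplex <- function(dup, pt, ann = NULL, targets,
                            featureSet = c("baseline", "bioaware"),
                            labels = NA_character_) {
  featureSet <- match.arg(featureSet)
  if (length(targets) == 0L) return(list())
  labels <- rep_len(labels, length(targets))
  if (featureSet == "bioaware" && is.null(ann)) ann <- annotateStructure(dup, pt)
  lapply(seq_along(targets), function(k) {
    if (featureSet == "baseline") {
      buildBaselineGraph(dup, pt, targets[k], labels[k])
    } else {
      buildBioawareGraph(dup, pt, ann, targets[k], labels[k])
    }
  })
}

#' Adenosine positions of a duplex
#' @param dup A [Duplex-class].
#' @return Integer vector of 1-based positions carrying \code{A}.
#' @export
adenosinePositions <- function(dup) {
  which(strsplit(dup@sequence, "", fixed = TRUE)[[1L]] == "A")
}

# ---- serialization ----------------------------------------------------------

.fmtNum <- function(x) sprintf("%.17g", x)

#' Serialize / deserialize a set of site graphs
#'
#' Writes a graph set as three tab-separated columnar tables in one directory:
#' \code{nodes.tsv} (graph id + node feature columns), \code{edges.tsv}
#' (graph id, src, dst, type, scalar columns) and \code{graphs.tsv} (the
#' manifest: graph id, duplex id, target position, label, feature set,
#' sequence). Numeric values are written with 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param graphs List of [SiteGraph-class] objects.
#' @param dir Output directory (created if missing).
#' @return \code{writeGraphSet} returns \code{dir}; \code{readGraphSet}
#'   returns the list of graphs.
#' @export
writeGraphSet <- function(graphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gid <- seq_along(graphs)
  man <- data.frame(
    graph_id = gid,
    duplex_id = vapply(graphs, function(g) g@duplexId, ""),
    target = vapply(graphs, function(g) g@targetIndex, 1L),
    label = vapply(graphs, function(g) g@label, ""),
    feature_set = vapply(graphs, function(g) g@featureSet, ""),
    sequence = vapply(graphs, function(g) g@sequence, ""),
    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(dir, "graphs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- do.call(rbind, lapply(gid, function(i) {
    X <- graphs[[i]]@nodeFeatures
    cbind(graph_id = i, node = seq_len(nrow(X)), X)
  }))
  nd <- as.data.frame(nodes)
  names(nd) <- c("graph_id", "node", paste0("f", seq_len(ncol(nodes) - 2L)))
  for (j in seq(3L, ncol(nd))) nd[[j]] <- .fmtNum(nd[[j]])
  utils::write.table(nd, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- do.call(rbind, lapply(gid, function(i) {
    g <- graphs[[i]]
    S <- g@edgeScalars
    df <- data.frame(graph_id = i, src = g@edgeSrc, dst = g@edgeDst,
                     type = g@edgeType, stringsAsFactors = FALSE)
    if (ncol(S) > 0L) {
      sd_ <- as.data.frame(S)
      names(sd_) <- paste0("s", seq_len(ncol(S)))
      for (j in seq_len(ncol(sd_))) sd_[[j]] <- .fmtNum(sd_[[j]])
      df <- cbind(df, sd_)
    }
    df
  }))
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeGraphSet
#' @export
readGraphSet <- function(dir) {
  man <- utils::read.table(file.path(dir, "graphs.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  edges <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(k) {
    gid <- as.integer(man$graph_id[k])
    nn <- nodes[nodes$graph_id == gid, , drop = FALSE]
    nn <- nn[order(nn$node), , drop = FALSE]
    X <- as.matrix(nn[, -(1:2), drop = FALSE])
    dimnames(X) <- NULL
    ee <- edges[edges$graph_id == gid, , drop = FALSE]
    scols <- grep("^s[0-9]+$", names(ee), value = TRUE)
    S <- if (length(scols)) {
      m <- as.matrix(ee[, scols, drop = FALSE]); dimnames(m) <- NULL; m
    } else matrix(numeric(0), nrow(ee), 0L)
    lab <- man$label[k]
    if (identical(lab, "") || is.na(lab)) lab <- NA_character_
    new("SiteGraph", duplexId = man$duplex_id[k], nodeFeatures = X,
        edgeSrc = as.integer(ee$src), edgeDst = as.integer(ee$dst),
        edgeType = ee$type, edgeScalars = S,
        targetIndex = as.integer(man$target[k]), label = lab,
        sequence = man$sequence[k], featureSet = man$feature_set[k])
  })
}
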