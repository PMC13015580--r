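# In silico perturbation analyses. All edits operate on copies of the input
# graphs (R value semantics; asserted by tests). The default "local edit"
# mode changes exactly what the perturbation describes — base one-hots
# (including neighbor blocks), pairing flags, pair edges and pair energies —
# and leaves stem/loop/junction annotations untouched; full re-annotation is
# available behind `reannotate = TRUE`.

COL_PAIRED <- 6L
COL_PREV <- 9:13
COL_NEXT <- 14:18
COL_NODE_ENERGY <- 22L
COL_EDGE_ENERGY <- 8L

.baseAt <- function(g, pos) substr(g@sequence, pos, pos)

.partnerOf <- function(g, pos) {
  e <- which(g@edgeSrc == pos & g@edgeType != "BACKBONE")
  if (length(e) == 0L) NA_integer_ else g@edgeDst[e[1L]]
}

.setBase <- function(g, pos, base) {
  L <- nrow(g@nodeFeatures)
  bi <- match(base, RNA_ALPHABET)
  g@nodeFeatures[pos, 1:5] <- 0
  g@nodeFeatures[pos, bi] <- 1
  substr(g@sequence, pos, pos) <- base
  if (g@featureSet == "bioaware") {
    if (pos > 1L) {
      g@nodeFeatures[pos - 1L, COL_NEXT] <- 0
      g@nodeFeatures[pos - 1L, COL_NEXT[1L] - 1L + bi] <- 1
    }
    if (pos < L) {
      g@nodeFeatures[pos + 1L, COL_PREV] <- 0
      g@nodeFeatures[pos + 1L, COL_PREV[1L] - 1L + bi] <- 1
    }
  }
  g
}

.removePairAt <- function(g, pos) {
  q <- .partnerOf(g, pos)
  if (is.na(q)) return(g)
  drop <- (g@edgeType != "BACKBONE") &
    ((g@edgeSrc == pos & g@edgeDst == q) | (g@edgeSrc == q & g@edgeDst == pos))
  g@edgeSrc <- g@edgeSrc[!drop]
  g@edgeDst <- g@edgeDst[!drop]
  g@edgeType <- g@edgeType[!drop]
  if (ncol(g@edgeScalars) > 0L) {
    g@edgeScalars <- g@edgeScalars[!drop, , drop = FALSE]
  }
  g@nodeFeatures[c(pos, q), COL_PAIRED] <- 0
  if (g@featureSet == "bioaware") {
    g@nodeFeatures[c(pos, q), COL_NODE_ENERGY] <- 0
  }
  g
}

# refresh type and energy of the pair at pos from the current bases
.refreshPairAt <- function(g, pos) {
  q <- .partnerOf(g, pos)
  if (is.na(q)) return(g)
  b1 <- .baseAt(g, pos)
  b2 <- .baseAt(g, q)
  en <- pairEnergy(b1, b2)
  idx <- which((g@edgeType != "BACKBONE") &
                 ((g@edgeSrc == pos & g@edgeDst == q) |
                    (g@edgeSrc == q & g@edgeDst == pos)))
  if (g@featureSet == "bioaware") {
    wob <- paste0(min(b1, b2), max(b1, b2)) == "GU"
    g@edgeType[idx] <- if (wob) "WOBBLE_PAIR" else "WC_PAIR"
    g@edgeScalars[idx, COL_EDGE_ENERGY] <- en / 3
    g@nodeFeatures[c(pos, q), COL_NODE_ENERGY] <- en / 3
  }
  g
}

# reconstruct duplex + pair table from the current graph state
.graphToStructure <- function(g) {
  L <- nrow(g@nodeFeatures)
  pt <- rep(NA_integer_, L)
  pe <- which(g@edgeType != "BACKBONE" & g@edgeSrc < g@edgeDst)
  pt[g@edgeSrc[pe]] <- g@edgeDst[pe]
  pt[g@edgeDst[pe]] <- g@edgeSrc[pe]
  list(dup = duplex(g@duplexId, g@sequence, pairTableToDotBracket(pt)),
       pt = pt)
}

.rebuildGraph <- function(g) {
  st <- .graphToStructure(g)
  if (g@featureSet == "baseline") {
    buildBaselineGraph(st$dup, st$pt, g@targetIndex, g@label)
  } else {
    buildBioawareGraph(st$dup, st$pt, annotateStructure(st$dup, st$pt),
                       g@targetIndex, g@label)
  }
}

# apply a base substitution; structureCoupled additionally disrupts/retains
# the pair at the mutated position according to pair validity
.mutateGraph <- function(g, pos, base, structureCoupled, reannotate = FALSE) {
  g <- .setBase(g, pos, base)
  if (structureCoupled) {
    q <- .partnerOf(g, pos)
    if (!is.na(q)) {
      if (isValidPair(base, .baseAt(g, q))) {
        g <- .refreshPairAt(g, pos)
      } else {
        g <- .removePairAt(g, pos)
      }
    }
  }
  if (reannotate) g <- .rebuildGraph(g)
  g
}

#' High-confidence edited sites
#'
#' Edited-labeled graphs whose model prediction is strictly above the cutoff
#' (default 0.7) — the site set the perturbation analyses operate on.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs Labeled [SiteGraph-class] list.
#' @param cutoff Strict lower bound on the prediction (default 0.7).
#' @return Sub-list of \code{graphs} (possibly empty).
#' @export
selectHighConfidence <- function(model, graphs, cutoff = 0.7) {
  if (length(graphs) == 0L) return(list())
  scores <- predictProb(model, graphs)
  lab <- vapply(graphs, function(g) g@label, "")
  graphs[!is.na(lab) & lab == "edited" & scores > cutoff]
}

.runMutagenesis <- function(model, graphs, window, structureCoupled,
                            reannotate, center) {
  if (length(graphs) == 0L) stop("empty site set")
  offsets <- setdiff(seq(-window, window), 0L)
  bases <- c("A", "C", "G", "U")
  orig <- predictProb(model, graphs)
  mutants <- list()
  slots <- list()  # (site, offset index, base index)
  for (si in seq_along(graphs)) {
    g <- graphs[[si]]
    L <- nrow(g@nodeFeatures)
    for (oi in seq_along(offsets)) {
      pos <- g@targetIndex + offsets[oi]
      if (pos < 1L || pos > L) next
      cur <- .baseAt(g, pos)
      for (bi in seq_along(bases)) {
        if (bases[bi] == cur) next  # identity mutation: delta is exactly 0
        mutants[[length(mutants) + 1L]] <-
          .mutateGraph(g, pos, bases[bi], structureCoupled, reannotate)
        slots[[length(slots) + 1L]] <- c(si, oi, bi)
      }
    }
  }
  sums <- matrix(0, length(offsets), length(bases))
  cnts <- matrix(0L, length(offsets), length(bases))
  # identity cells contribute delta 0 (still counted)
  for (si in seq_along(graphs)) {
    g <- graphs[[si]]
    L <- nrow(g@nodeFeatures)
    for (oi in seq_along(offsets)) {
      pos <- g@targetIndex + offsets[oi]
      if (pos < 1L || pos > L) next
      cnts[oi, ] <- cnts[oi, ] + 1L
    }
  }
  if (length(mutants)) {
    ms <- predictProb(model, mutants)
    sl <- do.call(rbind, slots)
    delta <- ms - orig[sl[, 1L]]
    for (k in seq_along(delta)) {
      sums[sl[k, 2L], sl[k, 3L]] <- sums[sl[k, 2L], sl[k, 3L]] + delta[k]
    }
  }
  vals <- sums / pmax(cnts, 1L)
  if (center) vals <- vals - rowMeans(vals)
  new("PreferenceMatrix", values = vals, offsets = as.integer(offsets),
      bases = bases, centered = center, nSites = length(graphs))
}

#' Sequence-only in silico mutagenesis
#'
#' For each offset in \code{-window..+window} (the target position 0 itself
#' excluded — only adenosine is relevant there) and each base, substitutes the
#' base identity while preserving the original pairing status and all edges,
#' rescores, and records the mean prediction change relative to the original.
#' Values are position-mean-centered by default to express relative
#' preferences.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs Site graphs to perturb (typically from
#'   [selectHighConfidence()]).
#' @param window Half-window around the target (default 3).
#' @param center Subtract the position-wise mean (default TRUE).
#' @return A [PreferenceMatrix-class] (offsets x bases).
#' @export
sequenceMutagenesis <- function(model, graphs, window = 3L, center = TRUE) {
  .runMutagenesis(model, graphs, window, structureCoupled = FALSE,
                  reannotate = FALSE, center = center)
}

#' Structure-coupled in silico mutagenesis
#'
#' As [sequenceMutagenesis()], but a mutation that breaks the Watson-Crick or
#' wobble validity of an existing pair also flips both endpoints to unpaired,
#' removes the two directed pair edges and zeroes the pair-energy features; a
#' mutation that keeps the pair valid retains it (retyped, energy refreshed).
#'
#' @inheritParams sequenceMutagenesis
#' @param reannotate Rebuild stem/loop/junction annotations from the mutated
#'   structure instead of the default local graph edit.
#' @return A [PreferenceMatrix-class].
#' @export
structureCoupledMutagenesis <- function(model, graphs, window = 3L,
                                        center = TRUE, reannotate = FALSE) {
  .runMutagenesis(model, graphs, window, structureCoupled = TRUE,
                  reannotate = reannotate, center = center)
}

#' Paired-minus-unpaired positional perturbation
#'
#' For each offset in \code{-range..+range} and each site where that position
#' is paired in the input structure, compares the prediction with the pair
#' retained (the original graph) against the pair removed, reporting the mean
#' difference (paired minus unpaired) and the number of contributing sites.
#' Positions that are natively unpaired contribute nothing (forcing a pair
#' would require inventing a partner). Offsets with no contributing site get
#' \code{NA}.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs Site graphs to perturb.
#' @param range Half-window (default 40).
#' @return data.frame with columns \code{offset}, \code{delta}, \code{count}.
#' @export
positionalPerturbation <- function(model, graphs, range = 40L) {
  if (length(graphs) == 0L) stop("empty site set")
  offsets <- seq(-range, range)
  orig <- predictProb(model, graphs)
  mutants <- list()
  slots <- list()
  for (si in seq_along(graphs)) {
    g <- graphs[[si]]
    L <- nrow(g@nodeFeatures)
    for (oi in seq_along(offsets)) {
      pos <- g@targetIndex + offsets[oi]
      if (pos < 1L || pos > L) next
      if (g@nodeFeatures[pos, COL_PAIRED] != 1) next
      mutants[[length(mutants) + 1L]] <- .removePairAt(g, pos)
      slots[[length(slots) + 1L]] <- c(si, oi)
    }
  }
  sums <- numeric(length(offsets))
  cnts <- integer(length(offsets))
  if (length(mutants)) {
    ms <- predictProb(model, mutants)
    sl <- do.call(rbind, slots)
    delta <- orig[sl[, 1L]] - ms  # paired (original) minus unpaired
    for (k in seq_along(delta)) {
      sums[sl[k, 2L]] <- sums[sl[k, 2L]] + delta[k]
      cnts[sl[k, 2L]] <- cnts[sl[k, 2L]] + 1L
    }
  }
  data.frame(offset = offsets,
             delta = ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA_real_),
             count = cnts)
}

#' Base-pairing interaction scan
#'
#' At each requested offset, systematically sets the sequence-side base and
#' its opposing partner base to all 16 combinations. Valid combinations
#' (Watson-Crick or wobble) keep the pair (flags 1, edge retained and
#' retyped, energy refreshed); invalid combinations disrupt it (flags 0, edge
#' removed). Each cell is the mean prediction over sites that have a partner
#' at that offset; sites without one are skipped and counted. At offset 0
#' only the adenosine row is biologically meaningful; other rows are reported
#' for completeness and flagged.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs Site graphs to perturb.
#' @param offsets Offsets to scan (default \code{c(-1, 0, 1)}).
#' @return Named list (one element per offset) of lists with \code{matrix}
#'   (4 x 4, rows = sequence-side base, columns = partner base),
#'   \code{nSites}, \code{skipped} and \code{relevantRows}.
#' @export
pairInteractionScan <- function(model, graphs, offsets = c(-1L, 0L, 1L)) {
  if (length(graphs) == 0L) stop("empty site set")
  bases <- c("A", "C", "G", "U")
  out <- vector("list", length(offsets))
  names(out) <- as.character(offsets)
  for (oi in seq_along(offsets)) {
    off <- offsets[oi]
    eligible <- list()
    partners <- integer(0)
    for (g in graphs) {
      pos <- g@targetIndex + off
      if (pos < 1L || pos > nrow(g@nodeFeatures)) next
      q <- .partnerOf(g, pos)
      if (is.na(q)) next
      eligible[[length(eligible) + 1L]] <- g
      partners <- c(partners, q)
    }
    skipped <- length(graphs) - length(eligible)
    if (length(eligible) == 0L) {
      stop("no site has a partner at offset ", off)
    }
    mutants <- vector("list", length(eligible) * 16L)
    k <- 0L
    for (si in seq_along(eligible)) {
      g <- eligible[[si]]
      pos <- g@targetIndex + off
      q <- partners[si]
      for (b1 in bases) for (b2 in bases) {
        m <- .setBase(g, pos, b1)
        m <- .setBase(m, q, b2)
        if (isValidPair(b1, b2)) {
          m <- .refreshPairAt(m, pos)
        } else {
          m <- .removePairAt(m, pos)
        }
        k <- k + 1L
        mutants[[k]] <- m
      }
    }
    scores <- predictProb(model, mutants)
    # filling order above: b2 fastest, then b1, then site
    arr <- aperm(array(scores, dim = c(4L, 4L, length(eligible))),
                 c(2L, 1L, 3L))
    mat <- apply(arr, c(1L, 2L), mean)
    dimnames(mat) <- list(seq_side = bases, partner = bases)
    out[[oi]] <- list(matrix = mat, nSites = length(eligible),
                      skipped = skipped,
                      relevantRows = if (off == 0L) "A" else bases)
  }
  out
}

#' Center a preference matrix by position
#'
#' Subtracts the row (position-wise) mean so each offset's values express
#' relative preferences.
#'
#' @param x Numeric matrix (offsets x bases) or [PreferenceMatrix-class].
#' @return Object of the same kind with zero row means.
#' @export
centerByPosition <- function(x) {
  if (is(x, "PreferenceMatrix")) {
    x@values <- x@values - rowMeans(x@values)
    x@centered <- TRUE
    return(x)
  }
  x - rowMeans(x)
}
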