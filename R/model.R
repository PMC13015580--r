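# The two architectures. Baseline: 3 stacked multi-head graph-attention
# layers (attention -> ReLU -> batch norm -> dropout), global mean pooling,
# one fully connected layer, sigmoid. Bio-aware: adds a typed-edge encoder
# feeding the attention logits, a 3/5-mer CNN sequence branch with masked
# max-pooling, an optional 4-head global attention pooling over post-GAT node
# embeddings, and a two-layer MLP fusion head.
#
# Self-loops are added to every node at batch time for attention stability;
# they carry edge type SELF and zero scalars, and are flagged so that
# downstream positional aggregation can exclude them.

LAYOUT_VERSION <- "adaredit-features-1"

EDGE_TYPE_LEVELS <- c("BACKBONE", "WC_PAIR", "WOBBLE_PAIR", "SELF")

#' Model configuration
#'
#' All architecture and optimization settings with their defaults: 3 GAT
#' layers of 4 heads (hidden width 64 = 16 per head, concatenated), dropout
#' 0.2, a 6-dim edge-type embedding concatenated with the 10 edge scalars and
#' passed through a small MLP to a 16-dim edge representation, 3-mer and 5-mer
#' convolutions with 48 channels each projected to a 48-dim sequence
#' embedding, optional 4-head global attention, 64-wide fusion hidden layer.
#' Optimizer: Adam, learning rate 3e-3, weight decay 1e-5, batch size 8,
#' binary cross-entropy loss (the small batches and the higher rate are what
#' lets attention heads sharpen enough to resolve 5'/3' direction from the
#' relative-distance feature within a ~100-epoch budget).
#'
#' @param featureSet \code{"baseline"} or \code{"bioaware"}.
#' @param globalAttention Enable the global attention pooling branch
#'   (bio-aware only).
#' @param edgeRepAllLayers Feed edge representations to all three attention
#'   layers (default) or only the first.
#' @param hiddenDim,heads,gatLayers,dropout,edgeTypeEmbedDim,edgeRepDim,cnnChannels,kernelSizes,seqEmbedDim,fusionHidden
#'   Architecture dimensions (see above).
#' @param lr,weightDecay,batchSize,epochs Optimization settings.
#' @param seed Integer seed for weight initialization and training shuffles.
#' @return A config list used by [initModel()] and [trainModel()].
#' @export
modelConfig <- function(featureSet = c("baseline", "bioaware"),
                        globalAttention = FALSE,
                        edgeRepAllLayers = TRUE,
                        hiddenDim = 64L, heads = 4L, gatLayers = 3L,
                        dropout = 0.2,
                        edgeTypeEmbedDim = 6L, edgeRepDim = 16L,
                        cnnChannels = 48L, kernelSizes = c(3L, 5L),
                        seqEmbedDim = 48L, fusionHidden = 64L,
                        lr = 3e-3, weightDecay = 1e-5, batchSize = 8L,
                        epochs = 200L, seed = 1L) {
  featureSet <- match.arg(featureSet)
  stopifnot(hiddenDim %% heads == 0L, hiddenDim > 0L, heads > 0L,
            gatLayers == 3L, dropout >= 0, dropout < 1,
            edgeTypeEmbedDim > 0L, edgeRepDim > 0L)
  list(featureSet = featureSet, globalAttention = globalAttention,
       edgeRepAllLayers = edgeRepAllLayers,
       hiddenDim = as.integer(hiddenDim), heads = as.integer(heads),
       gatLayers = as.integer(gatLayers), dropout = dropout,
       edgeTypeEmbedDim = as.integer(edgeTypeEmbedDim),
       edgeRepDim = as.integer(edgeRepDim),
       cnnChannels = as.integer(cnnChannels),
       kernelSizes = as.integer(kernelSizes),
       seqEmbedDim = as.integer(seqEmbedDim),
       fusionHidden = as.integer(fusionHidden),
       lr = lr, weightDecay = weightDecay,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed))
}

#' Editing-prediction model
#'
#' Holds the configuration, the parameter matrices and the batch-norm running
#' statistics of one model. Construct with [initModel()]; train with
#' [trainModel()]; score graphs with [predictProb()].
#'
#' @slot config Configuration list from [modelConfig()].
#' @slot params Named list of parameter matrices.
#' @slot bn Named list of batch-norm running statistics.
#' @slot layoutVersion Feature-layout tag checked on checkpoint load.
#' @export
setClass("AdarEditModel", representation(
  config = "list", params = "list", bn = "list", layoutVersion = "character"
))

setMethod("show", "AdarEditModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat("AdarEditModel (", cfg$featureSet, "): ", cfg$gatLayers, " GAT layers x ",
      cfg$heads, " heads, hidden ", cfg$hiddenDim,
      if (cfg$featureSet == "bioaware") {
        paste0(", edge rep ", cfg$edgeRepDim, ", seq embedding ",
               cfg$seqEmbedDim,
               if (cfg$globalAttention) ", global attention")
      },
      "; ", np, " parameters\n", sep = "")
})

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a model
#'
#' Glorot-uniform weight initialization, deterministic given
#' \code{config$seed}.
#'
#' @param config From [modelConfig()].
#' @return An [AdarEditModel-class].
#' @export
initModel <- function(config) {
  set.seed(config$seed)
  D <- config$hiddenDim
  H <- config$heads
  dIn <- if (config$featureSet == "baseline") 8L else 22L
  p <- list()
  for (l in seq_len(config$gatLayers)) {
    din <- if (l == 1L) dIn else D
    p[[paste0("W", l)]] <- .glorot(din, D)
    p[[paste0("aSrc", l)]] <- .glorot(1L, D)
    p[[paste0("aDst", l)]] <- .glorot(1L, D)
    p[[paste0("bnGamma", l)]] <- matrix(1, 1L, D)
    p[[paste0("bnBeta", l)]] <- matrix(0, 1L, D)
  }
  if (config$featureSet == "baseline") {
    p$Wout <- .glorot(D, 1L)
    p$bOut <- matrix(0, 1L, 1L)
  } else {
    ed <- config$edgeTypeEmbedDim
    er <- config$edgeRepDim
    p$typeEmb <- .glorot(length(EDGE_TYPE_LEVELS), ed)
    p$We1 <- .glorot(ed + 10L, er)
    p$be1 <- matrix(0, 1L, er)
    p$We2 <- .glorot(er, er)
    p$be2 <- matrix(0, 1L, er)
    nEdgeLayers <- if (config$edgeRepAllLayers) config$gatLayers else 1L
    for (l in seq_len(nEdgeLayers)) {
      p[[paste0("edgeAtt", l)]] <- .glorot(er, H)
    }
    cc <- config$cnnChannels
    for (k in config$kernelSizes) {
      p[[paste0("K", k)]] <- .glorot(5L * k, cc)
      p[[paste0("bK", k)]] <- matrix(0, 1L, cc)
    }
    p$Wproj <- .glorot(cc * length(config$kernelSizes), config$seqEmbedDim)
    p$bProj <- matrix(0, 1L, config$seqEmbedDim)
    if (config$globalAttention) {
      p$WkAtt <- .glorot(D, D)
      p$qAtt <- .glorot(1L, D)
      p$WvAtt <- .glorot(D, D)
    }
    fIn <- D + config$seqEmbedDim + if (config$globalAttention) D else 0L
    p$Wf1 <- .glorot(fIn, config$fusionHidden)
    p$bf1 <- matrix(0, 1L, config$fusionHidden)
    p$Wf2 <- .glorot(config$fusionHidden, 1L)
    p$bf2 <- matrix(0, 1L, 1L)
  }
  new("AdarEditModel", config = config, params = p, bn = list(),
      layoutVersion = LAYOUT_VERSION)
}

# ---- batching ---------------------------------------------------------------

.seqToInt <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_ALPHABET)
}

# per-graph static arrays computed once (valid for repeated batching)
.prepareGraph <- function(g, kernelSizes = c(3L, 5L)) {
  L <- nrow(g@nodeFeatures)
  typeId <- match(g@edgeType, EDGE_TYPE_LEVELS)
  typeId[is.na(typeId)] <- 1L  # baseline "PAIR" edges are untyped
  seqInt <- .seqToInt(g@sequence)
  convIdx <- lapply(kernelSizes, function(k) {
    ctr <- (k + 1L) %/% 2L
    idx <- matrix(0L, L, k)
    for (o in seq_len(k)) {
      pos <- seq_len(L) + o - ctr
      ok <- pos >= 1L & pos <= L
      idx[ok, o] <- (o - 1L) * 5L + seqInt[pos[ok]]
    }
    idx
  })
  names(convIdx) <- paste0("k", kernelSizes)
  list(X = g@nodeFeatures, src = g@edgeSrc, dst = g@edgeDst,
       typeId = typeId, scalars = g@edgeScalars, L = L,
       convIdx = convIdx, label = g@label, target = g@targetIndex)
}

prepareGraphs <- function(graphs, config) {
  lapply(graphs, .prepareGraph, kernelSizes = config$kernelSizes)
}

# assemble graphs prep[idx] into one disjoint batch with self-loops appended
.assembleBatch <- function(prep, idx) {
  sel <- prep[idx]
  Ls <- vapply(sel, function(p) p$L, 1L)
  offs <- cumsum(c(0L, Ls[-length(Ls)]))
  nNodes <- sum(Ls)
  X <- do.call(rbind, lapply(sel, function(p) p$X))
  src <- unlist(lapply(seq_along(sel), function(i) sel[[i]]$src + offs[i]))
  dst <- unlist(lapply(seq_along(sel), function(i) sel[[i]]$dst + offs[i]))
  typeId <- unlist(lapply(sel, function(p) p$typeId))
  nsc <- ncol(sel[[1L]]$scalars)
  scalars <- if (nsc > 0L) do.call(rbind, lapply(sel, function(p) p$scalars))
             else matrix(numeric(0), length(src), 0L)
  nE <- length(src)
  # self-loops
  src <- c(src, seq_len(nNodes))
  dst <- c(dst, seq_len(nNodes))
  typeId <- c(typeId, rep(4L, nNodes))
  if (nsc > 0L) scalars <- rbind(scalars, matrix(0, nNodes, nsc))
  isSelf <- c(rep(FALSE, nE), rep(TRUE, nNodes))
  nodeGraph <- rep(seq_along(sel), Ls)
  convIdx <- lapply(names(sel[[1L]]$convIdx), function(nm) {
    do.call(rbind, lapply(sel, function(p) p$convIdx[[nm]]))
  })
  names(convIdx) <- names(sel[[1L]]$convIdx)
  y <- vapply(sel, function(p) {
    if (is.na(p$label)) NA_real_ else as.numeric(p$label == "edited")
  }, 1)
  # fixed-degree incidence index matrices: degree is bounded (2 backbone
  # edges + 1 pair edge + 1 self-loop), so segment ops become a few gathers
  degIdx <- function(keys, n) {
    ord <- order(keys)
    k <- keys[ord]
    slot <- sequence(rle(k)$lengths)
    m <- matrix(0L, n, max(slot))
    m[cbind(k, slot)] <- ord
    m
  }
  srcIn <- degIdx(src, nNodes)
  dstIn <- degIdx(dst, nNodes)
  list(X = X, src = src, dst = dst, typeId = typeId, scalars = scalars,
       isSelf = isSelf, nodeGraph = nodeGraph, nNodes = nNodes,
       nGraphs = length(sel), convIdx = convIdx, y = y,
       srcIn = srcIn, dstIn = dstIn)
}

# ---- forward ----------------------------------------------------------------

# Builds the full tape for one batch. Returns tape, node ids of logits and
# parameters, and the first-layer attention coefficients (values).
.forwardBatch <- function(params, config, bnState, batch, training = FALSE) {
  tp <- adTape()
  pid <- lapply(params, function(p) adConst(tp, p))
  H <- config$heads
  bio <- config$featureSet == "bioaware"
  h <- adConst(tp, batch$X)

  erep <- NULL
  if (bio) {
    emb <- adGather(tp, pid$typeEmb, batch$typeId)
    ein <- adColBind(tp, emb, adConst(tp, batch$scalars))
    e1 <- adRelu(tp, adAddBias(tp, adMatmul(tp, ein, pid$We1), pid$be1))
    erep <- adAddBias(tp, adMatmul(tp, e1, pid$We2), pid$be2)
  }

  attn1 <- NULL
  for (l in seq_len(config$gatLayers)) {
    hw <- adMatmul(tp, h, pid[[paste0("W", l)]])
    sl <- adHeadDot(tp, hw, pid[[paste0("aSrc", l)]], H)
    sr <- adHeadDot(tp, hw, pid[[paste0("aDst", l)]], H)
    logit <- adAdd(tp, adGather(tp, sl, batch$src, batch$srcIn),
                   adGather(tp, sr, batch$dst, batch$dstIn))
    if (bio && (l == 1L || config$edgeRepAllLayers)) {
      logit <- adAdd(tp, logit,
                     adMatmul(tp, erep, pid[[paste0("edgeAtt", l)]]))
    }
    logit <- adLeakyRelu(tp, logit, 0.2)
    alpha <- adSegSoftmax(tp, logit, batch$dst, batch$nNodes,
                          inIdx = batch$dstIn)
    if (l == 1L) attn1 <- adVal(tp, alpha)
    msg <- adGather(tp, hw, batch$src, batch$srcIn)
    agg <- adSegSum(tp, adHeadMul(tp, msg, alpha, H), batch$dst,
                    batch$nNodes, inIdx = batch$dstIn)
    act <- adRelu(tp, agg)
    bn <- adBatchNorm(tp, act, pid[[paste0("bnGamma", l)]],
                      pid[[paste0("bnBeta", l)]], bnState,
                      paste0("bn", l), training)
    h <- adDropout(tp, bn, config$dropout, training)
  }

  pooled <- adSegMean(tp, h, batch$nodeGraph, batch$nGraphs)

  if (!bio) {
    logits <- adAddBias(tp, adMatmul(tp, pooled, pid$Wout), pid$bOut)
  } else {
    convs <- lapply(config$kernelSizes, function(k) {
      ci <- batch$convIdx[[paste0("k", k)]]
      acc <- adGather(tp, pid[[paste0("K", k)]], ci[, 1L])
      for (o in 2L:k) {
        acc <- adAdd(tp, acc, adGather(tp, pid[[paste0("K", k)]], ci[, o]))
      }
      adRelu(tp, adAddBias(tp, acc, pid[[paste0("bK", k)]]))
    })
    perPos <- if (length(convs) > 1L) do.call(adColBind, c(list(tp), convs))
              else convs[[1L]]
    pooledSeq <- adSegMax(tp, perPos, batch$nodeGraph, batch$nGraphs)
    seqEmb <- adAddBias(tp, adMatmul(tp, pooledSeq, pid$Wproj), pid$bProj)
    pieces <- list(pooled, seqEmb)
    if (config$globalAttention) {
      keys <- adMatmul(tp, h, pid$WkAtt)
      score <- adHeadDot(tp, keys, pid$qAtt, H)
      galpha <- adSegSoftmax(tp, score, batch$nodeGraph, batch$nGraphs)
      vals <- adMatmul(tp, h, pid$WvAtt)
      ctx <- adSegSum(tp, adHeadMul(tp, vals, galpha, H),
                      batch$nodeGraph, batch$nGraphs)
      pieces <- c(pieces, list(ctx))
    }
    fus <- do.call(adColBind, c(list(tp), pieces))
    f1 <- adRelu(tp, adAddBias(tp, adMatmul(tp, fus, pid$Wf1), pid$bf1))
    f1 <- adDropout(tp, f1, config$dropout, training)
    logits <- adAddBias(tp, adMatmul(tp, f1, pid$Wf2), pid$bf2)
  }
  list(tape = tp, logits = logits, pid = pid, attn1 = attn1)
}

.checkGraphsMatch <- function(model, graphs) {
  fs <- unique(vapply(graphs, function(g) g@featureSet, ""))
  if (length(fs) != 1L || fs != model@config$featureSet) {
    stop("graph featurization (", paste(fs, collapse = ","),
         ") does not match the model (", model@config$featureSet, ")")
  }
  d <- unique(vapply(graphs, function(g) ncol(g@nodeFeatures), 1L))
  dExp <- if (model@config$featureSet == "baseline") 8L else 22L
  if (length(d) != 1L || d != dExp) {
    stop("node feature dimension ", paste(d, collapse = ","),
         " does not match the expected ", dExp)
  }
}

#' Score site graphs
#'
#' Evaluation-mode forward pass (dropout off, batch normalization on running
#' statistics): deterministic for fixed weights.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs A [SiteGraph-class] or list of them.
#' @param chunkSize Number of graphs scored per batch.
#' @return Numeric vector of editing probabilities in (0, 1).
#' @export
predictProb <- function(model, graphs, chunkSize = 256L) {
  if (is(graphs, "SiteGraph")) graphs <- list(graphs)
  if (length(graphs) == 0L) return(numeric(0))
  .checkGraphsMatch(model, graphs)
  prep <- prepareGraphs(graphs, model@config)
  bn <- list2env(model@bn, parent = emptyenv())
  out <- numeric(length(graphs))
  starts <- seq(1L, length(graphs), by = chunkSize)
  for (s in starts) {
    idx <- s:min(s + chunkSize - 1L, length(graphs))
    batch <- .assembleBatch(prep, idx)
    fw <- .forwardBatch(model@params, model@config, bn, batch,
                        training = FALSE)
    z <- as.numeric(adVal(fw$tape, fw$logits))
    out[idx] <- 1 / (1 + exp(-z))
  }
  out
}

#' Edge representations from the typed-edge encoder
#'
#' Applies the bio-aware model's edge encoder (6-dim type embedding
#' concatenated with the 10 scalar attributes, then a small MLP) to the edges
#' of one graph. Two edges with identical type and scalars receive identical
#' representations.
#'
#' @param model A bio-aware [AdarEditModel-class].
#' @param graph A bio-aware [SiteGraph-class].
#' @return Numeric matrix, edges x 16.
#' @export
encodeEdges <- function(model, graph) {
  if (model@config$featureSet != "bioaware") {
    stop("edge encoding requires a bio-aware model")
  }
  typeId <- match(graph@edgeType, EDGE_TYPE_LEVELS)
  if (anyNA(typeId)) stop("unknown edge type: ",
                          paste(unique(graph@edgeType[is.na(typeId)]),
                                collapse = ","))
  if (ncol(graph@edgeScalars) != 10L) stop("bio-aware edges need 10 scalars")
  p <- model@params
  ein <- cbind(p$typeEmb[typeId, , drop = FALSE], graph@edgeScalars)
  h1 <- pmax(sweep(ein %*% p$We1, 2L, as.numeric(p$be1), "+"), 0)
  sweep(h1 %*% p$We2, 2L, as.numeric(p$be2), "+")
}

#' Sequence-branch embedding of one sequence
#'
#' Runs the bio-aware model's convolutional sequence branch (3-mer and 5-mer
#' filters, 48 channels each, masked max-pooling, projection) on a tokenized
#' sequence. Positions beyond \code{validLength} are masked out: altering
#' them cannot change the embedding.
#'
#' @param model A bio-aware [AdarEditModel-class].
#' @param sequence Character RNA sequence.
#' @param validLength Number of leading positions that are real (defaults to
#'   the full length); the rest is treated as padding.
#' @return Numeric vector of length \code{seqEmbedDim} (48).
#' @export
sequenceBranch <- function(model, sequence, validLength = nchar(sequence)) {
  if (model@config$featureSet != "bioaware") {
    stop("the sequence branch belongs to the bio-aware model")
  }
  if (validLength < 1L) stop("empty sequence")
  s <- substr(sequence, 1L, validLength)
  seqInt <- .seqToInt(s)
  if (anyNA(seqInt)) stop("sequence contains characters outside {A,C,G,U,N}")
  L <- length(seqInt)
  p <- model@params
  per <- lapply(model@config$kernelSizes, function(k) {
    ctr <- (k + 1L) %/% 2L
    K <- p[[paste0("K", k)]]
    acc <- matrix(0, L, ncol(K))
    for (o in seq_len(k)) {
      pos <- seq_len(L) + o - ctr
      ok <- pos >= 1L & pos <= L
      acc[ok, ] <- acc[ok, ] + K[(o - 1L) * 5L + seqInt[pos[ok]], , drop = FALSE]
    }
    pmax(sweep(acc, 2L, as.numeric(p[[paste0("bK", k)]]), "+"), 0)
  })
  pooled <- apply(do.call(cbind, per), 2L, max)
  as.numeric(pooled %*% p$Wproj + as.numeric(p$bProj))
}

#' Export first-layer attention coefficients
#'
#' Runs an evaluation-mode forward pass on one graph and returns the per-edge
#' attention coefficients of the requested GAT layer (default: first), one
#' column per head plus their mean. Self-loop rows (added internally for
#' attention stability) are included so that, per destination node and head,
#' the incoming coefficients sum to one.
#'
#' @param model An [AdarEditModel-class].
#' @param graph A [SiteGraph-class] matching the model's featurization.
#' @param layer Attention layer to export, in \code{1..gatLayers}.
#' @return data.frame with columns \code{src}, \code{dst}, \code{isSelf},
#'   \code{head1..headH}, \code{mean}.
#' @export
exportAttention <- function(model, graph, layer = 1L) {
  if (layer < 1L || layer > model@config$gatLayers) {
    stop("layer must be in 1..", model@config$gatLayers)
  }
  .checkGraphsMatch(model, list(graph))
  prep <- prepareGraphs(list(graph), model@config)
  batch <- .assembleBatch(prep, 1L)
  bn <- list2env(model@bn, parent = emptyenv())
  fw <- .forwardBatchAttn(model@params, model@config, bn, batch, layer)
  A <- fw
  df <- data.frame(src = batch$src, dst = batch$dst, isSelf = batch$isSelf)
  colnames(A) <- paste0("head", seq_len(ncol(A)))
  df <- cbind(df, as.data.frame(A))
  df$mean <- rowMeans(A)
  df
}

# forward capturing attention of an arbitrary layer (eval mode, no head)
.forwardBatchAttn <- function(params, config, bnState, batch, layer) {
  tp <- adTape()
  pid <- lapply(params, function(p) adConst(tp, p))
  H <- config$heads
  bio <- config$featureSet == "bioaware"
  h <- adConst(tp, batch$X)
  erep <- NULL
  if (bio) {
    emb <- adGather(tp, pid$typeEmb, batch$typeId)
    ein <- adColBind(tp, emb, adConst(tp, batch$scalars))
    e1 <- adRelu(tp, adAddBias(tp, adMatmul(tp, ein, pid$We1), pid$be1))
    erep <- adAddBias(tp, adMatmul(tp, e1, pid$We2), pid$be2)
  }
  for (l in seq_len(layer)) {
    hw <- adMatmul(tp, h, pid[[paste0("W", l)]])
    sl <- adHeadDot(tp, hw, pid[[paste0("aSrc", l)]], H)
    sr <- adHeadDot(tp, hw, pid[[paste0("aDst", l)]], H)
    logit <- adAdd(tp, adGather(tp, sl, batch$src),
                   adGather(tp, sr, batch$dst))
    if (bio && (l == 1L || config$edgeRepAllLayers)) {
      logit <- adAdd(tp, logit,
                     adMatmul(tp, erep, pid[[paste0("edgeAtt", l)]]))
    }
    logit <- adLeakyRelu(tp, logit, 0.2)
    alpha <- adSegSoftmax(tp, logit, batch$dst, batch$nNodes)
    if (l == layer) return(adVal(tp, alpha))
    msg <- adGather(tp, hw, batch$src)
    agg <- adSegSum(tp, adHeadMul(tp, msg, alpha, H), batch$dst, batch$nNodes)
    act <- adRelu(tp, agg)
    bn <- adBatchNorm(tp, act, pid[[paste0("bnGamma", l)]],
                      pid[[paste0("bnBeta", l)]], bnState,
                      paste0("bn", l), FALSE)
    h <- bn
  }
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the weights, the configuration, the batch-norm running
#' statistics and the feature-layout version tag. Loading refuses a
#' checkpoint whose layout tag differs from the package's.
#'
#' @param model An [AdarEditModel-class].
#' @param path File path.
#' @return \code{loadCheckpoint} returns the model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, bn = model@bn, config = model@config,
               layoutVersion = model@layoutVersion), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$layoutVersion, LAYOUT_VERSION)) {
    stop("checkpoint layout '", x$layoutVersion,
         "' does not match this package's layout '", LAYOUT_VERSION, "'")
  }
  new("AdarEditModel", config = x$config, params = x$params, bn = x$bn,
      layoutVersion = x$layoutVersion)
}
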