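# Training loop with per-epoch validation over the fixed threshold grid,
# F1-optimized checkpoint selection, and threshold-free AUROC/AUPRC.

#' The fixed decision-threshold grid
#'
#' 33 thresholds linearly spaced from 0.1 to 0.9 (step 0.025).
#'
#' @return Numeric vector of length 33.
#' @export
thresholdGrid <- function() seq(0.1, 0.9, length.out = 33L)

#' Confusion-matrix metrics over a threshold grid
#'
#' For each threshold \code{t} a prediction is positive iff
#' \code{score >= t}. Reports accuracy, F1, precision (positive predictive
#' value), recall (sensitivity) and specificity (true negative rate); any
#' ratio with a zero denominator is reported as 0 so grid scans are total.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @param thresholds Numeric thresholds (default [thresholdGrid()]).
#' @return data.frame with one row per threshold.
#' @export
metricTable <- function(scores, labels, thresholds = thresholdGrid()) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  out <- lapply(thresholds, function(t) {
    pred <- as.numeric(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- nPos - tp
    tn <- nNeg - fp
    sdiv <- function(a, b) if (b > 0) a / b else 0
    prec <- sdiv(tp, tp + fp)
    rec <- sdiv(tp, tp + fn)
    data.frame(threshold = t,
               accuracy = sdiv(tp + tn, length(labels)),
               f1 = sdiv(2 * prec * rec, prec + rec),
               precision = prec, recall = rec,
               specificity = sdiv(tn, tn + fp))
  })
  do.call(rbind, out)
}

#' Select the F1-maximizing (epoch, threshold) operating point
#'
#' Scans a history table of per-epoch, per-threshold validation metrics and
#' returns the checkpoint with the maximum F1; ties are broken by the
#' earliest epoch, then the lowest threshold.
#'
#' @param history data.frame with columns \code{epoch}, \code{threshold},
#'   \code{accuracy}, \code{f1}, \code{precision}, \code{recall},
#'   \code{specificity}.
#' @return A [ThresholdSearchResult-class].
#' @export
selectCheckpoint <- function(history) {
  if (is.null(history) || nrow(history) == 0L) stop("empty history")
  ord <- order(-history$f1, history$epoch, history$threshold)
  best <- history[ord[1L], ]
  new("ThresholdSearchResult", table = history,
      bestEpoch = as.integer(best$epoch),
      bestThreshold = as.numeric(best$threshold),
      bestF1 = as.numeric(best$f1))
}

#' Threshold-free discrimination: AUROC and AUPRC
#'
#' AUROC is the tie-corrected Mann-Whitney statistic (midranks); AUPRC is the
#' step-wise integral of the precision-recall curve (precision stepped at
#' each distinct score, summed over recall increments).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; both classes must be present.
#' @return Named numeric vector \code{c(auroc = , auprc = )}.
#' @export
evaluateThresholdFree <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auroc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # PR step integration over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y)
  allCum <- seq_along(y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tpCum[last]
  npred <- allCum[last]
  prec <- tp / npred
  recall <- tp / nPos
  dRec <- diff(c(0, recall))
  auprc <- sum(dRec * prec)
  c(auroc = auroc, auprc = auprc)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.gradsByName <- function(fw, loss) {
  grads <- adBackward(fw$tape, loss)
  out <- lapply(names(fw$pid), function(nm) grads[[fw$pid[[nm]]]])
  names(out) <- names(fw$pid)
  out
}

#' Train a model with per-epoch F1-optimized validation
#'
#' Minibatch Adam training with binary cross-entropy loss. After every epoch
#' the model is evaluated on the validation graphs over the 33-point
#' threshold grid; the returned checkpoint is the weights of the epoch whose
#' best threshold attained the maximum validation F1 (ties: earliest epoch,
#' lowest threshold). Train/validation site keys must already be disjoint
#' (see [excludeOverlap()]).
#'
#' @param trainGraphs,valGraphs Lists of labeled [SiteGraph-class] objects.
#' @param config From [modelConfig()]; \code{config$epochs} epochs are run,
#'   no early stopping.
#' @param verbose Print per-epoch loss and best F1.
#' @return List: \code{model} (the F1-selected checkpoint,
#'   [AdarEditModel-class]), \code{search} ([ThresholdSearchResult-class]),
#'   \code{history} (per-epoch data.frame of loss, AUROC, AUPRC, best F1),
#'   \code{finalModel} (weights after the last epoch).
#' @export
trainModel <- function(trainGraphs, valGraphs, config, verbose = FALSE) {
  if (length(trainGraphs) == 0L || length(valGraphs) == 0L) {
    stop("empty train or validation set")
  }
  labs <- vapply(trainGraphs, function(g) g@label, "")
  if (anyNA(labs) || !all(labs %in% c("edited", "non_edited"))) {
    stop("all training graphs must be labeled")
  }
  model <- initModel(config)
  .checkGraphsMatch(model, trainGraphs)
  .checkGraphsMatch(model, valGraphs)
  prep <- prepareGraphs(trainGraphs, config)
  prepVal <- prepareGraphs(valGraphs, config)
  yVal <- vapply(valGraphs, function(g) as.numeric(g@label == "edited"), 1)
  params <- model@params
  bn <- new.env(parent = emptyenv())
  adam <- .adamInit(params)
  n <- length(trainGraphs)
  grid <- thresholdGrid()
  histRows <- vector("list", config$epochs)
  epochLog <- vector("list", config$epochs)
  best <- list(f1 = -Inf, epoch = NA_integer_, threshold = NA_real_,
               params = NULL, bn = NULL)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    lossSum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batchSize - 1L, n)]
      batch <- .assembleBatch(prep, idx)
      fw <- .forwardBatch(params, config, bn, batch, training = TRUE)
      loss <- adBCEWithLogits(fw$tape, fw$logits, batch$y)
      lossSum <- lossSum + as.numeric(adVal(fw$tape, loss)) * length(idx)
      grads <- .gradsByName(fw, loss)
      upd <- .adamStep(params, grads, adam, config$lr, config$weightDecay)
      params <- upd$params
      adam <- upd$state
    }
    # validation pass (eval mode)
    evalModel <- new("AdarEditModel", config = config, params = params,
                     bn = as.list(bn), layoutVersion = LAYOUT_VERSION)
    scores <- .predictPrepared(evalModel, prepVal)
    mt <- metricTable(scores, yVal, grid)
    mt$epoch <- ep
    histRows[[ep]] <- mt[, c("epoch", "threshold", "accuracy", "f1",
                             "precision", "recall", "specificity")]
    tf <- evaluateThresholdFree(scores, yVal)
    bestRow <- mt[order(-mt$f1, mt$threshold)[1L], ]
    epochLog[[ep]] <- data.frame(epoch = ep, loss = lossSum / n,
                                 auroc = tf[["auroc"]], auprc = tf[["auprc"]],
                                 bestF1 = bestRow$f1,
                                 bestThreshold = bestRow$threshold)
    if (bestRow$f1 > best$f1 + 1e-15) {
      best <- list(f1 = bestRow$f1, epoch = ep, threshold = bestRow$threshold,
                   params = params, bn = as.list(bn))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val F1 %.4f (t=%.3f)  AUROC %.4f",
                      ep, lossSum / n, bestRow$f1, bestRow$threshold,
                      tf[["auroc"]]))
    }
  }
  history <- do.call(rbind, histRows)
  search <- selectCheckpoint(history)
  bestModel <- new("AdarEditModel", config = config, params = best$params,
                   bn = best$bn, layoutVersion = LAYOUT_VERSION)
  finalModel <- new("AdarEditModel", config = config, params = params,
                    bn = as.list(bn), layoutVersion = LAYOUT_VERSION)
  list(model = bestModel, search = search,
       history = do.call(rbind, epochLog), finalModel = finalModel)
}

# predict from already-prepared graphs (internal fast path)
.predictPrepared <- function(model, prep, chunkSize = 512L) {
  bn <- list2env(model@bn, parent = emptyenv())
  out <- numeric(length(prep))
  starts <- seq(1L, length(prep), by = chunkSize)
  for (s in starts) {
    idx <- s:min(s + chunkSize - 1L, length(prep))
    batch <- .assembleBatch(prep, idx)
    fw <- .forwardBatch(model@params, model@config, bn, batch,
                        training = FALSE)
    z <- as.numeric(adVal(fw$tape, fw$logits))
    out[idx] <- 1 / (1 + exp(-z))
  }
  out
}

#' Evaluate a trained model on labeled graphs
#'
#' Scores the graphs, reports the full metric table over the threshold grid,
#' the F1-best operating point and threshold-free AUROC/AUPRC. The operating
#' point is validation-tuned: treat these numbers as validation estimates
#' rather than unbiased test performance.
#'
#' @param model An [AdarEditModel-class].
#' @param graphs Labeled [SiteGraph-class] list.
#' @return List: \code{scores}, \code{labels}, \code{metricTable},
#'   \code{best} (row at the F1-optimal threshold), \code{auroc},
#'   \code{auprc}.
#' @export
evaluateModel <- function(model, graphs) {
  labs <- vapply(graphs, function(g) g@label, "")
  y <- as.numeric(labs == "edited")
  scores <- predictProb(model, graphs)
  mt <- metricTable(scores, y)
  bestRow <- mt[order(-mt$f1, mt$threshold)[1L], ]
  tf <- evaluateThresholdFree(scores, y)
  list(scores = scores, labels = y, metricTable = mt, best = bestRow,
       auroc = tf[["auroc"]], auprc = tf[["auprc"]])
}
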