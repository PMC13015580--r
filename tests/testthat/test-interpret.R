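test_that("positional attention features are 101-long, in [0,1], zero-padded", {
  m <- initModel(modelConfig("baseline", hiddenDim = 16L, seed = 9L))
  gs <- tinyLabeledGraphs("baseline")
  f <- positionalAttentionFeatures(m, gs[[1L]], window = 50L)
  expect_length(f, 101L)
  expect_true(all(f >= 0 & f <= 1))
  # tiny duplex: every offset beyond the sequence is exactly 0
  L <- nrow(gs[[1L]]@nodeFeatures)
  tgt <- gs[[1L]]@targetIndex
  outOfRange <- abs(as.integer(names(f))) > 0 &
    (tgt + as.integer(names(f)) < 1L | tgt + as.integer(names(f)) > L)
  expect_true(all(f[outOfRange] == 0))
  expect_gt(max(f), 0)
  expect_error(positionalAttentionFeatures(m, gs[[1L]], window = 0L),
               "positive")
})

test_that("positional features agree with brute-force re-aggregation of raw coefficients", {
  m <- initModel(modelConfig("baseline", hiddenDim = 16L, seed = 10L))
  for (seed in 1:30) {
    d <- randomDuplex(seed, lengthRange = c(40L, 90L))
    pt <- parseDotBracket(d@dotBracket)
    apos <- adenosinePositions(d)
    if (length(apos) == 0L) next
    g <- buildBaselineGraph(d, pt, apos[sample.int(length(apos), 1L)])
    f <- positionalAttentionFeatures(m, g, window = 50L)
    att <- exportAttention(m, g, layer = 1L)
    att <- att[!att$isSelf, ]
    L <- nrow(g@nodeFeatures)
    for (off in seq(-50L, 50L)) {
      pos <- g@targetIndex + off
      want <- if (pos < 1L || pos > L) 0 else {
        inc <- att$mean[att$dst == pos]
        if (length(inc)) max(inc) else 0
      }
      expect_equal(unname(f[as.character(off)]), want, tolerance = 1e-12)
    }
  }
})

# a separable construction: the feature at offset 0 determines the label
separableFeatures <- function(n = 240L, seed = 1L) {
  set.seed(seed)
  f <- matrix(stats::runif(n * 101L, 0, 0.45), n, 101L)
  colnames(f) <- -50:50
  y <- stats::rbinom(n, 1L, 0.5)
  f[y == 1L, 51L] <- stats::runif(sum(y), 0.55, 1)
  list(features = f, labels = y)
}

test_that("the attention classifier learns a separable construction and is seeded", {
  sep <- separableFeatures()
  fit1 <- fitAttentionClassifier(sep$features, sep$labels, seed = 2L)
  fit2 <- fitAttentionClassifier(sep$features, sep$labels, seed = 2L)
  expect_gte(fit1$metrics[["f1"]], 0.95)
  expect_identical(fit1$metrics, fit2$metrics)
  expect_error(fitAttentionClassifier(sep$features, rep(1, 240L), 1L),
               "single-class")
  expect_error(fitAttentionClassifier(sep$features[1:20, ], sep$labels[1:20]),
               "at least 50")
})

test_that("Shapley ranking is a permutation of all offsets, additive, and finds the signal", {
  sep <- separableFeatures(seed = 3L)
  fit <- fitAttentionClassifier(sep$features, sep$labels, seed = 3L)
  sr <- shapRank(fit, sep$features)
  expect_setequal(sr$ranking$offset, -50:50)
  expect_identical(sr$ranking$offset[1L], 0L)     # the only informative feature
  expect_true(all(diff(sr$ranking$meanAbsShap) <= 1e-12))
  # additivity: contributions + bias reconstruct the margin
  margin <- stats::predict(fit$classifier,
                           xgboost::xgb.DMatrix(sep$features),
                           outputmargin = TRUE)
  expect_equal(unname(rowSums(sr$shap)), unname(margin), tolerance = 1e-3)
  expect_error(shapRank(list(classifier = NULL), sep$features), "fitted")
})

test_that("top-k retraining keeps k features and full power on the separable case", {
  sep <- separableFeatures(seed = 4L)
  fit <- fitAttentionClassifier(sep$features, sep$labels, seed = 4L)
  sr <- shapRank(fit, sep$features)
  topk <- retrainTopK(sep$features, sep$labels, sr$ranking, k = 20L, seed = 4L)
  expect_length(topk$keptOffsets, 20L)
  expect_true(0L %in% topk$keptOffsets)
  expect_gte(topk$metrics[["f1"]], fit$metrics[["f1"]] - 0.02)
  expect_error(retrainTopK(sep$features, sep$labels, sr$ranking, k = 0L), "positive")
  # k = all features reproduces the full model exactly (same seed, same data)
  allk <- retrainTopK(sep$features, sep$labels, sr$ranking, k = 101L, seed = 4L)
  expect_length(allk$keptOffsets, 101L)
})

test_that("attention profiles partition counts across strata", {
  m <- initModel(modelConfig("baseline", hiddenDim = 16L, seed = 12L))
  gs <- tinyLabeledGraphs("baseline")
  prof <- attentionProfiles(m, gs, window = 10L)
  offs <- -10:10
  lab <- prof[prof$stratum_type == "label", ]
  base <- prof[prof$stratum_type == "base", ]
  pairing <- prof[prof$stratum_type == "pairing", ]
  for (o in offs) {
    lo <- lab[lab$offset == o, ]
    # edited + non_edited counts partition the in-bounds graphs
    inBounds <- sum(vapply(gs, function(g) {
      p <- g@targetIndex + o
      p >= 1L && p <= nrow(g@nodeFeatures)
    }, TRUE))
    expect_identical(sum(lo$count), inBounds)
    expect_identical(sum(base$count[base$offset == o]), inBounds)  # no Ns here
    expect_identical(sum(pairing$count[pairing$offset == o]), inBounds)
  }
  # all-identical graphs: zero variance within a stratum (means well-defined)
  same <- rep(gs[1L], 3L)
  p2 <- attentionProfiles(m, same, window = 5L)
  ed <- p2[p2$stratum_type == "label" & p2$stratum == "edited", ]
  expect_true(all(ed$count %in% c(0L, 3L)))
})
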