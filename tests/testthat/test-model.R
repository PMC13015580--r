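test_that("both architectures produce probabilities in (0,1), deterministically in eval mode", {
  for (fs in c("baseline", "bioaware")) {
    cfg <- modelConfig(fs, hiddenDim = 16L, seed = 5L,
                      globalAttention = (fs == "bioaware"))
    m <- initModel(cfg)
    gs <- tinyLabeledGraphs(fs)
    p1 <- predictProb(m, gs)
    p2 <- predictProb(m, gs)
    expect_identical(p1, p2)
    expect_true(all(p1 > 0 & p1 < 1))
  }
})

test_that("feature-dimension mismatch is refused", {
  cfg <- modelConfig("baseline", hiddenDim = 16L)
  m <- initModel(cfg)
  expect_error(predictProb(m, tinyLabeledGraphs("bioaware")),
               "does not match")
})

test_that("output is invariant to edge storage order", {
  for (fs in c("baseline", "bioaware")) {
    cfg <- modelConfig(fs, hiddenDim = 16L, seed = 8L)
    m <- initModel(cfg)
    g <- tinyLabeledGraphs(fs)[[2L]]
    set.seed(31)
    perm <- sample(length(g@edgeSrc))
    g2 <- g
    g2@edgeSrc <- g@edgeSrc[perm]
    g2@edgeDst <- g@edgeDst[perm]
    g2@edgeType <- g@edgeType[perm]
    if (ncol(g@edgeScalars) > 0L) {
      g2@edgeScalars <- g@edgeScalars[perm, , drop = FALSE]
    }
    expect_equal(predictProb(m, g), predictProb(m, g2), tolerance = 1e-10)
  }
})

test_that("edge encoder emits 16-dim representations, equal for identical edges", {
  cfg <- modelConfig("bioaware", hiddenDim = 16L, seed = 3L)
  m <- initModel(cfg)
  g <- tinyLabeledGraphs("bioaware")[[1L]]
  er <- encodeEdges(m, g)
  expect_identical(ncol(er), 16L)
  expect_identical(nrow(er), length(g@edgeSrc))
  # MLP input arithmetic: 6 (type embedding) + 10 (scalars) = 16
  expect_identical(ncol(m@params$We1), 16L)
  expect_identical(nrow(m@params$We1), 16L)
  # duplicate an edge record -> identical representation
  i <- which(g@edgeType == "WC_PAIR")[1L]
  j <- which(g@edgeType == "WC_PAIR")[2L]
  g@edgeScalars[j, ] <- g@edgeScalars[i, ]
  er2 <- encodeEdges(m, g)
  expect_equal(er2[i, ], er2[j, ])
  g@edgeType[1L] <- "MYSTERY"
  expect_error(encodeEdges(m, g), "unknown edge type")
})

test_that("sequence branch is 48-dim and blind to masked padding", {
  cfg <- modelConfig("bioaware", hiddenDim = 16L, seed = 4L)
  m <- initModel(cfg)
  s <- "GCAAGCAAGCUUGC"
  e1 <- sequenceBranch(m, s)
  expect_length(e1, 48L)
  e2 <- sequenceBranch(m, paste0(s, "NNNNNNN"), validLength = nchar(s))
  e3 <- sequenceBranch(m, paste0(s, "GGGGGGG"), validLength = nchar(s))
  expect_identical(e1, e2)
  expect_identical(e1, e3)
  expect_error(sequenceBranch(m, "", validLength = 0L), "empty")
  # both kernel widths feed pooling: 48 + 48 channels project to 48
  expect_identical(nrow(m@params$Wproj), 96L)
})

test_that("exported attention is a per-destination softmax over incoming edges", {
  for (fs in c("baseline", "bioaware")) {
    cfg <- modelConfig(fs, hiddenDim = 16L, seed = 6L)
    m <- initModel(cfg)
    g <- tinyLabeledGraphs(fs)[[1L]]
    att <- exportAttention(m, g, layer = 1L)
    heads <- grep("^head", names(att), value = TRUE)
    expect_length(heads, cfg$heads)
    expect_true(all(as.matrix(att[, heads]) >= 0))
    # coefficient rows = directed edges + one self-loop per node
    expect_identical(nrow(att),
                     length(g@edgeSrc) + nrow(g@nodeFeatures))
    for (h in heads) {
      sums <- tapply(att[[h]], att$dst, sum)
      expect_true(all(abs(sums - 1) < 1e-5))
    }
    expect_error(exportAttention(m, g, layer = 9L), "layer")
  }
})

test_that("autodiff gradients match finite differences (bio-aware, smooth sample)", {
  ns <- asNamespace("adaredit")
  cfg <- modelConfig("bioaware", hiddenDim = 8L, heads = 2L, dropout = 0,
                     cnnChannels = 6L, seqEmbedDim = 5L, fusionHidden = 7L,
                     globalAttention = TRUE, seed = 4L)
  m <- initModel(cfg)
  gs <- tinyLabeledGraphs("bioaware")
  prep <- ns$prepareGraphs(gs, cfg)
  batch <- ns$.assembleBatch(prep, seq_along(gs))
  bn <- new.env()
  lossOf <- function(params) {
    fw <- ns$.forwardBatch(params, cfg, bn, batch, training = TRUE)
    l <- ns$adBCEWithLogits(fw$tape, fw$logits, batch$y)
    list(val = as.numeric(ns$adVal(fw$tape, l)), fw = fw, l = l)
  }
  r <- lossOf(m@params)
  grads <- ns$adBackward(r$fw$tape, r$l)
  set.seed(99)
  worst <- 0
  for (nm in names(m@params)) {
    g <- grads[[r$fw$pid[[nm]]]]
    expect_false(is.null(g), label = paste("gradient reaches", nm))
    for (k in sample(length(m@params[[nm]]), min(3L, length(m@params[[nm]])))) {
      eps <- 1e-5
      up <- m@params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- m@params; dn[[nm]][k] <- dn[[nm]][k] - eps
      fd <- (lossOf(up)$val - lossOf(dn)$val) / (2 * eps)
      err <- abs(fd - g[k]) / max(1e-6, abs(fd), abs(g[k]))
      worst <- max(worst, err)
    }
  }
  # ReLU/LeakyReLU kinks make a handful of finite differences noisy;
  # a wrong vector-Jacobian product would show O(1) errors
  expect_lt(worst, 0.05)
})

test_that("every parameter group receives nonzero gradient on a training batch", {
  ns <- asNamespace("adaredit")
  for (fs in c("baseline", "bioaware")) {
    cfg <- modelConfig(fs, hiddenDim = 16L, dropout = 0,
                       globalAttention = (fs == "bioaware"), seed = 12L)
    m <- initModel(cfg)
    gs <- tinyLabeledGraphs(fs)
    prep <- ns$prepareGraphs(gs, cfg)
    batch <- ns$.assembleBatch(prep, seq_along(gs))
    bn <- new.env()
    fw <- ns$.forwardBatch(m@params, cfg, bn, batch, training = TRUE)
    l <- ns$adBCEWithLogits(fw$tape, fw$logits, batch$y)
    grads <- ns$adBackward(fw$tape, l)
    for (nm in names(m@params)) {
      g <- grads[[fw$pid[[nm]]]]
      expect_false(is.null(g), label = paste(fs, nm, "reached"))
      expect_gt(max(abs(g)), 0, label = paste(fs, nm, "nonzero"))
    }
  }
})

test_that("checkpoint round trip restores identical eval-mode outputs", {
  all_ <- smallPlantedSet(n = 10L, seed = 31L)$graphs
  lab <- vapply(all_, siteLabel, "")
  gs <- c(all_[which(lab == "edited")[1:6]],
          all_[which(lab == "non_edited")[1:6]])
  cfg <- modelConfig("baseline", hiddenDim = 16L, epochs = 2L,
                     batchSize = 6L, seed = 3L)
  res <- trainModel(gs[c(1:4, 7:10)], gs[c(5:6, 11:12)], cfg)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(res$model, path)
  back <- loadCheckpoint(path)
  expect_identical(predictProb(back, gs), predictProb(res$model, gs))
  # layout-mismatch refusal
  x <- readRDS(path)
  x$layoutVersion <- "other-layout-0"
  saveRDS(x, path)
  expect_error(loadCheckpoint(path), "layout")
})

test_that("the model can overfit a small planted set to training F1 = 1", {
  set <- smallPlantedSet(n = 40L, seed = 17L)
  gs <- set$graphs
  lab <- vapply(gs, siteLabel, "")
  # balance to 25/25
  idx <- c(which(lab == "edited")[1:25], which(lab == "non_edited")[1:25])
  gs <- gs[idx[!is.na(idx)]]
  cfg <- modelConfig("baseline", epochs = 120L, batchSize = 25L, seed = 2L,
                     dropout = 0.0)
  res <- trainModel(gs, gs, cfg)   # capacity check: evaluate on train
  expect_gte(res$search@bestF1, 1.0)
})
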