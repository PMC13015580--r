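# an initialized (untrained) model suffices for the mechanical contracts here
mutModel <- function(fs = "baseline") {
  initModel(modelConfig(fs, hiddenDim = 16L, seed = 44L))
}

test_that("high-confidence selection is strict and label-restricted", {
  m <- mutModel()
  gs <- tinyLabeledGraphs("baseline")
  scores <- predictProb(m, gs)
  labs <- vapply(gs, siteLabel, "")
  # cutoff exactly at a site's score excludes it
  hc <- selectHighConfidence(m, gs, cutoff = scores[1L])
  expect_false(any(vapply(hc, function(g) {
    identical(predictProb(m, g), scores[1L]) && g@targetIndex == gs[[1L]]@targetIndex
  }, TRUE)))
  # only edited-labeled graphs can be returned however high the score
  hcAll <- selectHighConfidence(m, gs, cutoff = 0)
  expect_true(all(vapply(hcAll, siteLabel, "") == "edited"))
  expect_identical(selectHighConfidence(m, list(), 0.7), list())
})

test_that("perturbations never mutate their input graphs", {
  for (fs in c("baseline", "bioaware")) {
    m <- mutModel(fs)
    gs <- tinyLabeledGraphs(fs)[1:2]
    snapshot <- lapply(gs, function(g) list(g@nodeFeatures, g@edgeSrc,
                                            g@edgeDst, g@edgeType,
                                            g@edgeScalars, g@sequence))
    invisible(sequenceMutagenesis(m, gs, window = 2L))
    invisible(structureCoupledMutagenesis(m, gs, window = 2L))
    invisible(positionalPerturbation(m, gs, range = 5L))
    after <- lapply(gs, function(g) list(g@nodeFeatures, g@edgeSrc,
                                         g@edgeDst, g@edgeType,
                                         g@edgeScalars, g@sequence))
    expect_identical(snapshot, after)
  }
})

test_that("sequence mutagenesis has the documented shape and identity behavior", {
  m <- mutModel()
  gs <- tinyLabeledGraphs("baseline")[1:3]
  pm <- sequenceMutagenesis(m, gs, window = 3L, center = FALSE)
  expect_identical(pm@offsets, c(-3L, -2L, -1L, 1L, 2L, 3L))  # no offset 0
  expect_identical(dim(pm@values), c(6L, 4L))
  # identity substitutions contribute exactly 0, so a site whose window is
  # all-A would give a zero A column; verify on a constructed case
  d <- duplex("aaa", "AAAAAAA", ".......")
  pt <- parseDotBracket(d@dotBracket)
  gA <- buildBaselineGraph(d, pt, 4L, "edited")
  pmA <- sequenceMutagenesis(m, list(gA), window = 1L, center = FALSE)
  expect_identical(pmA@values[, 1L], c(0, 0))   # A -> A is a no-op
  centered <- sequenceMutagenesis(m, gs, window = 3L, center = TRUE)
  expect_true(all(abs(rowMeans(centered@values)) < 1e-9))
  expect_error(sequenceMutagenesis(m, list(), 3L), "empty")
})

test_that("structure-coupled mutagenesis disrupts invalid pairs and retypes valid ones", {
  ns <- asNamespace("adaredit")
  d <- duplex("s", "GAAAAUC", "((...))")  # pairs: G1:C7 (WC), A2:U6 (WC)
  pt <- parseDotBracket(d@dotBracket)
  ann <- annotateStructure(d, pt)
  g <- buildBioawareGraph(d, pt, ann, target = 4L, label = "edited")
  # G1 -> A makes A:C invalid: both endpoints unpaired, 2 directed edges gone
  mut <- ns$.mutateGraph(g, 1L, "A", structureCoupled = TRUE)
  expect_identical(sum(mut@edgeType != "BACKBONE"),
                   sum(g@edgeType != "BACKBONE") - 2L)
  expect_identical(unname(mut@nodeFeatures[c(1L, 7L), 6]), c(0, 0))
  expect_identical(unname(mut@nodeFeatures[c(1L, 7L), 22]), c(0, 0))
  # A2 -> G keeps a valid wobble with U6: retained and retyped
  mut2 <- ns$.mutateGraph(g, 2L, "G", structureCoupled = TRUE)
  expect_identical(sum(mut2@edgeType != "BACKBONE"),
                   sum(g@edgeType != "BACKBONE"))
  pairEdge <- which(mut2@edgeSrc == 2L & mut2@edgeDst == 6L)
  expect_identical(mut2@edgeType[pairEdge], "WOBBLE_PAIR")
  expect_equal(mut2@edgeScalars[pairEdge, 8], -1 / 3)
  # unpaired position: structural state unchanged
  mut3 <- ns$.mutateGraph(g, 3L, "G", structureCoupled = TRUE)
  expect_identical(mut3@edgeType, g@edgeType)
  expect_identical(mut3@nodeFeatures[, 6], g@nodeFeatures[, 6])
})

test_that("sequence-only and structure-coupled analyses coincide on unpaired windows", {
  m <- mutModel()
  d <- duplex("u", "GGGAAUAAAUCCC", "(((.......)))")
  pt <- parseDotBracket(d@dotBracket)
  g <- buildBaselineGraph(d, pt, 7L, "edited")  # -3..+3 all unpaired
  a <- sequenceMutagenesis(m, list(g), window = 3L, center = FALSE)
  b <- structureCoupledMutagenesis(m, list(g), window = 3L, center = FALSE)
  expect_identical(a@values, b@values)
})

test_that("positional perturbation reports the full offset range with counts", {
  m <- mutModel()
  gs <- tinyLabeledGraphs("baseline")
  curve <- positionalPerturbation(m, gs, range = 40L)
  expect_identical(nrow(curve), 81L)
  expect_identical(curve$offset, -40:40)
  expect_true(all(is.na(curve$delta[curve$count == 0L])))
  expect_true(all(!is.na(curve$delta[curve$count > 0L])))
  # natively unpaired positions contribute nothing
  d <- tinyDuplex()
  pt <- parseDotBracket(d@dotBracket)
  unpairedOffsets <- which(is.na(pt)) - gs[[1L]]@targetIndex
  sub <- positionalPerturbation(m, gs[1L], range = 5L)
  for (o in intersect(unpairedOffsets, -5:5)) {
    expect_identical(sub$count[sub$offset == o], 0L)
  }
})

test_that("pair interaction scan covers all 16 combinations with validity-coupled structure", {
  m <- mutModel("bioaware")
  d <- duplex("p", "GGGGAUAUCCCC", "((((....))))")
  pt <- parseDotBracket(d@dotBracket)
  ann <- annotateStructure(d, pt)
  # target at 5 (A, unpaired); offset -1 lands on position 4 (paired to 9)
  g <- buildBioawareGraph(d, pt, ann, target = 5L, label = "edited")
  scan <- pairInteractionScan(m, list(g), offsets = -1L)
  mat <- scan[["-1"]]$matrix
  expect_identical(dim(mat), c(4L, 4L))
  expect_identical(scan[["-1"]]$nSites, 1L)
  expect_false(anyNA(mat))
  # spot-check the two structural states explicitly
  ns <- asNamespace("adaredit")
  gGC <- ns$.setBase(ns$.setBase(g, 4L, "G"), 9L, "C")
  gGC <- ns$.refreshPairAt(gGC, 4L)
  expect_equal(unname(mat["G", "C"]), predictProb(m, gGC))
  gAC <- ns$.setBase(ns$.setBase(g, 4L, "A"), 9L, "C")
  gAC <- ns$.removePairAt(gAC, 4L)
  expect_equal(unname(mat["A", "C"]), predictProb(m, gAC))
  # a site with no partner at the requested offset errors for that offset
  expect_error(pairInteractionScan(m, list(g), offsets = 0L), "no site has a partner")
})

test_that("position-wise centering zeroes row means and is idempotent", {
  m <- matrix(c(1, 2, 3, 5), 2L, byrow = TRUE)
  c1 <- centerByPosition(m)
  expect_equal(c1, matrix(c(-0.5, 0.5, -1, 1), 2L, byrow = TRUE))
  expect_equal(centerByPosition(c1), c1)
  expect_equal(centerByPosition(matrix(7, 3L, 4L)),
               matrix(0, 3L, 4L))
})
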