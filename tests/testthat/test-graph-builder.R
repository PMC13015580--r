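test_that("baseline graph has the documented layout and edge counts", {
  d <- duplex("d", "GCAAGC", "((..))")
  pt <- parseDotBracket(d@dotBracket)
  g <- buildBaselineGraph(d, pt, target = 4L)
  expect_identical(dim(g@nodeFeatures), c(6L, 8L))
  expect_identical(sum(g@edgeType == "BACKBONE"), 10L)   # 2(L-1)
  expect_identical(sum(g@edgeType != "BACKBONE"), 4L)    # 2 * pairs
  # one-hot block sums to 1; exactly one target flag; its rel dist is 0
  expect_true(all(rowSums(g@nodeFeatures[, 1:5]) == 1))
  expect_identical(sum(g@nodeFeatures[, 8]), 1)
  expect_identical(g@nodeFeatures[4L, 7], 0)
  expect_identical(g@nodeFeatures[4L, 8], 1)
  # pairing flags follow the structure
  expect_identical(g@nodeFeatures[, 6], c(1, 1, 0, 0, 1, 1))
})

test_that("target must be an in-range adenosine", {
  d <- duplex("d", "GCAAGC", "((..))")
  pt <- parseDotBracket(d@dotBracket)
  expect_error(buildBaselineGraph(d, pt, target = 2L), "not an adenosine")
  expect_error(buildBaselineGraph(d, pt, target = 9L), "out of range")
})

test_that("bio-aware nodes carry neighbor one-hots with N at boundaries", {
  d <- duplex("d", "GCAAGC", "((..))")
  pt <- parseDotBracket(d@dotBracket)
  g <- buildBioawareGraph(d, pt, annotateStructure(d, pt), target = 3L)
  expect_identical(dim(g@nodeFeatures), c(6L, 22L))
  # node 1: 5' neighbor is the boundary -> N (5th slot of the prev block)
  expect_identical(g@nodeFeatures[1L, 9:13], c(0, 0, 0, 0, 1))
  # node 1's 3' neighbor is C
  expect_identical(g@nodeFeatures[1L, 14:18], c(0, 1, 0, 0, 0))
  # node 3 (A): prev = C, next = A
  expect_identical(g@nodeFeatures[3L, 9:13], c(0, 1, 0, 0, 0))
  expect_identical(g@nodeFeatures[3L, 14:18], c(1, 0, 0, 0, 0))
})

test_that("bio-aware pair edges are typed and energies scaled into [-1, 0]", {
  d <- duplex("d", "GUAAAC", "((..))")  # pairs G:C (WC) and U:A (WC)
  pt <- parseDotBracket(d@dotBracket)
  g <- buildBioawareGraph(d, pt, annotateStructure(d, pt), target = 3L)
  pairIdx <- which(g@edgeType != "BACKBONE")
  expect_setequal(unique(g@edgeType[pairIdx]), "WC_PAIR")
  dG <- duplex("g", "GCAAGU", "((..))")  # outer pair G:U -> wobble
  ptG <- parseDotBracket(dG@dotBracket)
  gg <- buildBioawareGraph(dG, ptG, annotateStructure(dG, ptG), target = 3L)
  wob <- which(gg@edgeType == "WOBBLE_PAIR")
  expect_identical(length(wob), 2L)
  expect_equal(unique(gg@edgeScalars[wob, 8]), -1 / 3)
  # every feature value within [-1, 1] after the decided scalings
  expect_true(all(abs(gg@nodeFeatures) <= 1))
  expect_true(all(abs(gg@edgeScalars) <= 1))
})

test_that("noncanonical structural pairs are kept as WC_PAIR with zero energy", {
  d <- duplex("d", "ACAAGC", "((..))")  # outer pair A:C is invalid
  pt <- parseDotBracket(d@dotBracket)
  expect_message(
    g <- buildBioawareGraph(d, pt, annotateStructure(d, pt), target = 3L),
    "noncanonical")
  bad <- which(g@edgeSrc == 1L & g@edgeDst == 6L)
  expect_identical(g@edgeType[bad], "WC_PAIR")
  expect_identical(g@edgeScalars[bad, 8], 0)
})

test_that("edge-count formulas hold on random synthetic duplexes", {
  for (seed in 1:100) {
    d <- randomDuplex(seed)
    pt <- parseDotBracket(d@dotBracket)
    apos <- adenosinePositions(d)
    if (length(apos) == 0L) next
    g <- buildBaselineGraph(d, pt, apos[1L])
    L <- length(d)
    nPairs <- sum(!is.na(pt)) / 2L
    expect_identical(sum(g@edgeType == "BACKBONE"), 2L * (L - 1L))
    expect_identical(sum(g@edgeType != "BACKBONE"), as.integer(2L * nPairs))
    expect_true(all(abs(g@nodeFeatures) <= 1))
  }
})

test_that("graphs for two targets differ only in the position-centric columns", {
  d <- tinyDuplex()
  pt <- parseDotBracket(d@dotBracket)
  gs <- graphsForDuplex(d, pt, targets = adenosinePositions(d)[1:2],
                        featureSet = "baseline")
  expect_identical(length(gs), 2L)
  expect_identical(gs[[1L]]@edgeSrc, gs[[2L]]@edgeSrc)
  expect_identical(gs[[1L]]@edgeDst, gs[[2L]]@edgeDst)
  diffCols <- which(colSums(gs[[1L]]@nodeFeatures != gs[[2L]]@nodeFeatures) > 0)
  expect_true(all(diffCols %in% c(7L, 8L)))
  expect_identical(graphsForDuplex(d, pt, targets = integer(0)), list())
})

test_that("graph-set serialization round trip is bit-exact", {
  d <- randomDuplex(42L)
  pt <- parseDotBracket(d@dotBracket)
  ann <- annotateStructure(d, pt)
  apos <- adenosinePositions(d)[1:3]
  gs <- graphsForDuplex(d, pt, ann, targets = apos, featureSet = "bioaware",
                        labels = c("edited", "non_edited", NA))
  dir <- tempfile("gset")
  writeGraphSet(gs, dir)
  back <- readGraphSet(dir)
  expect_identical(length(back), 3L)
  for (k in seq_along(gs)) {
    expect_identical(back[[k]]@nodeFeatures, gs[[k]]@nodeFeatures)
    expect_identical(back[[k]]@edgeScalars, gs[[k]]@edgeScalars)
    expect_identical(back[[k]]@edgeSrc, gs[[k]]@edgeSrc)
    expect_identical(back[[k]]@edgeType, gs[[k]]@edgeType)
    expect_identical(back[[k]]@label, gs[[k]]@label)
    expect_identical(back[[k]]@sequence, gs[[k]]@sequence)
  }
})
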