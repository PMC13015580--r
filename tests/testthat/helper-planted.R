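# The planted-rule study: one strong-rule synthetic dataset (2,000 balanced
# sites), one baseline model trained on it, and the structure-shuffle
# ablation arm (same sites, dot-brackets permuted across duplexes before
# graph construction). Built lazily and cached for the whole test run because
# several acceptance properties share them.

.plantedCache <- new.env(parent = emptyenv())

plantedData <- function() {
  if (!is.null(.plantedCache$data)) return(.plantedCache$data)
  cfg <- syntheticConfig(nDuplexes = 1100L, seed = 11L)
  ds <- generateDataset(cfg, dir = tempfile("planted"))
  tab <- ds$editingTable
  tab$label <- classifySite(tab$editing_level, tab$coverage)
  tab <- tab[tab$label != "excluded", ]
  bal <- balanceClasses(tab, seed = 11L)
  set.seed(11)
  keep <- unlist(lapply(c("edited", "non_edited"), function(cl) {
    idx <- which(bal$label == cl)
    sample(idx, min(1000L, length(idx)))
  }))
  bal <- bal[sort(keep), ]
  sp <- splitDataset(bal, 0.8, seed = 11L)
  sp$val <- excludeOverlap(sp$train, sp$val)
  .plantedCache$data <- list(synth = ds, train = sp$train, val = sp$val)
  .plantedCache$data
}

plantedModel <- function() {
  if (!is.null(.plantedCache$model)) return(.plantedCache$model)
  pd <- plantedData()
  tr <- assembleGraphs(pd$synth$duplexes, pd$train, "baseline")
  va <- assembleGraphs(pd$synth$duplexes, pd$val, "baseline")
  cfg <- modelConfig("baseline", epochs = 40L, seed = 7L)
  res <- trainModel(tr, va, cfg)
  .plantedCache$model <- list(res = res, trainGraphs = tr, valGraphs = va)
  .plantedCache$model
}

# identical conditions to plantedModel except that structures are permuted
# across duplexes, decoupling pairing information from the sequences
plantedShuffled <- function() {
  if (!is.null(.plantedCache$shuffled)) return(.plantedCache$shuffled)
  pd <- plantedData()
  cfg <- modelConfig("baseline", epochs = 40L, seed = 7L)
  res <- trainModel(
    assembleGraphs(pd$synth$duplexes, pd$train, "baseline",
                   shuffleStructures = TRUE, seed = 3L),
    assembleGraphs(pd$synth$duplexes, pd$val, "baseline",
                   shuffleStructures = TRUE, seed = 3L),
    cfg)
  .plantedCache$shuffled <- res
  .plantedCache$shuffled
}
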