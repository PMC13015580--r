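# Shared fixtures and independent oracles used across test files.

# a small hairpin with 6 adenosines, used throughout the model tests
tinyDuplex <- function() {
  duplex("tiny", "GCAAGCAAGCAAGCUUGCUUGC", "(((((((((....)))))))))")
}

# random nested structure via the synthetic generator (guaranteed parseable)
randomDuplex <- function(seed, lengthRange = c(60L, 120L)) {
  cfg <- syntheticConfig(nDuplexes = 1L, lengthRange = lengthRange,
                         seed = seed)
  generateDuplex(cfg, seed = seed, id = paste0("rand_", seed))
}

# ---- brute-force structural oracles (deliberately naive re-implementations) -

# helix length by direct expansion around each pair
oracleStemLength <- function(pt) {
  L <- length(pt)
  out <- integer(L)
  for (i in seq_len(L)) {
    if (is.na(pt[i])) next
    a <- min(i, pt[i]); b <- max(i, pt[i])
    n <- 1L
    x <- a - 1L; y <- b + 1L          # extend outward
    while (x >= 1L && y <= L && !is.na(pt[x]) && pt[x] == y) {
      n <- n + 1L; x <- x - 1L; y <- y + 1L
    }
    x <- a + 1L; y <- b - 1L          # extend inward
    while (x < y && !is.na(pt[x]) && pt[x] == y) {
      n <- n + 1L; x <- x + 1L; y <- y - 1L
    }
    out[i] <- n
  }
  out
}

oracleLoopLength <- function(pt) {
  L <- length(pt)
  out <- integer(L)
  for (i in seq_len(L)) {
    if (!is.na(pt[i])) next
    a <- i; while (a > 1L && is.na(pt[a - 1L])) a <- a - 1L
    b <- i; while (b < L && is.na(pt[b + 1L])) b <- b + 1L
    out[i] <- b - a + 1L
  }
  out
}

oracleDistToJunction <- function(pt) {
  L <- length(pt)
  paired <- !is.na(pt)
  vapply(seq_len(L), function(i) {
    for (k in seq_len(L)) {
      if (i - k >= 1L && paired[i - k] != paired[i]) return(k)
      if (i + k <= L && paired[i + k] != paired[i]) return(k)
    }
    L
  }, 1L)
}

# brute-force confusion-matrix metrics at one threshold
oracleMetrics <- function(scores, labels, t) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= t
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  sdiv <- function(a, b) if (b > 0) a / b else 0
  prec <- sdiv(tp, tp + fp); rec <- sdiv(tp, tp + fn)
  c(accuracy = sdiv(tp + tn, length(scores)),
    f1 = sdiv(2 * prec * rec, prec + rec),
    precision = prec, recall = rec, specificity = sdiv(tn, tn + fp))
}

# labeled baseline graphs on one duplex (for quick model tests)
tinyLabeledGraphs <- function(featureSet = "baseline") {
  d <- tinyDuplex()
  pt <- parseDotBracket(d@dotBracket)
  graphsForDuplex(d, pt, targets = adenosinePositions(d),
                  featureSet = featureSet,
                  labels = rep(c("edited", "non_edited"), 3L))
}

# small planted-rule training problem (distinct duplexes, fast to learn)
smallPlantedSet <- function(n = 50L, seed = 5L, featureSet = "baseline") {
  cfg <- syntheticConfig(nDuplexes = n, lengthRange = c(40L, 60L),
                         seed = seed)
  duplexes <- list()
  sites <- list()
  for (i in seq_len(n)) {
    d <- generateDuplex(cfg, seed = seed + i, id = paste0("p", i))
    pt <- parseDotBracket(d@dotBracket)
    tab <- plantLabels(d, pt, cfg, seed = seed + 1000L + i)
    tab$label <- classifySite(pmin(pmax(tab$editing_level, 0), 1), 10000L)
    tab <- tab[tab$label != "excluded", ]
    duplexes[[d@id]] <- d
    sites[[i]] <- tab
  }
  sites <- do.call(rbind, sites)
  list(duplexes = duplexes, sites = sites,
       graphs = assembleGraphs(duplexes, sites, featureSet))
}
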