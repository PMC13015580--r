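# Turning per-adenosine editing tables into class-labeled, balanced, split
# datasets. Site keys are (duplex_id, position) pairs; positions are 1-based.

#' Classify an adenosine by editing level and coverage
#'
#' A site is \code{edited} when its editing level is at least 15\% with at
#' least 100 informative reads, \code{non_edited} when the level is below 1\%
#' with at least 100 reads, and \code{excluded} otherwise (the intermediate
#' 1-15\% band, and any site with insufficient coverage).
#'
#' @param level Numeric editing level(s) in \code{[0, 1]}.
#' @param coverage Integer read coverage(s), non-negative.
#' @return Character vector over \code{edited / non_edited / excluded}.
#' @examples
#' classifySite(0.20, 150)   # edited
#' classifySite(0.005, 200)  # non_edited
#' classifySite(0.08, 500)   # excluded (intermediate band)
#' @export
classifySite <- function(level, coverage) {
  if (any(level < 0 | level > 1)) stop("editing level outside [0, 1]")
  if (any(coverage < 0)) stop("negative coverage")
  ifelse(coverage >= 100 & level >= 0.15, "edited",
         ifelse(coverage >= 100 & level < 0.01, "non_edited", "excluded"))
}

#' Read / write an editing table
#'
#' Tab-separated table with columns \code{duplex_id}, \code{position}
#' (1-based), \code{editing_level} in \code{[0,1]}, \code{coverage},
#' \code{context} (tissue or species label).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
readEditingTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("duplex_id", "position", "editing_level", "coverage", "context")
  if (!all(need %in% names(df))) {
    stop("editing table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$editing_level < 0 | df$editing_level > 1)) {
    stop("editing_level outside [0, 1] in ", path)
  }
  df
}

#' @rdname readEditingTable
#' @param table Editing-record data.frame.
#' @export
writeEditingTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.siteKeys <- function(sites) paste(sites$duplex_id, sites$position, sep = ":")

#' Balance classes by downsampling the majority class
#'
#' Downsamples the majority class uniformly without replacement so both
#' classes have equal counts (50\% each); the minority class is untouched.
#' Deterministic given \code{seed}.
#'
#' @param sites Data.frame of labeled sites with a \code{label} column over
#'   \code{edited / non_edited}.
#' @param seed Integer RNG seed.
#' @return The balanced data.frame (original row order preserved).
#' @export
balanceClasses <- function(sites, seed = 1L) {
  nE <- sum(sites$label == "edited")
  nN <- sum(sites$label == "non_edited")
  if (nE == 0L || nN == 0L) {
    stop("cannot balance: one class is empty (edited = ", nE,
         ", non_edited = ", nN, ")")
  }
  m <- min(nE, nN)
  keep <- logical(nrow(sites))
  set.seed(seed)
  for (cl in c("edited", "non_edited")) {
    idx <- which(sites$label == cl)
    if (length(idx) > m) idx <- sort(sample(idx, m))
    keep[idx] <- TRUE
  }
  sites[keep, , drop = FALSE]
}

#' Split sites 80:20 into train and validation sets
#'
#' Random split on site keys, deterministic given \code{seed}. The training
#' fraction defaults to 0.8 and \code{|train| = round(f * n)}.
#'
#' @param sites Data.frame of sites (needs \code{duplex_id}, \code{position}).
#' @param trainFraction Fraction of sites assigned to training, in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with data.frames \code{train} and \code{val}, plus
#'   \code{seed}; keys are disjoint.
#' @export
splitDataset <- function(sites, trainFraction = 0.8, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be in (0, 1)")
  }
  n <- nrow(sites)
  if (n < 5L) stop("need at least 5 sites to split")
  set.seed(seed)
  nTrain <- round(trainFraction * n)
  idx <- sample.int(n, nTrain)
  list(train = sites[sort(idx), , drop = FALSE],
       val = sites[setdiff(seq_len(n), idx), , drop = FALSE],
       seed = seed)
}

#' Remove validation sites whose key appears in the training set
#'
#' Guards evaluation against the trivial case where the same
#' (duplex, position) site is scored after being trained on.
#'
#' @param train Data.frame of training sites.
#' @param valCandidates Data.frame of candidate validation sites.
#' @return \code{valCandidates} with overlapping keys removed.
#' @export
excludeOverlap <- function(train, valCandidates) {
  valCandidates[!(.siteKeys(valCandidates) %in% .siteKeys(train)), ,
                drop = FALSE]
}

#' Merge nearby editing sites into clusters
#'
#' Consecutive sorted positions at most \code{gap} bases apart share a
#' cluster (the 1,000 bp merge rule used when assembling cross-species
#' regions).
#'
#' @param positions Sorted integer vector of genomic positions.
#' @param gap Maximum within-cluster spacing (default 1000).
#' @return List of integer vectors, ordered by position.
#' @examples
#' clusterSites(c(100, 900, 2500))  # list(c(100, 900), 2500)
#' @export
clusterSites <- function(positions, gap = 1000L) {
  if (length(positions) == 0L) return(list())
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  brk <- c(0L, cumsum(diff(positions) > gap))
  unname(split(as.integer(positions), brk))
}

#' Select the window with the highest density of editing sites
#'
#' Slides a fixed-length window over a region and returns the half-open
#' interval \code{[start, start + window)} (1-based start) containing the
#' largest number of edited positions; ties go to the leftmost window. With
#' no edited sites the window at the region start is returned.
#'
#' @param regionLength Total region length.
#' @param editedPositions Integer positions of edited sites (1-based).
#' @param window Window length, at most \code{regionLength}.
#' @return List with \code{start}, \code{end} (half-open: end excluded) and
#'   \code{count}.
#' @export
selectDenseSegment <- function(regionLength, editedPositions, window = 400L) {
  if (window > regionLength) stop("window exceeds region length")
  if (length(editedPositions) == 0L) {
    return(list(start = 1L, end = as.integer(1L + window), count = 0L))
  }
  nStarts <- regionLength - window + 1L
  cnt <- integer(nStarts)
  # each edited site p covers windows with start in [p - window + 1, p]
  lo <- pmax(editedPositions - window + 1L, 1L)
  hi <- pmin(editedPositions, nStarts)
  ok <- lo <= hi
  d <- integer(nStarts + 1L)
  for (k in which(ok)) {
    d[lo[k]] <- d[lo[k]] + 1L
    d[hi[k] + 1L] <- d[hi[k] + 1L] - 1L
  }
  cnt <- cumsum(d[seq_len(nStarts)])
  s <- which.max(cnt)  # leftmost maximum
  list(start = as.integer(s), end = as.integer(s + window),
       count = as.integer(cnt[s]))
}

#' Proximity-selected negative adenosines
#'
#' Adenosines that are not themselves edited but lie within \code{window}
#' bases (inclusive) of any edited site; these have implied read support and
#' serve as high-confidence non-edited examples.
#'
#' @param editedPositions Integer positions of edited sites.
#' @param adenosinePositions Integer positions of candidate adenosines.
#' @param window Maximum distance in bases (default 20, inclusive).
#' @return Sorted integer vector of negative positions.
#' @examples
#' negativesNear(50, c(45, 69, 72))  # 45 and 69; 72 is 22 bases away
#' @export
negativesNear <- function(editedPositions, adenosinePositions, window = 20L) {
  if (length(editedPositions) == 0L) return(integer(0))
  cand <- setdiff(adenosinePositions, editedPositions)
  if (length(cand) == 0L) return(integer(0))
  dmin <- vapply(cand, function(p) min(abs(p - editedPositions)), 0)
  sort(as.integer(cand[dmin <= window]))
}

#' Classify, balance and split an editing table
#'
#' End-to-end dataset construction: classify every record with
#' [classifySite()], drop excluded sites, balance classes by downsampling and
#' split 80:20 — the split applied after balancing. When several contexts or
#' duplicate keys are present, \code{collapse = "max"} keeps one record per
#' (duplex, position) with the maximum editing level, \code{"none"} pools
#' per-context records as independent examples.
#'
#' @param table Editing-record data.frame (see [readEditingTable()]).
#' @param trainFraction Training fraction for [splitDataset()].
#' @param seed Integer RNG seed controlling balancing and splitting.
#' @param collapse \code{"none"} (default: pooled per-context labels) or
#'   \code{"max"} (collapse duplicate keys by maximum level).
#' @return List: \code{train}, \code{val} (labeled site data.frames),
#'   \code{counts} (per-stage record counts), \code{seed}.
#' @export
buildLabeledDataset <- function(table, trainFraction = 0.8, seed = 1L,
                                collapse = c("none", "max")) {
  collapse <- match.arg(collapse)
  counts <- c(read = nrow(table))
  if (collapse == "max") {
    key <- .siteKeys(table)
    ord <- order(key, -table$editing_level)
    table <- table[ord, , drop = FALSE]
    table <- table[!duplicated(.siteKeys(table)), , drop = FALSE]
  }
  table$label <- classifySite(table$editing_level, table$coverage)
  counts["excluded_intermediate"] <-
    sum(table$label == "excluded" & table$coverage >= 100)
  counts["excluded_coverage"] <- sum(table$coverage < 100)
  table <- table[table$label != "excluded", , drop = FALSE]
  counts["edited"] <- sum(table$label == "edited")
  counts["non_edited"] <- sum(table$label == "non_edited")
  balanced <- balanceClasses(table, seed = seed)
  counts["balanced"] <- nrow(balanced)
  sp <- splitDataset(balanced, trainFraction = trainFraction, seed = seed)
  sp$val <- excludeOverlap(sp$train, sp$val)
  counts["train"] <- nrow(sp$train)
  counts["val"] <- nrow(sp$val)
  list(train = sp$train, val = sp$val, counts = counts, seed = seed)
}
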