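test_that("site classification follows the 15%/1%/100-read rules", {
  expect_identical(classifySite(0.20, 150L), "edited")
  expect_identical(classifySite(0.005, 200L), "non_edited")
  expect_identical(classifySite(0.08, 500L), "excluded")   # intermediate band
  expect_identical(classifySite(0.50, 40L), "excluded")    # low coverage
  expect_identical(classifySite(0.15, 100L), "edited")     # boundary inclusive
  expect_identical(classifySite(0.01, 100L), "excluded")   # 1% is intermediate
  expect_error(classifySite(1.2, 100L), "outside")
})

test_that("class balancing downsamples the majority only, deterministically", {
  sites <- data.frame(duplex_id = "d", position = 1:80,
                      label = rep(c("edited", "non_edited"), c(30L, 50L)))
  b1 <- balanceClasses(sites, seed = 3L)
  b2 <- balanceClasses(sites, seed = 3L)
  expect_identical(b1, b2)
  expect_identical(sum(b1$label == "edited"), 30L)
  expect_identical(sum(b1$label == "non_edited"), 30L)
  expect_true(all(which(sites$label == "edited") %in%
                    match(b1$position[b1$label == "edited"], sites$position)))
  even <- data.frame(duplex_id = "d", position = 1:80,
                     label = rep(c("edited", "non_edited"), 40L))
  expect_identical(nrow(balanceClasses(even, 1L)), 80L)
  empty <- data.frame(duplex_id = "d", position = 1:5,
                      label = rep("non_edited", 5L))
  expect_error(balanceClasses(empty, 1L), "one class is empty")
})

test_that("80:20 split is sized, disjoint and seed-reproducible", {
  sites <- data.frame(duplex_id = rep(c("a", "b"), 50L), position = 1:100)
  sp <- splitDataset(sites, 0.8, seed = 9L)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$val), 20L)
  k <- function(x) paste(x$duplex_id, x$position)
  expect_length(intersect(k(sp$train), k(sp$val)), 0L)
  sp2 <- splitDataset(sites, 0.8, seed = 9L)
  expect_identical(sp, sp2)
  sp10 <- splitDataset(sites[1:10, ], 0.8, seed = 1L)
  expect_identical(nrow(sp10$train), 8L)
  expect_error(splitDataset(sites, 1.5, 1L), "trainFraction")
  expect_error(splitDataset(sites[1:3, ], 0.8, 1L), "at least 5")
})

test_that("overlap exclusion removes exactly the shared keys", {
  train <- data.frame(duplex_id = c("a", "a", "b"), position = c(1L, 2L, 5L))
  val <- data.frame(duplex_id = c("a", "b", "b"), position = c(2L, 5L, 9L))
  out <- excludeOverlap(train, val)
  expect_identical(nrow(out), 1L)
  expect_identical(out$position, 9L)
  expect_identical(nrow(excludeOverlap(train, train)), 0L)
  disjoint <- data.frame(duplex_id = "c", position = 1:3)
  expect_identical(excludeOverlap(train, disjoint), disjoint)
  # one shared key drops the count by exactly 1
  val2 <- data.frame(duplex_id = c("a", "c"), position = c(1L, 1L))
  expect_identical(nrow(excludeOverlap(train, val2)), 1L)
})

test_that("1000 bp clustering merges by gap and keeps order", {
  expect_identical(clusterSites(c(100L, 900L, 2500L)),
                   list(c(100L, 900L), 2500L))
  expect_identical(clusterSites(7L), list(7L))
  expect_identical(clusterSites(integer(0)), list())
  # boundary: exactly 1000 apart stays merged
  expect_identical(length(clusterSites(c(0L, 1000L))), 1L)
  expect_identical(length(clusterSites(c(0L, 1001L))), 2L)
  expect_error(clusterSites(c(5L, 1L)), "sorted")
})

test_that("densest segment maximizes edited count with leftmost ties (vs brute force)", {
  bruteForce <- function(regionLength, sites, window) {
    best <- c(start = 1L, count = -1L)
    for (s in seq_len(regionLength - window + 1L)) {
      cnt <- sum(sites >= s & sites < s + window)
      if (cnt > best["count"]) best <- c(start = s, count = cnt)
    }
    best
  }
  set.seed(42)
  for (rep in 1:50) {
    regionLength <- sample(100:400, 1L)
    window <- sample(20:80, 1L)
    sites <- sort(sample(regionLength, sample(1:15, 1L)))
    got <- selectDenseSegment(regionLength, sites, window)
    want <- bruteForce(regionLength, sites, window)
    expect_identical(got$start, unname(want["start"]))
    expect_identical(got$count, unname(want["count"]))
    expect_identical(got$end - got$start, window)
  }
  # all sites inside one window; and the no-sites fallback
  one <- selectDenseSegment(200L, c(10L, 12L, 14L), 50L)
  expect_identical(one$count, 3L)
  expect_identical(selectDenseSegment(100L, integer(0), 30L)$start, 1L)
  expect_error(selectDenseSegment(10L, 1L, 50L), "window")
})

test_that("proximity negatives use an inclusive 20-base window", {
  expect_identical(negativesNear(50L, c(45L, 69L, 72L)), c(45L, 69L))
  expect_identical(negativesNear(integer(0), c(1L, 2L)), integer(0))
  expect_identical(negativesNear(100L, 120L), 120L)  # exactly 20 -> included
  expect_identical(negativesNear(100L, 121L), integer(0))
  expect_identical(negativesNear(c(10L, 40L), c(10L, 30L)), 30L)
})

test_that("classify -> balance -> split pipeline keeps labels consistent and keys disjoint", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(60:200, 1L)
    tab <- data.frame(
      duplex_id = sample(paste0("d", 1:8), n, replace = TRUE),
      position = sample(500L, n),
      editing_level = stats::runif(n)^3,  # skewed so both classes occur
      coverage = sample(c(50L, 150L, 400L), n, replace = TRUE),
      context = "t")
    tab <- tab[!duplicated(paste(tab$duplex_id, tab$position)), ]
    lab <- classifySite(tab$editing_level, tab$coverage)
    if (sum(lab == "edited") < 3L || sum(lab == "non_edited") < 3L) next
    ds <- buildLabeledDataset(tab, seed = rep)
    all_ <- rbind(ds$train, ds$val)
    expect_identical(all_$label,
                     classifySite(all_$editing_level, all_$coverage))
    expect_identical(sum(all_$label == "edited"),
                     sum(all_$label == "non_edited"))
    k <- function(x) paste(x$duplex_id, x$position)
    expect_length(intersect(k(ds$train), k(ds$val)), 0L)
  }
})

test_that("editing-table IO validates columns and round trips", {
  tab <- data.frame(duplex_id = "d", position = 1:3,
                    editing_level = c(0, 0.5, 1), coverage = c(10L, 200L, 90L),
                    context = "liver")
  path <- tempfile(fileext = ".tsv")
  writeEditingTable(tab, path)
  expect_equal(readEditingTable(path), tab)
  writeLines("a\tb", path)
  expect_error(readEditingTable(path), "columns")
})
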