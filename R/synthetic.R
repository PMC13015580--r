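# Self-consistent synthetic duplexes with planted editing rules. A duplex is
# built as left arm + hairpin linker + (mutated) reverse complement of the
# left arm, with the dot-bracket constructed jointly with the sequence, so
# the structure is nested and involution-consistent without any folding.
# Editing levels follow a logistic link over planted sequence/structure rules
# whose signs mirror known ADAR biochemistry: unpaired targets and a 5' U are
# favoured, a 5' G suppresses, a 3' G enhances.

.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Synthetic dataset configuration
#'
#' Defaults define the package's standard study conditions: 400 duplexes of
#' 40-70 nt, 3\% per-position stem mismatch rate, 3\% internal-loop rate
#' with loops of 2-5 nt, 8\% asymmetric-bulge rate of 1-3 nt
#' (bulges shift the pairing register, so partner geometry is duplex-specific
#' and structure is not recoverable from sequence positions), 18\% fray rate
#' (complementary but unpaired single positions), strong planted rules
#' \code{w = (w0 = -3, wUnpaired = 5, w5U = 1, w5G = 2, w3G = 1)} with
#' Gaussian noise sd 0.5 on the logit scale, and log-normal read coverage
#' (median 200, sdlog 0.6). Two constraints fix the intercept and the
#' unpaired weight: the rule span must straddle both class cutoffs (1\% and
#' 15\% editing) so both classes occur, and the unpaired effect must exceed
#' the 2.87-logit exclusion gap between the cutoffs so that pairing status
#' genuinely flips labels — otherwise editability would be recoverable from
#' sequence alone and structure ablations would be vacuous.
#'
#' @param nDuplexes Number of duplexes.
#' @param lengthRange Total duplex length range (nt), linker included.
#' @param mismatchRate Per-position probability that a stem position of the
#'   right arm is mutated; the pair survives only if still Watson-Crick or
#'   wobble valid.
#' @param loopRate Per-position probability that a symmetric internal loop
#'   starts at a stem position.
#' @param loopLenRange Internal loop length range (nt).
#' @param bulgeRate Per-position probability that an asymmetric bulge starts
#'   at a stem position (extra unpaired bases on one strand only; shifts the
#'   pairing register).
#' @param bulgeLenRange Bulge length range (nt).
#' @param frayRate Per-position probability that a stem position is frayed:
#'   the strands stay perfectly complementary but the position is unpaired
#'   (helix breathing). Frayed positions make pairing status genuinely
#'   structural — unrecoverable from sequence.
#' @param linkerRange Hairpin linker length range (nt). The wide default
#'   makes arm lengths vary between same-length duplexes, so structures are
#'   not positionally interchangeable.
#' @param weights Named numeric: \code{w0}, \code{wUnpaired}, \code{w5U},
#'   \code{w5G} (entered with a minus sign), \code{w3G}.
#' @param baseFreqs Named base frequencies for arm/linker/bulge draws
#'   (default AU-rich, as in UTR-derived inverted repeats).
#' @param noiseSd Gaussian noise sd on the logit scale.
#' @param coverageMeanlog,coverageSdlog Log-normal read-coverage parameters.
#' @param context Context label written to editing records.
#' @param seed Integer seed.
#' @return Config list for [generateDuplex()], [plantLabels()],
#'   [generateDataset()].
#' @export
syntheticConfig <- function(nDuplexes = 400L,
                            lengthRange = c(40L, 70L),
                            mismatchRate = 0.03,
                            loopRate = 0.03,
                            loopLenRange = c(2L, 5L),
                            bulgeRate = 0.08,
                            bulgeLenRange = c(1L, 3L),
                            frayRate = 0.18,
                            linkerRange = c(3L, 15L),
                            baseFreqs = c(A = 0.22, C = 0.18, G = 0.32,
                                          U = 0.28),
                            weights = c(w0 = -3, wUnpaired = 5, w5U = 1,
                                        w5G = 2, w3G = 1),
                            noiseSd = 0.5,
                            coverageMeanlog = log(200),
                            coverageSdlog = 0.6,
                            context = "synthetic",
                            seed = 1L) {
  stopifnot(nDuplexes >= 1L, lengthRange[1L] <= lengthRange[2L],
            mismatchRate >= 0, mismatchRate <= 1,
            loopRate >= 0, loopRate <= 1, noiseSd >= 0)
  need <- c("w0", "wUnpaired", "w5U", "w5G", "w3G")
  if (!all(need %in% names(weights))) {
    stop("weights must be named: ", paste(need, collapse = ", "))
  }
  if (lengthRange[1L] < 2L * 10L + linkerRange[2L]) {
    stop("length range infeasible: duplexes need arms of at least 10 nt")
  }
  stopifnot(abs(sum(baseFreqs) - 1) < 1e-9,
            setequal(names(baseFreqs), c("A", "C", "G", "U")),
            linkerRange[1L] <= linkerRange[2L],
            loopLenRange[1L] <= loopLenRange[2L],
            bulgeRate >= 0, bulgeRate <= 1, frayRate >= 0, frayRate <= 1,
            bulgeLenRange[1L] <= bulgeLenRange[2L])
  list(nDuplexes = as.integer(nDuplexes),
       lengthRange = as.integer(lengthRange),
       mismatchRate = mismatchRate, loopRate = loopRate,
       loopLenRange = as.integer(loopLenRange),
       bulgeRate = bulgeRate, bulgeLenRange = as.integer(bulgeLenRange),
       frayRate = frayRate, baseFreqs = baseFreqs,
       linkerRange = as.integer(linkerRange),
       weights = weights, noiseSd = noiseSd,
       coverageMeanlog = coverageMeanlog, coverageSdlog = coverageSdlog,
       context = context, seed = as.integer(seed))
}

#' Generate one synthetic inverted-repeat duplex
#'
#' Draws a left arm, a short hairpin linker and an imperfect reverse
#' complement of the left arm. Three kinds of imperfection are planted while
#' walking the stem: point mismatches (the right-strand base is mutated; the
#' pair survives only when the mutant is still Watson-Crick/wobble valid),
#' symmetric internal loops (both strands keep their bases — complementary
#' but unpaired), and asymmetric bulges (extra unpaired bases on one strand
#' only, which shift the pairing register so the partner geometry is
#' duplex-specific). The emitted dot-bracket always parses and its pair table
#' is involution-consistent by construction — no folding is involved.
#'
#' @param config From [syntheticConfig()].
#' @param seed Integer seed (one duplex per seed; deterministic).
#' @param id Duplex identifier.
#' @return A [Duplex-class].
#' @export
generateDuplex <- function(config, seed = config$seed, id = paste0("synth_", seed)) {
  set.seed(seed)
  total <- sample(config$lengthRange[1L]:config$lengthRange[2L], 1L)
  linkerLen <- sample(config$linkerRange[1L]:config$linkerRange[2L], 1L)
  armLen <- (total - linkerLen) %/% 2L
  bf <- config$baseFreqs[c("A", "C", "G", "U")]
  left <- sample(names(bf), armLen, replace = TRUE, prob = bf)
  linker <- sample(names(bf), linkerLen, replace = TRUE, prob = bf)
  leftPaired <- rep(TRUE, armLen)   # does left position i keep a partner?
  rightChar <- character(0)         # right arm, 5' -> 3' (walks left arm 3' -> 5')
  rightPartner <- integer(0)        # left index paired to each right position (NA = none)
  rnd <- function() sample(names(bf), 1L, prob = bf)

  frayRate <- if (is.null(config$frayRate)) 0 else config$frayRate
  i <- armLen
  while (i >= 1L) {
    u <- stats::runif(1L)
    if (u < frayRate) {
      # frayed position: strands complementary but unpaired (breathing)
      leftPaired[i] <- FALSE
      rightChar <- c(rightChar, unname(.COMPLEMENT[left[i]]))
      rightPartner <- c(rightPartner, NA_integer_)
      i <- i - 1L
    } else if (u < frayRate + config$loopRate) {
      # symmetric internal loop: both strands keep bases, no pairs
      len <- min(sample(config$loopLenRange[1L]:config$loopLenRange[2L], 1L), i)
      for (k in i:(i - len + 1L)) {
        leftPaired[k] <- FALSE
        rightChar <- c(rightChar, unname(.COMPLEMENT[left[k]]))
        rightPartner <- c(rightPartner, NA_integer_)
      }
      i <- i - len
    } else if (u < frayRate + config$loopRate + config$bulgeRate) {
      # asymmetric bulge on one strand; shifts the register
      len <- sample(config$bulgeLenRange[1L]:config$bulgeLenRange[2L], 1L)
      if (stats::runif(1L) < 0.5) {
        # right-strand bulge: extra unpaired bases, no left counterpart
        for (b in seq_len(len)) {
          rightChar <- c(rightChar, rnd())
          rightPartner <- c(rightPartner, NA_integer_)
        }
      } else {
        # left-strand bulge: left positions without right counterpart
        len <- min(len, i)
        leftPaired[i:(i - len + 1L)] <- FALSE
        i <- i - len
      }
    } else {
      base <- unname(.COMPLEMENT[left[i]])
      if (stats::runif(1L) < config$mismatchRate) {
        base <- sample(setdiff(c("A", "C", "G", "U"), base), 1L)
      }
      ok <- isValidPair(left[i], base)
      leftPaired[i] <- ok
      rightChar <- c(rightChar, base)
      rightPartner <- c(rightPartner, if (ok) i else NA_integer_)
      i <- i - 1L
    }
  }

  sequence <- c(left, linker, rightChar)
  db <- c(ifelse(leftPaired, "(", "."),
          rep(".", linkerLen),
          ifelse(is.na(rightPartner), ".", ")"))
  duplex(id, paste(sequence, collapse = ""), paste(db, collapse = ""))
}

#' Plant editing levels and coverages on a duplex
#'
#' For every adenosine \code{i}, draws
#' \deqn{score = w_0 + w_{unpaired} 1[i unpaired] + w_{5U} 1[base_{i-1}=U]
#'       - w_{5G} 1[base_{i-1}=G] + w_{3G} 1[base_{i+1}=G] + N(0, sd)}
#' and sets the editing level to \code{plogis(score)}; coverage is log-normal
#' (rounded). Deterministic given \code{seed}.
#'
#' @param dup A [Duplex-class].
#' @param pt Pair table from [parseDotBracket()].
#' @param config From [syntheticConfig()] (weights, noise, coverage).
#' @param seed Integer seed.
#' @return Editing-record data.frame (duplex_id, position, editing_level,
#'   coverage, context).
#' @export
plantLabels <- function(dup, pt, config, seed = config$seed) {
  set.seed(seed)
  bases <- strsplit(dup@sequence, "", fixed = TRUE)[[1L]]
  L <- length(bases)
  apos <- which(bases == "A")
  if (length(apos) == 0L) {
    return(data.frame(duplex_id = character(0), position = integer(0),
                      editing_level = numeric(0), coverage = integer(0),
                      context = character(0)))
  }
  w <- config$weights
  prev <- ifelse(apos > 1L, bases[pmax(apos - 1L, 1L)], "N")
  nxt <- ifelse(apos < L, bases[pmin(apos + 1L, L)], "N")
  score <- w[["w0"]] +
    w[["wUnpaired"]] * as.numeric(is.na(pt[apos])) +
    w[["w5U"]] * as.numeric(prev == "U") -
    w[["w5G"]] * as.numeric(prev == "G") +
    w[["w3G"]] * as.numeric(nxt == "G") +
    stats::rnorm(length(apos), 0, config$noiseSd)
  level <- stats::plogis(score)
  coverage <- pmax(0L, as.integer(round(stats::rlnorm(
    length(apos), config$coverageMeanlog, config$coverageSdlog))))
  data.frame(duplex_id = dup@id, position = apos, editing_level = level,
             coverage = coverage, context = config$context,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes a dot-bracket structure file, an editing table TSV and a manifest
#' TSV (per-stage counts and the config's seeds) into \code{dir}. The outputs
#' pass the classify/balance/split pipeline end to end; byte-identical on
#' re-run with the same config.
#'
#' @param config From [syntheticConfig()].
#' @param dir Output directory.
#' @return List: \code{structures}, \code{editing}, \code{manifest} (paths),
#'   \code{duplexes}, \code{editingTable}, \code{counts}.
#' @export
generateDataset <- function(config, dir = tempfile("synthdata")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  duplexes <- vector("list", config$nDuplexes)
  tables <- vector("list", config$nDuplexes)
  for (i in seq_len(config$nDuplexes)) {
    dseed <- config$seed + 7919L * i
    duplexes[[i]] <- generateDuplex(config, seed = dseed,
                                    id = sprintf("synth_%05d", i))
    pt <- parseDotBracket(duplexes[[i]]@dotBracket)
    tables[[i]] <- plantLabels(duplexes[[i]], pt, config,
                               seed = dseed + 1L)
  }
  names(duplexes) <- vapply(duplexes, function(d) d@id, "")
  editing <- do.call(rbind, tables)
  lab <- classifySite(editing$editing_level, editing$coverage)
  nE <- sum(lab == "edited"); nN <- sum(lab == "non_edited")
  if (nE < 2L || nN < 2L) {
    stop("config yields too few sites per class after filtering: edited = ",
         nE, ", non_edited = ", nN, ", excluded = ", sum(lab == "excluded"))
  }
  structPath <- file.path(dir, "structures.dbn")
  editPath <- file.path(dir, "editing.tsv")
  manPath <- file.path(dir, "manifest.tsv")
  writeDotBracketFile(duplexes, structPath)
  writeEditingTable(editing, editPath)
  counts <- c(duplexes = config$nDuplexes, adenosines = nrow(editing),
              edited = nE, non_edited = nN,
              excluded = sum(lab == "excluded"))
  man <- data.frame(key = c(names(counts), "seed", "context"),
                    value = c(unname(counts), config$seed, config$context))
  utils::write.table(man, manPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(structures = structPath, editing = editPath, manifest = manPath,
       duplexes = duplexes, editingTable = editing, counts = counts)
}

#' Assemble labeled site graphs from duplexes and a labeled site table
#'
#' Builds one position-centric graph per labeled site, resolving duplex ids
#' against a named duplex list. With \code{shuffleStructures = TRUE} the
#' dot-brackets are permuted across duplexes of compatible length before
#' graph construction (structure-ablation control: sequences keep their
#' labels but pairing information is scrambled).
#'
#' @param duplexes Named list of [Duplex-class] objects.
#' @param sites Labeled site data.frame (duplex_id, position, label).
#' @param featureSet \code{"baseline"} or \code{"bioaware"}.
#' @param shuffleStructures Permute structures across duplexes (ablation).
#' @param seed Seed for the shuffle.
#' @return List of labeled [SiteGraph-class] objects.
#' @export
assembleGraphs <- function(duplexes, sites,
                           featureSet = c("baseline", "bioaware"),
                           shuffleStructures = FALSE, seed = 1L) {
  featureSet <- match.arg(featureSet)
  missing <- setdiff(unique(sites$duplex_id), names(duplexes))
  if (length(missing)) {
    stop("no structure for duplex id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (shuffleStructures) {
    # permute dot-brackets within length classes so lengths still match
    set.seed(seed)
    lens <- vapply(duplexes, length, 1L)
    for (ln in unique(lens)) {
      idx <- which(lens == ln)
      if (length(idx) < 2L) next
      perm <- sample(idx)
      dbs <- vapply(duplexes[perm], function(d) d@dotBracket, "")
      for (k in seq_along(idx)) {
        duplexes[[idx[k]]]@dotBracket <- dbs[k]
      }
    }
  }
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(sites))
  for (r in seq_len(nrow(sites))) {
    did <- sites$duplex_id[r]
    ctx <- cache[[did]]
    if (is.null(ctx)) {
      d <- duplexes[[did]]
      pt <- parseDotBracket(d@dotBracket)
      ann <- if (featureSet == "bioaware") annotateStructure(d, pt) else NULL
      ctx <- list(d = d, pt = pt, ann = ann)
      cache[[did]] <- ctx
    }
    out[[r]] <- if (featureSet == "baseline") {
      buildBaselineGraph(ctx$d, ctx$pt, sites$position[r], sites$label[r])
    } else {
      buildBioawareGraph(ctx$d, ctx$pt, ctx$ann, sites$position[r],
                         sites$label[r])
    }
  }
  out
}
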