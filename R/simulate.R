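# Synthetic benchmarks: sequences with planted tandem repeat arrays under
# controlled substitution and indel loads, the substitution-load statistic
# x, and the two benchmark experiments (Z versus x for a 30-nt unit;
# detection rate Y versus x for a 6-nt unit).

#' Planted repeat specification constructor
#'
#' Defaults describe the 30-nt benchmark: a 3000-nt core of 100 tandem
#' copies of a random 30-nt unit with 50 insertions and 50 deletions and
#' no flanks.  The 6-nt benchmark uses \code{unitLength = 6, copies = 100,
#' nInsertions = 5, nDeletions = 5, flankLength = 300} (1200 nt total).
#'
#' @param unitLength,copies,nInsertions,nDeletions,nSubstitutions,flankLength,seed
#'   see \linkS4class{PlantedRepeatSpec}.
#' @return a \linkS4class{PlantedRepeatSpec}.
#' @export
plantedRepeatSpec <- function(unitLength = 30L, copies = 100L,
                              nInsertions = 50L, nDeletions = 50L,
                              nSubstitutions = 0L, flankLength = 0L,
                              seed = 1L) {
  new("PlantedRepeatSpec", unitLength = as.integer(unitLength),
      copies = as.integer(copies), nInsertions = as.integer(nInsertions),
      nDeletions = as.integer(nDeletions),
      nSubstitutions = as.integer(nSubstitutions),
      flankLength = as.integer(flankLength), seed = as.integer(seed))
}

#' Substitution draws needed for a target load x
#'
#' Inverse of the load statistic: x = 2 * draws / core length, so
#' draws = round(x * core / 2).
#'
#' @param x target substitution load.
#' @param spec a \linkS4class{PlantedRepeatSpec} giving the core geometry.
#' @return an integer draw count.
#' @export
substitutionsForLoad <- function(x, spec) {
  as.integer(round(x * spec@unitLength * spec@copies / 2))
}

#' Plant a tandem repeat array with substitutions and indels
#'
#' Builds a random unit, tandem-copies it, applies the substitution draws
#' (uniform position over the core, replacement base uniform over all four
#' bases, so a quarter of draws are silent; every draw still counts in the
#' mutation vector y), then applies single-base insertions and deletions at
#' distinct uniform core positions, and finally appends random flanks.
#' Planted unit spans are mapped through the indels.
#'
#' @param spec a \linkS4class{PlantedRepeatSpec}.
#' @return a list with elements \code{seq} (\linkS4class{EncodedSequence}),
#'   \code{y} (per-position substitution draw counts over the pre-indel
#'   core), and \code{truth} (a \code{GRanges} of post-indel unit spans
#'   with a period column).
#' @export
plantTandemRepeats <- function(spec) {
  stopifnot(is(spec, "PlantedRepeatSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    uL <- spec@unitLength
    core <- rep(sample.int(4L, uL, replace = TRUE), spec@copies)
    coreLen <- length(core)
    y <- integer(coreLen)
    if (spec@nSubstitutions > 0L) {
      pos <- sample.int(coreLen, spec@nSubstitutions, replace = TRUE)
      repl <- sample.int(4L, spec@nSubstitutions, replace = TRUE)
      core[pos] <- repl  # duplicated positions: later draws overwrite
      y <- tabulate(pos, nbins = coreLen)
    }
    labels <- rep(seq_len(spec@copies), each = uL)
    nIndel <- spec@nInsertions + spec@nDeletions
    insAfter <- integer(0)
    delAt <- integer(0)
    if (nIndel > 0L) {
      posAll <- sample.int(coreLen, nIndel)
      insAfter <- posAll[seq_len(spec@nInsertions)]
      delAt <- posAll[seq.int(spec@nInsertions + 1L, nIndel)]
    }
    insBase <- sample.int(4L, length(insAfter), replace = TRUE)
    keep <- rep(TRUE, coreLen)
    keep[delAt] <- FALSE
    insFlag <- logical(coreLen)
    insFlag[insAfter] <- TRUE
    insLookup <- integer(coreLen)
    insLookup[insAfter] <- seq_along(insAfter)
    # expand: each surviving base, then any insertion placed after it;
    # inserted bases inherit the unit label of their anchor position
    emit <- keep + insFlag
    lab2 <- rep(labels, emit)
    codeList <- integer(sum(emit))
    idx <- 1L
    for (p in seq_len(coreLen)) {
      if (keep[p]) {
        codeList[idx] <- core[p]
        idx <- idx + 1L
      }
      if (insFlag[p]) {
        codeList[idx] <- insBase[insLookup[p]]
        idx <- idx + 1L
      }
    }
    flank1 <- sample.int(4L, spec@flankLength, replace = TRUE)
    flank2 <- sample.int(4L, spec@flankLength, replace = TRUE)
    codes <- c(flank1, codeList, flank2)
    seq <- new("EncodedSequence", id = "planted", codes = as.integer(codes),
               ambiguous = integer())
    # truth spans: contiguous run of each unit label, offset by the flank
    offs <- spec@flankLength
    present <- sort(unique(lab2))
    starts <- ends <- integer(length(present))
    for (ui in seq_along(present)) {
      w <- which(lab2 == present[ui])
      starts[ui] <- offs + min(w)
      ends[ui] <- offs + max(w)
    }
    truth <- GenomicRanges::GRanges(
      seqnames = "planted",
      ranges = IRanges::IRanges(start = starts, end = ends),
      period = spec@unitLength, unit = present)
    list(seq = seq, y = y, truth = truth)
  })
}

#' Substitution load x between repeat copies
#'
#' The average number of substitutions per nucleotide between any two
#' repeat copies: over all ordered pairs of distinct units (i, j), the sum
#' of the draws landing in unit i plus those in unit j, normalized by the
#' unit length times the pair count.  Collapses to
#' 2 * sum(y) / core length, so it is linear in the total draw count and
#' symmetric under unit relabeling.
#'
#' @param y per-position substitution draw counts over the pre-indel core.
#' @param spec the \linkS4class{PlantedRepeatSpec}.
#' @return the load x.
#' @export
mutationLoad <- function(y, spec) {
  stopifnot(length(y) == spec@unitLength * spec@copies)
  u <- vapply(seq_len(spec@copies), function(i) {
    sum(y[seq.int((i - 1L) * spec@unitLength + 1L, i * spec@unitLength)])
  }, numeric(1))
  m <- spec@copies
  pairSum <- sum(outer(u, u, "+")) - sum(u + u)  # ordered pairs, i != j
  nPairs <- m * (m - 1L)
  pairSum / (spec@unitLength * nPairs)
}

#' Z-versus-x curve on the 30-nt benchmark
#'
#' For each spec on the substitution ladder: generate the sequence,
#' compute the load x, and compute the shuffle-based Z at the planted
#' period.
#'
#' @param ladder list of \linkS4class{PlantedRepeatSpec}.
#' @param config a \linkS4class{GAConfig}.
#' @param gaps a \linkS4class{GapParams}.
#' @param nShuffles shuffles per Z estimate.
#' @param seed RNG seed.
#' @return a data.frame with columns x, z, observed, meanNull, sdNull.
#' @export
zVsXExperiment <- function(ladder, config = gaConfig(),
                           gaps = gapParams(), nShuffles = 200L,
                           seed = 1L) {
  rows <- lapply(seq_along(ladder), function(i) {
    spec <- ladder[[i]]
    sim <- plantTandemRepeats(spec)
    zr <- zStatistic(sim$seq, spec@unitLength, config = config,
                     gaps = gaps, nShuffles = nShuffles,
                     seed = deriveSeed(seed, "zvx", i))
    data.frame(x = mutationLoad(sim$y, spec), z = zr@z,
               observed = zr@observed, meanNull = zr@meanNull,
               sdNull = sqrt(zr@varNull))
  })
  do.call(rbind, rows)
}

#' Detection-rate curve on the 6-nt benchmark
#'
#' For each spec: over replicates, generate the sequence, run the full
#' repeat caller, and count planted units at least half covered by called
#' regions whose period equals the planted unit length exactly (harmonic
#' periods count as misses).  Y = K / copies, averaged over replicates.
#'
#' @param specs list of \linkS4class{PlantedRepeatSpec} (6-nt geometry).
#' @param config a \linkS4class{ScanConfig}.
#' @param replicates independent sequences per spec.
#' @param minCoverage unit coverage fraction counted as detected (0.5).
#' @return a data.frame with columns x, y, k (mean detected units), and
#'   replicates.
#' @export
detectionRateExperiment <- function(specs, config = scanConfig(),
                                    replicates = 5L, minCoverage = 0.5) {
  rows <- lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    ks <- numeric(replicates)
    xs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      spec2 <- spec
      spec2@seed <- deriveSeed(spec@seed, "rep", r)
      sim <- plantTandemRepeats(spec2)
      cfg <- config
      cfg@seed <- deriveSeed(config@seed, "det", si, r)
      regions <- callRepeats(sim$seq, cfg)
      ks[r] <- countDetectedUnits(sim$truth, regions, spec@unitLength,
                                  minCoverage)
      xs[r] <- mutationLoad(sim$y, spec2)
    }
    data.frame(x = mean(xs), y = mean(ks) / spec@copies, k = mean(ks),
               replicates = replicates)
  })
  do.call(rbind, rows)
}

# planted units >= minCoverage covered by the union of regions with the
# exact period
countDetectedUnits <- function(truth, regions, period, minCoverage = 0.5) {
  if (!length(regions)) return(0L)
  hit <- regions[regions$period == period]
  if (!length(hit)) return(0L)
  cov <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(hit)),
    GenomicRanges::granges(truth))
  if (!length(cov)) return(0L)
  ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(truth), cov)
  covered <- numeric(length(truth))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(truth)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(cov)[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  sum(covered / IRanges::width(GenomicRanges::ranges(truth)) >= minCoverage)
}
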