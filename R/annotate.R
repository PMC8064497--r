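# Overlap analysis of called repeats with annotation features (exons,
# transposons): the >= 80% intersection rule and the Monte-Carlo X
# enrichment statistic from random relocation of the features.

#' Read annotation features from BED or TSV
#'
#' BED (0-based half-open, name column used as the class label) or a
#' header-less TSV with columns seq_id, start, end, class (1-based
#' inclusive coordinates).
#'
#' @param path input file.
#' @param format "bed" or "tsv".
#' @return a \code{GRanges} with a \code{classLabel} column.
#' @export
readFeatures <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "bed") {
    GenomicRanges::GRanges(
      seqnames = df[[1]],
      ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
      classLabel = if (ncol(df) >= 4L) df[[4]] else NA_character_)
  } else {
    GenomicRanges::GRanges(
      seqnames = df[[1]],
      ranges = IRanges::IRanges(start = df[[2]], end = df[[3]]),
      classLabel = if (ncol(df) >= 4L) df[[4]] else NA_character_)
  }
}

#' Count repeat regions covered by features
#'
#' A repeat region counts as intersecting if at least \code{minFraction}
#' of its own length is covered by the union of the features on the same
#' sequence (the fraction is of the repeat's length, so short features can
#' still cover a repeat jointly).
#'
#' @param regions a \code{GRanges} of repeat regions.
#' @param features a \code{GRanges} of annotation features.
#' @param minFraction required covered fraction (default 0.8).
#' @return integer count.
#' @export
overlapCount <- function(regions, features, minFraction = 0.8) {
  if (!length(regions) || !length(features)) return(0L)
  feat <- GenomicRanges::reduce(GenomicRanges::granges(features))
  ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(regions), feat)
  covered <- numeric(length(regions))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(regions)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(feat)[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  sum(covered / IRanges::width(GenomicRanges::ranges(regions)) >=
        minFraction)
}

#' Monte-Carlo X statistic from the observed and null overlap counts
#'
#' X = (C - C_bar) / sqrt(D), where C is the observed intersection count
#' and C_bar, D the mean and variance of the count under random feature
#' relocation.
#'
#' @param c observed count.
#' @param cBar null mean.
#' @param dC null variance.
#' @return the X statistic.
#' @export
xStatistic <- function(c, cBar, dC) {
  if (dC <= 0) stop("null variance must be positive")
  (c - cBar) / sqrt(dC)
}

#' Overlap enrichment by random feature relocation
#'
#' Counts the observed overlaps, then relocates every feature uniformly at
#' random within its sequence (length preserved, never past the sequence
#' end, overlaps among shuffled features allowed), re-counting each time;
#' returns the X statistic of the observed count against the shuffle
#' distribution.
#'
#' @param regions a \code{GRanges} of repeat regions.
#' @param features a \code{GRanges} of features.
#' @param seqLengths named vector of sequence lengths.
#' @param nShuffles number of relocations (>= 30).
#' @param seed RNG seed.
#' @param minFraction coverage fraction of the intersection rule.
#' @return an \linkS4class{OverlapResult}.
#' @export
permutationXStatistic <- function(regions, features, seqLengths,
                                  nShuffles = 100L, seed = 1L,
                                  minFraction = 0.8) {
  if (nShuffles < 30L) stop("use at least 30 shuffles")
  cObs <- overlapCount(regions, features, minFraction)
  widths <- IRanges::width(GenomicRanges::ranges(features))
  chroms <- as.character(GenomicRanges::seqnames(features))
  if (!all(chroms %in% names(seqLengths)))
    stop("seqLengths must name every feature sequence")
  maxStart <- seqLengths[chroms] - widths + 1
  if (any(maxStart < 1)) stop("feature longer than its sequence")
  counts <- withSeed(seed, vapply(seq_len(nShuffles), function(i) {
    st <- floor(runif(length(widths), min = 1, max = maxStart + 1))
    sh <- GenomicRanges::GRanges(
      seqnames = chroms,
      ranges = IRanges::IRanges(start = as.integer(st), width = widths))
    overlapCount(regions, sh, minFraction)
  }, numeric(1)))
  v <- var(counts)
  if (!is.finite(v) || v <= 0)
    stop("zero variance across shuffles; increase nShuffles")
  new("OverlapResult", c = as.integer(cObs), cBar = mean(counts), dC = v,
      xStat = xStatistic(cObs, mean(counts), v))
}
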