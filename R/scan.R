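# Genome scanning driver: slide the window along the chromosome, run the
# genetic algorithm per (window, period) cell to build the mF_max(k, n)
# surface, then call repeats as two-dimensional local maxima above F0.

#' Scan configuration constructor
#'
#' @param windowLength window length L in bases (default 650).
#' @param step window step in bases (default 10).
#' @param nMin,nMax period range (default 2..50).
#' @param neighborhood local-maximum neighborhood, in window-grid units
#'   (default 64, i.e. +/- 640 bases at the default step).
#' @param f0 detection threshold on mF_max (default 390, the FDR < 0.01
#'   calibration on shuffled chromosomes).
#' @param tripletThreshold x3 cutoff of the triplet filter (default 3.0).
#' @param r2PerPosition per-column squared norm of the cell populations
#'   (default 110; see \code{\link{r2TargetFlat}}); NA selects the
#'   period-dependent \code{\link{r2Target}} formula, under which
#'   short-period scores dominate and a fixed f0 is not comparable across
#'   periods.
#' @param ga a \linkS4class{GAConfig}.
#' @param gaps a \linkS4class{GapParams}.
#' @param seed global seed; every (window, period) cell derives its own
#'   deterministic seed from it, so cells can be computed in any order.
#' @return a \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(windowLength = 650L, step = 10L, nMin = 2L,
                       nMax = 50L, neighborhood = 64L, f0 = 390.0,
                       tripletThreshold = 3.0, r2PerPosition = 110.0,
                       ga = gaConfig(), gaps = gapParams(), seed = 1L) {
  new("ScanConfig", windowLength = as.integer(windowLength),
      step = as.integer(step), nMin = as.integer(nMin),
      nMax = as.integer(nMax), neighborhood = as.integer(neighborhood),
      f0 = f0, tripletThreshold = tripletThreshold,
      r2PerPosition = as.numeric(r2PerPosition), ga = ga, gaps = gaps,
      seed = as.integer(seed))
}

#' Scan a sequence to build the mF_max(k, n) surface
#'
#' For every window start k on the step grid and every period n in range,
#' runs the matrix optimization and records its best score.  Windows that
#' fail the triplet filter, or that overlap a run of more than 50
#' ambiguous input bases, are skipped and hold score 0 (they still count
#' as zero-valued competitors in the maxima neighborhoods).
#'
#' @param chrom an \linkS4class{EncodedSequence} of length >= windowLength.
#' @param config a \linkS4class{ScanConfig}.
#' @return a \linkS4class{ScanSurface}.
#' @export
scanSequence <- function(chrom, config = scanConfig()) {
  stopifnot(is(chrom, "EncodedSequence"), is(config, "ScanConfig"))
  L <- config@windowLength
  len <- length(chrom@codes)
  if (len < L)
    stop("sequence shorter than the window length")
  starts <- seq.int(1L, len - L + 1L, by = config@step)
  periods <- seq.int(config@nMin, config@nMax)
  ambRuns <- ambiguousRuns(chrom)
  id <- if (is.na(chrom@id)) "seq" else chrom@id
  scores <- matrix(0, nrow = length(starts), ncol = length(periods))
  skipped <- logical(length(starts))
  matrices <- vector("list", length(starts))
  for (wi in seq_along(starts)) {
    k <- starts[wi]
    win <- new("EncodedSequence", id = id,
               codes = chrom@codes[k:(k + L - 1L)], ambiguous = integer())
    if (length(ambRuns) &&
        any(IRanges::overlapsAny(
          ambRuns, IRanges::IRanges(k, k + L - 1L)))) {
      skipped[wi] <- TRUE
      next
    }
    if (!passesTripletFilter(tripletStatistic(win),
                             config@tripletThreshold)) {
      skipped[wi] <- TRUE
      next
    }
    bg <- tabulate(win@codes, 4L) / L
    cellMats <- vector("list", length(periods))
    for (ni in seq_along(periods)) {
      n <- periods[ni]
      r2n <- if (is.na(config@r2PerPosition)) r2Target(n) else
        r2TargetFlat(n, config@r2PerPosition)
      res <- optimizePWM(win, n, background = bg, gaps = config@gaps,
                         config = config@ga, r2 = r2n,
                         seed = deriveSeed(config@seed, id, k, n))
      scores[wi, ni] <- res@mfmax
      cellMats[[ni]] <- res@matrix
    }
    matrices[[wi]] <- cellMats
  }
  new("ScanSurface", scores = scores, starts = starts,
      periods = as.integer(periods), skippedWindows = skipped,
      matrices = matrices, seqId = id)
}

#' Extract repeat regions from a scan surface
#'
#' Two passes: first, one-dimensional local maxima along the window axis
#' within +/- neighborhood grid steps for each period (all competitors are
#' zeroed); then surviving cells must strictly exceed every surviving cell
#' of any other period in the same window neighborhood, and exceed F0.
#' Each winner is traced back through its cached matrix to the aligned
#' span, yielding the region coordinates.
#'
#' @param surface a \linkS4class{ScanSurface}.
#' @param config the \linkS4class{ScanConfig} used for the scan.
#' @param chrom the scanned sequence (needed for alignment coordinates; if
#'   omitted, regions span the whole source window).
#' @return a \code{GRanges} with metadata columns period, mfmax, consensus,
#'   and list columns matrix and alignment.
#' @export
findLocalMaxima <- function(surface, config = scanConfig(), chrom = NULL) {
  stopifnot(is(surface, "ScanSurface"))
  sc <- surface@scores
  nb <- config@neighborhood
  K <- nrow(sc)
  P <- ncol(sc)
  kept <- matrix(FALSE, K, P)
  peak <- sc
  for (p in seq_len(P)) {
    col <- sc[, p]
    for (k in which(col > 0)) {
      lo <- max(1L, k - nb)
      hi <- min(K, k + nb)
      others <- col[lo:hi][-(k - lo + 1L)]
      if (all(col[k] > others)) kept[k, p] <- TRUE
    }
    peak[!kept[, p], p] <- 0
  }
  winners <- which(kept, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(winners))) {
    k <- winners[r, 1L]
    p <- winners[r, 2L]
    v <- peak[k, p]
    if (v <= config@f0) next
    lo <- max(1L, k - nb)
    hi <- min(K, k + nb)
    rivals <- peak[lo:hi, -p, drop = FALSE]
    if (any(rivals >= v)) next
    out[[length(out) + 1L]] <- c(k = unname(k), p = unname(p))
  }
  L <- config@windowLength
  if (!length(out)) {
    return(GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      period = integer(), mfmax = numeric(), consensus = character()))
  }
  rows <- do.call(rbind, out)
  starts <- ends <- integer(nrow(rows))
  periodv <- integer(nrow(rows))
  mfv <- numeric(nrow(rows))
  cons <- character(nrow(rows))
  matList <- vector("list", nrow(rows))
  alnList <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    k <- rows[r, "k"]
    p <- rows[r, "p"]
    wstart <- surface@starts[k]
    n <- surface@periods[p]
    W <- surface@matrices[[k]][[p]]
    matList[[r]] <- W
    periodv[r] <- n
    mfv[r] <- peak[k, p]
    cons[r] <- consensusSequence(W)
    if (!is.null(chrom)) {
      win <- new("EncodedSequence", id = surface@seqId,
                 codes = chrom@codes[wstart:(wstart + L - 1L)],
                 ambiguous = integer())
      aln <- tracebackAlignment(win, W, config@gaps)
      alnList[[r]] <- aln
      if (aln@i0 > 0L) {
        starts[r] <- wstart + aln@i0 - 1L
        ends[r] <- wstart + aln@im - 1L
      } else {
        starts[r] <- wstart
        ends[r] <- wstart + L - 1L
      }
    } else {
      alnList[r] <- list(NULL)
      starts[r] <- wstart
      ends[r] <- wstart + L - 1L
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = surface@seqId,
    ranges = IRanges::IRanges(start = starts, end = ends))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    period = periodv, mfmax = mfv, consensus = cons,
    matrix = I(matList), alignment = I(alnList))
  gr
}

#' Call tandem repeat regions in a sequence
#'
#' Runs \code{\link{scanSequence}} then \code{\link{findLocalMaxima}} and
#' returns the regions sorted by start; deterministic given the config
#' seed.
#'
#' @param chrom an \linkS4class{EncodedSequence}.
#' @param config a \linkS4class{ScanConfig}.
#' @return a \code{GRanges} of called repeats.
#' @export
callRepeats <- function(chrom, config = scanConfig()) {
  surface <- scanSequence(chrom, config)
  gr <- findLocalMaxima(surface, config, chrom = chrom)
  GenomicRanges::sort(gr)
}
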