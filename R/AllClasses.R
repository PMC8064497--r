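#' @import methods
#' @importFrom stats runif rnorm sd var setNames
#' @importFrom utils head tail write.table read.table
NULL

#' Encoded DNA sequence
#'
#' DNA held as integer codes 1..4 (a, t, c, g), the carrier for all dynamic
#' programming and statistics in the package.  Positions that were IUPAC
#' ambiguity codes in the input (and were replaced by random bases during
#' encoding) are recorded in \code{ambiguous}.
#'
#' @slot id single character label.
#' @slot codes integer vector with values in \{1, 2, 3, 4\}.
#' @slot ambiguous integer positions that carried ambiguity codes.
#' @exportClass EncodedSequence
setClass("EncodedSequence",
  representation(id = "character", codes = "integer", ambiguous = "integer"),
  prototype(id = NA_character_, codes = integer(), ambiguous = integer()))

setValidity("EncodedSequence", function(object) {
  if (length(object@codes) < 1L)
    return("sequence must contain at least one base")
  if (anyNA(object@codes) || any(object@codes < 1L | object@codes > 4L))
    return("codes must all be in {1, 2, 3, 4}")
  if (length(object@id) != 1L)
    return("id must be a single string")
  TRUE
})

#' Nucleotide/position frequency matrix
#'
#' 4 x n counts accumulated by pairing a random sequence of length \code{L1}
#' against the periodic position sequence 1..n repeated; the raw material for
#' a random position weight matrix.
#'
#' @slot counts 4 x n integer count matrix.
#' @slot L1 generating sequence length.
#' @exportClass FrequencyMatrix
setClass("FrequencyMatrix",
  representation(counts = "matrix", L1 = "integer"))

setValidity("FrequencyMatrix", function(object) {
  if (nrow(object@counts) != 4L)
    return("counts must have 4 rows")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (sum(object@counts) != object@L1)
    return("total count must equal L1")
  TRUE
})

#' Position weight matrix (PWM)
#'
#' A 4 x n real scoring matrix.  After standardization all matrices in a
#' population share a common squared norm R2 (see \code{\link{r2Target}}
#' and \code{\link{r2TargetFlat}}) and background projection Kd = -1.5,
#' making their alignment scores comparable.
#'
#' @slot weights 4 x n numeric matrix.
#' @slot r2 sum of squared entries.
#' @slot kd sum of entries weighted by the background p1(i) * p2(j).
#' @exportClass WeightMatrix
setClass("WeightMatrix",
  representation(weights = "matrix", r2 = "numeric", kd = "numeric"))

setValidity("WeightMatrix", function(object) {
  if (nrow(object@weights) != 4L)
    return("weights must have 4 rows")
  if (!all(is.finite(object@weights)))
    return("weights must be finite")
  TRUE
})

#' Population of weight matrices
#'
#' The genetic algorithm's population: an ordered collection of
#' \linkS4class{WeightMatrix} objects of common period with their fitness
#' vector V (non-increasing after ranking).
#'
#' @slot matrices list of \linkS4class{WeightMatrix}.
#' @slot fitness numeric vector V, NA before evaluation.
#' @exportClass MatrixSet
setClass("MatrixSet",
  representation(matrices = "list", fitness = "numeric"))

setValidity("MatrixSet", function(object) {
  if (length(object@matrices) != length(object@fitness))
    return("fitness must have one entry per matrix")
  ns <- vapply(object@matrices, function(m) ncol(m@weights), integer(1))
  if (length(unique(ns)) > 1L)
    return("all matrices must share the same period n")
  TRUE
})

#' Triplet-periodicity statistic
#'
#' The 3 x 4 phase-by-base count matrix of a window, the mutual-information
#' statistic 2I (chi-square with 6 df under the null) and its normal-argument
#' transform x3 = sqrt(4I) - sqrt(11).
#'
#' @slot m3 3 x 4 count matrix (phase x base).
#' @slot twoI the 2I statistic.
#' @slot x3 normal-scale transform.
#' @exportClass TripletStat
setClass("TripletStat",
  representation(m3 = "matrix", twoI = "numeric", x3 = "numeric"))

#' Affine gap costs
#'
#' @slot d gap-open cost (default 25).
#' @slot e gap-extension cost (default 6).
#' @exportClass GapParams
setClass("GapParams",
  representation(d = "numeric", e = "numeric"),
  prototype(d = 25.0, e = 6.0))

setValidity("GapParams", function(object) {
  if (object@d < object@e || object@e < 0)
    return("gap costs must satisfy d >= e >= 0")
  TRUE
})

#' Profile alignment result
#'
#' Best affine-gap score of a window against the tandem-extended PWM, with
#' the aligned span and the traceback path.  \code{pairs} is a two-column
#' matrix (window position, profile grid position), 0 denoting a gap.
#'
#' @slot fmax best score.
#' @slot i0,im first/last aligned window positions (1-based, 0 if empty).
#' @slot j0,jm first/last aligned profile grid positions.
#' @slot pairs traceback path.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(fmax = "numeric", i0 = "integer", im = "integer",
                 j0 = "integer", jm = "integer", pairs = "matrix"))

#' Genetic algorithm configuration
#'
#' @slot populationSize number of matrices N (reference scale 500).
#' @slot mutationFraction fraction of matrices mutated per cycle (0.05).
#' @slot mutationRange range of the uniform replacement value (-10..10).
#' @slot stallLimit consecutive cycles with V(1) strictly below the running
#'   best before stopping (5).  The population best can fall below the
#'   running best only because mutation may hit any matrix, including the
#'   current best; the best matrix and score are kept as bookkeeping
#'   regardless.
#' @slot maxCycles hard cycle cap (1e4).
#' @slot protectBest if TRUE the current best matrix is excluded from
#'   mutation (elitism); default FALSE, under which the stall rule is
#'   reachable and runs last until the population stops recovering.
#' @exportClass GAConfig
setClass("GAConfig",
  representation(populationSize = "integer", mutationFraction = "numeric",
                 mutationRange = "numeric", stallLimit = "integer",
                 maxCycles = "integer", protectBest = "logical"),
  prototype(populationSize = 500L, mutationFraction = 0.05,
            mutationRange = c(-10, 10), stallLimit = 5L, maxCycles = 10000L,
            protectBest = FALSE))

setValidity("GAConfig", function(object) {
  if (object@populationSize < 4L)
    return("populationSize must be at least 4")
  if (object@mutationFraction <= 0 || object@mutationFraction > 1)
    return("mutationFraction must be in (0, 1]")
  if (object@stallLimit < 1L || object@maxCycles < 1L)
    return("stallLimit and maxCycles must be >= 1")
  if (length(object@mutationRange) != 2L ||
      object@mutationRange[1] > object@mutationRange[2])
    return("mutationRange must be c(lo, hi) with lo <= hi")
  TRUE
})

#' Genetic algorithm result
#'
#' @slot matrix best weight matrix mQ.
#' @slot mfmax best score mF_max (running best over cycles).
#' @slot cycles number of cycles run.
#' @slot converged TRUE if stopped by the stall rule rather than the cap.
#' @exportClass GAResult
setClass("GAResult",
  representation(matrix = "WeightMatrix", mfmax = "numeric",
                 cycles = "integer", converged = "logical"))

#' Scan configuration
#'
#' Parameters of the sliding-window genome scan: window length L (650),
#' window step (10), period range (2..50), local-maximum neighborhood in
#' window-grid units (64), detection threshold F0 (390) and the triplet
#' filter cutoff (3.0).
#'
#' @slot windowLength,step,nMin,nMax,neighborhood integers.
#' @slot f0,tripletThreshold numeric thresholds.
#' @slot r2PerPosition squared norm per matrix column used to standardize
#'   the per-cell populations (see \code{\link{r2TargetFlat}}); set to NA
#'   to fall back to the period-dependent \code{\link{r2Target}} formula.
#' @slot ga \linkS4class{GAConfig}.
#' @slot gaps \linkS4class{GapParams}.
#' @slot seed global seed for per-cell seed derivation.
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(windowLength = "integer", step = "integer",
                 nMin = "integer", nMax = "integer",
                 neighborhood = "integer", f0 = "numeric",
                 tripletThreshold = "numeric", r2PerPosition = "numeric",
                 ga = "GAConfig", gaps = "GapParams", seed = "integer"),
  prototype(windowLength = 650L, step = 10L, nMin = 2L, nMax = 50L,
            neighborhood = 64L, f0 = 390.0, tripletThreshold = 3.0,
            r2PerPosition = 110.0, seed = 1L))

setValidity("ScanConfig", function(object) {
  if (object@step < 1L) return("step must be >= 1")
  if (!is.na(object@r2PerPosition) && object@r2PerPosition <= 0)
    return("r2PerPosition must be positive (or NA for the r2Target formula)")
  if (object@nMin < 2L || object@nMax > 50L || object@nMin > object@nMax)
    return("period range must satisfy 2 <= nMin <= nMax <= 50")
  if (object@windowLength <= object@nMax)
    return("window length must exceed the largest period")
  TRUE
})

#' Scan score surface
#'
#' mF_max(k, n) over window starts k (rows) and periods n (columns), with
#' the per-cell winning matrices cached for traceback of called regions.
#'
#' @slot scores windows x periods score matrix.
#' @slot starts 1-based window start coordinates (rows).
#' @slot periods periods (columns).
#' @slot skippedWindows logical, TRUE where the triplet/ambiguity filter
#'   excluded the window (scores are 0 there).
#' @slot matrices list (by window) of lists (by period) of weight matrices.
#' @slot seqId scanned sequence id.
#' @exportClass ScanSurface
setClass("ScanSurface",
  representation(scores = "matrix", starts = "integer", periods = "integer",
                 skippedWindows = "logical", matrices = "list",
                 seqId = "character"))

#' Shuffle-based significance result
#'
#' @slot z the Z statistic (observed - null mean) / null sd.
#' @slot nShuffles number of shuffles behind the null.
#' @slot meanNull,varNull moments of the shuffle null.
#' @slot observed observed mF_max.
#' @slot nullScores the individual shuffle scores.
#' @exportClass ZResult
setClass("ZResult",
  representation(z = "numeric", nShuffles = "integer", meanNull = "numeric",
                 varNull = "numeric", observed = "numeric",
                 nullScores = "numeric"))

#' FDR threshold calibration result
#'
#' @slot f0 calibrated threshold.
#' @slot tRand,tReal maxima counts on shuffled / real sequences at f0.
#' @slot fdr tRand / (tRand + tReal).
#' @slot grid thresholds examined.
#' @exportClass FDRCalibration
setClass("FDRCalibration",
  representation(f0 = "numeric", tRand = "integer", tReal = "integer",
                 fdr = "numeric", grid = "numeric"))

#' Planted tandem repeat specification
#'
#' Geometry of a synthetic benchmark sequence: a random unit tandem-copied,
#' point substitutions drawn over the core, single-base indels, and random
#' flanks.  Defaults are the 30-nt benchmark (3000-nt core, 50 + 50 indels,
#' no flanks); the 6-nt benchmark uses unitLength = 6, 5 + 5 indels and
#' 300-nt flanks.
#'
#' @slot unitLength repeat unit length n.
#' @slot copies number of tandem copies.
#' @slot nInsertions,nDeletions single-base indel counts.
#' @slot nSubstitutions substitution draws over the core.
#' @slot flankLength random flank added on each side.
#' @slot seed RNG seed.
#' @exportClass PlantedRepeatSpec
setClass("PlantedRepeatSpec",
  representation(unitLength = "integer", copies = "integer",
                 nInsertions = "integer", nDeletions = "integer",
                 nSubstitutions = "integer", flankLength = "integer",
                 seed = "integer"),
  prototype(unitLength = 30L, copies = 100L, nInsertions = 50L,
            nDeletions = 50L, nSubstitutions = 0L, flankLength = 0L,
            seed = 1L))

setValidity("PlantedRepeatSpec", function(object) {
  core <- object@unitLength * object@copies
  if (object@nDeletions >= core)
    return("cannot delete more bases than the core contains")
  if (object@nSubstitutions < 0L)
    return("nSubstitutions must be >= 0")
  TRUE
})

#' Interval overlap enrichment result
#'
#' @slot c observed count of repeat regions covered >= 80\% by features.
#' @slot cBar,dC mean and variance of the count over feature shuffles.
#' @slot xStat (c - cBar) / sqrt(dC).
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(c = "integer", cBar = "numeric", dC = "numeric",
                 xStat = "numeric"))
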