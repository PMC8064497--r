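# Shuffle-based significance and threshold calibration: the null model for
# a repeat score is the same optimization run on composition-preserving
# shuffles of the sequence.

#' Shuffle-based Z statistic for a period
#'
#' Runs the matrix optimization on the sequence to get the observed
#' mF_max, repeats it on \code{nShuffles} independent shuffles of the
#' sequence to build the empirical null, and returns
#' Z = (observed - null mean) / null sd.  The null variance is the
#' unbiased sample variance over the shuffle set.  A repeat is considered
#' significant at Z > 8 in the method's calibration.
#'
#' @param S an \linkS4class{EncodedSequence}.
#' @param n period length.
#' @param config a \linkS4class{GAConfig} for the optimization.
#' @param gaps a \linkS4class{GapParams}.
#' @param nShuffles shuffles behind the null (reference scale 200).
#' @param seed RNG seed.
#' @param r2 standardization norm target; the default is the flat
#'   per-column norm of \code{\link{r2TargetFlat}}, under which the null
#'   optimization plateaus quickly (Z itself is scale-free, but the flat
#'   scale keeps observed and null runs on the same optimization regime as
#'   the scanning pipeline).
#' @return a \linkS4class{ZResult}.
#' @export
zStatistic <- function(S, n, config = gaConfig(), gaps = gapParams(),
                       nShuffles = 200L, seed = 1L, r2 = r2TargetFlat(n)) {
  stopifnot(is(S, "EncodedSequence"))
  obs <- optimizePWM(S, n, gaps = gaps, config = config, r2 = r2,
                     seed = deriveSeed(seed, "observed", n))@mfmax
  nullScores <- vapply(seq_len(nShuffles), function(i) {
    sh <- shuffleSequence(S, seed = deriveSeed(seed, "shuffle", i))
    optimizePWM(sh, n, gaps = gaps, config = config, r2 = r2,
                seed = deriveSeed(seed, "null", i, n))@mfmax
  }, numeric(1))
  m <- mean(nullScores)
  v <- var(nullScores)
  if (!is.finite(v) || v <= 0)
    stop("shuffle null has zero variance; increase nShuffles or check S")
  new("ZResult", z = (obs - m) / sqrt(v), nShuffles = as.integer(nShuffles),
      meanNull = m, varNull = v, observed = obs, nullScores = nullScores)
}

#' Calibrate the detection threshold F0 by shuffling
#'
#' Calls repeats on the real sequences and on one shuffle of each, counts
#' surviving local maxima at every candidate threshold on a grid, and
#' returns the smallest threshold whose false discovery rate
#' Trand / (Trand + Treal) is below the target.
#'
#' @param sequences list of \linkS4class{EncodedSequence}.
#' @param config a \linkS4class{ScanConfig}; its f0 is ignored here.
#' @param targetFdr target false discovery rate (default 0.01).
#' @param grid candidate thresholds (default seq(200, 800, by = 10)).
#' @return an \linkS4class{FDRCalibration}.
#' @export
calibrateThreshold <- function(sequences, config = scanConfig(),
                               targetFdr = 0.01,
                               grid = seq(200, 800, by = 10)) {
  if (is(sequences, "EncodedSequence")) sequences <- list(sequences)
  if (!length(sequences)) stop("at least one sequence is required")
  if (targetFdr <= 0 || targetFdr >= 1) stop("targetFdr must be in (0, 1)")
  cfg0 <- config
  cfg0@f0 <- 0  # keep all maxima; threshold on the grid afterwards
  realScores <- numeric(0)
  randScores <- numeric(0)
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    realScores <- c(realScores, callRepeats(s, cfg0)$mfmax)
    sh <- shuffleSequence(s, seed = deriveSeed(cfg0@seed, "calib", i))
    randScores <- c(randScores, callRepeats(sh, cfg0)$mfmax)
  }
  for (f0 in sort(grid)) {
    tReal <- sum(realScores > f0)
    tRand <- sum(randScores > f0)
    if (tReal + tRand == 0L) next
    fdr <- tRand / (tRand + tReal)
    if (fdr < targetFdr) {
      return(new("FDRCalibration", f0 = f0, tRand = as.integer(tRand),
                 tReal = as.integer(tReal), fdr = fdr, grid = grid))
    }
  }
  bestFdr <- min(vapply(grid, function(f0) {
    tr <- sum(randScores > f0)
    te <- sum(realScores > f0)
    if (tr + te == 0L) NA_real_ else tr / (tr + te)
  }, numeric(1)), na.rm = TRUE)
  stop(sprintf(
    "target FDR %.3g unreachable on the grid; best achievable %.3g",
    targetFdr, bestFdr))
}
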