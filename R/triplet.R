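# Triplet-periodicity filter: windows whose bases depend on the reading
# phase 1,2,3 (i.e. indel-free period-3 structure, mostly coding sequence)
# are excluded from the scan before any matrix optimization.

#' Triplet-periodicity statistic of a window
#'
#' Counts the 3 x 4 matrix m3(phase, base) with the phase of position i
#' cycling 1, 2, 3 from the window start, and computes the mutual-information
#' G-statistic
#' \deqn{2I = 2[\sum m_3 \ln m_3 - \sum x \ln x - \sum y \ln y + L \ln L]}
#' (with 0 ln 0 = 0), which is chi-square distributed with
#' (3 - 1)(4 - 1) = 6 degrees of freedom for a random window.  The
#' normal-argument transform is x3 = sqrt(4I) - sqrt(11) (the classical
#' sqrt(2 chi^2) - sqrt(2 df - 1) approximation).
#'
#' @param S an \linkS4class{EncodedSequence} window of length >= 30.
#' @return a \linkS4class{TripletStat}.
#' @export
tripletStatistic <- function(S) {
  stopifnot(is(S, "EncodedSequence"))
  s <- S@codes
  L <- length(s)
  if (L < 30L) stop("window too short for the triplet statistic (L >= 30)")
  phase <- rep_len(1:3, L)
  m3 <- matrix(tabulate(phase + 3L * (s - 1L), nbins = 12L), nrow = 3L)
  xlx <- function(v) sum(ifelse(v > 0, v * log(v), 0))
  twoI <- 2 * (xlx(m3) - xlx(rowSums(m3)) - xlx(colSums(m3)) + L * log(L))
  twoI <- max(twoI, 0)  # guard tiny negative rounding
  x3 <- sqrt(2 * twoI) - sqrt(11)
  new("TripletStat", m3 = m3, twoI = twoI, x3 = x3)
}

#' Triplet filter decision
#'
#' A window is analyzed only if x3 is strictly below the threshold (default
#' 3.0 on the normal scale); windows at or above it carry indel-free triplet
#' periodicity and are skipped.
#'
#' @param stat a \linkS4class{TripletStat}.
#' @param threshold cutoff on x3.
#' @return TRUE if the window passes (is analyzed).
#' @export
passesTripletFilter <- function(stat, threshold = 3.0) {
  stopifnot(is(stat, "TripletStat"))
  stat@x3 < threshold
}
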