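# Affine-gap profile alignment: the fitness kernel of the whole method.
# A window S of length L is aligned against the tandem-extended profile of
# its weight matrix (grid column j scores from matrix column ((j-1) mod n)+1).
# The match state has free boundary zeros (the alignment may start anywhere),
# gap states cannot start before the alignment, and the score is the largest
# match-state value on the far boundaries of the L x L grid.  There is no
# max(0, .) inside the recursion.

#' Affine gap costs constructor
#'
#' @param d gap-open cost (default 25).
#' @param e gap-extension cost (default 6).
#' @return a \linkS4class{GapParams}.
#' @export
gapParams <- function(d = 25.0, e = 6.0) {
  new("GapParams", d = as.numeric(d), e = as.numeric(e))
}

checkAlignArgs <- function(S, W) {
  stopifnot(is(S, "EncodedSequence"), is(W, "WeightMatrix"))
  if (length(S@codes) < ncol(W@weights))
    stop("window shorter than the matrix period")
  if (!all(is.finite(W@weights)))
    stop("weight matrix contains non-finite entries")
}

#' Score a window against the tandem-extended profile
#'
#' Returns the best affine-gap alignment score F_max (the GA's objective
#' function for one matrix).
#'
#' @param S an \linkS4class{EncodedSequence} window.
#' @param W a standardized \linkS4class{WeightMatrix}.
#' @param gaps a \linkS4class{GapParams}.
#' @return the score, a single numeric.
#' @export
scoreProfileAlignment <- function(S, W, gaps = gapParams()) {
  checkAlignArgs(S, W)
  .dpScore(S@codes, W@weights, gaps@d, gaps@e)
}

#' Optimal alignment with traceback
#'
#' Recovers the alignment path behind F_max: from the best far-boundary
#' match cell back to the first cell with score zero.  Ties prefer
#' diagonal over vertical over horizontal steps.
#'
#' @inheritParams scoreProfileAlignment
#' @return an \linkS4class{AlignmentResult}.
#' @export
tracebackAlignment <- function(S, W, gaps = gapParams()) {
  checkAlignArgs(S, W)
  r <- .dpTraceback(S@codes, W@weights, gaps@d, gaps@e)
  new("AlignmentResult", fmax = r$fmax,
      i0 = as.integer(r$i0), im = as.integer(r$im),
      j0 = as.integer(r$j0), jm = as.integer(r$jm),
      pairs = r$pairs)
}

#' Brute-force alignment score (test oracle)
#'
#' Exhaustive enumeration of every monotone affine-gap path under the same
#' boundary and terminal conventions as the dynamic program; exponential,
#' guarded to windows of at most 12 bases.  Exists to validate the DP, not
#' for production use.
#'
#' @inheritParams scoreProfileAlignment
#' @return the exact optimum score.
#' @export
bruteForceAlign <- function(S, W, gaps = gapParams()) {
  checkAlignArgs(S, W)
  if (length(S@codes) > 12L)
    stop("brute-force enumeration is limited to windows of length <= 12")
  .bruteForceScore(S@codes, W@weights, gaps@d, gaps@e)
}

#' Recompute an alignment's score from its traceback path
#'
#' Sums the matrix scores of matched pairs and subtracts affine gap costs
#' (d to open, e to extend); used to assert internal consistency of the
#' traceback.
#'
#' @param aln an \linkS4class{AlignmentResult}.
#' @param S,W,gaps the inputs the alignment was computed from.
#' @return the recomputed score.
#' @export
alignmentScore <- function(aln, S, W, gaps = gapParams()) {
  stopifnot(is(aln, "AlignmentResult"))
  p <- aln@pairs
  if (nrow(p) == 0L) return(0)
  n <- ncol(W@weights)
  score <- 0
  prevGap <- 0L  # 0 none, 1 window-gap column, 2 profile-gap column
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1L]
    j <- p[k, 2L]
    if (i > 0L && j > 0L) {
      score <- score + W@weights[S@codes[i], (j - 1L) %% n + 1L]
      prevGap <- 0L
    } else if (j == 0L) {          # gap in profile (window base unmatched)
      score <- score - if (prevGap == 2L) gaps@e else gaps@d
      prevGap <- 2L
    } else {                       # gap in window
      score <- score - if (prevGap == 1L) gaps@e else gaps@d
      prevGap <- 1L
    }
  }
  score
}

#' Render an alignment as repeat-unit rows
#'
#' Text rendering with one row per repeat unit: matched window bases in
#' upper case at their profile position, gaps as '.', profile positions 10
#' and 11 headed 'a' and 'b' for periods of 10 or more.
#'
#' @param aln an \linkS4class{AlignmentResult}.
#' @param S the aligned window.
#' @param n the period.
#' @return a character vector of lines.
#' @export
renderAlignment <- function(aln, S, n) {
  p <- aln@pairs
  if (nrow(p) == 0L) return(character())
  bases <- c("A", "T", "C", "G")
  # column label row
  lab <- vapply(seq_len(n), function(j) {
    if (j < 10L) as.character(j) else letters[j - 9L]
  }, character(1))
  lines <- paste0("NO\t", paste(lab, collapse = ""))
  row <- character(0)
  unitNo <- 1L
  lastCol <- 0L
  flush <- function(row, unitNo) {
    sprintf("%d\t%s", unitNo, paste(row, collapse = ""))
  }
  out <- character(0)
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1L]
    j <- p[k, 2L]
    col <- if (j > 0L) (j - 1L) %% n + 1L else lastCol
    if (j > 0L && col <= lastCol && length(row)) {
      out <- c(out, flush(row, unitNo))
      unitNo <- unitNo + 1L
      row <- character(0)
    }
    row <- c(row, if (i > 0L) bases[S@codes[i]] else ".")
    if (j > 0L) lastCol <- col
  }
  if (length(row)) out <- c(out, flush(row, unitNo))
  c(lines, out)
}
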