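# Random position weight matrix (RPWM) generation: frequency matrices from
# a random sequence paired against the periodic position sequence, binomial
# z-score normalization, and standardization of every matrix to a common
# squared norm R2 and background projection Kd so that alignment scores of
# different matrices are comparable.

#' Target squared norm for a standardized matrix
#'
#' All matrices of period n are scaled to R2 = 55000 / n^0.61; the exponent
#' and constant are the method's defaults, exposed for sensitivity analysis.
#'
#' @param n period length.
#' @param constant,exponent scaling parameters.
#' @return the R2 target.
#' @export
r2Target <- function(n, constant = 55000, exponent = 0.61) {
  constant / n^exponent
}

#' Period-independent (flat) norm target for region calling
#'
#' Alternative R2 target with a constant squared norm per matrix column:
#' R2 = perPosition * n, i.e. a per-cell root-mean-square of
#' sqrt(perPosition / 4) (about 5.2 at the default).  Under
#' \code{\link{r2Target}} the per-cell magnitude grows steeply as the
#' period shrinks, so optimized alignment scores of short-period matrices
#' dominate those of longer periods by an order of magnitude and no single
#' detection threshold can serve a period range.  With the flat target,
#' cell weights stay on the scale of the gap costs (opening a gap costs
#' about five cell standard deviations), gap-skipping through random
#' sequence is unprofitable, and null score levels are approximately
#' period-independent, which makes the fixed threshold \code{f0 = 390} of
#' \code{\link{scanConfig}} meaningful across periods.  Used as the default
#' norm by the scanning/region-calling pipeline and by
#' \code{\link{zStatistic}}; \code{\link{r2Target}} remains available for
#' standardization to the formula scale.
#'
#' @param n period length.
#' @param perPosition squared norm per matrix column (default 110).
#' @return the R2 target.
#' @export
r2TargetFlat <- function(n, perPosition = 110) {
  perPosition * n
}

#' Build a random frequency matrix
#'
#' Generates a random equiprobable sequence S1 of length \code{L1} and pairs
#' it against the periodic position sequence S2 = 1, 2, ..., n repeated,
#' accumulating the 4 x n count matrix m(i, j).
#'
#' @param n period length (2..50).
#' @param L1 generating sequence length (default 10000).
#' @param seed RNG seed.
#' @return a \linkS4class{FrequencyMatrix}.
#' @export
buildFrequencyMatrix <- function(n, L1 = 10000L, seed = 1L) {
  if (n < 2L || n > 50L) stop("period n must be in [2, 50]")
  if (L1 < n) stop("L1 must be at least n")
  s1 <- withSeed(seed, sample.int(4L, L1, replace = TRUE))
  s2 <- rep_len(seq_len(n), L1)
  counts <- matrix(tabulate(s1 + 4L * (s2 - 1L), nbins = 4L * n), nrow = 4L)
  new("FrequencyMatrix", counts = counts, L1 = as.integer(L1))
}

#' Normalize a frequency matrix to a weight matrix
#'
#' Each cell becomes the standardized deviation of the observed count from
#' its expectation under independence of base and position:
#' m1(i, j) = (m(i, j) - L1 p(i, j)) / sqrt(L1 p(i, j) (1 - p(i, j))),
#' with p(i, j) = x(i) y(j) / L1^2 from the marginals.
#'
#' @param M a \linkS4class{FrequencyMatrix}.
#' @return an unstandardized \linkS4class{WeightMatrix} (r2/kd slots NA).
#' @export
normalizeMatrix <- function(M) {
  stopifnot(is(M, "FrequencyMatrix"))
  m <- M@counts
  L1 <- M@L1
  x <- rowSums(m)
  y <- colSums(m)
  if (any(x == 0) || any(y == 0))
    stop("cannot normalize: zero marginal in the frequency matrix")
  p <- outer(x, y) / L1^2
  w <- (m - L1 * p) / sqrt(L1 * p * (1 - p))
  new("WeightMatrix", weights = w, r2 = NA_real_, kd = NA_real_)
}

#' Standardize a weight matrix to fixed R2 and Kd
#'
#' Applies the affine map M' = a M1 + b B, B(i, j) = p1(i) p2(j) with
#' p2(j) = 1/n, solving (a, b) in closed form so that the background
#' projection Kd = sum(M' B) equals \code{kd} and the squared norm
#' R2 = sum(M'^2) equals \code{r2}.  The cross terms cancel, so
#' a = sqrt((r2 - kd^2/c2) / (R1 - K1^2/c2)) with c2 = sum(B^2); the
#' positive root keeps the matrix's pattern.  Idempotent.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param background length-4 nucleotide probabilities p1 of the scanned
#'   window (default equiprobable).
#' @param r2 target squared norm (default \code{r2Target(n)}).
#' @param kd target background projection (default -1.5).
#' @return a standardized \linkS4class{WeightMatrix}.
#' @export
standardizeMatrix <- function(W, background = rep(0.25, 4),
                              r2 = r2Target(ncol(weights(W))), kd = -1.5) {
  stopifnot(is(W, "WeightMatrix"))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 probabilities summing to 1")
  m1 <- W@weights
  n <- ncol(m1)
  B <- outer(background, rep(1 / n, n))
  c2 <- sum(B^2)
  K1 <- sum(m1 * B)
  R1 <- sum(m1^2)
  denom <- R1 - K1^2 / c2
  if (denom < 1e-9 * max(R1, 1))
    stop("degenerate matrix: proportional to the background, cannot standardize")
  num <- r2 - kd^2 / c2
  if (num <= 0)
    stop("targets unreachable: r2 must exceed kd^2 / sum(B^2)")
  a <- sqrt(num / denom)
  b <- (kd - a * K1) / c2
  w <- a * m1 + b * B
  new("WeightMatrix", weights = w, r2 = sum(w^2), kd = sum(w * B))
}

#' Generate a population of standardized random matrices
#'
#' N independent matrices, each built from a distinct random generating
#' sequence, normalized and standardized to the common R2/Kd targets.
#'
#' @param n period length.
#' @param N population size (reference scale 500; GA needs >= 4).
#' @param background window nucleotide probabilities for standardization.
#' @param seed RNG seed.
#' @param L1 generating sequence length.
#' @param r2,kd standardization targets.
#' @return a \linkS4class{MatrixSet} with unevaluated (NA) fitness.
#' @export
generatePopulation <- function(n, N = 500L, background = rep(0.25, 4),
                               seed = 1L, L1 = 10000L,
                               r2 = r2Target(n), kd = -1.5) {
  if (N < 4L) stop("population size must be at least 4")
  mats <- vector("list", N)
  for (i in seq_len(N)) {
    fm <- buildFrequencyMatrix(n, L1 = L1, seed = deriveSeed(seed, i))
    mats[[i]] <- standardizeMatrix(normalizeMatrix(fm), background,
                                   r2 = r2, kd = kd)
  }
  new("MatrixSet", matrices = mats, fitness = rep(NA_real_, N))
}

#' Consensus sequence of a weight matrix
#'
#' The base with the largest weight in each column, as a lower-case string;
#' descriptive summary of the repeat unit a matrix encodes.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @return a string of length n.
#' @export
consensusSequence <- function(W) {
  paste(c("a", "t", "c", "g")[apply(W@weights, 2L, which.max)],
        collapse = "")
}

#' Serialize a weight matrix to TSV
#'
#' Four rows labeled a/t/c/g, n columns, full float precision; round-trip
#' exact to 1e-12 via \code{\link{readMatrixTsv}}.
#'
#' @param W a \linkS4class{WeightMatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMatrixTsv <- function(W, path) {
  m <- W@weights
  rownames(m) <- c("a", "t", "c", "g")
  df <- data.frame(base = rownames(m),
                   format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("base", seq_len(ncol(m))))
  invisible(path)
}

#' Read a weight matrix from TSV
#'
#' @param path file written by \code{\link{writeMatrixTsv}}.
#' @return a \linkS4class{WeightMatrix} (r2/kd recomputed against an
#'   equiprobable background).
#' @export
readMatrixTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  n <- ncol(m)
  B <- outer(rep(0.25, 4), rep(1 / n, n))
  new("WeightMatrix", weights = m, r2 = sum(m^2), kd = sum(m * B))
}
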