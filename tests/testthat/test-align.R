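randomInstance <- function(L, n) {
  s <- new("EncodedSequence", id = "w", codes = sample(4L, L, TRUE),
           ambiguous = integer())
  w <- matrix(runif(4 * n, -8, 8), 4, n)
  W <- new("WeightMatrix", weights = w, r2 = sum(w^2), kd = 0)
  list(s = s, W = W)
}

test_that("DP boundary semantics: alignment may start and end anywhere", {
  # window "aa" against n = 2 with q(a,1) = 3, q(a,2) = -1: the best path
  # matches the second base against profile column 1 starting from the
  # zero boundary, score 3 (not the full-diagonal 3 - 1 = 2)
  s <- encodeSequence("aa")
  w <- matrix(c(3, -5, -5, -5, -1, -5, -5, -5), 4, 2)
  W <- new("WeightMatrix", weights = w, r2 = sum(w^2), kd = 0)
  expect_equal(scoreProfileAlignment(s, W), 3)
  aln <- tracebackAlignment(s, W)
  expect_equal(fmax(aln), 3)
  expect_identical(aln@i0, 2L)
  expect_identical(aln@im, 2L)
})

test_that("an all-negative matrix yields the empty alignment with score 0", {
  s <- encodeSequence("acgtacgt")
  w <- matrix(-1, 4, 4)
  W <- new("WeightMatrix", weights = w, r2 = sum(w^2), kd = 0)
  expect_equal(scoreProfileAlignment(s, W), 0)
  aln <- tracebackAlignment(s, W)
  expect_equal(fmax(aln), 0)
  expect_identical(nrow(aln@pairs), 0L)
})

test_that("DP matches the brute-force oracle on random small instances", {
  set.seed(42)
  for (i in 1:150) {
    L <- sample(4:10, 1L)
    n <- sample(2:4, 1L)
    inst <- randomInstance(L, n)
    d <- runif(1, 2, 12)
    e <- runif(1, 0.5, d)
    gp <- gapParams(d, e)
    expect_equal(scoreProfileAlignment(inst$s, inst$W, gp),
                 bruteForceAlign(inst$s, inst$W, gp), tolerance = 1e-9)
  }
})

test_that("traceback score equals fmax when recomputed from the path", {
  set.seed(7)
  for (i in 1:40) {
    inst <- randomInstance(sample(20:60, 1L), sample(2:6, 1L))
    gp <- gapParams(6, 2)
    aln <- tracebackAlignment(inst$s, inst$W, gp)
    expect_equal(alignmentScore(aln, inst$s, inst$W, gp), fmax(aln),
                 tolerance = 1e-9)
    expect_equal(fmax(aln), scoreProfileAlignment(inst$s, inst$W, gp),
                 tolerance = 1e-9)
    # the path is monotone and within bounds
    p <- aln@pairs
    if (nrow(p)) {
      iw <- p[p[, "window"] > 0, "window"]
      jg <- p[p[, "grid"] > 0, "grid"]
      expect_true(all(diff(iw) == 1L))
      expect_true(all(diff(jg) == 1L))
      expect_identical(aln@i0, unname(iw[1]))
      expect_identical(aln@im, unname(iw[length(iw)]))
    }
  }
})

test_that("a perfect tandem aligns gaplessly along the diagonal", {
  unit <- c(1L, 3L, 4L, 2L, 2L)
  s <- new("EncodedSequence", id = "p", codes = rep(unit, 8L),
           ambiguous = integer())
  w <- matrix(-2, 4, 5)
  for (j in 1:5) w[unit[j], j] <- 4
  W <- new("WeightMatrix", weights = w, r2 = sum(w^2), kd = 0)
  aln <- tracebackAlignment(s, W)
  expect_equal(fmax(aln), 4 * 40)
  expect_true(all(aln@pairs > 0L))  # no gaps
  expect_identical(aln@i0, 1L)
  expect_identical(aln@im, 40L)
})

test_that("gap costs validate and brute force is guarded", {
  expect_error(gapParams(2, 5), "d >= e >= 0")
  inst <- randomInstance(20L, 3L)
  expect_error(bruteForceAlign(inst$s, inst$W), "length <= 12")
})

test_that("renderAlignment produces one row per repeat unit", {
  unit <- c(1L, 2L, 3L)
  s <- new("EncodedSequence", id = "p", codes = rep(unit, 4L),
           ambiguous = integer())
  w <- matrix(-2, 4, 3); for (j in 1:3) w[unit[j], j] <- 4
  W <- new("WeightMatrix", weights = w, r2 = sum(w^2), kd = 0)
  aln <- tracebackAlignment(s, W)
  lines <- renderAlignment(aln, s, 3L)
  expect_identical(length(lines), 5L)  # header + 4 units
  expect_match(lines[2], "ATC")
})
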