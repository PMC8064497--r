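shortWindow <- function(seed = 1L, L = 120L) {
  withr <- NULL  # no dependency: plain RNG scoping
  set.seed(seed)
  new("EncodedSequence", id = "w", codes = sample(4L, L, TRUE),
      ambiguous = integer())
}

test_that("gaConfig validates its fields", {
  expect_error(gaConfig(populationSize = 3), "at least 4")
  expect_error(gaConfig(mutationFraction = 0), "mutationFraction")
  expect_error(gaConfig(stallLimit = 0), ">= 1")
  expect_error(gaConfig(mutationRange = c(5, -5)), "mutationRange")
})

test_that("evaluatePopulation ranks fitness non-increasingly", {
  S <- shortWindow(2L)
  Q <- generatePopulation(3L, N = 8L, seed = 1L, L1 = 1000L)
  R <- evaluatePopulation(S, Q)
  v <- fitnessValues(R)
  expect_false(anyNA(v))
  expect_true(all(diff(v) <= 0))
  expect_equal(v[1], scoreProfileAlignment(S, R@matrices[[1]]))
})

test_that("mutation changes ~5% of matrices and preserves the invariants", {
  Q <- generatePopulation(4L, N = 20L, seed = 3L, L1 = 1000L)
  set.seed(1)
  M <- mutatePopulation(Q, gaConfig(populationSize = 20L))
  changed <- vapply(seq_len(20L), function(i) {
    !identical(weights(M@matrices[[i]]), weights(Q@matrices[[i]]))
  }, logical(1))
  expect_identical(sum(changed), 1L)  # ceiling(0.05 * 20)
  for (i in which(changed)) {
    expect_lt(abs(M@matrices[[i]]@r2 - r2Target(4L)), 1e-6)
  }
  expect_true(all(is.na(fitnessValues(M)[changed])))
})

test_that("breeding replaces the worst matrix with a standardized child", {
  S <- shortWindow(5L)
  Q <- evaluatePopulation(S, generatePopulation(3L, N = 10L, seed = 2L,
                                                L1 = 1000L))
  worst <- weights(Q@matrices[[10L]])
  set.seed(2)
  B <- breedPopulation(Q, gaConfig(populationSize = 10L))
  expect_identical(length(B), 10L)
  expect_false(identical(weights(B@matrices[[10L]]), worst))
  expect_lt(abs(B@matrices[[10L]]@r2 - r2Target(3L)), 1e-6)
  expect_true(is.na(fitnessValues(B)[10L]))
  # survivors are untouched
  for (i in 1:9) {
    expect_identical(weights(B@matrices[[i]]), weights(Q@matrices[[i]]))
  }
})

test_that("optimizePWM is seed-reproducible and mFmax never decreases", {
  S <- shortWindow(8L, 150L)
  cfg <- gaConfig(populationSize = 8L, maxCycles = 40L, stallLimit = 10L)
  a <- optimizePWM(S, 5L, config = cfg, seed = 11L)
  b <- optimizePWM(S, 5L, config = cfg, seed = 11L)
  expect_equal(fmax(a), fmax(b))
  expect_identical(weights(a@matrix), weights(b@matrix))
  # the returned score is attained by the returned matrix
  expect_equal(scoreProfileAlignment(S, a@matrix), fmax(a), tolerance = 1e-9)
  # more budget cannot do worse (same seed, longer run)
  cfg2 <- gaConfig(populationSize = 8L, maxCycles = 120L, stallLimit = 10L)
  c <- optimizePWM(S, 5L, config = cfg2, seed = 11L)
  expect_gte(fmax(c), fmax(a) - 1e-9)
})

test_that("optimizePWM improves on the initial population for a clean signal", {
  unit <- c(2L, 4L, 1L, 3L)
  S <- new("EncodedSequence", id = "p", codes = rep(unit, 40L),
           ambiguous = integer())
  cfg <- gaConfig(populationSize = 12L, maxCycles = 150L, stallLimit = 60L)
  res <- optimizePWM(S, 4L, config = cfg, seed = 4L, r2 = r2TargetFlat(4L))
  init <- evaluatePopulation(
    S, generatePopulation(4L, N = 12L,
                          background = tabulate(codes(S), 4L) / length(S),
                          seed = rpwmtr:::deriveSeed(4L, 7L),
                          r2 = r2TargetFlat(4L)))
  expect_gt(fmax(res), fitnessValues(init)[1])
  # the optimized matrix recovers the planted unit up to tandem phase
  rotations <- c("tgac", "gact", "actg", "ctga")
  expect_true(consensusSequence(res@matrix) %in% rotations)
})

test_that("the stall rule terminates runs on featureless input", {
  S <- shortWindow(13L, 100L)
  cfg <- gaConfig(populationSize = 8L, maxCycles = 5000L, stallLimit = 5L)
  res <- optimizePWM(S, 3L, config = cfg, seed = 2L, r2 = r2TargetFlat(3L))
  expect_true(res@converged)
  expect_lt(res@cycles, 5000L)
})
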