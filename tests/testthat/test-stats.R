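test_that("zStatistic is deterministic and separates signal from noise", {
  set.seed(21)
  unit <- sample(4L, 5L, TRUE)
  S <- new("EncodedSequence", id = "s", codes = rep(unit, 40L),
           ambiguous = integer())
  cfg <- gaConfig(populationSize = 8L, maxCycles = 60L, stallLimit = 30L)
  z1 <- zStatistic(S, 5L, config = cfg, nShuffles = 8L, seed = 9L)
  z2 <- zStatistic(S, 5L, config = cfg, nShuffles = 8L, seed = 9L)
  expect_equal(z1@z, z2@z)
  expect_identical(z1@nullScores, z2@nullScores)
  expect_identical(z1@nShuffles, 8L)
  expect_equal(z1@z, (z1@observed - z1@meanNull) / sqrt(z1@varNull))
  # a perfect tandem sits far above its own shuffle null
  expect_gt(z1@z, 3)
  # a random sequence of the same composition does not
  sh <- shuffleSequence(S, seed = 1L)
  z0 <- zStatistic(sh, 5L, config = cfg, nShuffles = 8L, seed = 9L)
  expect_lt(z0@z, z1@z)
})

test_that("zStatistic null scores match independent shuffle optimizations", {
  set.seed(3)
  S <- new("EncodedSequence", id = "s", codes = sample(4L, 120L, TRUE),
           ambiguous = integer())
  cfg <- gaConfig(populationSize = 6L, maxCycles = 20L, stallLimit = 10L)
  zr <- zStatistic(S, 4L, config = cfg, nShuffles = 4L, seed = 5L)
  sh1 <- shuffleSequence(S, seed = rpwmtr:::deriveSeed(5L, "shuffle", 1L))
  direct <- optimizePWM(sh1, 4L, config = cfg, r2 = r2TargetFlat(4L),
                        seed = rpwmtr:::deriveSeed(5L, "null", 1L, 4L))
  expect_equal(zr@nullScores[1], fmax(direct))
})

test_that("calibrateThreshold picks the smallest grid value under the FDR", {
  # repeat-bearing sequences versus their shuffles: the planted signal
  # scores clear the null, so a grid point separating them exists
  set.seed(55)
  mkSeq <- function(seed) {
    set.seed(seed)
    unit <- sample(4L, 5L, TRUE)
    new("EncodedSequence", id = paste0("s", seed),
        codes = c(sample(4L, 30L, TRUE), rep(unit, 36L),
                  sample(4L, 30L, TRUE)),
        ambiguous = integer())
  }
  seqs <- lapply(1:2, mkSeq)
  cfg <- scanConfig(windowLength = 120L, step = 60L, nMin = 5L, nMax = 5L,
                    neighborhood = 1L,
                    ga = gaConfig(populationSize = 8L, maxCycles = 60L,
                                  stallLimit = 30L), seed = 2L)
  cal <- calibrateThreshold(seqs, cfg, targetFdr = 0.1,
                            grid = seq(100, 800, by = 25))
  expect_s4_class(cal, "FDRCalibration")
  expect_lt(cal@fdr, 0.1)
  expect_gt(cal@tReal, 0L)
  expect_true(cal@f0 %in% cal@grid)
  expect_error(calibrateThreshold(list(), cfg), "at least one sequence")
  expect_error(calibrateThreshold(seqs, cfg, targetFdr = 1.5), "in \\(0, 1\\)")
})

test_that("an unreachable FDR target raises a diagnostic error", {
  set.seed(8)
  S <- new("EncodedSequence", id = "r", codes = sample(4L, 130L, TRUE),
           ambiguous = integer())
  cfg <- scanConfig(windowLength = 120L, step = 120L, nMin = 3L, nMax = 3L,
                    ga = gaConfig(populationSize = 6L, maxCycles = 30L,
                                  stallLimit = 15L), seed = 4L)
  # a pure-noise sequence cannot separate real from shuffled at FDR 1e-6
  expect_error(
    calibrateThreshold(S, cfg, targetFdr = 1e-6, grid = c(10, 20)),
    "unreachable")
})
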