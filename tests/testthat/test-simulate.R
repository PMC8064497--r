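test_that("plantTandemRepeats respects the requested geometry", {
  spec <- plantedRepeatSpec(unitLength = 6L, copies = 50L,
                            nInsertions = 4L, nDeletions = 7L,
                            flankLength = 40L, seed = 11L)
  sim <- plantTandemRepeats(spec)
  # total length: flanks + core + insertions - deletions
  expect_identical(length(sim$seq), 2L * 40L + 50L * 6L + 4L - 7L)
  expect_identical(length(sim$y), 300L)
  expect_true(all(sim$y == 0L))  # no substitutions requested
  # truth spans tile the post-indel core without touching the flanks
  expect_identical(length(sim$truth), 50L)
  expect_identical(min(GenomicRanges::start(sim$truth)), 41L)
  expect_identical(max(GenomicRanges::end(sim$truth)),
                   40L + 50L * 6L + 4L - 7L)
  expect_true(all(sim$truth$period == 6L))
  # deterministic in the seed
  sim2 <- plantTandemRepeats(spec)
  expect_identical(codes(sim$seq), codes(sim2$seq))
})

test_that("with no mutations the core is an exact tandem array", {
  spec <- plantedRepeatSpec(unitLength = 8L, copies = 20L,
                            nInsertions = 0L, nDeletions = 0L,
                            flankLength = 0L, seed = 3L)
  sim <- plantTandemRepeats(spec)
  m <- matrix(codes(sim$seq), nrow = 8L)
  expect_true(all(m == m[, 1]))
  expect_true(all(IRanges::width(GenomicRanges::ranges(sim$truth)) == 8L))
})

test_that("substitution draws are recorded in y and change the sequence", {
  base <- plantedRepeatSpec(unitLength = 10L, copies = 30L,
                            nInsertions = 0L, nDeletions = 0L, seed = 19L)
  clean <- plantTandemRepeats(base)
  mut <- base
  mut@nSubstitutions <- 150L
  sim <- plantTandemRepeats(mut)
  expect_identical(sum(sim$y), 150L)
  expect_identical(length(sim$y), 300L)
  # about 3/4 of draws change the base (replacement is uniform over 4)
  nDiff <- sum(codes(sim$seq) != codes(clean$seq))
  expect_gt(nDiff, 0)
  expect_lte(nDiff, 150)
})

test_that("mutationLoad collapses to 2*sum(y)/coreLength", {
  spec <- plantedRepeatSpec(unitLength = 6L, copies = 40L)
  set.seed(1)
  y <- rpois(240L, 0.5)
  expect_equal(mutationLoad(y, spec), 2 * sum(y) / 240)
  expect_error(mutationLoad(y[-1], spec), "length")
})

test_that("substitutionsForLoad inverts the load statistic", {
  spec <- plantedRepeatSpec(unitLength = 30L, copies = 100L)
  for (x in c(0.5, 1, 3.2, 4)) {
    draws <- substitutionsForLoad(x, spec)
    expect_equal(2 * draws / 3000, x, tolerance = 1e-3)
  }
  # realized loads track the target closely on a planted sequence
  spec@nSubstitutions <- substitutionsForLoad(2.0, spec)
  sim <- plantTandemRepeats(spec)
  expect_equal(mutationLoad(sim$y, spec), 2.0, tolerance = 1e-6)
})

test_that("countDetectedUnits applies the coverage and exact-period rules", {
  truth <- GenomicRanges::GRanges("s", IRanges::IRanges(
    start = seq(1, 55, by = 6), width = 6L), period = 6L,
    unit = 1:10)
  # a called region covering the first 33 bases: units 1-5 fully covered,
  # unit 6 covered 3/6 = exactly the 0.5 threshold
  regions <- GenomicRanges::GRanges("s", IRanges::IRanges(1L, 33L),
                                    period = 6L)
  expect_identical(rpwmtr:::countDetectedUnits(truth, regions, 6L, 0.5), 6L)
  # a harmonic period does not count
  regions$period <- 12L
  expect_identical(rpwmtr:::countDetectedUnits(truth, regions, 6L, 0.5), 0L)
  expect_identical(
    rpwmtr:::countDetectedUnits(truth, GenomicRanges::GRanges(), 6L, 0.5), 0L)
})

test_that("detectionRateExperiment detects a clean short-period array", {
  # period 7, not a multiple of 3: an indel-free triplet-periodic array
  # would be removed by the coding filter by design
  spec <- plantedRepeatSpec(unitLength = 7L, copies = 40L,
                            nInsertions = 0L, nDeletions = 0L,
                            flankLength = 60L, seed = 23L)
  cfg <- scanConfig(windowLength = 200L, step = 80L, nMin = 6L, nMax = 8L,
                    neighborhood = 2L, f0 = 390,
                    ga = gaConfig(populationSize = 12L, maxCycles = 120L,
                                  stallLimit = 60L), seed = 6L)
  res <- detectionRateExperiment(list(spec), cfg, replicates = 2L)
  expect_identical(nrow(res), 1L)
  expect_equal(res$x, 0)
  expect_gt(res$y, 0.5)
  expect_equal(res$k, res$y * 40)
})
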