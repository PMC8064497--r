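fakeSurface <- function(scores, starts, periods) {
  W <- standardizeMatrix(normalizeMatrix(buildFrequencyMatrix(periods[1],
                                                              seed = 1L)))
  mats <- lapply(seq_along(starts), function(i) {
    lapply(periods, function(n) W)
  })
  new("ScanSurface", scores = scores, starts = as.integer(starts),
      periods = as.integer(periods),
      skippedWindows = logical(length(starts)), matrices = mats,
      seqId = "s")
}

test_that("findLocalMaxima applies the strict F0 threshold", {
  sc <- matrix(0, 5, 1)
  sc[3, 1] <- 389.9
  cfg <- scanConfig(windowLength = 100L, step = 10L, nMin = 2L, nMax = 2L,
                    neighborhood = 2L)
  surf <- fakeSurface(sc, seq(1, 41, 10), 2L)
  expect_length(findLocalMaxima(surf, cfg), 0L)
  sc[3, 1] <- 390.1
  surf2 <- fakeSurface(sc, seq(1, 41, 10), 2L)
  gr <- findLocalMaxima(surf2, cfg)
  expect_length(gr, 1L)
  expect_identical(gr$period, 2L)
  expect_equal(gr$mfmax, 390.1)
})

test_that("a higher rival inside the neighborhood suppresses a peak", {
  # two periods; period 1 has a 400 peak, period 2 a 500 peak nearby
  sc <- matrix(0, 9, 2)
  sc[4, 1] <- 400
  sc[6, 2] <- 500
  cfg <- scanConfig(windowLength = 100L, step = 10L, nMin = 2L, nMax = 3L,
                    neighborhood = 3L)
  surf <- fakeSurface(sc, seq(1, 81, 10), c(2L, 3L))
  gr <- findLocalMaxima(surf, cfg)
  expect_length(gr, 1L)
  expect_identical(gr$period, 3L)
  # far apart (outside +/- neighborhood) both survive
  sc2 <- matrix(0, 9, 2)
  sc2[1, 1] <- 400
  sc2[9, 2] <- 500
  gr2 <- findLocalMaxima(fakeSurface(sc2, seq(1, 81, 10), c(2L, 3L)), cfg)
  expect_length(gr2, 2L)
})

test_that("within a period only the 1-D local maximum survives", {
  sc <- matrix(0, 6, 1)
  sc[2, 1] <- 450
  sc[3, 1] <- 460
  cfg <- scanConfig(windowLength = 100L, step = 10L, nMin = 2L, nMax = 2L,
                    neighborhood = 2L)
  gr <- findLocalMaxima(fakeSurface(sc, seq(1, 51, 10), 2L), cfg)
  expect_length(gr, 1L)
  expect_equal(gr$mfmax, 460)
})

test_that("scanSequence builds the surface and skips filtered windows", {
  set.seed(31)
  unit <- sample(4L, 6L, TRUE)
  chrom <- new("EncodedSequence", id = "c",
               codes = c(sample(4L, 40L, TRUE), rep(unit, 30L),
                         sample(4L, 40L, TRUE)),
               ambiguous = integer())
  cfg <- scanConfig(windowLength = 120L, step = 60L, nMin = 6L, nMax = 6L,
                    f0 = 100, neighborhood = 1L,
                    ga = gaConfig(populationSize = 8L, maxCycles = 30L,
                                  stallLimit = 30L), seed = 5L)
  surf <- scanSequence(chrom, cfg)
  expect_identical(dim(surf@scores),
                   c(length(seq(1L, length(chrom) - 120L + 1L, 60L)), 1L))
  expect_true(all(surf@scores[!surf@skippedWindows, ] > 0))
  # identical reruns: per-cell seeds derive from the config seed
  surf2 <- scanSequence(chrom, cfg)
  expect_identical(surf@scores, surf2@scores)
})

test_that("windows overlapping long ambiguous runs are skipped", {
  txt <- paste0(strrep("acgt", 30), strrep("n", 60), strrep("acgt", 30))
  chrom <- encodeSequence(txt, id = "amb")
  cfg <- scanConfig(windowLength = 100L, step = 100L, nMin = 3L, nMax = 3L,
                    ga = gaConfig(populationSize = 8L, maxCycles = 10L,
                                  stallLimit = 10L), seed = 1L)
  surf <- scanSequence(chrom, cfg)
  # the middle window overlaps the 60-base ambiguous run
  expect_true(surf@skippedWindows[2L])
  expect_equal(surf@scores[2L, 1L], 0)
})

test_that("callRepeats finds a planted repeat and reports its span", {
  set.seed(77)
  unit <- sample(4L, 8L, TRUE)
  chrom <- new("EncodedSequence", id = "chr",
               codes = c(sample(4L, 60L, TRUE), rep(unit, 40L),
                         sample(4L, 60L, TRUE)),
               ambiguous = integer())
  cfg <- scanConfig(windowLength = 200L, step = 60L, nMin = 7L, nMax = 9L,
                    neighborhood = 4L, f0 = 390,
                    ga = gaConfig(populationSize = 12L, maxCycles = 120L,
                                  stallLimit = 60L), seed = 3L)
  gr <- callRepeats(chrom, cfg)
  expect_gte(length(gr), 1L)
  expect_true(8L %in% gr$period)
  hit <- gr[gr$period == 8L][1L]
  planted <- GenomicRanges::GRanges("chr", IRanges::IRanges(61L, 380L))
  ov <- GenomicRanges::pintersect(GenomicRanges::granges(hit), planted)
  # the called span (bounded by the 200-nt window) lies inside the array
  expect_gt(IRanges::width(ov) / IRanges::width(hit), 0.9)
  expect_identical(nchar(hit$consensus), 8L)
})
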