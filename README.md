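# rpwmtr

Detection of highly divergent tandem repeats (TRs) in DNA by genetic-
algorithm optimization of random position weight matrices (PWMs) against
sliding sequence windows.

A window is scored by the best affine-gap local alignment between the
window and a 4 x n weight matrix tiled periodically along an unbounded
grid.  A genetic algorithm evolves a population of standardized random
matrices per (window, period) cell; repeat regions are called as
two-dimensional local maxima of the resulting score surface above a
fixed threshold (F0 = 390).  Triplet-periodic windows (mostly coding
sequence) are excluded with a chi-square mutual-information filter, and
significance can be assessed with a shuffle-based Z statistic.  The
package also ships synthetic planted-repeat benchmark generators, FDR
threshold calibration, and Monte-Carlo interval-overlap enrichment
statistics.

See the methods vignette (`vignettes/methods.Rmd`) for the model, the
score-scale calibration, and the problem-size scaling choices.

## Worked example

Plant a divergent 6-nt tandem array (60 copies, substitution load
x = 1.0, a few indels, random flanks), then call repeats and score
significance:

```r
library(rpwmtr)

spec <- plantedRepeatSpec(unitLength = 6L, copies = 60L, nInsertions = 3L,
                          nDeletions = 3L, flankLength = 120L, seed = 7L)
spec@nSubstitutions <- substitutionsForLoad(1.0, spec)
sim <- plantTandemRepeats(spec)
sim$seq
#> EncodedSequence planted of length 600
#>   head: gttatgcatgggtatcaagagggtggatga

cfg <- scanConfig(windowLength = 200L, step = 60L, nMin = 5L, nMax = 7L,
                  neighborhood = 2L,
                  ga = gaConfig(populationSize = 16L, maxCycles = 150L,
                                stallLimit = 65L),
                  seed = 11L)
regions <- callRepeats(sim$seq, cfg)
regions
#> GRanges object with 1 range and 5 metadata columns:
#>       seqnames    ranges strand |    period     mfmax   consensus
#>          <Rle> <IRanges>  <Rle> | <integer> <numeric> <character>
#>   [1]  planted   192-380      * |         6   470.827      gctgcc
#>               matrix         alignment
#>               <list>            <list>
#>   [1] <WeightMatrix> <AlignmentResult>

zStatistic(sim$seq, 6L,
           config = gaConfig(populationSize = 16L, maxCycles = 150L,
                             stallLimit = 65L),
           nShuffles = 10L, seed = 3L)
#> ZResult: Z = 13.51 (observed 630.1 vs null 105.3 +/- 38.9, 10 shuffles)
```

The called region recovers the planted array (true span 121-480 here;
the call is the aligned core of the best-scoring window) at the planted
period 6, and the array is far outside the shuffle null.

## Command line

A thin CLI wraps the same functions:

```sh
inst/exec/rpwmtr simulate --unit 6 --copies 100 --flank 300 \
    --insertions 5 --deletions 5 --load 1.0 --seed 1 \
    --out planted.fa --out-bed truth.bed
inst/exec/rpwmtr scan --fasta planted.fa --out-tsv regions.tsv \
    --out-bed regions.bed --step 100 --n-min 2 --n-max 12 \
    --population 16 --seed 1
inst/exec/rpwmtr zscore --fasta planted.fa --period 6 --shuffles 25 --seed 1
inst/exec/rpwmtr overlap --regions regions.tsv --features exons.bed \
    --lengths lengths.tsv --shuffles 100 --seed 1
```

## Tests and benchmark measurements

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "rpwmtr",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`tests/testthat/test-acceptance.R` holds one test per acceptance
criterion.  The benchmark script writes the four measured targets
(`t1`: Z at substitution load 3.2 on the 30-nt benchmark, `t2`/`t3`:
detection fractions at loads 3.0 / 4.0 on the 6-nt benchmark, `t4`:
mean triplet statistic over random windows) as JSON, computed at run
time.  Two reference endpoints (`t1` and the detection fractions at
high load) are not reachable from the published constants at any
compute scale — the standardized matrices' background projection caps
the attainable score of a divergent array below the detection
threshold — and the suite reports the honest measured values rather
than adjusting constants; the methods vignette documents the analysis.
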