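# Genetic algorithm over the matrix population for one window: evaluate
# (alignment score per matrix, ranked), mutate (one random cell of a random
# 5% of matrices redrawn in [-10, 10], then re-standardized), breed (drop
# the worst, cross two rank-weighted parents column-block-wise), with the
# running best protected (elitism) and a five-cycle stall rule.

#' Genetic algorithm configuration constructor
#'
#' @param populationSize matrices in the population (reference scale 500).
#' @param mutationFraction fraction of matrices mutated per cycle.
#' @param mutationRange uniform replacement range for a mutated cell.
#' @param stallLimit consecutive cycles with the population best strictly
#'   below the running best before stopping.
#' @param maxCycles hard cap on cycles.
#' @param protectBest exclude the current best matrix from mutation
#'   (default FALSE; see \linkS4class{GAConfig}).
#' @return a \linkS4class{GAConfig}.
#' @export
gaConfig <- function(populationSize = 500L, mutationFraction = 0.05,
                     mutationRange = c(-10, 10), stallLimit = 5L,
                     maxCycles = 10000L, protectBest = FALSE) {
  new("GAConfig", populationSize = as.integer(populationSize),
      mutationFraction = mutationFraction,
      mutationRange = as.numeric(mutationRange),
      stallLimit = as.integer(stallLimit),
      maxCycles = as.integer(maxCycles),
      protectBest = isTRUE(protectBest))
}

# restandardize a raw 4 x n weights matrix; returns the matrix only
restandardizeWeights <- function(w, background, r2, kd) {
  W <- standardizeMatrix(new("WeightMatrix", weights = w,
                             r2 = NA_real_, kd = NA_real_),
                         background = background, r2 = r2, kd = kd)
  W@weights
}

# one mutation event on raw weights (uses the ambient RNG)
mutateWeightsOnce <- function(w, range, background, r2, kd) {
  i <- sample.int(4L, 1L)
  j <- sample.int(ncol(w), 1L)
  w[i, j] <- runif(1L, range[1], range[2])
  restandardizeWeights(w, background, r2, kd)
}

# rank-weighted parent sampling: ranks 1..m (1 = best) get weight m - r + 1
sampleParents <- function(m) {
  w <- rev(seq_len(m))
  p1 <- sample.int(m, 1L, prob = w)
  repeat {
    p2 <- sample.int(m, 1L, prob = w)
    if (p2 != p1) break
  }
  c(p1, p2)
}

# single-point column-block crossover of two raw weight matrices
crossoverWeights <- function(wa, wb) {
  n <- ncol(wa)
  cpt <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
  cbind(wa[, seq_len(cpt), drop = FALSE],
        wb[, seq(cpt + 1L, n), drop = FALSE])
}

#' Evaluate and rank a matrix population against a window
#'
#' Scores every matrix with the affine-gap profile aligner and orders the
#' set so the fitness vector V is non-increasing (V(1) = best).
#'
#' @param S the window, an \linkS4class{EncodedSequence}.
#' @param Q a \linkS4class{MatrixSet}.
#' @param gaps a \linkS4class{GapParams}.
#' @return the ranked \linkS4class{MatrixSet}.
#' @export
evaluatePopulation <- function(S, Q, gaps = gapParams()) {
  stopifnot(is(Q, "MatrixSet"))
  fit <- vapply(Q@matrices,
                function(W) scoreProfileAlignment(S, W, gaps), numeric(1))
  ord <- order(fit, decreasing = TRUE)
  new("MatrixSet", matrices = Q@matrices[ord], fitness = fit[ord])
}

#' Mutate a fraction of the population
#'
#' ceil(mutationFraction * N) randomly chosen matrices each get one
#' uniformly chosen cell replaced by a uniform draw from mutationRange,
#' and are re-standardized so the R2/Kd invariants hold.  Any matrix may
#' be mutated, including the current best, unless
#' \code{config@protectBest}; the running best is kept as bookkeeping by
#' \code{\link{optimizePWM}} either way.  Uses the ambient RNG stream.
#'
#' @param Q a ranked \linkS4class{MatrixSet}.
#' @param config a \linkS4class{GAConfig}.
#' @param background window base probabilities for re-standardization.
#' @param r2,kd standardization targets.
#' @return the mutated \linkS4class{MatrixSet} (fitness of mutated entries
#'   reset to NA).
#' @export
mutatePopulation <- function(Q, config = gaConfig(),
                             background = rep(0.25, 4),
                             r2 = r2Target(period(Q@matrices[[1]])),
                             kd = -1.5) {
  stopifnot(is(Q, "MatrixSet"))
  N <- length(Q@matrices)
  nm <- min(ceiling(config@mutationFraction * N), N - 1L)
  candidates <- seq_len(N)
  if (config@protectBest && !anyNA(Q@fitness))
    candidates <- candidates[-which.max(Q@fitness)]
  chosen <- sample(candidates, nm)
  mats <- Q@matrices
  fit <- Q@fitness
  for (i in chosen) {
    w <- mutateWeightsOnce(mats[[i]]@weights, config@mutationRange,
                           background, r2, kd)
    mats[[i]] <- new("WeightMatrix", weights = w, r2 = sum(w^2),
                     kd = NA_real_)
    fit[i] <- NA_real_
  }
  new("MatrixSet", matrices = mats, fitness = fit)
}

#' Replace the worst matrix by a descendant of two parents
#'
#' Drops the minimum-fitness matrix, samples two distinct parents with
#' probability increasing linearly from the worst to the best rank, builds
#' the descendant by single-point column-block crossover, re-standardizes
#' it and restores the population to size N.  Uses the ambient RNG stream.
#'
#' @inheritParams mutatePopulation
#' @return the new \linkS4class{MatrixSet} (descendant fitness NA).
#' @export
breedPopulation <- function(Q, config = gaConfig(),
                            background = rep(0.25, 4),
                            r2 = r2Target(period(Q@matrices[[1]])),
                            kd = -1.5) {
  stopifnot(is(Q, "MatrixSet"))
  N <- length(Q@matrices)
  if (N < 4L) stop("breeding requires a population of at least 4")
  ord <- order(Q@fitness, decreasing = TRUE, na.last = TRUE)
  mats <- Q@matrices[ord]
  fit <- Q@fitness[ord]
  # exclude the worst, parents from the remaining ranked N - 1
  par <- sampleParents(N - 1L)
  child <- crossoverWeights(mats[[par[1]]]@weights, mats[[par[2]]]@weights)
  child <- restandardizeWeights(child, background, r2, kd)
  mats[[N]] <- new("WeightMatrix", weights = child, r2 = sum(child^2),
                   kd = NA_real_)
  fit[N] <- NA_real_
  new("MatrixSet", matrices = mats, fitness = fit)
}

#' Optimize a matrix against a window by the genetic algorithm
#'
#' Generates the random standardized population and iterates
#' evaluate / mutate / breed, re-scoring only matrices that changed.
#' The running best mF_max never decreases.  A cycle whose population best
#' V(1) is at least the running best counts as a success and resets the
#' stall counter (equality included: the best matrix surviving untouched
#' is a success); \code{stallLimit} consecutive cycles with V(1) strictly
#' below the running best stop the run, as does \code{maxCycles}.  Since
#' mutation may hit the current best matrix, long runs persist as long as
#' the population keeps re-attaining its record.
#'
#' @param S the window, an \linkS4class{EncodedSequence}.
#' @param n period length (2..50).
#' @param background base probabilities of S for standardization (default:
#'   computed from S).
#' @param gaps a \linkS4class{GapParams}.
#' @param config a \linkS4class{GAConfig}.
#' @param seed RNG seed; the run is bit-reproducible given the seed.
#' @param r2,kd standardization targets.
#' @return a \linkS4class{GAResult}.
#' @export
optimizePWM <- function(S, n, background = NULL, gaps = gapParams(),
                        config = gaConfig(), seed = 1L,
                        r2 = r2Target(n), kd = -1.5) {
  stopifnot(is(S, "EncodedSequence"))
  if (n < 2L || n > 50L) stop("period n must be in [2, 50]")
  if (is.null(background))
    background <- tabulate(S@codes, 4L) / length(S@codes)
  # zero-frequency bases get a floor so the standardization background
  # stays a proper distribution over all four bases
  if (any(background == 0)) {
    background <- (background + 1e-4) / sum(background + 1e-4)
  }
  withSeed(seed, {
    N <- config@populationSize
    Q <- generatePopulation(n, N = N, background = background,
                            seed = deriveSeed(seed, 7L), r2 = r2, kd = kd)
    mats <- lapply(Q@matrices, function(m) m@weights)
    fit <- vapply(mats, function(w) .dpScore(S@codes, w, gaps@d, gaps@e),
                  numeric(1))
    bestIdx <- which.max(fit)
    mF <- fit[bestIdx]
    mQw <- mats[[bestIdx]]
    stall <- 0L
    cycles <- 0L
    nm <- min(ceiling(config@mutationFraction * N), N - 1L)
    rng <- config@mutationRange
    while (cycles < config@maxCycles) {
      cycles <- cycles + 1L
      # mutation: any matrix may be hit unless protectBest
      cand <- seq_len(N)
      if (config@protectBest) cand <- cand[-which.max(fit)]
      chosen <- sample(cand, nm)
      for (i in chosen) {
        mats[[i]] <- mutateWeightsOnce(mats[[i]], rng, background, r2, kd)
        fit[i] <- .dpScore(S@codes, mats[[i]], gaps@d, gaps@e)
      }
      # breeding: drop the worst, parents rank-weighted among the rest
      worst <- which.min(fit)
      ranked <- order(fit, decreasing = TRUE)
      pool <- ranked[ranked != worst]
      par <- sampleParents(length(pool))
      child <- crossoverWeights(mats[[pool[par[1]]]], mats[[pool[par[2]]]])
      child <- restandardizeWeights(child, background, r2, kd)
      mats[[worst]] <- child
      fit[worst] <- .dpScore(S@codes, child, gaps@d, gaps@e)
      v1 <- max(fit)
      if (v1 >= mF) {
        if (v1 > mF) {
          mF <- v1
          mQw <- mats[[which.max(fit)]]
        }
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config@stallLimit) break
      }
    }
    B <- outer(background, rep(1 / n, n))
    new("GAResult",
        matrix = new("WeightMatrix", weights = mQw, r2 = sum(mQw^2),
                     kd = sum(mQw * B)),
        mfmax = mF, cycles = cycles,
        converged = stall >= config@stallLimit)
  })
}
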