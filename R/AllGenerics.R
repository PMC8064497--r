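#' Accessors for rpwmtr classes
#'
#' Small accessor generics: \code{seqId} (sequence label), \code{codes}
#' (integer-encoded bases), \code{weights} (4 x n PWM entries), \code{period}
#' (repeat unit length n), \code{fitnessValues} (GA fitness vector V) and
#' \code{fmax} (alignment score).
#'
#' @param x an rpwmtr object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases seqId codes weights period fitnessValues fmax
NULL

#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname accessors
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname accessors
#' @export
setGeneric("weights", function(x) standardGeneric("weights"))

#' @rdname accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname accessors
#' @export
setGeneric("fitnessValues", function(x) standardGeneric("fitnessValues"))

#' @rdname accessors
#' @export
setGeneric("fmax", function(x) standardGeneric("fmax"))

#' @rdname accessors
setMethod("seqId", "EncodedSequence", function(x) x@id)

#' @rdname accessors
setMethod("codes", "EncodedSequence", function(x) x@codes)

#' @rdname accessors
setMethod("weights", "WeightMatrix", function(x) x@weights)

#' @rdname accessors
setMethod("period", "WeightMatrix", function(x) ncol(x@weights))

#' @rdname accessors
setMethod("period", "FrequencyMatrix", function(x) ncol(x@counts))

#' @rdname accessors
setMethod("period", "PlantedRepeatSpec", function(x) x@unitLength)

#' @rdname accessors
setMethod("fitnessValues", "MatrixSet", function(x) x@fitness)

#' @rdname accessors
setMethod("fmax", "AlignmentResult", function(x) x@fmax)

#' @rdname accessors
setMethod("fmax", "GAResult", function(x) x@mfmax)

setMethod("length", "EncodedSequence", function(x) length(x@codes))

setMethod("length", "MatrixSet", function(x) length(x@matrices))

setMethod("show", "EncodedSequence", function(object) {
  cat("EncodedSequence", if (!is.na(object@id)) object@id else "<unnamed>",
      "of length", length(object@codes))
  if (length(object@ambiguous))
    cat(" (", length(object@ambiguous), " ambiguous positions randomized)",
        sep = "")
  cat("\n  head:", paste(c("a", "t", "c", "g")[head(object@codes, 30L)],
                         collapse = ""), "\n")
})

setMethod("show", "WeightMatrix", function(object) {
  cat("WeightMatrix with period n =", ncol(object@weights),
      sprintf("\n  R2 = %.4f, Kd = %.4f\n", object@r2, object@kd))
})

setMethod("show", "MatrixSet", function(object) {
  cat("MatrixSet of", length(object@matrices), "matrices, period n =",
      if (length(object@matrices)) ncol(object@matrices[[1]]@weights) else NA)
  if (!anyNA(object@fitness))
    cat(sprintf("\n  fitness V(1) = %.2f .. V(N) = %.2f",
                max(object@fitness), min(object@fitness)))
  cat("\n")
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: fmax = %.1f, window span %d..%d (%d columns)\n",
              object@fmax, object@i0, object@im, nrow(object@pairs)))
})

setMethod("show", "GAResult", function(object) {
  cat(sprintf("GAResult: mFmax = %.1f after %d cycles (%s), period n = %d\n",
              object@mfmax, object@cycles,
              if (object@converged) "converged" else "cycle cap",
              ncol(object@matrix@weights)))
})

setMethod("show", "ZResult", function(object) {
  cat(sprintf(
    "ZResult: Z = %.2f (observed %.1f vs null %.1f +/- %.1f, %d shuffles)\n",
    object@z, object@observed, object@meanNull, sqrt(object@varNull),
    object@nShuffles))
})

setMethod("show", "ScanSurface", function(object) {
  cat("ScanSurface for", object@seqId, ":", length(object@starts),
      "windows x", length(object@periods), "periods;",
      sum(object@skippedWindows), "windows filtered\n")
})

setMethod("show", "FDRCalibration", function(object) {
  cat(sprintf("FDRCalibration: F0 = %g (Trand = %d, Treal = %d, FDR = %.4f)\n",
              object@f0, object@tRand, object@tReal, object@fdr))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: C = %d, expected %.2f (var %.2f), X = %.4f\n",
              object@c, object@cBar, object@dC, object@xStat))
})
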