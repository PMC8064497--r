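# Sequence input/output: encoding DNA to integer codes, composition-
# preserving shuffles, FASTA reading and region table writers.

IUPAC_AMBIGUOUS <- c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v", "n")

#' Encode a DNA string as integer codes
#'
#' Replaces a, t, c, g by 1, 2, 3, 4 (case-insensitive).  IUPAC ambiguity
#' codes (N, R, Y, ...) are replaced by a base drawn uniformly from the four
#' nucleotides under a dedicated seed, and their positions are recorded in
#' the returned object, so that long ambiguous runs can be excluded from
#' scanning downstream.
#'
#' @param text single DNA string.
#' @param id sequence label.
#' @param ambiguitySeed seed for the ambiguity randomization.
#' @return an \linkS4class{EncodedSequence}.
#' @examples
#' codes(encodeSequence("ATCGatcg"))
#' @export
encodeSequence <- function(text, id = NA_character_, ambiguitySeed = 101L) {
  if (length(text) != 1L || !is.character(text))
    stop("'text' must be a single string")
  if (nchar(text) == 0L)
    stop("empty sequence")
  chars <- strsplit(tolower(text), "", fixed = TRUE)[[1]]
  code <- match(chars, c("a", "t", "c", "g"))
  amb <- which(is.na(code))
  if (length(amb)) {
    bad <- amb[!(chars[amb] %in% IUPAC_AMBIGUOUS)]
    if (length(bad))
      stop(sprintf("non-IUPAC character '%s' at position %d",
                   chars[bad[1]], bad[1]))
    code[amb] <- withSeed(deriveSeed(ambiguitySeed, length(chars)),
                          sample.int(4L, length(amb), replace = TRUE))
  }
  new("EncodedSequence", id = id, codes = as.integer(code),
      ambiguous = as.integer(amb))
}

#' Decode integer codes back to a DNA string
#'
#' @param seq an \linkS4class{EncodedSequence} or integer code vector.
#' @return a lower-case DNA string.
#' @export
decodeSequence <- function(seq) {
  if (is(seq, "EncodedSequence")) seq <- seq@codes
  paste(c("a", "t", "c", "g")[seq], collapse = "")
}

#' Shuffle a sequence preserving composition
#'
#' Uniform random permutation (Fisher-Yates contract) of the sequence's
#' bases: length and mononucleotide composition are exactly preserved.
#' Used to build the empirical null for the Z statistic and the FDR
#' calibration.
#'
#' @param seq an \linkS4class{EncodedSequence}.
#' @param seed RNG seed (required: shuffles must be reproducible).
#' @return a shuffled \linkS4class{EncodedSequence}.
#' @export
shuffleSequence <- function(seq, seed) {
  stopifnot(is(seq, "EncodedSequence"))
  perm <- withSeed(seed, sample.int(length(seq@codes)))
  new("EncodedSequence", id = seq@id, codes = seq@codes[perm],
      ambiguous = integer())
}

#' Read a FASTA file as encoded sequences
#'
#' One \linkS4class{EncodedSequence} per record, ids taken from the first
#' whitespace-delimited token of each header.  Ambiguity codes are handled
#' as in \code{\link{encodeSequence}}.
#'
#' @param path FASTA file (multi-record, wrapped lines supported).
#' @param ambiguitySeed seed for ambiguity randomization.
#' @return list of \linkS4class{EncodedSequence}.
#' @export
readFasta <- function(path, ambiguitySeed = 101L) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- encodeSequence(as.character(set[[i]]), id = ids[i],
                               ambiguitySeed = deriveSeed(ambiguitySeed, i))
  }
  out
}

#' Write encoded sequences to FASTA
#'
#' @param seqs list of \linkS4class{EncodedSequence}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "EncodedSequence")) seqs <- list(seqs)
  dna <- Biostrings::DNAStringSet(vapply(seqs, decodeSequence, character(1)))
  names(dna) <- vapply(seqs, function(s) {
    if (is.na(s@id)) "sequence" else s@id
  }, character(1))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

# Runs of >= minRun consecutive ambiguous positions, as an IRanges.
ambiguousRuns <- function(seq, minRun = 51L) {
  flag <- logical(length(seq@codes))
  flag[seq@ambiguous] <- TRUE
  r <- IRanges::reduce(IRanges::IRanges(which(flag), width = 1L))
  r[IRanges::width(r) >= minRun]
}

#' Write called repeat regions as TSV
#'
#' 1-based inclusive coordinates; columns seq_id, start, end, period_n,
#' mFmax, Z, consensus.
#'
#' @param regions a GRanges from \code{\link{callRepeats}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRegionsTsv <- function(regions, path) {
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    period_n = regions$period,
    mFmax = round(regions$mfmax, 1),
    Z = if (!is.null(regions$z)) round(regions$z, 2) else NA,
    consensus = if (!is.null(regions$consensus)) regions$consensus else NA,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called repeat regions as BED6
#'
#' 0-based half-open coordinates; score = round(mFmax), name = TR_n<period>.
#'
#' @param regions a GRanges from \code{\link{callRepeats}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    chromStart = GenomicRanges::start(regions) - 1L,
    chromEnd = GenomicRanges::end(regions),
    name = paste0("TR_n", regions$period),
    score = round(regions$mfmax),
    strand = ".",
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
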