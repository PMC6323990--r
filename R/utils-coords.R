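# Coordinate plumbing shared by the ORF catalog, exporters and fixtures.
# All genomic and transcript coordinates are 1-based closed (IRanges
# convention); BED conversion happens only in the BED writer/reader.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Encode genomic blocks as a deterministic string key
#'
#' Blocks are serialized as \code{"contig:strand:start-end[,start-end]"}
#' in transcript (5' to 3') order. The key is used to deduplicate ORFs
#' that yield the same product at the same locus and to match external
#' ribosome-profiling detections to catalog entries.
#'
#' @param blocks a \code{GRanges} of genomic blocks in transcript order.
#' @return a single character key.
#' @seealso [decodeBlocks()]
#' @export
encodeBlocks <- function(blocks) {
  stopifnot(is(blocks, "GRanges"))
  if (length(blocks) == 0L) return("")
  ctg <- as.character(GenomicRanges::seqnames(blocks))
  std <- as.character(BiocGenerics::strand(blocks))
  stopifnot(length(unique(ctg)) == 1L, length(unique(std)) == 1L)
  paste0(ctg[1L], ":", std[1L], ":",
         paste0(BiocGenerics::start(blocks), "-", BiocGenerics::end(blocks),
                collapse = ","))
}

#' Decode a block key back into a GRanges
#' @param key a key produced by [encodeBlocks()].
#' @return a \code{GRanges} in transcript order.
#' @export
decodeBlocks <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  stopifnot(length(parts) == 3L)
  se <- do.call(rbind, lapply(strsplit(parts[3L], ",", fixed = TRUE)[[1L]],
    function(b) as.integer(strsplit(b, "-", fixed = TRUE)[[1L]])))
  GRanges(parts[1L], IRanges(se[, 1L], se[, 2L]), strand = parts[2L])
}

# Transcript-order cumulative coordinates of exons: for exon i (in tx
# order) the transcript positions it covers are txoff[i]+1 .. txoff[i+1].
.txOffsets <- function(exons) c(0L, cumsum(BiocGenerics::width(exons)))

#' Map a transcript interval to genomic blocks
#'
#' Projects a transcript-coordinate interval (1-based closed) through a
#' transcript's exon chain onto the genome. Returned blocks are maximal
#' genomically contiguous runs, ordered 5' to 3' along the transcript
#' (descending genomic coordinates on the minus strand).
#'
#' @param exons transcript exons as a \code{GRanges} in transcript order.
#' @param txStart,txEnd the transcript interval (1-based closed).
#' @return a \code{GRanges} of genomic blocks.
#' @export
txToGenome <- function(exons, txStart, txEnd) {
  L <- sum(BiocGenerics::width(exons))
  if (txStart < 1L || txEnd > L || txStart > txEnd)
    stop("transcript interval [", txStart, ",", txEnd,
         "] outside transcript of length ", L)
  off <- .txOffsets(exons)
  std <- as.character(BiocGenerics::strand(exons))[1L]
  ctg <- as.character(GenomicRanges::seqnames(exons))[1L]
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(exons)) {
    lo <- max(txStart, off[i] + 1L)
    hi <- min(txEnd, off[i + 1L])
    if (lo > hi) next
    if (std == "+") {
      gs <- BiocGenerics::start(exons)[i] + (lo - off[i] - 1L)
      ge <- BiocGenerics::start(exons)[i] + (hi - off[i] - 1L)
    } else {
      ge <- BiocGenerics::end(exons)[i] - (lo - off[i] - 1L)
      gs <- BiocGenerics::end(exons)[i] - (hi - off[i] - 1L)
    }
    starts <- c(starts, gs); ends <- c(ends, ge)
  }
  # merge genomically contiguous neighbours (introduced by abutting exons)
  if (length(starts) > 1L) {
    keep <- rep(TRUE, length(starts))
    for (i in seq_len(length(starts) - 1L)) {
      contig <- if (std == "+") starts[i + 1L] == ends[i] + 1L
                else ends[i + 1L] == starts[i] - 1L
      if (contig) {
        if (std == "+") ends[i + 1L] <- ends[i + 1L] else ends[i + 1L] <- ends[i]
        if (std == "+") starts[i + 1L] <- starts[i] else starts[i + 1L] <- starts[i + 1L]
        keep[i] <- FALSE
      }
    }
    starts <- starts[keep]; ends <- ends[keep]
  }
  GRanges(ctg, IRanges(starts, ends), strand = std)
}

# Extract the spliced sequence of genomic blocks given in transcript order.
.spliceBlocks <- function(blocks, genome) {
  ctg <- as.character(GenomicRanges::seqnames(blocks))[1L]
  if (!ctg %in% names(genome)) stop("contig not in genome: ", ctg)
  contig <- genome[[ctg]]
  if (any(BiocGenerics::start(blocks) < 1L) ||
      any(BiocGenerics::end(blocks) > length(contig)))
    stop("block outside contig bounds on ", ctg)
  std <- as.character(BiocGenerics::strand(blocks))[1L]
  pieces <- lapply(seq_along(blocks), function(i) {
    s <- Biostrings::subseq(contig, BiocGenerics::start(blocks)[i],
                            BiocGenerics::end(blocks)[i])
    if (std == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  paste0(unlist(pieces), collapse = "")
}

# Translate a DNA string with the standard genetic code; codons containing
# N (or any non-ACGT base) yield X. `trimStop` drops one trailing stop.
.translateDna <- function(nt, trimStop = TRUE) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  if (trimStop && n > 0L && !is.na(aa[n]) && aa[n] == "*") aa <- aa[-n]
  paste0(aa, collapse = "")
}

# First genomic base of the start codon / last genomic base of the stop
# codon for an entry's blocks (transcript order).
.startCodonPos <- function(blocks) {
  std <- as.character(BiocGenerics::strand(blocks))[1L]
  if (std == "+") BiocGenerics::start(blocks)[1L]
  else BiocGenerics::end(blocks)[1L]
}

.stopCodonPos <- function(blocks) {
  std <- as.character(BiocGenerics::strand(blocks))[1L]
  n <- length(blocks)
  if (std == "+") BiocGenerics::end(blocks)[n]
  else BiocGenerics::start(blocks)[n]
}
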