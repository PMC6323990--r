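# ORF enumeration on spliced transcripts (polycistronic model), mapping
# to genomic blocks, localization relative to the annotated CDS,
# deduplication into protein entries and accession assignment.

#' Enumerate candidate ORFs on a transcript sequence
#'
#' Scans all three reading frames for ATG-initiated ORFs that end at the
#' first in-frame stop codon (TAA/TAG/TGA) and encode a protein of at
#' least \code{minCodons} amino acids (the stop codon is not counted).
#' Codons containing N translate to X and never terminate an ORF. In
#' mode \code{"longest_per_stop"} only the 5'-most qualifying ATG per
#' (frame, stop) pair is reported; \code{"all_starts"} reports every
#' qualifying ATG. ORFs lacking an in-frame stop before the end of the
#' transcript are excluded unless \code{includeStopless = TRUE}.
#'
#' @param txSeq transcript sequence (character, A/C/G/T/N).
#' @param minCodons minimum protein length in amino acids (default 30).
#' @param mode \code{"longest_per_stop"} (default) or
#'   \code{"all_starts"}.
#' @param includeStopless also report 3'-truncated ORFs without a stop.
#' @return a \code{data.frame} with columns \code{tx_start},
#'   \code{tx_end} (1-based closed, ATG first base through stop codon
#'   last base), \code{frame} (0/1/2), \code{protein}, \code{nt} (stop
#'   codon included), \code{has_stop}.
#' @examples
#' enumerateOrfs(paste0("ATG", strrep("GCT", 30), "TAA"), minCodons = 30)
#' @export
enumerateOrfs <- function(txSeq, minCodons = 30L,
                          mode = c("longest_per_stop", "all_starts"),
                          includeStopless = FALSE) {
  mode <- match.arg(mode)
  stopifnot(minCodons >= 1L)
  txSeq <- toupper(txSeq)
  L <- nchar(txSeq)
  out <- list()
  for (f in 0:2) {
    n <- (L - f) %/% 3L
    if (n < minCodons + 1L && !includeStopless && n < minCodons) next
    if (n == 0L) next
    pos <- f + 1L + 3L * (seq_len(n) - 1L)
    codons <- substring(txSeq, pos, pos + 2L)
    S <- which(codons %in% STOP_CODONS)
    A <- which(codons == "ATG")
    if (!length(A)) next
    nextStop <- if (length(S)) S[findInterval(A, S) + 1L] else rep(NA_integer_, length(A))
    keep <- !is.na(nextStop) & (nextStop - A) >= minCodons
    a <- A[keep]; s <- nextStop[keep]
    if (mode == "longest_per_stop" && length(a)) {
      first <- !duplicated(s)  # A ascending => first ATG per stop is 5'-most
      a <- a[first]; s <- s[first]
    }
    for (i in seq_along(a)) {
      ts <- pos[a[i]]; te <- pos[s[i]] + 2L
      nt <- substring(txSeq, ts, te)
      out[[length(out) + 1L]] <- data.frame(
        tx_start = ts, tx_end = te, frame = f,
        protein = .translateDna(nt, trimStop = TRUE),
        nt = nt, has_stop = TRUE, stringsAsFactors = FALSE)
    }
    if (includeStopless) {
      tail <- if (length(S)) A[A > S[length(S)]] else A
      tail <- tail[(n - tail + 1L) >= minCodons]
      if (mode == "longest_per_stop" && length(tail)) tail <- tail[1L]
      for (a0 in tail) {
        ts <- pos[a0]; te <- pos[n] + 2L
        nt <- substring(txSeq, ts, te)
        out[[length(out) + 1L]] <- data.frame(
          tx_start = ts, tx_end = te, frame = f,
          protein = .translateDna(nt, trimStop = FALSE),
          nt = nt, has_stop = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tx_start = integer(), tx_end = integer(),
                      frame = integer(), protein = character(),
                      nt = character(), has_stop = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$tx_start, res$tx_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Map an ORF's transcript interval to genomic blocks
#'
#' Thin wrapper over [txToGenome()] for a transcript of a
#' \code{TranscriptSet}: blocks are maximal genomically contiguous runs
#' ordered 5' to 3' along the transcript.
#'
#' @param x a \code{TranscriptSet}.
#' @param uid transcript uid.
#' @param txStart,txEnd ORF interval in transcript coordinates.
#' @return a \code{GRanges} of genomic blocks.
#' @export
mapOrfToGenome <- function(x, uid, txStart, txEnd) {
  txToGenome(x@exons[[uid]], txStart, txEnd)
}

#' Localize an ORF relative to the annotated CDS
#'
#' For an ORF on an ncRNA the localization is \code{"ncRNA"}. For an
#' mRNA it is the set of regions the ORF interval overlaps by at least
#' one nucleotide, among the 5'UTR, the CDS (annotated CDS plus its stop
#' codon) and the 3'UTR (after the stop codon), serialized as e.g.
#' \code{"5UTR;CDS"}.
#'
#' @param x a \code{TranscriptSet}.
#' @param uid transcript uid.
#' @param txStart,txEnd ORF interval in transcript coordinates.
#' @return a character scalar such as \code{"5UTR"}, \code{"5UTR;CDS"}
#'   or \code{"ncRNA"}.
#' @export
localizeOrf <- function(x, uid, txStart, txEnd) {
  td <- x@txData[uid, ]
  if (td$biotype == "ncRNA") return("ncRNA")
  L <- sum(BiocGenerics::width(x@exons[[uid]]))
  cs <- td$cds_start; ce <- td$cds_end + 3L  # stop codon belongs to the CDS
  parts <- character()
  if (cs > 1L && txStart <= cs - 1L) parts <- c(parts, "5UTR")
  if (txStart <= ce && txEnd >= cs) parts <- c(parts, "CDS")
  if (ce < L && txEnd >= ce + 1L) parts <- c(parts, "3UTR")
  paste(parts, collapse = ";")
}

#' Deduplicate ORF candidates into protein entries
#'
#' Candidates with identical protein sequence AND identical genomic
#' blocks collapse into one protein entry listing all source
#' transcripts; identical protein sequences from different genomic loci
#' stay separate. Entry gene labels come from the reconciled
#' (\code{merged_gene}) gene of the source transcripts.
#'
#' @param candidates a \code{data.frame} with columns \code{uid},
#'   \code{tx_start}, \code{tx_end}, \code{frame}, \code{protein},
#'   \code{nt}, \code{has_stop}, \code{block_key}, \code{localization}
#'   (one row per ORF candidate per transcript).
#' @param x the \code{MergedTranscriptome} (or \code{TranscriptSet}) the
#'   candidates were enumerated from.
#' @return a \code{ProteinCatalog} without categories or accessions.
#' @export
deduplicateOrfs <- function(candidates, x) {
  td <- x@txData
  gene <- if ("merged_gene" %in% colnames(td)) td$merged_gene else td$gene_id
  names(gene) <- td$uid
  if (nrow(candidates) == 0L) {
    en <- DataFrame(entry_id = character(), protein = character(),
                    nt = character(), gene = character(),
                    contig = character(), strand = character(),
                    block_key = character(), has_stop = logical())
    as0 <- DataFrame(entry_id = character(), uid = character(),
                     transcript_id = character(), source = character(),
                     biotype = character(), tx_start = integer(),
                     tx_end = integer(), localization = character())
    return(new("ProteinCatalog", entries = en, associations = as0))
  }
  key <- paste(candidates$protein, candidates$block_key, sep = "#")
  grp <- match(key, unique(key))
  first <- !duplicated(key)
  en <- candidates[first, c("protein", "nt", "block_key", "has_stop"),
                   drop = FALSE]
  blk <- lapply(en$block_key, decodeBlocks)
  en$contig <- vapply(blk, function(b)
    as.character(GenomicRanges::seqnames(b))[1L], "")
  en$strand <- vapply(blk, function(b)
    as.character(BiocGenerics::strand(b))[1L], "")
  en$gstart <- vapply(blk, function(b) min(BiocGenerics::start(b)), 0L)
  en$gene <- unname(gene[candidates$uid[first]])
  # deterministic entry order: contig, genomic start, strand, protein
  o <- order(en$contig, en$gstart, en$strand, en$protein)
  en <- en[o, , drop = FALSE]
  en$entry_id <- sprintf("E%05d", seq_len(nrow(en)))
  grp <- match(match(key, unique(key)), (seq_along(unique(key)))[o])
  as1 <- data.frame(entry_id = en$entry_id[grp],
                    uid = candidates$uid,
                    transcript_id = td[candidates$uid, "transcript_id"],
                    source = td[candidates$uid, "source"],
                    biotype = td[candidates$uid, "biotype"],
                    tx_start = candidates$tx_start,
                    tx_end = candidates$tx_end,
                    localization = candidates$localization,
                    stringsAsFactors = FALSE)
  as1 <- as1[order(as1$entry_id, as1$uid), , drop = FALSE]
  rownames(as1) <- NULL
  en <- en[, c("entry_id", "protein", "nt", "gene", "contig", "strand",
               "gstart", "block_key", "has_stop")]
  rownames(en) <- en$entry_id
  new("ProteinCatalog", entries = DataFrame(en),
      associations = DataFrame(as1))
}

#' Enumerate, map, localize and deduplicate ORFs over a transcriptome
#'
#' Runs [enumerateOrfs()] on every transcript of a merged transcriptome,
#' maps each candidate to genomic blocks, localizes it relative to the
#' annotated CDS and collapses duplicates into protein entries.
#'
#' @param x a \code{MergedTranscriptome} (or \code{TranscriptSet}).
#' @param genome a \code{DNAStringSet}.
#' @inheritParams enumerateOrfs
#' @return a \code{ProteinCatalog} (pre-classification).
#' @export
buildOrfCatalog <- function(x, genome, minCodons = 30L,
                            mode = c("longest_per_stop", "all_starts"),
                            includeStopless = FALSE) {
  mode <- match.arg(mode)
  rows <- list()
  for (uid in names(x@exons)) {
    seq <- .spliceBlocks(x@exons[[uid]], genome)
    orfs <- enumerateOrfs(seq, minCodons = minCodons, mode = mode,
                          includeStopless = includeStopless)
    if (nrow(orfs) == 0L) next
    orfs$uid <- uid
    orfs$block_key <- vapply(seq_len(nrow(orfs)), function(i)
      encodeBlocks(txToGenome(x@exons[[uid]], orfs$tx_start[i],
                              orfs$tx_end[i])), "")
    orfs$localization <- vapply(seq_len(nrow(orfs)), function(i)
      localizeOrf(x, uid, orfs$tx_start[i], orfs$tx_end[i]), "")
    rows[[uid]] <- orfs
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(uid = character(), tx_start = integer(), tx_end = integer(),
               frame = integer(), protein = character(), nt = character(),
               has_stop = logical(), block_key = character(),
               localization = character(), stringsAsFactors = FALSE)
  message("enumerated ", nrow(candidates), " ORF candidate(s) on ",
          length(x@exons), " transcript(s)")
  deduplicateOrfs(candidates, x)
}

#' Assign accessions to a classified catalog
#'
#' RefProt entries keep their matched source accession; novel isoforms
#' receive \code{II_} serials and alternative proteins \code{IP_}
#' serials. Serials are assigned in the catalog's deterministic entry
#' order (contig, genomic start, strand, protein sequence) starting at
#' \code{offset}, so reruns on identical input yield identical
#' accessions.
#'
#' @param catalog a classified \code{ProteinCatalog} (column
#'   \code{category} set; RefProts carry \code{ref_accession}).
#' @param offset first serial number (default 1).
#' @return the catalog with an \code{accession} column.
#' @export
assignAccessions <- function(catalog, offset = 1L) {
  en <- catalog@entries
  if (!"category" %in% colnames(en) || anyNA(en$category))
    stop("catalog has unclassified entries")
  o <- order(en$contig, en$gstart, en$strand, en$protein)
  acc <- rep(NA_character_, nrow(en))
  isoSerial <- offset; altSerial <- offset
  for (i in o) {
    acc[i] <- switch(en$category[i],
      RefProt = en$ref_accession[i],
      Isoform = { a <- sprintf("II_%06d", isoSerial)
                  isoSerial <- isoSerial + 1L; a },
      AltProt = { a <- sprintf("IP_%06d", altSerial)
                  altSerial <- altSerial + 1L; a })
  }
  en$accession <- acc
  catalog@entries <- en
  validObject(catalog)
  catalog
}
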