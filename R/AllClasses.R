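#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps reduce start end width
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet readAAStringSet writeXStringSet reverseComplement
#'   GENETIC_CODE pairwiseAlignment score pattern subject nmatch nmismatch
#' @importFrom BiocGenerics width start end strand
NULL

#' Set of spliced transcript models
#'
#' A \code{TranscriptSet} holds transcript models assembled from a GTF or
#' GFF3 annotation: per-transcript exon blocks (ordered 5' to 3' in
#' transcript orientation) and a metadata table with gene assignment,
#' biotype, source annotation tag and, for mRNAs, the annotated CDS in
#' transcript coordinates (1-based, stop codon excluded).
#'
#' Rows of \code{txData} are keyed by \code{uid}, a source-qualified
#' transcript identifier (\code{"<source>|<transcript_id>"}) so that the
#' same transcript identifier may occur in two source annotations.
#'
#' @slot exons a named \code{GRangesList}, one element per transcript,
#'   names equal to \code{txData$uid}; exons are stored in transcript
#'   (5' to 3') order, i.e. descending genomic coordinates on the minus
#'   strand.
#' @slot txData a \code{DataFrame} with columns \code{uid},
#'   \code{transcript_id}, \code{gene_id}, \code{contig}, \code{strand},
#'   \code{biotype} (\code{"mRNA"} or \code{"ncRNA"}), \code{source},
#'   \code{cds_start}, \code{cds_end} (transcript coordinates, \code{NA}
#'   for ncRNA).
#'
#' @aliases TranscriptSet-class
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  td <- object@txData
  msgs <- character()
  required <- c("uid", "transcript_id", "gene_id", "contig", "strand",
                "biotype", "source", "cds_start", "cds_end")
  if (!all(required %in% colnames(td)))
    return(paste("txData must have columns:", paste(required, collapse = ", ")))
  if (length(object@exons) != nrow(td))
    return("exons and txData lengths differ")
  if (nrow(td) == 0L) return(TRUE)
  if (!identical(names(object@exons), as.character(td$uid)))
    msgs <- c(msgs, "names(exons) must equal txData$uid")
  if (anyDuplicated(td$uid))
    msgs <- c(msgs, "duplicated transcript uid")
  if (!all(td$biotype %in% c("mRNA", "ncRNA")))
    msgs <- c(msgs, "biotype must be mRNA or ncRNA")
  bad <- td$biotype == "mRNA" & (is.na(td$cds_start) | is.na(td$cds_end))
  if (any(bad)) msgs <- c(msgs, "mRNA transcripts must carry an annotated CDS")
  bad <- td$biotype == "ncRNA" & !(is.na(td$cds_start) & is.na(td$cds_end))
  if (any(bad)) msgs <- c(msgs, "ncRNA transcripts must not carry a CDS")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Merged transcriptome across two source annotations
#'
#' Union of two \code{TranscriptSet}s in which every transcript keeps its
#' source tag. Transcript pairs that are structurally identical across
#' sources (same contig, strand and exact exon boundary chain) are
#' recorded in \code{sharedIds}, and genes are reconciled across sources
#' into merged gene labels (column \code{merged_gene} of \code{txData}).
#'
#' @slot sharedIds a \code{DataFrame} with columns \code{uid_a},
#'   \code{uid_b}: structurally identical cross-source transcript pairs.
#'
#' @aliases MergedTranscriptome-class
#' @exportClass MergedTranscriptome
setClass("MergedTranscriptome", contains = "TranscriptSet",
  representation(sharedIds = "DataFrame"))

#' Catalog of deduplicated predicted proteins
#'
#' One row of \code{entries} per distinct (protein sequence, genomic
#' blocks) product; \code{associations} links each entry to every source
#' transcript that encodes it, with the ORF interval in that transcript's
#' coordinates and its localization relative to the annotated CDS.
#'
#' Categories follow the reference / novel-isoform / alternative-protein
#' partition: \code{RefProt} entries keep their source accession, novel
#' isoforms receive \code{II_} serials and alternative proteins \code{IP_}
#' serials.
#'
#' @slot entries a \code{DataFrame}, one row per protein entry.
#' @slot associations a \code{DataFrame}, one row per
#'   (entry, transcript) association.
#'
#' @aliases ProteinCatalog-class
#' @exportClass ProteinCatalog
setClass("ProteinCatalog",
  representation(entries = "DataFrame", associations = "DataFrame"))

setValidity("ProteinCatalog", function(object) {
  en <- object@entries
  msgs <- character()
  if (!all(c("entry_id", "protein", "nt", "gene", "contig", "strand",
             "block_key") %in% colnames(en)))
    return("entries lacks required columns")
  if (anyDuplicated(en$entry_id)) msgs <- c(msgs, "duplicated entry_id")
  if ("accession" %in% colnames(en)) {
    acc <- en$accession[!is.na(en$accession)]
    if (anyDuplicated(acc)) msgs <- c(msgs, "duplicated accession")
  }
  if ("category" %in% colnames(en) && !all(is.na(en$category) |
      en$category %in% c("RefProt", "Isoform", "AltProt")))
    msgs <- c(msgs, "invalid category")
  if ("category" %in% colnames(en) && "accession" %in% colnames(en)) {
    iso <- !is.na(en$category) & en$category == "Isoform" & !is.na(en$accession)
    if (any(iso) && !all(startsWith(en$accession[iso], "II_")))
      msgs <- c(msgs, "Isoform accessions must start with II_")
    alt <- !is.na(en$category) & en$category == "AltProt" & !is.na(en$accession)
    if (any(alt) && !all(startsWith(en$accession[alt], "IP_")))
      msgs <- c(msgs, "AltProt accessions must start with IP_")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Index of known reference proteins
#'
#' Exact-sequence lookup over one or more reference protein sets
#' (typically the protein products of each source annotation plus an
#' external curated set). Duplicate sequences are allowed and map to all
#' their accessions.
#'
#' @slot records a \code{DataFrame} with columns \code{accession},
#'   \code{protein}, \code{source}, \code{gene}.
#' @slot priority character vector of source tags, in decreasing lookup
#'   priority.
#'
#' @aliases KnownProteinIndex-class
#' @exportClass KnownProteinIndex
setClass("KnownProteinIndex",
  representation(records = "DataFrame", priority = "character"))

#' Alignment scoring and significance parameters
#'
#' Parameters for protein local alignment and its Karlin-Altschul
#' bit-score normalization, plus the homology significance filter: a
#' minimum bit score (default 40) and a minimum query coverage (default
#' 0.5, i.e. the aligned span must cover at least half of the query).
#'
#' @slot matrixName name of the substitution matrix (a matrix bundled
#'   with \pkg{Biostrings}, e.g. \code{"BLOSUM62"}).
#' @slot gapOpen,gapExtend affine gap penalties (positive).
#' @slot lambda,k Karlin-Altschul parameters; bits =
#'   (lambda * S - ln k) / ln 2.
#' @slot minBits,minOverlapFrac significance filter thresholds.
#'
#' @aliases ScoringParams-class
#' @exportClass ScoringParams
setClass("ScoringParams",
  representation(matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric", lambda = "numeric", k = "numeric",
                 minBits = "numeric", minOverlapFrac = "numeric"))

setValidity("ScoringParams", function(object) {
  if (object@lambda <= 0 || object@k <= 0)
    return("lambda and k must be positive")
  if (object@minOverlapFrac <= 0 || object@minOverlapFrac > 1)
    return("minOverlapFrac must lie in (0, 1]")
  TRUE
})

#' Construct alignment scoring parameters
#'
#' Defaults are the standard gapped BLOSUM62 parameters (gap open 11,
#' extend 1, lambda 0.267, K 0.041) with the significance filter at 40
#' bits over 50\% query coverage.
#'
#' @param matrixName substitution matrix name known to \pkg{Biostrings}.
#' @param gapOpen,gapExtend affine gap penalties.
#' @param lambda,k Karlin-Altschul scale and prefactor.
#' @param minBits minimum bit score for a significant hit.
#' @param minOverlapFrac minimum aligned fraction of the query.
#' @return a \code{ScoringParams} object.
#' @examples
#' scoringParams()
#' @export
scoringParams <- function(matrixName = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1, lambda = 0.267, k = 0.041,
                          minBits = 40, minOverlapFrac = 0.5) {
  new("ScoringParams", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, k = k, minBits = minBits,
      minOverlapFrac = minOverlapFrac)
}

setMethod("show", "TranscriptSet", function(object) {
  td <- object@txData
  cat(class(object), "with", nrow(td), "transcripts (",
      sum(td$biotype == "mRNA"), "mRNA /", sum(td$biotype == "ncRNA"),
      "ncRNA ) from", length(unique(td$source)), "source annotation(s)\n")
  if (is(object, "MergedTranscriptome"))
    cat("  shared across sources:", nrow(object@sharedIds),
        "structurally identical pair(s)\n")
})

setMethod("show", "ProteinCatalog", function(object) {
  en <- object@entries
  cat("ProteinCatalog with", nrow(en), "entries")
  if ("category" %in% colnames(en) && nrow(en) && !all(is.na(en$category))) {
    tab <- table(factor(en$category, c("RefProt", "Isoform", "AltProt")))
    cat(" (Total ", nrow(en), " / Ref ", tab[["RefProt"]], " / II_ ",
        tab[["Isoform"]], " / IP_ ", tab[["AltProt"]], ")", sep = "")
  }
  cat("\n ", nrow(object@associations), "transcript association(s)\n")
})

setMethod("show", "KnownProteinIndex", function(object) {
  cat("KnownProteinIndex with", nrow(object@records), "records from sources:",
      paste(object@priority, collapse = " > "), "\n")
})

setMethod("show", "ScoringParams", function(object) {
  cat("ScoringParams:", object@matrixName, "gap", object@gapOpen, "/",
      object@gapExtend, "; lambda", object@lambda, "K", object@k,
      "; filter >=", object@minBits, "bits, coverage >=",
      object@minOverlapFrac, "\n")
})

# ---- accessors ----

#' @describeIn TranscriptSet-class number of transcripts.
#' @param x,object a \code{TranscriptSet}.
#' @export
nTranscripts <- function(x) nrow(x@txData)

#' Transcript metadata table
#' @param x a \code{TranscriptSet} or \code{ProteinCatalog}.
#' @return a \code{DataFrame}.
#' @export
txData <- function(x) x@txData

#' Per-transcript exon blocks
#' @param x a \code{TranscriptSet}.
#' @param uid optional transcript uid(s) to subset.
#' @return a \code{GRangesList} (or \code{GRanges} for a single uid).
#' @export
txExons <- function(x, uid = NULL) {
  if (is.null(uid)) return(x@exons)
  if (length(uid) == 1L) x@exons[[uid]] else x@exons[uid]
}

#' Transcript lengths (sum of exon widths)
#' @param x a \code{TranscriptSet}.
#' @return named integer vector.
#' @export
txLengths <- function(x) {
  setNames(vapply(x@exons, function(g) sum(BiocGenerics::width(g)), 0L),
           names(x@exons))
}

#' Structurally shared transcript pairs of a merged transcriptome
#' @param x a \code{MergedTranscriptome}.
#' @return a \code{DataFrame} with columns \code{uid_a}, \code{uid_b}.
#' @export
sharedIds <- function(x) x@sharedIds

#' Protein entry table of a catalog
#' @param x a \code{ProteinCatalog}.
#' @return a \code{DataFrame}, one row per protein entry.
#' @export
proteinEntries <- function(x) x@entries

#' Transcript associations of a catalog
#' @param x a \code{ProteinCatalog}.
#' @return a \code{DataFrame}, one row per (entry, transcript) pair.
#' @export
proteinAssociations <- function(x) x@associations

#' Known-protein records of an index
#' @param x a \code{KnownProteinIndex}.
#' @return a \code{DataFrame}.
#' @export
knownRecords <- function(x) x@records
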