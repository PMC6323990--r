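# Reading the genome and the two transcript annotations, building
# transcript models and merging the annotations into one exhaustive
# transcriptome.

#' Load a genome FASTA
#'
#' Reads all contigs of a genome FASTA, normalizes soft-masked
#' (lowercase) bases to uppercase and validates the alphabet.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(path) {
  stopifnot(file.exists(path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  if (any(BiocGenerics::width(g) == 0L)) stop("empty contig in ", path)
  g <- DNAStringSet(toupper(as.character(g)))
  bad <- grepl("[^ACGTN]", as.character(g))
  if (any(bad))
    stop("contig with non-ACGTN characters: ",
         paste(names(g)[bad], collapse = ", "))
  g
}

# genomic position -> transcript coordinate through an exon chain given
# in transcript order
.genomeToTx <- function(exons, pos) {
  off <- .txOffsets(exons)
  std <- as.character(BiocGenerics::strand(exons))[1L]
  for (i in seq_along(exons)) {
    s <- BiocGenerics::start(exons)[i]; e <- BiocGenerics::end(exons)[i]
    if (pos >= s && pos <= e) {
      return(if (std == "+") off[i] + (pos - s + 1L)
             else off[i] + (e - pos + 1L))
    }
  }
  NA_integer_
}

# order exons 5'->3' in transcript orientation
.txOrder <- function(gr) {
  o <- order(BiocGenerics::start(gr))
  if (as.character(BiocGenerics::strand(gr))[1L] == "-") o <- rev(o)
  gr[o]
}

#' Parse a transcript annotation into transcript models
#'
#' Reads a GTF or GFF3 annotation and assembles one transcript model per
#' transcript: exon blocks in transcript order and, where CDS features
#' are present, the annotated CDS in transcript coordinates. Transcripts
#' without a CDS are tagged \code{ncRNA}. Dialect conventions are
#' honoured at the boundary: GTF CDS features exclude the stop codon and
#' are stored as given; GFF3 CDS features include it and are trimmed by
#' 3 nt, and a non-zero phase on the first CDS segment triggers a
#' warning. A CDS whose length is not a multiple of 3 is dropped with a
#' warning and the transcript reverts to \code{ncRNA}.
#'
#' @param path annotation file path.
#' @param dialect \code{"gtf"} or \code{"gff3"}.
#' @param sourceTag label recorded as the transcript's source annotation
#'   (e.g. \code{"annotA"}).
#' @return a \code{TranscriptSet}.
#' @export
parseAnnotation <- function(path, dialect = c("gtf", "gff3"),
                            sourceTag = "annotA") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  typ <- as.character(gr$type)

  if (dialect == "gtf") {
    txOf <- gr$transcript_id
    geneOf <- gr$gene_id
    knownTx <- unique(txOf[typ %in% c("exon", "CDS")])
  } else {
    # GFF3: transcripts are features whose Parent is a gene feature
    geneIds <- gr$ID[typ == "gene"]
    par <- vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    isTx <- !is.na(par) & par %in% geneIds
    txOf <- ifelse(typ %in% c("exon", "CDS"), par, NA_character_)
    geneOfTx <- setNames(par[isTx], gr$ID[isTx])
    knownTx <- names(geneOfTx)
    geneOf <- geneOfTx[txOf]
  }

  isExon <- typ == "exon"
  isCds <- typ == "CDS"
  if (dialect == "gff3") {
    unknown <- (isExon | isCds) & !(txOf %in% knownTx)
    if (any(unknown)) {
      warning(sum(unknown), " exon/CDS record(s) with unknown transcript skipped")
      isExon <- isExon & !unknown
      isCds <- isCds & !unknown
    }
  }

  txs <- sort(unique(txOf[isExon]))
  uids <- paste(sourceTag, txs, sep = "|")
  exonsL <- vector("list", length(txs))
  td <- data.frame(uid = uids, transcript_id = txs,
                   gene_id = NA_character_, contig = NA_character_,
                   strand = NA_character_, biotype = "ncRNA",
                   source = sourceTag, cds_start = NA_integer_,
                   cds_end = NA_integer_, stringsAsFactors = FALSE)
  nSkipped <- 0L
  for (i in seq_along(txs)) {
    sel <- isExon & txOf == txs[i]
    ex <- gr[sel]
    ctg <- unique(as.character(GenomicRanges::seqnames(ex)))
    std <- unique(as.character(BiocGenerics::strand(ex)))
    if (length(ctg) != 1L || length(std) != 1L || !std %in% c("+", "-"))
      stop("transcript ", txs[i], " has exons on mixed strands or contigs")
    ex <- .txOrder(GRanges(ctg, IRanges(BiocGenerics::start(ex),
                                        BiocGenerics::end(ex)), strand = std))
    if (sum(BiocGenerics::width(IRanges::reduce(ex))) !=
        sum(BiocGenerics::width(ex)))
      stop("transcript ", txs[i], " has overlapping exons")
    exonsL[[i]] <- ex
    td$contig[i] <- ctg; td$strand[i] <- std
    td$gene_id[i] <- geneOf[which(sel)[1L]]

    csel <- isCds & txOf == txs[i]
    if (any(csel)) {
      cds <- gr[csel]
      g1 <- min(BiocGenerics::start(cds)); g2 <- max(BiocGenerics::end(cds))
      tp <- sort(c(.genomeToTx(ex, g1), .genomeToTx(ex, g2)))
      if (anyNA(tp)) { warning("CDS outside exons for ", txs[i]); next }
      cs <- tp[1L]; ce <- tp[2L]
      if (dialect == "gff3") {
        ph <- gr$phase[csel]
        fiveMost <- which.min(vapply(seq_along(cds), function(j)
          .genomeToTx(ex, if (std == "+") BiocGenerics::start(cds)[j]
                          else BiocGenerics::end(cds)[j]), 0L))
        if (!is.null(ph) && !is.na(ph[fiveMost]) && ph[fiveMost] != 0L)
          warning("non-zero phase at CDS start of ", txs[i])
        ce <- ce - 3L  # GFF3 CDS includes the stop codon
      }
      if ((ce - cs + 1L) %% 3L != 0L) {
        warning("CDS length not a multiple of 3 for ", txs[i], "; dropped")
      } else {
        td$cds_start[i] <- cs; td$cds_end[i] <- ce
        td$biotype[i] <- "mRNA"
      }
    }
  }
  message("parsed ", length(txs), " transcript(s), ",
          sum(td$biotype == "mRNA"), " mRNA, from ", path,
          if (nSkipped) paste0(" (", nSkipped, " skipped)") else "")
  exg <- GRangesList(exonsL)
  names(exg) <- uids
  new("TranscriptSet", exons = exg, txData = DataFrame(td, row.names = uids))
}

# structural identity key of a transcript: contig, strand, exon chain
.structureKey <- function(exons) {
  s <- sort(BiocGenerics::start(exons)); e <- sort(BiocGenerics::end(exons))
  paste0(as.character(GenomicRanges::seqnames(exons))[1L], "|",
         as.character(BiocGenerics::strand(exons))[1L], "|",
         paste0(s, "-", e, collapse = ";"))
}

# minimal union-find
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge two source annotations into one exhaustive transcriptome
#'
#' Takes the union of two transcript sets, each transcript keeping its
#' source tag. Cross-source transcript pairs with identical contig,
#' strand and exact exon boundary chain are recorded as shared
#' (structural identity; identifiers are ignored). Genes are reconciled
#' across sources: genes sharing a gene name, and same-strand genes whose
#' transcript spans overlap, are merged into one reconciled gene whose
#' label (column \code{merged_gene}) is the lexicographically smallest
#' member gene id.
#'
#' @param setA,setB \code{TranscriptSet}s from the two source
#'   annotations (either may be empty).
#' @return a \code{MergedTranscriptome}.
#' @export
mergeAnnotations <- function(setA, setB) {
  td <- rbind(as.data.frame(setA@txData), as.data.frame(setB@txData))
  exons <- c(setA@exons, setB@exons)
  if (nrow(td)) {
    rownames(td) <- td$uid
    names(exons) <- td$uid
  }

  keysA <- vapply(as.list(setA@exons), .structureKey, "")
  keysB <- vapply(as.list(setB@exons), .structureKey, "")
  shared <- merge(
    data.frame(uid_a = names(setA@exons), key = unname(keysA),
               stringsAsFactors = FALSE),
    data.frame(uid_b = names(setB@exons), key = unname(keysB),
               stringsAsFactors = FALSE),
    by = "key")[, c("uid_a", "uid_b")]
  shared <- shared[order(shared$uid_a, shared$uid_b), , drop = FALSE]
  rownames(shared) <- NULL

  # gene reconciliation by name, then by same-strand genomic overlap
  td$merged_gene <- NA_character_
  if (nrow(td)) {
    gkey <- paste(td$source, td$gene_id, sep = "|")
    genes <- unique(gkey)
    parent <- seq_along(genes)
    name <- sub("^[^|]*\\|", "", genes)
    for (nm in unique(name)) {
      idx <- which(name == nm)
      for (j in idx[-1]) {
        r1 <- .ufFind(parent, idx[1L]); r2 <- .ufFind(parent, j)
        parent[max(r1, r2)] <- min(r1, r2)
      }
    }
    spans <- do.call(rbind, lapply(genes, function(g) {
      sel <- gkey == g
      data.frame(contig = td$contig[sel][1L], strand = td$strand[sel][1L],
        start = min(vapply(exons[td$uid[sel]], function(x)
          min(BiocGenerics::start(x)), 0L)),
        end = max(vapply(exons[td$uid[sel]], function(x)
          max(BiocGenerics::end(x)), 0L)))
    }))
    gr <- GRanges(spans$contig, IRanges(spans$start, spans$end),
                  strand = spans$strand)
    ov <- IRanges::findOverlaps(gr, gr)
    for (h in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[h]; j <- S4Vectors::subjectHits(ov)[h]
      if (i < j) {
        r1 <- .ufFind(parent, i); r2 <- .ufFind(parent, j)
        parent[max(r1, r2)] <- min(r1, r2)
      }
    }
    root <- vapply(seq_along(genes), function(i) .ufFind(parent, i), 0L)
    label <- vapply(seq_along(genes), function(i)
      min(name[root == root[i]]), "")
    td$merged_gene <- label[match(gkey, genes)]
  }

  new("MergedTranscriptome", exons = exons,
      txData = DataFrame(td, row.names = rownames(td)),
      sharedIds = DataFrame(shared))
}

#' Spliced transcript sequence
#'
#' Concatenates a transcript's exon sequences in transcript order,
#' reverse-complementing on the minus strand.
#'
#' @param x a \code{TranscriptSet}.
#' @param genome a \code{DNAStringSet} from [loadGenome()].
#' @param uid transcript uid (or plain transcript id if unambiguous).
#' @return the spliced sequence as a character string.
#' @export
splicedSequence <- function(x, genome, uid) {
  if (!uid %in% names(x@exons)) {
    hit <- which(x@txData$transcript_id == uid)
    if (length(hit) != 1L) stop("unknown or ambiguous transcript: ", uid)
    uid <- x@txData$uid[hit]
  }
  .spliceBlocks(x@exons[[uid]], genome)
}
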