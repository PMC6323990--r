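# Serialization of the catalog: protein/DNA FASTA, BED12 and TSV.

.fastaHeader <- function(en, as1) {
  txs <- vapply(en$entry_id, function(id)
    paste(as1$transcript_id[as1$entry_id == id], collapse = ","), "")
  paste(en$accession, en$category, en$gene, txs, sep = "|")
}

#' Write the catalog as FASTA
#'
#' One record per entry, header
#' \code{accession|category|gene|transcript,transcript,...}, sequences
#' wrapped at 60 columns. The \code{"protein"} flavor writes amino-acid
#' sequences; \code{"dna"} writes the ORF nucleotide sequence including
#' the stop codon.
#'
#' @param catalog a finalized \code{ProteinCatalog} (accessions
#'   assigned).
#' @param path output file.
#' @param flavor \code{"protein"} or \code{"dna"}.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(catalog, path, flavor = c("protein", "dna")) {
  flavor <- match.arg(flavor)
  en <- catalog@entries
  if (nrow(en) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(en$accession)
  en <- en[o, , drop = FALSE]
  seqs <- if (flavor == "protein")
    AAStringSet(as.character(en$protein)) else
    DNAStringSet(as.character(en$nt))
  names(seqs) <- .fastaHeader(en, catalog@associations)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

TIER_BED_SCORE <- c(predicted = 0L, supported = 500L, high = 1000L)

#' Write the catalog as BED12
#'
#' One BED12 line per entry: chromStart/chromEnd span the genomic
#' blocks (0-based half-open at this boundary), name is the accession,
#' the score column encodes the confidence tier (predicted 0 /
#' supported 500 / high 1000), thickStart/thickEnd repeat the span, and
#' blockCount/blockSizes/blockStarts carry the ORF's genomic blocks.
#' Entries lacking blocks are skipped with a warning.
#'
#' @param catalog a finalized \code{ProteinCatalog}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(catalog, path) {
  en <- catalog@entries
  if (nrow(en) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  keep <- nzchar(en$block_key)
  if (any(!keep)) warning(sum(!keep), " entr(ies) without blocks skipped")
  en <- en[keep, , drop = FALSE]
  en <- en[order(en$accession), , drop = FALSE]
  lines <- vapply(seq_len(nrow(en)), function(i) {
    b <- decodeBlocks(en$block_key[i])
    o <- order(BiocGenerics::start(b))  # BED blocks are genomic-ascending
    bs <- BiocGenerics::start(b)[o]; be <- BiocGenerics::end(b)[o]
    chromStart <- bs[1L] - 1L; chromEnd <- be[length(be)]
    tier <- if ("tier" %in% colnames(en) && !is.na(en$tier[i]))
      TIER_BED_SCORE[[en$tier[i]]] else 0L
    paste(en$contig[i], chromStart, chromEnd, en$accession[i], tier,
          en$strand[i], chromStart, chromEnd, "0", length(bs),
          paste0(paste0(be - bs + 1L, collapse = ","), ","),
          paste0(paste0(bs - 1L - chromStart, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the catalog as a TSV result table
#'
#' Tab-separated, UTF-8, no quoting, header row, deterministic row
#' order (by accession). List-valued fields (transcripts, localization)
#' are ";"-joined. A \code{domains} column is reserved for downstream
#' functional-domain annotation and left empty.
#'
#' @param catalog a finalized \code{ProteinCatalog}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCatalogTsv <- function(catalog, path) {
  en <- as.data.frame(catalog@entries)
  as1 <- as.data.frame(catalog@associations)
  biotypes <- vapply(en$entry_id, function(id)
    paste(unique(as1$biotype[as1$entry_id == id]), collapse = ";"), "")
  txs <- vapply(en$entry_id, function(id)
    paste(as1$transcript_id[as1$entry_id == id], collapse = ";"), "")
  locs <- vapply(en$entry_id, function(id)
    paste(unique(unlist(strsplit(as1$localization[as1$entry_id == id], ";"))),
          collapse = ";"), "")
  col <- function(nm, default) if (nm %in% colnames(en)) en[[nm]] else default
  tab <- data.frame(
    accession = en$accession, category = en$category, gene = en$gene,
    transcripts = txs, biotype = biotypes, localization = locs,
    length_aa = col("length_aa", nchar(en$protein)),
    mw_da = round(col("mw_da", NA_real_), 2),
    pi = round(col("pi", NA_real_), 2),
    kozak = col("kozak", NA), tis = col("tis", NA),
    conservation_score = col("conservation_score", 0L),
    ms_score = col("ms_score", 0L), te_score = col("te_score", 0L),
    tier = col("tier", NA_character_), domains = "",
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$accession), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
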