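# Shared fixture bundle, generated once per test session.

.fixtureCache <- new.env()

fixtureBundle <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.fixtureCache[[key]])) {
    dir <- file.path(tempdir(), paste0("orfeome_fixture_", seed))
    fx <- generateLocusSet(seed, dir)
    genome <- loadGenome(fx$paths$genome)
    suppressWarnings(suppressMessages({
      setA <- parseAnnotation(fx$paths$annotA, "gtf", "annotA")
      setB <- parseAnnotation(fx$paths$annotB, "gff3", "annotB")
      merged <- mergeAnnotations(setA, setB)
      idx <- buildKnownIndex(list(
        list(path = fx$paths$knownA, source = "annotA"),
        list(path = fx$paths$knownB, source = "annotB"),
        list(path = fx$paths$external, source = "external")))
      catalog <- buildOrfCatalog(merged, genome)
      catalog <- classifyCatalog(catalog, idx)
      catalog <- assignAccessions(catalog)
      catalog <- annotateFeatures(catalog, merged, genome)
      catalog <- addEvidence(catalog)
    }))
    .fixtureCache[[key]] <- list(fx = fx, genome = genome, setA = setA,
                                 setB = setB, merged = merged, idx = idx,
                                 catalog = catalog)
  }
  .fixtureCache[[key]]
}

# minimal hand-built TranscriptSet for coordinate-level unit tests
makeTxSet <- function(contig, strand, exons, cds = NULL,
                      uid = "t|tx1", gene = "g1", source = "t") {
  gr <- GenomicRanges::GRanges(contig,
    IRanges::IRanges(exons[, 1L], exons[, 2L]), strand = strand)
  o <- order(GenomicRanges::start(gr))
  if (strand == "-") o <- rev(o)
  gr <- gr[o]
  ex <- GenomicRanges::GRangesList(setNames(list(gr), uid))
  td <- S4Vectors::DataFrame(
    uid = uid, transcript_id = sub("^.*\\|", "", uid), gene_id = gene,
    contig = contig, strand = strand,
    biotype = if (is.null(cds)) "ncRNA" else "mRNA", source = source,
    cds_start = if (is.null(cds)) NA_integer_ else cds[1L],
    cds_end = if (is.null(cds)) NA_integer_ else cds[2L],
    merged_gene = gene, row.names = uid)
  new("TranscriptSet", exons = ex, txData = td)
}
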