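test_that("genome loading normalizes case and rejects malformed input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtN"), fa)
  g <- loadGenome(fa)
  expect_identical(names(g), "chr1")
  expect_identical(as.character(g[["chr1"]]), "ACGTN")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), dup)
  expect_error(loadGenome(dup), "duplicate contig")

  # IUPAC ambiguity codes other than N are rejected by the strict alphabet
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTRY"), bad)
  expect_error(loadGenome(bad), "non-ACGTN")
})

test_that("GTF parsing converts coordinates and infers biotype", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 1, 90, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "CDS", 10, 69, ".", "+", "0",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 200, 260, ".", "+", ".",
          'gene_id "g2"; transcript_id "t2";', sep = "\t")), gtf)
  ts <- suppressMessages(parseAnnotation(gtf, "gtf", "annotA"))
  td <- txData(ts)
  expect_equal(nTranscripts(ts), 2L)
  t1 <- td[td$transcript_id == "t1", ]
  # GTF 1-based inclusive CDS 10..69 -> transcript coords 10..69
  expect_equal(t1$cds_start, 10L)
  expect_equal(t1$cds_end, 69L)
  expect_equal(t1$biotype, "mRNA")
  expect_equal((t1$cds_end - t1$cds_start + 1L) %% 3L, 0L)
  expect_equal(td[td$transcript_id == "t2", "biotype"], "ncRNA")
})

test_that("minus-strand exons come out in transcript (5' to 3') order", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 10, 50, ".", "-", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 100, 160, ".", "-", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), gtf)
  ts <- suppressMessages(parseAnnotation(gtf, "gtf", "annotA"))
  ex <- txExons(ts, "annotA|t1")
  expect_equal(GenomicRanges::start(ex), c(100L, 10L))  # descending
})

test_that("mixed strands or contigs within one transcript are an error", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 10, 50, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 100, 160, ".", "-", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), gtf)
  expect_error(suppressMessages(parseAnnotation(gtf, "gtf", "a")),
               "mixed strands")
})

test_that("merging records structural identity and keeps source tags", {
  fb <- fixtureBundle()
  merged <- fb$merged
  expect_equal(nTranscripts(merged),
               nTranscripts(fb$setA) + nTranscripts(fb$setB))
  expect_equal(nrow(sharedIds(merged)), fb$fx$sharedStructural)
  # symmetric up to label swap
  swapped <- mergeAnnotations(fb$setB, fb$setA)
  expect_equal(nrow(sharedIds(swapped)), nrow(sharedIds(merged)))
  expect_setequal(sharedIds(swapped)$uid_b, sharedIds(merged)$uid_a)
  # cross-source gene reconciliation maps paired transcripts together
  td <- txData(merged)
  sh <- sharedIds(merged)
  expect_true(all(td[sh$uid_a, "merged_gene"] == td[sh$uid_b, "merged_gene"]))
  # A-only transcript present but unshared
  aonly <- setdiff(td$uid[td$source == "annotA"], sh$uid_a)
  expect_true(length(aonly) >= 1L)
})

test_that("different splice forms of one gene are retained, not shared", {
  gtfA <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "s", "exon", 1, 300, ".", "+", ".",
                   'gene_id "g1"; transcript_id "tA";', sep = "\t"), gtfA)
  gtfB <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "s", "exon", 1, 100, ".", "+", ".",
          'gene_id "g1"; transcript_id "tB";', sep = "\t"),
    paste("chr1", "s", "exon", 200, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "tB";', sep = "\t")), gtfB)
  m <- suppressMessages(mergeAnnotations(
    parseAnnotation(gtfA, "gtf", "annotA"),
    parseAnnotation(gtfB, "gtf", "annotB")))
  expect_equal(nTranscripts(m), 2L)
  expect_equal(nrow(sharedIds(m)), 0L)
  expect_equal(length(unique(txData(m)$merged_gene)), 1L)
})

test_that("spliced sequences honour exon order and strand", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c", "ACGTTTGGG"), fa)
  g <- loadGenome(fa)
  plus <- makeTxSet("c", "+", rbind(c(1, 3), c(7, 9)))
  expect_identical(splicedSequence(plus, g, "t|tx1"), "ACGGGG")
  minus <- makeTxSet("c", "-", rbind(c(1, 6)))
  expect_identical(splicedSequence(minus, g, "t|tx1"), "AAACGT")
})

test_that("spliced sequences round-trip through genomic block mapping", {
  fb <- fixtureBundle()
  for (uid in names(txExons(fb$merged))) {
    ex <- txExons(fb$merged, uid)
    L <- sum(GenomicRanges::width(ex))
    blocks <- txToGenome(ex, 1L, L)
    direct <- splicedSequence(fb$merged, fb$genome, uid)
    expect_identical(Orfeome:::.spliceBlocks(blocks, fb$genome), direct,
                     info = uid)
  }
})

test_that("annotation parse is stable under write-free re-parse", {
  fb <- fixtureBundle()
  again <- suppressMessages(parseAnnotation(fb$fx$paths$annotA, "gtf",
                                            "annotA"))
  expect_identical(as.data.frame(txData(again)),
                   as.data.frame(txData(fb$setA)))
})
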