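senseCodons <- setdiff(names(Biostrings::GENETIC_CODE)
                       [Biostrings::GENETIC_CODE != "*"], "ATG")

orfOf <- function(nSense, seed = 1) {
  set.seed(seed)
  paste0("ATG", paste(sample(senseCodons, nSense, TRUE), collapse = ""),
         "TAA")
}

test_that("minimum-length boundary keeps 30-aa products and drops 29-aa", {
  expect_equal(nrow(enumerateOrfs(orfOf(28))), 0L)   # 29-aa product
  kept <- enumerateOrfs(orfOf(29))                   # 30-aa product
  expect_equal(nrow(kept), 1L)
  expect_equal(nchar(kept$protein), 30L)
  expect_equal(kept$tx_start, 1L)
  expect_equal(kept$tx_end, 93L)
})

test_that("no ATG or no in-frame stop yields no ORFs", {
  expect_equal(nrow(enumerateOrfs(paste(rep("GGC", 50), collapse = ""))), 0L)
  noStop <- paste0("ATG", paste(rep("GGC", 40), collapse = ""))
  expect_equal(nrow(enumerateOrfs(noStop)), 0L)
  withTail <- enumerateOrfs(noStop, includeStopless = TRUE)
  expect_equal(nrow(withTail), 1L)
  expect_false(withTail$has_stop)
})

test_that("nested same-stop starts follow the enumeration mode", {
  seq <- paste0("ATG", orfOf(29, seed = 2))  # ATGATG... shared stop
  all <- enumerateOrfs(seq, mode = "all_starts")
  expect_equal(nrow(all), 2L)
  expect_equal(sort(all$tx_start), c(1L, 4L))
  one <- enumerateOrfs(seq, mode = "longest_per_stop")
  expect_equal(nrow(one), 1L)
  expect_equal(one$tx_start, 1L)  # 5'-most ATG
})

test_that("codons containing N translate to X and do not stop an ORF", {
  set.seed(3)
  body <- paste(sample(senseCodons, 29, TRUE), collapse = "")
  seq <- paste0("ATG", "AAN", body, "TAA")
  res <- enumerateOrfs(seq, minCodons = 30)
  expect_equal(nrow(res), 1L)
  expect_identical(substr(res$protein, 2, 2), "X")
  expect_equal(nchar(res$protein), 31L)
})

test_that("enumeration matches the brute-force scan on random transcripts", {
  set.seed(42)
  for (rep in 1:25) {
    seq <- randomDna(sample(300:1500, 1))
    for (mode in c("all_starts", "longest_per_stop")) {
      got <- enumerateOrfs(seq, minCodons = 10, mode = mode)
      exp <- bruteOrfScan(seq, minCodons = 10, mode = mode)
      expect_equal(got[, c("tx_start", "tx_end", "frame")], exp,
                   info = paste(mode, rep))
    }
  }
})

test_that("ORF length bookkeeping holds across the fixture catalog", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  w <- vapply(en$block_key, function(k)
    sum(GenomicRanges::width(decodeBlocks(k))), 0L)
  expect_true(all(3L * (nchar(en$protein) + 1L) == w))
  expect_true(all(substr(en$protein, 1, 1) == "M"))
})

test_that("transcript intervals project onto genomic blocks correctly", {
  plus <- makeTxSet("c", "+", rbind(c(101, 400)))
  b <- mapOrfToGenome(plus, "t|tx1", 31, 120)
  expect_equal(GenomicRanges::start(b), 131L)
  expect_equal(GenomicRanges::end(b), 220L)

  minus <- makeTxSet("c", "-", rbind(c(1, 300)))
  b <- mapOrfToGenome(minus, "t|tx1", 1, 90)
  expect_equal(GenomicRanges::start(b), 211L)
  expect_equal(GenomicRanges::end(b), 300L)

  twoEx <- makeTxSet("c", "+", rbind(c(1, 100), c(201, 320)))
  b <- mapOrfToGenome(twoEx, "t|tx1", 61, 150)
  expect_equal(length(b), 2L)
  expect_equal(sum(GenomicRanges::width(b)), 90L)
  expect_equal(GenomicRanges::start(b), c(61L, 201L))
  expect_error(mapOrfToGenome(twoEx, "t|tx1", 100, 500), "outside")
})

test_that("localization covers UTRs, CDS, ncRNA and overlap sets", {
  mrna <- makeTxSet("c", "+", rbind(c(1, 600)), cds = c(101, 397))
  expect_identical(localizeOrf(mrna, "t|tx1", 1, 93), "5UTR")
  expect_identical(localizeOrf(mrna, "t|tx1", 91, 250), "5UTR;CDS")
  expect_identical(localizeOrf(mrna, "t|tx1", 450, 560), "3UTR")
  expect_identical(localizeOrf(mrna, "t|tx1", 1, 600), "5UTR;CDS;3UTR")
  nc <- makeTxSet("c", "+", rbind(c(1, 600)))
  expect_identical(localizeOrf(nc, "t|tx1", 10, 100), "ncRNA")
})

test_that("deduplication collapses identical products at one locus only", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  as1 <- as.data.frame(proteinAssociations(fb$catalog))
  # parent transcripts exist in both annotations: CDS entries carry two
  # associations, one per source, collapsed into a single entry
  truth <- fb$fx$truth
  for (i in seq_len(nrow(truth))) {
    hit <- en[en$block_key == truth$block_key[i], ]
    expect_equal(nrow(hit), 1L, info = truth$orf_id[i])
    expect_equal(sum(as1$entry_id == hit$entry_id), truth$n_tx[i],
                 info = truth$orf_id[i])
  }
  # same protein at two loci stays separate
  cand <- data.frame(
    uid = c("t|tx1", "t|tx1"), tx_start = c(1L, 1L), tx_end = c(9L, 9L),
    frame = 0L, protein = "MK", nt = "ATGAAATAA", has_stop = TRUE,
    block_key = c("c:+:1-9", "c:+:101-109"),
    localization = "ncRNA", stringsAsFactors = FALSE)
  two <- deduplicateOrfs(cand, makeTxSet("c", "+", rbind(c(1, 600))))
  expect_equal(nrow(proteinEntries(two)), 2L)
})

test_that("accession assignment is ordered, prefixed and reproducible", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  expect_true(all(startsWith(en$accession[en$category == "Isoform"], "II_")))
  expect_true(all(startsWith(en$accession[en$category == "AltProt"], "IP_")))
  expect_false(any(duplicated(en$accession)))
  # serial order follows (contig, genomic start)
  alt <- en[en$category == "AltProt", ]
  o <- order(alt$contig, alt$gstart, alt$strand, alt$protein)
  expect_identical(alt$accession[o], sort(alt$accession))
  # rerun on the same catalog reproduces accessions
  cat2 <- suppressMessages(assignAccessions(classifyCatalog(
    buildOrfCatalog(fb$merged, fb$genome), fb$idx)))
  expect_identical(as.data.frame(proteinEntries(cat2))$accession,
                   en$accession)
  # unclassified input is refused
  raw <- suppressMessages(buildOrfCatalog(fb$merged, fb$genome))
  expect_error(assignAccessions(raw), "unclassified")
})
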