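writeProteinFastaFile <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), f)
  f
}

test_that("known index strips stops, keeps duplicates, checks alphabet", {
  f1 <- writeProteinFastaFile(c(P1 = "MKLV", P2 = "MTTT*"))
  f2 <- writeProteinFastaFile(c(Q1 = "MKLV"))
  idx <- buildKnownIndex(list(list(path = f1, source = "annotA"),
                              list(path = f2, source = "annotB")))
  rec <- as.data.frame(knownRecords(idx))
  expect_equal(nrow(rec), 3L)
  expect_identical(rec$protein[rec$accession == "P2"], "MTTT")
  expect_setequal(rec$accession[rec$protein == "MKLV"], c("P1", "Q1"))

  empty <- buildKnownIndex(list())
  expect_equal(nrow(knownRecords(empty)), 0L)

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">B1", "MKOV"), bad)  # O (pyrrolysine) outside the alphabet
  expect_error(buildKnownIndex(list(list(path = bad, source = "x"))),
               "non-amino-acid")
})

test_that("RefProt matching is exact, full-length, priority-ordered", {
  f1 <- writeProteinFastaFile(c(PA = "MKLVAAA"))
  f2 <- writeProteinFastaFile(c(PB = "MKLVAAA", PC = "MDDD"))
  idx <- buildKnownIndex(list(list(path = f1, source = "annotA"),
                              list(path = f2, source = "annotB")))
  expect_identical(matchRefProt("MKLVAAA", idx), "PA")  # annotA wins
  expect_identical(matchRefProt("MDDD", idx), "PC")
  expect_identical(matchRefProt("MKLVAA", idx), NA_character_)  # truncated
  expect_identical(matchRefProt("XMKLVAAA", idx), NA_character_)
})

test_that("argument A fires on high-identity, high-coverage truncations", {
  set.seed(10)
  ref <- paste0("M", randomProtein(99))
  cand <- paste0("M", substr(ref, 41, 100))  # C-terminal 60 %
  v <- similarityFilter(cand, "", refProteins = ref, refAccessions = "R1")
  expect_true(v$is_isoform)
  expect_identical(v$argument, "A_identity_coverage")
  expect_identical(v$matched_refprot, "R1")
  expect_gte(v$identity_pct, 80)
  expect_gte(v$coverage_pct, 50)
})

test_that("argument B needs a shared start/stop coordinate plus similarity", {
  set.seed(11)
  ref <- paste0("M", randomProtein(99))
  cand <- paste0("M", randomProtein(74), substr(ref, 76, 100))
  refKey <- "chr1:+:1000-1302"          # stop codon last base at 1302
  candKeyShared <- "chr1:+:1100-1302"   # same stop coordinate
  candKeyOther <- "chr1:+:1100-1299"
  hit <- similarityFilter(cand, candKeyShared, refProteins = ref,
                          refBlockKeys = refKey, refAccessions = "R1")
  expect_true(hit$is_isoform)
  expect_identical(hit$argument, "B_anchored_similarity")
  expect_gte(hit$matcher_score, 100)
  expect_gte(hit$coverage_pct, 20)
  # without the anchor the same pair is not an isoform
  miss <- similarityFilter(cand, candKeyOther, refProteins = ref,
                           refBlockKeys = refKey, refAccessions = "R1")
  expect_false(miss$is_isoform)
  # with the score threshold read as a ceiling, the anchored pair fails
  ceil <- similarityFilter(cand, candKeyShared, refProteins = ref,
                           refBlockKeys = refKey, refAccessions = "R1",
                           scoreBDirection = "max")
  expect_false(ceil$is_isoform)
})

test_that("frame-shifted and unrelated products pass no argument", {
  set.seed(12)
  ref <- paste0("M", randomProtein(99))
  alt <- paste0("M", randomProtein(50))
  v <- similarityFilter(alt, "chr1:+:500-652", refProteins = ref,
                        refBlockKeys = "chr1:+:1000-1302",
                        refAccessions = "R1")
  expect_false(v$is_isoform)
  expect_identical(v$argument, "none")
  none <- similarityFilter(alt, "", refProteins = character())
  expect_false(none$is_isoform)
})

test_that("classification partitions the catalog exactly", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  expect_false(anyNA(en$category))
  tab <- table(factor(en$category, c("RefProt", "Isoform", "AltProt")))
  expect_equal(sum(tab), nrow(en))
  expect_equal(tab[["AltProt"]],
               nrow(en) - tab[["RefProt"]] - tab[["Isoform"]])
})

test_that("planted categories and localizations are fully recovered", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  as1 <- as.data.frame(proteinAssociations(fb$catalog))
  truth <- fb$fx$truth
  expect_equal(nrow(en), nrow(truth))  # scrubbed fixture: catalog == truth
  for (i in seq_len(nrow(truth))) {
    hit <- en[en$block_key == truth$block_key[i], ]
    expect_equal(nrow(hit), 1L, info = truth$orf_id[i])
    expect_identical(hit$category, truth$category[i], info = truth$orf_id[i])
    expect_identical(hit$protein, truth$protein[i], info = truth$orf_id[i])
    locs <- unique(unlist(strsplit(
      as1$localization[as1$entry_id == hit$entry_id], ";")))
    expect_setequal(locs, strsplit(truth$localization[i], ";")[[1L]])
  }
})

test_that("growing the known index never demotes a RefProt", {
  fb <- fixtureBundle()
  en <- as.data.frame(proteinEntries(fb$catalog))
  novel <- en$protein[en$category == "AltProt"][1L]
  extra <- writeProteinFastaFile(c(NEW1 = novel))
  idx2 <- buildKnownIndex(list(
    list(path = fb$fx$paths$knownA, source = "annotA"),
    list(path = fb$fx$paths$knownB, source = "annotB"),
    list(path = fb$fx$paths$external, source = "external"),
    list(path = extra, source = "extra")))
  cat2 <- suppressMessages(classifyCatalog(
    buildOrfCatalog(fb$merged, fb$genome), idx2))
  en2 <- as.data.frame(proteinEntries(cat2))
  wasRef <- en$entry_id[en$category == "RefProt"]
  expect_true(all(en2$category[en2$entry_id %in% wasRef] == "RefProt"))
  expect_identical(en2$category[en2$protein == novel], "RefProt")
})
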