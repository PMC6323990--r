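evidenceBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fb <- fixtureBundle()
      ev <- generateEvidenceTables(7, fb$fx$truth,
                                   file.path(tempdir(), "orfeome_evidence"))
      peps <- readPeptideTable(ev$paths$peptides)
      dets <- readRiboseqTable(ev$paths$riboseq)
      catalog <- addEvidence(fb$catalog, peps, dets)
      asg <- assignPeptides(peps, fb$catalog)
      cache <<- list(fb = fb, ev = ev, peps = peps, dets = dets,
                     catalog = catalog, asg = asg)
    }
    cache
  }
})

test_that("peptides are assigned with strict RefProt priority", {
  eb <- evidenceBundle()
  en <- as.data.frame(proteinEntries(eb$fb$catalog))
  asg <- eb$asg
  # every observation is accounted for
  expect_true(all(asg$status %in%
    c("refprot", "unique", "ambiguous", "unmatched", "skipped")))
  expect_equal(nrow(asg), nrow(eb$peps))
  # no peptide assigned to a novel entry matches any RefProt sequence
  refSeqs <- en$protein[en$category == "RefProt"]
  novelIds <- en$entry_id[en$category != "RefProt"]
  for (i in which(asg$status == "unique")) {
    expect_true(all(strsplit(asg$assigned[i], ";")[[1L]] %in% novelIds))
    expect_false(any(vapply(refSeqs, function(s)
      grepl(asg$peptide[i], s, fixed = TRUE), TRUE)), info = asg$peptide[i])
  }
  # the planted RefProt/isoform shared peptide went to the RefProt only
  expect_true(any(asg$status == "refprot"))
  # the planted two-novel-matches peptide is ambiguous and unassigned
  expect_true(any(asg$status == "ambiguous"))
  expect_true(all(asg$assigned[asg$status == "ambiguous"] == ""))
})

test_that("illegal peptides are skipped with a warning", {
  fb <- fixtureBundle()
  obs <- data.frame(study_id = "S", peptide = "MK9LV", psm_count = 1,
                    fdr = 0, stringsAsFactors = FALSE)
  expect_warning(res <- assignPeptides(obs, fb$catalog), "illegal")
  expect_identical(res$status, "skipped")
})

test_that("MS score sums unique peptides per study", {
  asg <- data.frame(
    study_id = c("A", "A", "B", "B"),
    peptide = c("PEPTIDEK", "PEPTIDER", "PEPTIDEK", "PEPTIDEK"),
    status = "unique", assigned = "E1", stringsAsFactors = FALSE)
  expect_equal(msScore("E1", asg), 3L)  # 2 in A, 1 in B (dedup within B)
  expect_equal(msScore("E2", asg), 0L)
})

test_that("TE score counts distinct passing studies", {
  entry <- data.frame(block_key = "c:+:1-99", accession = "IP_000001",
                      stringsAsFactors = FALSE)
  det <- data.frame(
    study_id = c("R1", "R2", "R3", "R1"),
    block_key = "c:+:1-99",
    p_value = c(0.001, 0.5, 0.002, 0.003), stringsAsFactors = FALSE)
  expect_equal(teScore(entry, det), 2L)  # R2 fails cutoff, R1 dedup
  expect_equal(teScore(entry, det[0, ]), 0L)
  # accession-based matching
  det2 <- data.frame(study_id = "R9", accession = "IP_000001",
                     p_value = 0.001, stringsAsFactors = FALSE)
  expect_equal(teScore(entry, det2), 1L)
})

test_that("confidence tiers follow the two-peptide rule", {
  expect_identical(confidenceTier("AltProt", 2L, 0L, 0L, 2L), "high")
  expect_identical(confidenceTier("AltProt", 0L, 1L, 0L, 0L), "supported")
  expect_identical(confidenceTier("RefProt", 5L, 0L, 0L, 5L), "supported")
  expect_identical(confidenceTier("AltProt", 0L, 0L, 1L, 0L), "supported")
  expect_identical(confidenceTier("AltProt", 0L, 0L, 0L, 0L), "predicted")
})

test_that("fixture evidence reproduces the planted score table", {
  eb <- evidenceBundle()
  en <- as.data.frame(proteinEntries(eb$catalog))
  truth <- eb$fb$fx$truth
  for (i in seq_len(nrow(eb$ev$expected))) {
    e <- eb$ev$expected[i, ]
    hit <- en[en$block_key == truth$block_key[truth$orf_id == e$orf_id], ]
    expect_equal(hit$ms_score, e$ms_score, info = e$orf_id)
    expect_equal(hit$te_score, e$te_score, info = e$orf_id)
    expect_equal(hit$unique_peptides, e$unique_peptides, info = e$orf_id)
    expect_identical(hit$tier, e$tier, info = e$orf_id)
  }
})

test_that("scores are monotone as studies are appended", {
  eb <- evidenceBundle()
  firstStudy <- eb$peps[eb$peps$study_id == "MS1", ]
  cat1 <- addEvidence(eb$fb$catalog, firstStudy,
                      eb$dets[eb$dets$study_id == "RS1", ])
  cat2 <- addEvidence(eb$fb$catalog, eb$peps, eb$dets)
  en1 <- as.data.frame(proteinEntries(cat1))
  en2 <- as.data.frame(proteinEntries(cat2))
  expect_true(all(en2$ms_score >= en1$ms_score))
  expect_true(all(en2$te_score >= en1$te_score))
})
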