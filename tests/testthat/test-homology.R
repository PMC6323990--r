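test_that("local alignment basics: identity, coverage, no-alignment", {
  p <- scoringParams()
  set.seed(20)
  a <- randomProtein(100)
  full <- localAlign(a, a, p)
  expect_equal(full$identity_pct, 100)
  expect_equal(full$query_cover_frac, 1.0)
  none <- localAlign(strrep("K", 20), strrep("D", 20), p)
  expect_equal(none$raw_score, 0)
  expect_equal(none$query_cover_frac, 0)
})

test_that("alignment scores equal a brute-force Gotoh DP oracle", {
  p <- scoringParams()
  mat <- Orfeome:::.getMatrix("BLOSUM62")
  set.seed(21)
  for (i in 1:12) {
    a <- randomProtein(sample(10:60, 1))
    b <- randomProtein(sample(10:60, 1))
    # make some pairs related so scores exercise gaps
    if (i %% 2 == 0) b <- paste0(substr(a, 1, 20), b)
    got <- localAlign(a, b, p)$raw_score
    exp <- gotohLocalScore(a, b, mat, p@gapOpen, p@gapExtend)
    expect_equal(got, max(exp, 0), info = i)
  }
})

test_that("bit-score normalization follows the Karlin-Altschul form", {
  p <- scoringParams()  # lambda 0.267, k 0.041
  expect_equal(bitScore(100, p), 43.13, tolerance = 0.01)
  expect_equal(bitScore(0, p), -log(0.041) / log(2), tolerance = 1e-9)
  raws <- seq(0, 500, by = 10)
  expect_true(all(diff(bitScore(raws, p)) > 0))
})

test_that("significance needs both 40 bits and 50 % query coverage", {
  p <- scoringParams()
  aln <- function(bits, cover) list(bit_score = bits, query_cover_frac = cover)
  expect_true(isSignificant(aln(45, 0.8), p))
  expect_false(isSignificant(aln(45, 0.3), p))
  expect_false(isSignificant(aln(39.9, 1.0), p))
  expect_true(isSignificant(aln(40, 0.5), p))
})

test_that("ortholog inference recovers planted groups and rejects decoys", {
  pt <- generateProteomes(11)
  g2 <- inferOrthologs(pt$proteomes$S1, pt$proteomes$S2)
  truth2 <- pt$truth[pt$truth$species == "S2", ]
  expect_equal(nrow(g2), nrow(truth2))  # 100 % recall, no extra groups
  for (i in seq_len(nrow(truth2))) {
    row <- g2[g2$seed_a == truth2$seed_a[i] |
              grepl(truth2$seed_a[i], g2$inparalogs_a, fixed = TRUE), ]
    expect_equal(nrow(row), 1L, info = truth2$seed_a[i])
    membersB <- sort(setdiff(unlist(strsplit(
      c(row$seed_b, row$inparalogs_b), ";")), ""))
    expect_identical(membersB,
                     sort(strsplit(truth2$members_b[i], ";")[[1L]]))
    expect_identical(row$relationship, truth2$relationship[i])
  }
  # no decoy appears anywhere
  all_members <- unlist(strsplit(
    c(g2$seed_a, g2$seed_b, g2$inparalogs_a, g2$inparalogs_b), ";"))
  expect_false(any(grepl("_D", all_members)))
})

test_that("ortholog inference is reciprocal up to label swap", {
  pt <- generateProteomes(13, nSpecies = 2, nDecoys = 0)
  ab <- inferOrthologs(pt$proteomes$S1, pt$proteomes$S2)
  ba <- inferOrthologs(pt$proteomes$S2, pt$proteomes$S1)
  expect_equal(nrow(ab), nrow(ba))
  pairs_ab <- sort(paste(ab$seed_a, ab$seed_b))
  pairs_ba <- sort(paste(ba$seed_b, ba$seed_a))
  expect_identical(pairs_ab, pairs_ba)
})

test_that("paralog inference excludes same-gene isoforms", {
  pt <- generateProteomes(11)
  para <- inferParalogs(pt$proteomes$S2, pt$genes$S2)
  expect_equal(nrow(para), 1L)  # the planted duplication, different genes
  expect_setequal(c(para$protein_a, para$protein_b), c("S2_P1", "S2_P1dup"))
  # isoforms of one gene are excluded
  iso <- c(A1 = pt$proteomes$S2[["S2_P1"]], A2 = pt$proteomes$S2[["S2_P1"]])
  expect_equal(nrow(inferParalogs(iso, c(A1 = "g", A2 = "g"))), 0L)
  expect_equal(nrow(inferParalogs(character(), character())), 0L)
})

test_that("conservation score counts species, not groups", {
  tabs <- list(
    sp1 = data.frame(seed_a = c("P1", "P1"), seed_b = c("X1", "X2"),
                     inparalogs_a = "", inparalogs_b = "",
                     stringsAsFactors = FALSE),
    sp2 = data.frame(seed_a = "P2", seed_b = "Y1",
                     inparalogs_a = "P1", inparalogs_b = "",
                     stringsAsFactors = FALSE),
    sp3 = data.frame(seed_a = character(), seed_b = character(),
                     inparalogs_a = character(), inparalogs_b = character(),
                     stringsAsFactors = FALSE))
  expect_equal(conservationScore("P1", tabs), 2L)  # two groups in sp1 = 1
  expect_equal(conservationScore("P2", tabs), 1L)
  expect_equal(conservationScore("P9", tabs), 0L)
})

test_that("planted conservation counts are recovered across species", {
  pt <- generateProteomes(11)
  tabs <- list(S2 = inferOrthologs(pt$proteomes$S1, pt$proteomes$S2),
               S3 = inferOrthologs(pt$proteomes$S1, pt$proteomes$S3))
  got <- vapply(names(pt$expectedConservation), conservationScore, 0L,
                orthologTables = tabs)
  expect_identical(got, pt$expectedConservation)
})
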