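# Translation-initiation context motifs and physicochemical properties.

IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Initiation-context motif patterns
#'
#' Two IUPAC-degenerate nucleotide patterns anchored on the initiator
#' ATG: the simplified Kozak motif \code{RNNATGG} (3 nt upstream, 1 nt
#' downstream; R = A/G) and the high-efficiency translation-initiation
#' motif \code{RYMRMVAUGGC} (6 nt upstream, 2 nt downstream; Y = U/C,
#' M = A/C, V = A/C/G; U is equivalent to T).
#'
#' @param name \code{"kozak_simplified"} or \code{"tis_high_efficiency"}.
#' @return a list with \code{name}, \code{pattern}, \code{upstream},
#'   \code{downstream}.
#' @examples
#' motifPattern("kozak_simplified")
#' @export
motifPattern <- function(name = c("kozak_simplified", "tis_high_efficiency")) {
  name <- match.arg(name)
  switch(name,
    kozak_simplified = list(name = name, pattern = "RNNATGG",
                            upstream = 3L, downstream = 1L),
    tis_high_efficiency = list(name = name, pattern = "RYMRMVAUGGC",
                               upstream = 6L, downstream = 2L))
}

#' Match an initiation-context motif around an ATG
#'
#' Tests whether the transcript context around an initiator ATG matches
#' an IUPAC-degenerate motif. The full window (\code{upstream} bases
#' before the A of the ATG through \code{downstream} bases after the G)
#' must exist within the transcript; windows truncated by a transcript
#' end score \code{FALSE}.
#'
#' @param txSeq transcript sequence (character).
#' @param atgPos 1-based position of the A of the initiator ATG;
#'   \code{txSeq} must carry ATG there.
#' @param pattern a pattern from [motifPattern()].
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' matchMotif("AAGCCATGGA", 6, motifPattern("kozak_simplified"))
#' @export
matchMotif <- function(txSeq, atgPos, pattern) {
  txSeq <- toupper(txSeq)
  if (substring(txSeq, atgPos, atgPos + 2L) != "ATG")
    stop("no ATG at position ", atgPos)
  lo <- atgPos - pattern$upstream
  hi <- atgPos + 2L + pattern$downstream
  if (lo < 1L || hi > nchar(txSeq)) return(FALSE)
  window <- strsplit(substring(txSeq, lo, hi), "")[[1L]]
  pat <- strsplit(toupper(pattern$pattern), "")[[1L]]
  stopifnot(length(window) == length(pat))
  all(vapply(seq_along(pat), function(i)
    window[i] %in% IUPAC_NT[[pat[i]]], TRUE))
}

# average residue masses (Da); terminal water added once per chain
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
AA_MONO_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
WATER_AVG <- 18.01524
WATER_MONO <- 18.010565

#' Protein molecular weight
#'
#' Sum of residue masses plus one water, using average masses by default
#' (monoisotopic available via \code{monoisotopic = TRUE}).
#'
#' @param proteinSeq amino-acid string over the 20 standard residues.
#' @param monoisotopic use monoisotopic masses.
#' @return mass in Daltons.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(proteinSeq, monoisotopic = FALSE) {
  if (!nzchar(proteinSeq)) stop("empty protein sequence")
  aa <- strsplit(toupper(proteinSeq), "")[[1L]]
  tab <- if (monoisotopic) AA_MONO_MASS else AA_AVG_MASS
  m <- tab[aa]
  if (anyNA(m))
    stop("unknown residue(s): ", paste(unique(aa[is.na(m)]), collapse = ", "))
  sum(m) + if (monoisotopic) WATER_MONO else WATER_AVG
}

# EMBOSS-style pKa set; config-replaceable through the pKa argument
PKA_DEFAULT <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                 H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, the C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R).
#'
#' @param proteinSeq amino-acid string.
#' @param pH pH value(s).
#' @param pKa named pKa set (see \code{PKA_DEFAULT}).
#' @return net charge (vectorized over \code{pH}).
#' @export
proteinCharge <- function(proteinSeq, pH, pKa = PKA_DEFAULT) {
  aa <- strsplit(toupper(proteinSeq), "")[[1L]]
  counts <- table(factor(aa, names(AA_AVG_MASS)))
  pos <- function(pk) 1 / (1 + 10^(pH - pk))   # protonated basic group
  neg <- function(pk) -1 / (1 + 10^(pk - pH))  # deprotonated acidic group
  ch <- pos(pKa[["Nterm"]]) + neg(pKa[["Cterm"]])
  ch <- ch + counts[["K"]] * pos(pKa[["K"]]) + counts[["R"]] * pos(pKa[["R"]]) +
    counts[["H"]] * pos(pKa[["H"]]) + counts[["D"]] * neg(pKa[["D"]]) +
    counts[["E"]] * neg(pKa[["E"]]) + counts[["C"]] * neg(pKa[["C"]]) +
    counts[["Y"]] * neg(pKa[["Y"]])
  ch
}

#' Protein isoelectric point
#'
#' The pH at which the net charge crosses zero. The charge is strictly
#' decreasing in pH, so the root is unique; it is found by bisection on
#' [0, 14] to the requested tolerance.
#'
#' @inheritParams proteinCharge
#' @param tol bisection tolerance in pH units (default 0.001).
#' @return the isoelectric point (pH units).
#' @examples
#' isoelectricPoint("GGGG")  # midpoint of the terminal pKa values, 6.1
#' @export
isoelectricPoint <- function(proteinSeq, pKa = PKA_DEFAULT, tol = 0.001) {
  aa <- strsplit(toupper(proteinSeq), "")[[1L]]
  if (!all(aa %in% names(AA_AVG_MASS)))
    stop("unknown residue(s) in protein sequence")
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (proteinCharge(proteinSeq, mid, pKa) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Annotate features for every entry of a catalog
#'
#' Fills in protein length, molecular weight, isoelectric point and the
#' two initiation-context motif flags. A motif flag is \code{TRUE} when
#' the motif matches around the initiator ATG on at least one associated
#' transcript (contexts differ between transcripts of one product when
#' the ATG sits at different distances from the transcript start).
#' Proteins containing X (from N bases) get \code{NA} weight and pI.
#'
#' @param catalog a \code{ProteinCatalog}.
#' @param x the \code{MergedTranscriptome} the catalog came from.
#' @param genome a \code{DNAStringSet}.
#' @return the catalog with feature columns \code{length_aa},
#'   \code{mw_da}, \code{pi}, \code{kozak}, \code{tis}.
#' @export
annotateFeatures <- function(catalog, x, genome) {
  en <- catalog@entries
  as1 <- catalog@associations
  kz <- motifPattern("kozak_simplified")
  tis <- motifPattern("tis_high_efficiency")
  en$length_aa <- nchar(en$protein)
  hasX <- grepl("X", en$protein, fixed = TRUE)
  en$mw_da <- ifelse(hasX, NA_real_,
    vapply(as.character(en$protein), function(p)
      if (nzchar(p)) molecularWeight(p) else NA_real_, 0))
  en$pi <- ifelse(hasX, NA_real_,
    vapply(as.character(en$protein), function(p)
      if (nzchar(p)) isoelectricPoint(p) else NA_real_, 0))
  seqCache <- new.env()
  getSeq <- function(uid) {
    if (is.null(seqCache[[uid]]))
      seqCache[[uid]] <- .spliceBlocks(x@exons[[uid]], genome)
    seqCache[[uid]]
  }
  en$kozak <- FALSE; en$tis <- FALSE
  for (e in seq_len(nrow(en))) {
    rows <- which(as1$entry_id == en$entry_id[e])
    for (r in rows) {
      s <- getSeq(as1$uid[r])
      if (!en$kozak[e]) en$kozak[e] <- matchMotif(s, as1$tx_start[r], kz)
      if (!en$tis[e]) en$tis[e] <- matchMotif(s, as1$tx_start[r], tis)
      if (en$kozak[e] && en$tis[e]) break
    }
  }
  catalog@entries <- en
  catalog
}
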