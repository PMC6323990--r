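# Cross-species ortholog and within-species paralog inference with a
# reciprocal-best-hit approach gated by a bit-score / query-coverage
# significance filter, and the per-protein conservation score.

#' Karlin-Altschul bit score
#'
#' Normalizes a raw local-alignment score:
#' bits = (lambda * S - ln K) / ln 2.
#'
#' @param raw raw alignment score(s).
#' @param p a \code{ScoringParams}.
#' @return bit score(s).
#' @examples
#' bitScore(100, scoringParams())  # 43.13
#' @export
bitScore <- function(raw, p = scoringParams()) {
  (p@lambda * raw - log(p@k)) / log(2)
}

#' Local protein alignment with coverage and identity
#'
#' Optimal Smith-Waterman local alignment under the parameter set's
#' substitution matrix and affine gap penalties. Identity is computed
#' over aligned columns; query coverage is the aligned query span
#' divided by the query length. A best score of 0 or less is reported
#' as no alignment.
#'
#' @param query,subject amino-acid strings (query first).
#' @param p a \code{ScoringParams}.
#' @return a list: \code{raw_score}, \code{bit_score},
#'   \code{identity_pct}, \code{query_cover_frac}, \code{query_span},
#'   \code{subject_span} (1-based closed spans, \code{NA} when no
#'   alignment).
#' @export
localAlign <- function(query, subject, p = scoringParams()) {
  stopifnot(nzchar(query), nzchar(subject))
  mat <- .getMatrix(p@matrixName)
  al <- Biostrings::pairwiseAlignment(
    AAString(query), AAString(subject), type = "local",
    substitutionMatrix = mat, gapOpening = p@gapOpen,
    gapExtension = p@gapExtend)
  sc <- Biostrings::score(al)
  if (sc <= 0)
    return(list(raw_score = 0, bit_score = bitScore(0, p), identity_pct = 0,
                query_cover_frac = 0, query_span = c(NA, NA),
                subject_span = c(NA, NA)))
  qs <- BiocGenerics::start(Biostrings::pattern(al))
  qe <- BiocGenerics::end(Biostrings::pattern(al))
  cols <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  list(raw_score = sc, bit_score = bitScore(sc, p),
       identity_pct = if (cols) 100 * Biostrings::nmatch(al) / cols else 0,
       query_cover_frac = (qe - qs + 1L) / nchar(query),
       query_span = c(qs, qe),
       subject_span = c(BiocGenerics::start(Biostrings::subject(al)),
                        BiocGenerics::end(Biostrings::subject(al))))
}

#' Homology significance filter
#'
#' A directed comparison is significant when its bit score reaches
#' \code{minBits} (default 40) AND the aligned span covers at least
#' \code{minOverlapFrac} (default 50\%) of the query sequence.
#'
#' @param aln result of [localAlign()].
#' @param p a \code{ScoringParams}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isSignificant <- function(aln, p = scoringParams()) {
  aln$bit_score >= p@minBits && aln$query_cover_frac >= p@minOverlapFrac
}

# all-vs-all significant directed hits between two named sequence
# vectors; one vectorized pairwiseAlignment call per subject
.allHits <- function(qs, ss, p) {
  mat <- .getMatrix(p@matrixName)
  qset <- AAStringSet(unlist(qs))
  qlen <- nchar(qs)
  rows <- list()
  for (sn in names(ss)) {
    al <- Biostrings::pairwiseAlignment(
      qset, AAString(ss[[sn]]), type = "local",
      substitutionMatrix = mat, gapOpening = p@gapOpen,
      gapExtension = p@gapExtend)
    sc <- Biostrings::score(al)
    bits <- bitScore(pmax(sc, 0), p)
    span <- BiocGenerics::end(Biostrings::pattern(al)) -
      BiocGenerics::start(Biostrings::pattern(al)) + 1L
    cover <- ifelse(sc > 0, span / qlen, 0)
    nm <- Biostrings::nmatch(al); nmm <- Biostrings::nmismatch(al)
    ident <- ifelse(sc > 0 & (nm + nmm) > 0, 100 * nm / (nm + nmm), 0)
    ok <- sc > 0 & bits >= p@minBits & cover >= p@minOverlapFrac &
      names(qs) != sn
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        query = names(qs)[ok], subject = sn, bits = bits[ok],
        identity = ident[ok], coverage = cover[ok],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query = character(), subject = character(),
                      bits = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# best subject per query by bits, ties broken lexicographically
.bestHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query, -hits$bits, hits$subject), , drop = FALSE]
  hits[!duplicated(hits$query), , drop = FALSE]
}

#' Infer ortholog groups between two species
#'
#' All-vs-all local alignments are filtered for significance
#' ([isSignificant()]); reciprocal best hits seed ortholog groups (ties
#' broken lexicographically). Within each species, additional sequences
#' whose significant score to their own seed member is at least that
#' member's score to its seed partner are included as inparalogs. The
#' group relationship (one-to-one, one-to-many, many-to-one,
#' many-to-many) follows the inparalog counts on each side.
#'
#' @param proteomeA,proteomeB named character vectors of protein
#'   sequences (names are protein identifiers, unique within and across
#'   the two proteomes).
#' @param p a \code{ScoringParams}.
#' @return a \code{data.frame}, one row per group: \code{seed_a},
#'   \code{seed_b}, \code{bits}, \code{inparalogs_a},
#'   \code{inparalogs_b} (";"-joined, empty when none),
#'   \code{relationship}.
#' @export
inferOrthologs <- function(proteomeA, proteomeB, p = scoringParams()) {
  ab <- .allHits(proteomeA, proteomeB, p)
  ba <- .allHits(proteomeB, proteomeA, p)
  bestAB <- .bestHits(ab)
  bestBA <- .bestHits(ba)
  groups <- list()
  for (i in seq_len(nrow(bestAB))) {
    a <- bestAB$query[i]; b <- bestAB$subject[i]
    j <- which(bestBA$query == b)
    if (!length(j) || bestBA$subject[j] != a) next
    seedBits <- min(bestAB$bits[i], bestBA$bits[j])
    inA <- .inparalogs(proteomeA, a, bestAB$bits[i], p, exclude = a)
    inB <- .inparalogs(proteomeB, b, bestBA$bits[j], p, exclude = b)
    rel <- if (!length(inA) && !length(inB)) "one-to-one"
      else if (!length(inA)) "one-to-many"
      else if (!length(inB)) "many-to-one"
      else "many-to-many"
    groups[[length(groups) + 1L]] <- data.frame(
      seed_a = a, seed_b = b, bits = seedBits,
      inparalogs_a = paste(inA, collapse = ";"),
      inparalogs_b = paste(inB, collapse = ";"),
      relationship = rel, stringsAsFactors = FALSE)
  }
  if (!length(groups))
    return(data.frame(seed_a = character(), seed_b = character(),
                      bits = numeric(), inparalogs_a = character(),
                      inparalogs_b = character(),
                      relationship = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, groups)
  res[order(res$seed_a), , drop = FALSE]
}

# same-species sequences scoring >= seedBits against the seed member
.inparalogs <- function(proteome, seed, seedBits, p, exclude) {
  others <- proteome[setdiff(names(proteome), exclude)]
  if (!length(others)) return(character(0))
  hits <- .allHits(others, proteome[seed], p)
  sort(hits$query[hits$bits >= seedBits])
}

#' Infer within-species paralog pairs
#'
#' Significant symmetric pairs within one proteome, excluding
#' comparisons between sequences of the same gene (isoforms are not
#' paralogs). A pair is reported when both directed comparisons pass the
#' significance filter.
#'
#' @param proteome named character vector of protein sequences.
#' @param genes named character vector mapping protein id to gene.
#' @param p a \code{ScoringParams}.
#' @return a \code{data.frame} with columns \code{protein_a},
#'   \code{protein_b} (a < b), \code{bits}, \code{identity},
#'   \code{coverage}.
#' @export
inferParalogs <- function(proteome, genes, p = scoringParams()) {
  nms <- names(proteome)
  rows <- list()
  if (length(nms) > 1L) {
    for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
      a <- nms[i]; b <- nms[j]
      if (!is.na(genes[[a]]) && !is.na(genes[[b]]) &&
          genes[[a]] == genes[[b]]) next
      f <- localAlign(proteome[[a]], proteome[[b]], p)
      r <- localAlign(proteome[[b]], proteome[[a]], p)
      if (isSignificant(f, p) && isSignificant(r, p))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_a = min(a, b), protein_b = max(a, b),
          bits = min(f$bit_score, r$bit_score),
          identity = f$identity_pct, coverage = min(f$query_cover_frac,
                                                    r$query_cover_frac),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_a = character(), protein_b = character(),
                      bits = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Conservation score across species
#'
#' Number of species (among those compared) in which at least one
#' ortholog group contains the protein, either as seed or inparalog.
#' Several groups in one species still contribute one.
#'
#' @param accession protein identifier on the query-species side
#'   (\code{seed_a} / \code{inparalogs_a} columns).
#' @param orthologTables a named list (one element per compared species)
#'   of group tables from [inferOrthologs()] run with the query species
#'   as proteome A.
#' @return an integer count of species.
#' @export
conservationScore <- function(accession, orthologTables) {
  inSpecies <- vapply(orthologTables, function(tab) {
    if (!nrow(tab)) return(FALSE)
    any(tab$seed_a == accession) ||
      any(accession %in% unlist(strsplit(tab$inparalogs_a[nzchar(tab$inparalogs_a)], ";")))
  }, TRUE)
  sum(inSpecies)
}
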