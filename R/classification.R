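# Partition of the ORFeome into RefProts, novel Isoforms and AltProts:
# exact matching against known protein sets, then the two-argument
# similarity filter within each reconciled gene.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Build an exact-lookup index of known reference proteins
#'
#' Reads one or more protein FASTA files into a single index. Trailing
#' stop symbols (\code{*}) are stripped; duplicate sequences are allowed
#' and keep every accession. Lookup priority across sources follows the
#' order of \code{files}.
#'
#' @param files a list of entries \code{list(path =, source =, geneMap =)}
#'   where \code{geneMap} is an optional named character vector mapping
#'   accession to gene.
#' @return a \code{KnownProteinIndex}.
#' @export
buildKnownIndex <- function(files) {
  recs <- lapply(files, function(f) {
    aa <- Biostrings::readAAStringSet(f$path)
    acc <- sub("\\s.*$", "", names(aa))
    seqs <- sub("\\*+$", "", toupper(as.character(aa)))
    bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"), seqs)
    if (any(bad))
      stop("non-amino-acid alphabet in record(s): ",
           paste(acc[bad], collapse = ", "), " of ", f$path)
    gene <- if (!is.null(f$geneMap)) unname(f$geneMap[acc]) else
      rep(NA_character_, length(acc))
    data.frame(accession = acc, protein = unname(seqs), source = f$source,
               gene = gene, stringsAsFactors = FALSE)
  })
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(accession = character(), protein = character(),
               source = character(), gene = character(),
               stringsAsFactors = FALSE)
  pri <- unique(vapply(files, function(f) f$source, ""))
  new("KnownProteinIndex", records = DataFrame(recs), priority = pri)
}

#' Exact full-length match of a protein against the known index
#'
#' Returns the accession of an indexed record whose sequence equals the
#' query exactly and over its full length, or \code{NA} if none.
#' When several sources match, the accession from the highest-priority
#' source (the order the index was built with, e.g. first annotation >
#' second annotation > external set) is returned, ties broken by
#' accession.
#'
#' @param proteinSeq amino-acid string.
#' @param idx a \code{KnownProteinIndex}.
#' @return accession (character) or \code{NA_character_}.
#' @export
matchRefProt <- function(proteinSeq, idx) {
  rec <- idx@records
  hit <- which(rec$protein == proteinSeq)
  if (!length(hit)) return(NA_character_)
  pr <- match(rec$source[hit], idx@priority)
  hit <- hit[order(pr, rec$accession[hit])]
  rec$accession[hit[1L]]
}

# identity-oriented protein matrix: match +5 / mismatch -4
.identityMatrix <- function() {
  letters <- c(AA20, "X", "*")
  m <- matrix(-4, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 5
  m["X", ] <- -4; m[, "X"] <- -4  # X never counts as a match
  m
}

.getMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# local alignment of candidate (pattern) vs reference (subject);
# returns score, identity % over aligned columns, candidate span fraction
.localAlnStats <- function(candidate, ref, mat, gapOpen, gapExtend) {
  al <- Biostrings::pairwiseAlignment(
    AAString(candidate), AAString(ref), type = "local",
    substitutionMatrix = mat, gapOpening = gapOpen, gapExtension = gapExtend)
  sc <- Biostrings::score(al)
  if (sc <= 0)
    return(list(score = 0, identity = 0, span = 0))
  cols <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  span <- BiocGenerics::end(Biostrings::pattern(al)) -
    BiocGenerics::start(Biostrings::pattern(al)) + 1L
  list(score = sc,
       identity = if (cols) 100 * Biostrings::nmatch(al) / cols else 0,
       span = span / nchar(candidate))
}

#' Two-argument similarity filter for novel-isoform calls
#'
#' Decides whether an unannotated product is a novel isoform of one of
#' its gene's reference proteins. Argument A fires when a local
#' alignment to a same-gene RefProt reaches at least
#' \code{minIdentity} \% identity over an aligned span of at least
#' \code{minCoverageA} of the candidate's length. Argument B fires when
#' the candidate shares the exact genomic coordinate of the start
#' codon's first base or the stop codon's last base with a same-gene
#' RefProt (same contig and strand) and a stringent-matrix local
#' alignment scores at least \code{minScoreB} over a span of at least
#' \code{minCoverageB} of the candidate's length. The candidate is an
#' isoform if either argument fires.
#'
#' The stringent-matrix score threshold is applied as a minimum: a
#' maximum-score ceiling would declare dissimilar sequences isoforms,
#' defeating the filter; \code{scoreBDirection = "max"} restores the
#' ceiling reading.
#'
#' @param protein candidate protein sequence.
#' @param blockKey candidate genomic blocks key (see [encodeBlocks()]).
#' @param refProteins character vector of same-gene RefProt sequences.
#' @param refBlockKeys their block keys (parallel to
#'   \code{refProteins}).
#' @param refAccessions their accessions.
#' @param minIdentity,minCoverageA argument A thresholds (default 80\%
#'   identity over 50\% of the candidate length).
#' @param minScoreB,minCoverageB argument B thresholds (default score
#'   100 over 20\% of the candidate length).
#' @param matrixB stringent substitution matrix for argument B (default
#'   PAM30).
#' @param scoreBDirection \code{"min"} (default) or \code{"max"}.
#' @return a list: \code{is_isoform}, \code{matched_refprot},
#'   \code{argument} (\code{"A_identity_coverage"},
#'   \code{"B_anchored_similarity"} or \code{"none"}),
#'   \code{identity_pct}, \code{coverage_pct}, \code{matcher_score}.
#' @export
similarityFilter <- function(protein, blockKey, refProteins,
                             refBlockKeys = character(),
                             refAccessions = paste0("REF", seq_along(refProteins)),
                             minIdentity = 80, minCoverageA = 0.5,
                             minScoreB = 100, minCoverageB = 0.2,
                             matrixB = "PAM30",
                             scoreBDirection = c("min", "max")) {
  scoreBDirection <- match.arg(scoreBDirection)
  verdict <- list(is_isoform = FALSE, matched_refprot = NA_character_,
                  argument = "none", identity_pct = 0, coverage_pct = 0,
                  matcher_score = 0)
  if (!length(refProteins)) return(verdict)
  idm <- .identityMatrix()
  pam <- .getMatrix(matrixB)
  cb <- if (nzchar(blockKey)) decodeBlocks(blockKey) else NULL
  for (i in seq_along(refProteins)) {
    a <- .localAlnStats(protein, refProteins[i], idm, 10, 0.5)
    if (a$identity >= minIdentity && a$span >= minCoverageA) {
      return(list(is_isoform = TRUE, matched_refprot = refAccessions[i],
                  argument = "A_identity_coverage",
                  identity_pct = a$identity, coverage_pct = 100 * a$span,
                  matcher_score = a$score))
    }
    anchored <- FALSE
    if (!is.null(cb) && i <= length(refBlockKeys) && nzchar(refBlockKeys[i])) {
      rb <- decodeBlocks(refBlockKeys[i])
      sameLoc <- as.character(GenomicRanges::seqnames(cb))[1L] ==
        as.character(GenomicRanges::seqnames(rb))[1L] &&
        as.character(BiocGenerics::strand(cb))[1L] ==
        as.character(BiocGenerics::strand(rb))[1L]
      anchored <- sameLoc && (.startCodonPos(cb) == .startCodonPos(rb) ||
                              .stopCodonPos(cb) == .stopCodonPos(rb))
    }
    if (anchored) {
      b <- .localAlnStats(protein, refProteins[i], pam, 10, 0.5)
      pass <- if (scoreBDirection == "min") b$score >= minScoreB
              else b$score <= minScoreB
      if (pass && b$span >= minCoverageB) {
        return(list(is_isoform = TRUE, matched_refprot = refAccessions[i],
                    argument = "B_anchored_similarity",
                    identity_pct = b$identity, coverage_pct = 100 * b$span,
                    matcher_score = b$score))
      }
    }
  }
  verdict
}

#' Classify a deduplicated catalog into RefProt / Isoform / AltProt
#'
#' First pass: entries whose protein exactly matches the known index
#' become RefProts and keep the matched accession. Second pass: each
#' remaining entry is tested with the similarity filter against the
#' RefProt entries of its reconciled gene; hits become Isoforms, the
#' rest AltProts, so that
#' \code{|AltProt| = |total| - |RefProt| - |Isoform|} holds exactly.
#'
#' @param catalog a deduplicated \code{ProteinCatalog}.
#' @param idx a \code{KnownProteinIndex}.
#' @param ... thresholds passed on to [similarityFilter()].
#' @return the catalog with columns \code{category},
#'   \code{ref_accession}, \code{isoform_argument} filled in.
#' @export
classifyCatalog <- function(catalog, idx, ...) {
  en <- catalog@entries
  n <- nrow(en)
  en$category <- rep(NA_character_, n)
  en$ref_accession <- rep(NA_character_, n)
  en$isoform_argument <- rep(NA_character_, n)
  if (n == 0L) { catalog@entries <- en; return(catalog) }
  for (i in seq_len(n)) {
    acc <- matchRefProt(en$protein[i], idx)
    if (!is.na(acc)) {
      en$category[i] <- "RefProt"
      en$ref_accession[i] <- acc
    }
  }
  refIdx <- which(en$category %in% "RefProt")
  for (i in which(is.na(en$category))) {
    sameGene <- refIdx[en$gene[refIdx] == en$gene[i]]
    v <- similarityFilter(en$protein[i], en$block_key[i],
                          refProteins = as.character(en$protein[sameGene]),
                          refBlockKeys = as.character(en$block_key[sameGene]),
                          refAccessions = as.character(en$ref_accession[sameGene]),
                          ...)
    if (v$is_isoform) {
      en$category[i] <- "Isoform"
      en$isoform_argument[i] <- v$argument
      en$ref_accession[i] <- v$matched_refprot
    } else {
      en$category[i] <- "AltProt"
    }
  }
  tab <- table(factor(en$category, c("RefProt", "Isoform", "AltProt")))
  message("classified catalog: Total ", n, " / Ref ", tab[["RefProt"]],
          " / II_ ", tab[["Isoform"]], " / IP_ ", tab[["AltProt"]])
  catalog@entries <- en
  catalog
}
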