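# Ingestion of externally produced MS peptide tables and ribosome
# profiling detection tables; uniqueness-aware peptide assignment and
# the per-protein MS / TE scores and confidence tier.

#' Read a peptide identification table
#'
#' Tab-separated with header columns \code{study_id}, \code{peptide},
#' \code{psm_count}, \code{fdr}. Upstream search-engine FDR filtering is
#' assumed already applied; rows are re-filtered only on the columns
#' present.
#'
#' @param path TSV file path.
#' @param minLength minimum peptide length retained (default 6).
#' @return a \code{data.frame} of peptide observations.
#' @export
readPeptideTable <- function(path, minLength = 6L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "peptide", "psm_count") %in% colnames(tab)))
  tab$peptide <- toupper(tab$peptide)
  tab[nchar(tab$peptide) >= minLength, , drop = FALSE]
}

#' Read a ribosome-profiling ORF detection table
#'
#' Tab-separated with header columns \code{study_id}, \code{contig},
#' \code{strand}, \code{blocks} (comma-separated \code{start-end}
#' genomic intervals, 1-based closed, in transcript order),
#' \code{p_value}, \code{readcount}. An optional \code{accession} column
#' is honoured for direct matching.
#'
#' @param path TSV file path.
#' @return a \code{data.frame} of detections with a \code{block_key}
#'   column.
#' @export
readRiboseqTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "p_value") %in% colnames(tab)))
  if (all(c("contig", "strand", "blocks") %in% colnames(tab)))
    tab$block_key <- paste0(tab$contig, ":", tab$strand, ":", tab$blocks)
  tab
}

#' Assign peptides to catalog proteins with RefProt priority
#'
#' A peptide maps to a protein when it is an exact substring of the
#' protein sequence. Peptides matching at least one RefProt are
#' assigned ONLY to the matching RefProt(s); peptides matching no
#' RefProt but exactly one novel entry are that entry's unique
#' peptides; peptides matching several novel entries and no RefProt are
#' flagged ambiguous and assigned to none. Peptides with illegal
#' characters are skipped with a warning.
#'
#' @param observations a \code{data.frame} from [readPeptideTable()].
#' @param catalog a classified \code{ProteinCatalog}.
#' @param equateIL treat I and L as indistinguishable.
#' @return a \code{data.frame}: one row per observation, with
#'   \code{status} (\code{"refprot"}, \code{"unique"},
#'   \code{"ambiguous"}, \code{"unmatched"}, \code{"skipped"}) and
#'   \code{assigned} (";"-joined entry ids).
#' @export
assignPeptides <- function(observations, catalog, equateIL = FALSE) {
  en <- catalog@entries
  if (!"category" %in% colnames(en) || anyNA(en$category))
    stop("catalog must be classified before peptide assignment")
  prot <- as.character(en$protein)
  if (equateIL) prot <- gsub("I", "L", prot, fixed = TRUE)
  isRef <- en$category == "RefProt"
  out <- observations
  out$status <- "unmatched"
  out$assigned <- ""
  legal <- paste0("^[", paste(AA20, collapse = ""), "]+$")
  for (i in seq_len(nrow(out))) {
    pep <- out$peptide[i]
    if (!grepl(legal, pep)) {
      warning("peptide with illegal characters skipped: ", pep)
      out$status[i] <- "skipped"
      next
    }
    q <- if (equateIL) gsub("I", "L", pep, fixed = TRUE) else pep
    hit <- which(vapply(prot, function(s) grepl(q, s, fixed = TRUE), TRUE))
    if (!length(hit)) next
    refHit <- hit[isRef[hit]]
    if (length(refHit)) {
      out$status[i] <- "refprot"
      out$assigned[i] <- paste(en$entry_id[refHit], collapse = ";")
    } else if (length(hit) == 1L) {
      out$status[i] <- "unique"
      out$assigned[i] <- en$entry_id[hit]
    } else {
      out$status[i] <- "ambiguous"
    }
  }
  out
}

#' Per-protein MS score
#'
#' Sum over studies of the number of distinct unique peptides assigned
#' to the protein in that study (a peptide seen in two studies counts
#' once per study). For RefProts, peptides assigned under RefProt
#' priority count the same way.
#'
#' @param entryId catalog entry id.
#' @param assignments output of [assignPeptides()].
#' @return integer MS score.
#' @export
msScore <- function(entryId, assignments) {
  sel <- assignments$status %in% c("unique", "refprot") &
    vapply(strsplit(assignments$assigned, ";"), function(a)
      entryId %in% a, TRUE)
  if (!any(sel)) return(0L)
  sum(vapply(split(assignments$peptide[sel], assignments$study_id[sel]),
             function(p) length(unique(p)), 0L))
}

#' Per-protein TE (translation) score
#'
#' Number of distinct ribosome-profiling studies with at least one
#' detection of the ORF passing the p-value cutoff. Detections match a
#' catalog entry by exact genomic-blocks equality (\code{block_key}) or
#' by accession.
#'
#' @param entry one-row slice of the catalog entry table (needs
#'   \code{block_key}; \code{accession} honoured when present).
#' @param detections a \code{data.frame} from [readRiboseqTable()].
#' @param pCutoff detection p-value cutoff (default 0.01).
#' @return integer TE score.
#' @export
teScore <- function(entry, detections, pCutoff = 0.01) {
  if (!nrow(detections)) return(0L)
  hit <- rep(FALSE, nrow(detections))
  if ("block_key" %in% colnames(detections))
    hit <- hit | detections$block_key == entry$block_key
  if ("accession" %in% colnames(detections) &&
      "accession" %in% colnames(entry) && !is.na(entry$accession))
    hit <- hit | (!is.na(detections$accession) &
                  detections$accession == entry$accession)
  hit <- hit & detections$p_value <= pCutoff
  length(unique(detections$study_id[hit]))
}

#' Confidence tier of a catalog entry
#'
#' \code{"high"}: novel entry (Isoform or AltProt) with at least two
#' cumulative unique peptides. \code{"supported"}: any MS, translation
#' or conservation evidence. \code{"predicted"}: no evidence.
#'
#' @param category entry category.
#' @param msScore,teScore,conservationScore evidence scores.
#' @param uniquePeptides cumulative distinct unique peptides of the
#'   entry (across studies); for novel entries this equals the distinct
#'   peptides behind \code{msScore}.
#' @return \code{"high"}, \code{"supported"} or \code{"predicted"}.
#' @export
confidenceTier <- function(category, msScore, teScore, conservationScore,
                           uniquePeptides = msScore) {
  if (category %in% c("Isoform", "AltProt") && uniquePeptides >= 2L)
    return("high")
  if (msScore >= 1L || teScore >= 1L || conservationScore >= 1L)
    return("supported")
  "predicted"
}

#' Aggregate MS and Ribo-seq evidence into a catalog
#'
#' Runs peptide assignment, computes per-entry MS and TE scores and the
#' confidence tier, and stores them in the entry table (columns
#' \code{ms_score}, \code{te_score}, \code{unique_peptides},
#' \code{tier}). The \code{conservation_score} column is created as 0
#' when absent (fill it with [addConservation()] first when ortholog
#' tables are available).
#'
#' @param catalog a classified \code{ProteinCatalog}.
#' @param peptides peptide observations ([readPeptideTable()]), or
#'   \code{NULL}.
#' @param detections Ribo-seq detections ([readRiboseqTable()]), or
#'   \code{NULL}.
#' @param pCutoff TE detection p-value cutoff (default 0.01).
#' @param equateIL passed to [assignPeptides()].
#' @return the catalog with evidence columns filled.
#' @export
addEvidence <- function(catalog, peptides = NULL, detections = NULL,
                        pCutoff = 0.01, equateIL = FALSE) {
  en <- catalog@entries
  if (!"conservation_score" %in% colnames(en))
    en$conservation_score <- 0L
  asg <- if (!is.null(peptides) && nrow(peptides))
    assignPeptides(peptides, catalog, equateIL = equateIL)
  else data.frame(study_id = character(), peptide = character(),
                  status = character(), assigned = character(),
                  stringsAsFactors = FALSE)
  en$ms_score <- vapply(en$entry_id, msScore, 0L, assignments = asg)
  en$unique_peptides <- vapply(en$entry_id, function(id) {
    sel <- asg$status %in% c("unique", "refprot") &
      vapply(strsplit(asg$assigned, ";"), function(a) id %in% a, TRUE)
    length(unique(asg$peptide[sel]))
  }, 0L)
  det <- if (!is.null(detections)) detections else
    data.frame(study_id = character(), p_value = numeric())
  en$te_score <- vapply(seq_len(nrow(en)), function(i)
    teScore(as.data.frame(en[i, , drop = FALSE]), det, pCutoff), 0L)
  en$tier <- vapply(seq_len(nrow(en)), function(i)
    confidenceTier(en$category[i], en$ms_score[i], en$te_score[i],
                   en$conservation_score[i], en$unique_peptides[i]), "")
  catalog@entries <- en
  catalog
}

#' Fill per-entry conservation scores from ortholog tables
#'
#' @param catalog a \code{ProteinCatalog} with accessions assigned.
#' @param orthologTables named list of group tables (see
#'   [conservationScore()]).
#' @return the catalog with the \code{conservation_score} column set.
#' @export
addConservation <- function(catalog, orthologTables) {
  en <- catalog@entries
  key <- if ("accession" %in% colnames(en) && !anyNA(en$accession))
    as.character(en$accession) else as.character(en$entry_id)
  en$conservation_score <- vapply(key, conservationScore, 0L,
                                  orthologTables = orthologTables)
  catalog@entries <- en
  catalog
}
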