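# Orchestration of the full annotation run: prediction (annotation ->
# ORF catalog -> classification -> features -> exports) and the two
# evidence-collection stages (orthologs, MS/Ribo-seq).

#' Run the prediction stage end to end
#'
#' Loads the genome and the two source annotations, merges them, builds
#' and classifies the ORF catalog, assigns accessions, annotates
#' features, and writes the TSV / BED12 / FASTA exports plus a JSON run
#' manifest (inputs, parameters, package version). Reruns on identical
#' inputs produce byte-identical outputs.
#'
#' @param genomePath genome FASTA.
#' @param annotations list of \code{list(path =, dialect =, tag =)} for
#'   one or two source annotations.
#' @param knownProteins list of \code{list(path =, source =)} reference
#'   protein FASTA files, in decreasing match priority.
#' @param outDir output directory (created if needed).
#' @param minCodons minimum protein length (default 30).
#' @param mode ORF enumeration mode (see [enumerateOrfs()]).
#' @return the finalized \code{ProteinCatalog}, invisibly; files
#'   \code{catalog.tsv}, \code{catalog.bed}, \code{proteins.fa},
#'   \code{orfs_dna.fa}, \code{manifest.json} appear in \code{outDir}.
#' @export
runBuild <- function(genomePath, annotations, knownProteins, outDir,
                     minCodons = 30L,
                     mode = c("longest_per_stop", "all_starts")) {
  mode <- match.arg(mode)
  for (f in c(genomePath, vapply(annotations, `[[`, "", "path"),
              vapply(knownProteins, `[[`, "", "path")))
    if (!file.exists(f)) stop("missing input: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- loadGenome(genomePath)
  sets <- lapply(annotations, function(a)
    parseAnnotation(a$path, a$dialect, a$tag))
  merged <- if (length(sets) == 2L) mergeAnnotations(sets[[1L]], sets[[2L]])
    else mergeAnnotations(sets[[1L]],
      new("TranscriptSet", exons = GRangesList(),
          txData = DataFrame(uid = character(), transcript_id = character(),
            gene_id = character(), contig = character(),
            strand = character(), biotype = character(),
            source = character(), cds_start = integer(),
            cds_end = integer())))
  idx <- buildKnownIndex(knownProteins)
  catalog <- buildOrfCatalog(merged, genome, minCodons = minCodons,
                             mode = mode)
  catalog <- classifyCatalog(catalog, idx)
  catalog <- assignAccessions(catalog)
  catalog <- annotateFeatures(catalog, merged, genome)
  catalog <- addEvidence(catalog)  # zero evidence columns + tier
  writeCatalogTsv(catalog, file.path(outDir, "catalog.tsv"))
  writeBed(catalog, file.path(outDir, "catalog.bed"))
  writeProteinFasta(catalog, file.path(outDir, "proteins.fa"), "protein")
  writeProteinFasta(catalog, file.path(outDir, "orfs_dna.fa"), "dna")
  manifest <- list(
    stage = "build",
    inputs = list(genome = genomePath,
                  annotations = lapply(annotations, function(a)
                    a[c("path", "dialect", "tag")]),
                  known_proteins = lapply(knownProteins, function(k)
                    k[c("path", "source")])),
    parameters = list(min_codons = minCodons, mode = mode),
    package_version = as.character(utils::packageVersion("Orfeome")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(catalog)
}

#' Run ortholog/paralog inference against other species
#'
#' Aligns the catalog's proteins against each provided species
#' proteome, writes per-species ortholog group tables and a paralog
#' table, and returns the catalog with conservation scores filled.
#'
#' @param catalog a finalized \code{ProteinCatalog}.
#' @param speciesFastas named list of protein FASTA paths (one per
#'   comparison species).
#' @param outDir output directory.
#' @param params a \code{ScoringParams}.
#' @return the catalog with \code{conservation_score} set, invisibly.
#' @export
runOrthologs <- function(catalog, speciesFastas, outDir,
                         params = scoringParams()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  en <- catalog@entries
  query <- setNames(as.character(en$protein), en$accession)
  tables <- list()
  for (sp in names(speciesFastas)) {
    aa <- Biostrings::readAAStringSet(speciesFastas[[sp]])
    other <- setNames(sub("\\*+$", "", as.character(aa)),
                      sub("\\s.*$", "", names(aa)))
    tab <- inferOrthologs(query, other, params)
    utils::write.table(tab, file.path(outDir, paste0("orthologs_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tables[[sp]] <- tab
  }
  genes <- setNames(as.character(en$gene), en$accession)
  para <- inferParalogs(query, genes, params)
  utils::write.table(para, file.path(outDir, "paralogs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  catalog <- addConservation(catalog, tables)
  invisible(catalog)
}

#' Run evidence aggregation and refresh the exports
#'
#' Ingests peptide and Ribo-seq tables, recomputes MS/TE scores and
#' confidence tiers (keeping any conservation scores already present)
#' and rewrites the TSV and BED exports with evidence columns filled.
#'
#' @param catalog a finalized \code{ProteinCatalog}.
#' @param peptidePaths character vector of peptide TSV paths (may be
#'   empty).
#' @param riboseqPaths character vector of Ribo-seq TSV paths (may be
#'   empty).
#' @param outDir output directory.
#' @param pCutoff TE detection p-value cutoff (default 0.01).
#' @return the catalog with evidence columns, invisibly.
#' @export
runEvidence <- function(catalog, peptidePaths = character(),
                        riboseqPaths = character(), outDir,
                        pCutoff = 0.01) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  peps <- if (length(peptidePaths))
    do.call(rbind, lapply(peptidePaths, readPeptideTable)) else NULL
  dets <- if (length(riboseqPaths))
    do.call(rbind, lapply(riboseqPaths, readRiboseqTable)) else NULL
  catalog <- addEvidence(catalog, peps, dets, pCutoff = pCutoff)
  writeCatalogTsv(catalog, file.path(outDir, "catalog.tsv"))
  writeBed(catalog, file.path(outDir, "catalog.bed"))
  invisible(catalog)
}
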