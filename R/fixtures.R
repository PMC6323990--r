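# Deterministic synthetic-data generator: toy genome with planted genes,
# two annotation dialects of the same loci, planted uORFs / 3'UTR ORFs /
# CDS-overlapping frame-shifted ORFs / ncRNA ORFs / truncation and
# anchored isoforms, reference protein sets, mutated cross-species
# proteomes and evidence tables, each with an exact ground-truth table.
#
# Planted transcripts contain an ATG only where an ORF is planted
# (rejection sampling scrubs every accidental ATG, including those formed
# across codon or splice junctions), so the enumerated catalog of a
# fixture is exactly its truth table.

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
SENSE_NO_ATG <- setdiff(SENSE_CODONS, "ATG")

.randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

.countAtg <- function(s) {
  m <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

.atgPositions <- function(s) {
  m <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# random sequence guaranteed free of ATG (T of any accidental ATG -> C)
.scrubbedNt <- function(n) {
  s <- .randNt(n)
  while (.countAtg(s) > 0L) {
    p <- .atgPositions(s)[1L]
    substr(s, p + 1L, p + 1L) <- "C"
  }
  s
}

# run of sense non-ATG codons whose concatenation contains no ATG (the
# offending junction codons are resampled locally until clean)
.senseBody <- function(n) {
  body <- sample(SENSE_NO_ATG, n, replace = TRUE)
  repeat {
    pos <- .atgPositions(paste(body, collapse = ""))
    if (!length(pos)) return(body)
    ci <- (pos[1L] - 1L) %/% 3L + 1L   # junction ATG spans ci, ci+1
    body[ci] <- sample(SENSE_NO_ATG, 1L)
    if (ci < n) body[ci + 1L] <- sample(SENSE_NO_ATG, 1L)
  }
}

# ORF cassette encoding an nAA-residue protein: ATG + (nAA-1) sense
# non-ATG codons + stop; resampled until it contains exactly one ATG
# (none formed across codon junctions). `inject` overwrites body codons
# (1-based body index = protein residue - 1) to plant shared peptides.
.orfCassette <- function(nAA, stop = "TAA", firstCodon = NULL, inject = NULL) {
  repeat {
    body <- .senseBody(nAA - 1L)
    if (!is.null(firstCodon)) body[1L] <- firstCodon
    if (!is.null(inject)) body[inject$at] <- inject$codons
    s <- paste0("ATG", paste(body, collapse = ""), stop)
    if (.countAtg(s) == 1L) return(s)
  }
}

# split a nucleotide string into codons (length must be divisible by 3)
.codons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.UTR_LEN <- 110L

# Build one gene of a given role. Returns locus sequence (sense
# orientation), strand, transcripts (exon intervals in locus
# coordinates, transcript order; CDS in transcript coordinates) and the
# planted ORFs with expected category / localization.
.buildGene <- function(role, geneId, shared) {
  strand <- switch(role, utr3orf = "-", aonly = "-", "+")
  repeat {
    tx2 <- NULL
    if (role == "uorf") {
      uorf <- .orfCassette(30L, firstCodon = "GCT")
      shared$uorfBody <- .codons(uorf)[2:30]  # body codons = residues 2..30
      pad1 <- paste0(.scrubbedNt(4L), "GCC")  # favourable Kozak context
      utr5 <- paste0(pad1, uorf, .scrubbedNt(10L))
      cds <- .orfCassette(80L)
      tx <- paste0(utr5, cds, .scrubbedNt(.UTR_LEN))
      exonW <- c(150L, nchar(tx) - 150L); intrW <- 120L
      cdsTx <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds) - 3L)
      planted <- list(
        list(suffix = "CDS", txStart = cdsTx[1L],
             txEnd = cdsTx[2L] + 3L, category = "RefProt", loc = "CDS"),
        list(suffix = "uORF", txStart = 8L, txEnd = 8L + nchar(uorf) - 1L,
             category = "AltProt", loc = "5UTR"))
    } else if (role == "utr3orf") {
      inj <- if (!is.null(shared$uorfBody))
        list(at = 5:14, codons = shared$uorfBody[5:14]) else NULL
      cass <- .orfCassette(32L, inject = inj)
      utr5 <- .scrubbedNt(.UTR_LEN)
      cds <- .orfCassette(70L)
      utr3 <- paste0(.scrubbedNt(6L), cass, .scrubbedNt(5L))
      tx <- paste0(utr5, cds, utr3)
      exonW <- c(200L, nchar(tx) - 200L); intrW <- 150L
      cdsTx <- c(.UTR_LEN + 1L, .UTR_LEN + nchar(cds) - 3L)
      u3start <- .UTR_LEN + nchar(cds) + 7L
      planted <- list(
        list(suffix = "CDS", txStart = cdsTx[1L], txEnd = cdsTx[2L] + 3L,
             category = "RefProt", loc = "CDS"),
        list(suffix = "u3ORF", txStart = u3start,
             txEnd = u3start + nchar(cass) - 1L,
             category = "AltProt", loc = "3UTR"))
    } else if (role == "cdsalt") {
      ok <- FALSE
      for (try in 1:500) {
        alt <- .orfCassette(34L)           # 105 nt, protein 34 aa
        body <- .senseBody(119L)
        cds <- paste0("ATG", paste(body, collapse = ""), "TGA")
        s0 <- 62L                          # frame +1 relative to the CDS
        cds <- paste0(substr(cds, 1L, s0 - 1L), alt,
                      substr(cds, s0 + nchar(alt), nchar(cds)))
        cc <- .codons(cds)
        if (.countAtg(cds) == 2L &&
            !any(cc[-length(cc)] %in% STOP_CODONS) &&
            cc[length(cc)] %in% STOP_CODONS &&
            identical(.atgPositions(cds), c(1L, s0))) { ok <- TRUE; break }
      }
      if (!ok) stop("could not plant CDS-overlapping ORF")
      utr5 <- .scrubbedNt(.UTR_LEN)
      tx <- paste0(utr5, cds, .scrubbedNt(.UTR_LEN))
      exonW <- c(.UTR_LEN + nchar(cds) + 30L,
                 nchar(tx) - (.UTR_LEN + nchar(cds) + 30L))
      intrW <- 130L
      planted <- list(
        list(suffix = "CDS", txStart = .UTR_LEN + 1L,
             txEnd = .UTR_LEN + nchar(cds), category = "RefProt",
             loc = "CDS"),
        list(suffix = "altORF", txStart = .UTR_LEN + s0,
             txEnd = .UTR_LEN + s0 + nchar(alt) - 1L,
             category = "AltProt", loc = "CDS"))
      cdsTx <- c(.UTR_LEN + 1L, .UTR_LEN + nchar(cds) - 3L)
    } else if (role %in% c("isoA", "isoB")) {
      utr5 <- .scrubbedNt(.UTR_LEN)
      cds <- .orfCassette(100L)            # 303 nt
      tx <- paste0(utr5, cds, .scrubbedNt(.UTR_LEN))
      exonW <- c(.UTR_LEN + 90L, nchar(tx) - (.UTR_LEN + 90L))
      intrW <- 400L
      cdsTx <- c(.UTR_LEN + 1L, .UTR_LEN + nchar(cds) - 3L)
      planted <- list(
        list(suffix = "CDS", txStart = cdsTx[1L], txEnd = cdsTx[2L] + 3L,
             category = "RefProt", loc = "CDS"))
      # isoform exon inside the intron, spliced onto a C-terminal part
      # of the parent CDS at a codon boundary (shared stop codon)
      intronStart <- exonW[1L] + 1L                 # locus coords
      exon2Start <- exonW[1L] + intrW + 1L
      if (role == "isoA") {
        i1 <- c(intronStart + 40L, intronStart + 40L + 11L)  # 9 pad + ATG
        i1seq <- paste0(.scrubbedNt(9L), "ATG")
        fromCodon <- 41L
      } else {
        novel <- paste(sample(SENSE_NO_ATG, 74L, replace = TRUE),
                       collapse = "")
        i1seq <- paste0(.scrubbedNt(6L), "ATG", novel)
        i1 <- c(intronStart + 20L, intronStart + 20L + nchar(i1seq) - 1L)
        fromCodon <- 76L
      }
      # locus position of the first base of parent CDS codon `fromCodon`
      # (codon 31 is the first codon of exon 2)
      e2 <- c(exon2Start + 3L * (fromCodon - 31L),
              exon2Start + (nchar(tx) - exonW[1L]) - 1L)
      tx2exons <- rbind(i1, e2)
      tx2seq <- NA_character_  # filled after locus assembly
      orfLen <- 3L * (nchar(i1seq) - (regexpr("ATG", i1seq, fixed = TRUE) - 1L)) # placeholder
      tx2 <- list(exonsLocus = tx2exons, i1seq = i1seq,
                  atgInI1 = as.integer(regexpr("ATG", i1seq, fixed = TRUE)),
                  fromCodon = fromCodon)
    } else if (role == "ncorf") {
      cass <- .orfCassette(40L)            # 126 nt
      tx <- paste0(.scrubbedNt(40L), cass, .scrubbedNt(40L))
      exonW <- c(100L, nchar(tx) - 100L); intrW <- 200L
      cdsTx <- NULL
      planted <- list(
        list(suffix = "ncORF", txStart = 41L, txEnd = 40L + nchar(cass),
             category = "AltProt", loc = "ncRNA"))
    } else if (role == "extref") {
      cds <- .orfCassette(90L)
      tx <- paste0(.scrubbedNt(.UTR_LEN), cds, .scrubbedNt(.UTR_LEN))
      exonW <- c(250L, nchar(tx) - 250L); intrW <- 100L
      cdsTx <- c(.UTR_LEN + 1L, .UTR_LEN + nchar(cds) - 3L)
      planted <- list(
        list(suffix = "CDS", txStart = cdsTx[1L], txEnd = cdsTx[2L] + 3L,
             category = "RefProt", loc = "CDS"))
    } else if (role == "aonly") {
      cds <- .orfCassette(75L)
      tx <- paste0(.scrubbedNt(.UTR_LEN), cds, .scrubbedNt(.UTR_LEN))
      exonW <- nchar(tx); intrW <- integer(0)
      cdsTx <- c(.UTR_LEN + 1L, .UTR_LEN + nchar(cds) - 3L)
      planted <- list(
        list(suffix = "CDS", txStart = cdsTx[1L], txEnd = cdsTx[2L] + 3L,
             category = "RefProt", loc = "CDS"))
    } else stop("unknown gene role: ", role)

    # assemble the locus (sense orientation) from exons and introns
    stopifnot(sum(exonW) == nchar(tx))
    introns <- vapply(intrW, .scrubbedNt, "")
    pieces <- character(0); cur <- 0L
    exonLocus <- matrix(0L, nrow = length(exonW), ncol = 2L)
    locusPos <- 0L
    for (i in seq_along(exonW)) {
      exonLocus[i, ] <- c(locusPos + 1L, locusPos + exonW[i])
      pieces <- c(pieces, substr(tx, cur + 1L, cur + exonW[i]))
      cur <- cur + exonW[i]; locusPos <- locusPos + exonW[i]
      if (i <= length(introns)) {
        pieces <- c(pieces, introns[i])
        locusPos <- locusPos + intrW[i]
      }
    }
    locus <- paste(pieces, collapse = "")

    # splice the isoform exon into the locus and derive its transcript
    if (!is.null(tx2)) {
      el <- tx2$exonsLocus
      substr(locus, el[1L, 1L], el[1L, 2L]) <- tx2$i1seq
      tx2seq <- paste0(substr(locus, el[1L, 1L], el[1L, 2L]),
                       substr(locus, el[2L, 1L], el[2L, 2L]))
      atg <- tx2$atgInI1
      orfEnd <- (el[1L, 2L] - el[1L, 1L] + 1L) +
        3L * (100L - tx2$fromCodon + 1L) + 3L
      tx2 <- list(exonsLocus = el, txSeq = tx2seq,
                  planted = list(list(
                    suffix = if (role == "isoA") "ISO_A" else "ISO_B",
                    txStart = atg, txEnd = orfEnd,
                    category = "Isoform", loc = "ncRNA")))
    }

    # accept only if every transcript's ATG set equals the planted set
    txOk <- function(seq, orfs) {
      identical(.atgPositions(seq),
                sort(vapply(orfs, function(o) o$txStart, 0L)))
    }
    expMain <- planted
    if (!txOk(tx, expMain)) next
    if (!is.null(tx2) && !txOk(tx2$txSeq, tx2$planted)) next

    return(list(geneId = geneId, role = role, strand = strand,
                locus = locus, txSeq = tx, exonLocus = exonLocus,
                cdsTx = if (is.null(cdsTx)) NULL else cdsTx,
                planted = planted, tx2 = tx2))
  }
}

# locus-coordinate intervals (transcript order) -> genomic GRanges
.locusToGenomic <- function(exonLocus, strand, contig, offset, locusLen) {
  if (strand == "+") {
    GRanges(contig, IRanges(offset + exonLocus[, 1L],
                            offset + exonLocus[, 2L]), strand = "+")
  } else {
    GRanges(contig,
            IRanges(offset + locusLen - exonLocus[, 2L] + 1L,
                    offset + locusLen - exonLocus[, 1L] + 1L),
            strand = "-")
  }
}

.gtfAttr <- function(gene, tx)
  sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)

.writeGtf <- function(records, path) {
  lines <- character(0)
  for (r in records) {
    ex <- r$exons[order(BiocGenerics::start(r$exons))]
    for (i in seq_along(ex))
      lines <- c(lines, paste("", "fixture", "exon",
        BiocGenerics::start(ex)[i], BiocGenerics::end(ex)[i], ".",
        r$strand, ".", .gtfAttr(r$gene, r$tx), sep = "\t"))
    if (!is.null(r$cds)) {
      cds <- r$cds[order(BiocGenerics::start(r$cds))]
      for (i in seq_along(cds))
        lines <- c(lines, paste("", "fixture", "CDS",
          BiocGenerics::start(cds)[i], BiocGenerics::end(cds)[i], ".",
          r$strand, "0", .gtfAttr(r$gene, r$tx), sep = "\t"))
    }
    lines <- sub("^\t", paste0(r$contig, "\t"), lines)
  }
  # prefix contigs (sub above only fixes lines of the final record)
  writeLines(lines, path)
  invisible(path)
}

.writeGff3 <- function(records, path) {
  lines <- "##gff-version 3"
  genesSeen <- character(0)
  for (r in records) {
    ex <- r$exons[order(BiocGenerics::start(r$exons))]
    gs <- min(BiocGenerics::start(ex)); ge <- max(BiocGenerics::end(ex))
    if (!r$gene %in% genesSeen) {
      lines <- c(lines, paste(r$contig, "fixture", "gene", gs, ge, ".",
        r$strand, ".", paste0("ID=", r$gene), sep = "\t"))
      genesSeen <- c(genesSeen, r$gene)
    }
    ftype <- if (is.null(r$cds)) "ncRNA" else "mRNA"
    lines <- c(lines, paste(r$contig, "fixture", ftype, gs, ge, ".",
      r$strand, ".", paste0("ID=", r$tx, ";Parent=", r$gene), sep = "\t"))
    for (i in seq_along(ex))
      lines <- c(lines, paste(r$contig, "fixture", "exon",
        BiocGenerics::start(ex)[i], BiocGenerics::end(ex)[i], ".",
        r$strand, ".", paste0("Parent=", r$tx), sep = "\t"))
    if (!is.null(r$cds)) {
      cds <- r$cds  # transcript order: phase accumulates 5'->3'
      cum <- 0L
      phases <- integer(length(cds))
      for (i in seq_along(cds)) {
        phases[i] <- (3L - (cum %% 3L)) %% 3L
        cum <- cum + BiocGenerics::width(cds)[i]
      }
      o <- order(BiocGenerics::start(cds))
      for (i in o)
        lines <- c(lines, paste(r$contig, "fixture", "CDS",
          BiocGenerics::start(cds)[i], BiocGenerics::end(cds)[i], ".",
          r$strand, phases[i],
          paste0("ID=cds_", r$tx, ";Parent=", r$tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.writeFastaChar <- function(seqs, path, aa = TRUE) {
  x <- if (aa) AAStringSet(seqs) else DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Generate a synthetic locus set with planted ground truth
#'
#' Produces every input the annotation pipeline consumes: a toy genome,
#' the same loci described in two annotation dialects (GTF and GFF3,
#' with different transcript identifiers), reference protein FASTA
#' files per source plus an external (curated-style) set, and a truth
#' table listing every planted ORF with its expected category and
#' localization.
#'
#' Gene roles cycle through: a gene with a 5'UTR uORF; a minus-strand
#' gene with a 3'UTR ORF; a gene with a CDS-overlapping ORF in a
#' shifted frame; a gene with a planted truncation isoform (satisfying
#' the identity/coverage argument of the similarity filter); a gene
#' with a planted anchored isoform (shared stop codon, similarity only
#' over its C-terminal quarter); an ncRNA gene with an ORF; an mRNA
#' whose protein is present only in the external protein set; and a
#' minus-strand single-exon gene present in only one annotation.
#' Transcripts carry an ATG only at planted ORF starts, so the
#' enumerated catalog equals the truth table exactly.
#'
#' @param seed integer seed; output is byte-identical across runs for a
#'   fixed seed.
#' @param outDir directory to write files into (created if needed).
#' @param nGenes number of genes (default 8, one per role).
#' @return a list with \code{paths} (genome, annotA, annotB, knownA,
#'   knownB, external), \code{truth} (data.frame: orf_id, gene,
#'   category, localization, protein, block_key, n_tx) and
#'   \code{sharedStructural} (expected number of cross-source
#'   structurally identical transcript pairs).
#' @export
generateLocusSet <- function(seed, outDir = tempfile("locusset"),
                             nGenes = 8L) {
  set.seed(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  roles <- c("uorf", "utr3orf", "cdsalt", "isoA", "isoB", "ncorf",
             "extref", "aonly")
  shared <- new.env()
  genes <- lapply(seq_len(nGenes), function(i)
    .buildGene(roles[(i - 1L) %% length(roles) + 1L],
               sprintf("G%02d", i), shared))

  contigs <- list()
  cursor <- list()
  truthRows <- list()
  recA <- list(); recB <- list()
  protA <- character(); protB <- character(); protX <- character()

  for (g in genes) {
    contig <- paste0("chr", c("I", "II")[((match(g$geneId,
      vapply(genes, `[[`, "", "geneId")) - 1L) %/% 4L) %% 2L + 1L])
    if (is.null(contigs[[contig]])) { contigs[[contig]] <- ""; cursor[[contig]] <- 0L }
    gap <- .randNt(300L)
    offset <- cursor[[contig]] + 300L
    Lg <- nchar(g$locus)
    seg <- if (g$strand == "+") g$locus else
      as.character(Biostrings::reverseComplement(DNAString(g$locus)))
    contigs[[contig]] <- paste0(contigs[[contig]], gap, seg)
    cursor[[contig]] <- offset + Lg

    exGR <- .locusToGenomic(g$exonLocus, g$strand, contig, offset, Lg)
    cdsGR <- if (!is.null(g$cdsTx))
      txToGenome(exGR, g$cdsTx[1L], g$cdsTx[2L]) else NULL
    # GFF3 CDS features include the stop codon; GTF features exclude it
    cdsGRB <- if (!is.null(g$cdsTx))
      txToGenome(exGR, g$cdsTx[1L], g$cdsTx[2L] + 3L) else NULL
    prot <- if (!is.null(g$cdsTx))
      .translateDna(substr(g$txSeq, g$cdsTx[1L], g$cdsTx[2L] + 3L)) else NULL

    txA <- paste0("A_", g$geneId, "T1")
    txB <- paste0("B_", g$geneId, "T1")
    if (g$role != "aonly") {
      recB[[length(recB) + 1L]] <- list(contig = contig, gene = g$geneId,
        tx = txB, strand = g$strand, exons = exGR, cds = cdsGRB)
    }
    recA[[length(recA) + 1L]] <- list(contig = contig, gene = g$geneId,
      tx = txA, strand = g$strand, exons = exGR, cds = cdsGR)

    if (!is.null(prot)) {
      if (g$role == "extref") {
        protX[paste0("SP_", g$geneId)] <- prot
      } else if (g$role == "aonly") {
        protA[paste0("REFA_", g$geneId)] <- prot
      } else {
        protA[paste0("REFA_", g$geneId)] <- prot
        protB[paste0("REFB_", g$geneId)] <- prot
      }
    }

    for (o in g$planted) {
      blocks <- txToGenome(exGR, o$txStart, o$txEnd)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        orf_id = paste0(g$geneId, "_", o$suffix), gene = g$geneId,
        category = o$category, localization = o$loc,
        protein = .translateDna(substr(g$txSeq, o$txStart, o$txEnd)),
        block_key = encodeBlocks(blocks),
        n_tx = if (g$role == "aonly") 1L else 2L,
        stringsAsFactors = FALSE)
    }

    if (!is.null(g$tx2)) {
      ex2GR <- .locusToGenomic(g$tx2$exonsLocus, g$strand, contig, offset, Lg)
      tx2id <- paste0("B_", g$geneId, "T2")
      recB[[length(recB) + 1L]] <- list(contig = contig, gene = g$geneId,
        tx = tx2id, strand = g$strand, exons = ex2GR, cds = NULL)
      for (o in g$tx2$planted) {
        blocks <- txToGenome(ex2GR, o$txStart, o$txEnd)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          orf_id = paste0(g$geneId, "_", o$suffix), gene = g$geneId,
          category = o$category, localization = o$loc,
          protein = .translateDna(substr(g$tx2$txSeq, o$txStart, o$txEnd)),
          block_key = encodeBlocks(blocks), n_tx = 1L,
          stringsAsFactors = FALSE)
      }
    }
  }

  # two decoy proteins present only in the external set
  protX["SP_DECOY1"] <- paste(sample(AA20, 100L, TRUE), collapse = "")
  protX["SP_DECOY2"] <- paste(sample(AA20, 120L, TRUE), collapse = "")

  paths <- list(genome = file.path(outDir, "genome.fa"),
                annotA = file.path(outDir, "annotA.gtf"),
                annotB = file.path(outDir, "annotB.gff3"),
                knownA = file.path(outDir, "knownA.fa"),
                knownB = file.path(outDir, "knownB.fa"),
                external = file.path(outDir, "external.fa"),
                truth = file.path(outDir, "truth.tsv"))
  .writeFastaChar(unlist(contigs), paths$genome, aa = FALSE)
  .writeGtf(recA, paths$annotA)
  .writeGff3(recB, paths$annotB)
  .writeFastaChar(protA, paths$knownA)
  .writeFastaChar(protB, paths$knownB)
  .writeFastaChar(protX, paths$external)
  truth <- do.call(rbind, truthRows)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nShared <- sum(vapply(genes, function(g) g$role != "aonly", TRUE))
  list(paths = paths, truth = truth, sharedStructural = nShared)
}

# mutate a protein at an exact number of positions (substitutions only)
.mutateProtein <- function(seq, divergence) {
  aa <- strsplit(seq, "")[[1L]]
  nMut <- round(divergence * length(aa))
  if (nMut > 0L) {
    pos <- sample(length(aa), nMut)
    for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  }
  paste(aa, collapse = "")
}

#' Generate synthetic proteomes with planted orthology
#'
#' A common ancestor set of random proteins is point-mutated
#' independently per species at the given divergence. One duplication
#' is planted in species 2 (a near-identical extra copy of its first
#' protein, expected to join the first ortholog group as an inparalog,
#' making it one-to-many from species 1). When at least three species
#' are requested, ancestor 2 is dropped from species 3, lowering that
#' protein's conservation score by one. Random decoy proteins that
#' should join no group are appended to species 1 and 2.
#'
#' @param seed integer seed.
#' @param nSpecies number of species (>= 2).
#' @param divergence per-residue substitution fraction, recycled across
#'   species (default 0.1).
#' @param nAncestors ancestor proteins (default 6).
#' @param lengthRange ancestor protein length range (default 100-160).
#' @param nDecoys total decoy proteins (default 50, split between
#'   species 1 and 2).
#' @return a list: \code{proteomes} (named list of named character
#'   vectors, ids \code{S<i>_P<k>}), \code{genes} (per species, protein
#'   id -> gene), \code{truth} (data.frame: ancestor, seed_a, seed_b
#'   per species pair from species 1's viewpoint, relationship),
#'   \code{expectedConservation} (named integer vector for species 1
#'   proteins).
#' @export
generateProteomes <- function(seed, nSpecies = 3L, divergence = 0.1,
                              nAncestors = 6L, lengthRange = c(100L, 160L),
                              nDecoys = 50L) {
  set.seed(seed)
  stopifnot(nSpecies >= 2L)
  divergence <- rep_len(divergence, nSpecies)
  anc <- vapply(seq_len(nAncestors), function(i)
    paste(sample(AA20, sample(lengthRange[1L]:lengthRange[2L], 1L), TRUE),
          collapse = ""), "")
  proteomes <- list(); genes <- list()
  for (s in seq_len(nSpecies)) {
    keep <- seq_len(nAncestors)
    if (s == 3L) keep <- setdiff(keep, 2L)  # ancestor 2 lost in species 3
    ids <- sprintf("S%d_P%d", s, keep)
    prots <- setNames(vapply(anc[keep], .mutateProtein, "",
                             divergence = divergence[s]), ids)
    gn <- setNames(sprintf("g%d", keep), ids)
    if (s == 2L) {  # planted duplication: extra near-copy, its own gene
      dup <- .mutateProtein(prots[["S2_P1"]], 0.02)
      prots <- c(prots, S2_P1dup = dup)
      gn <- c(gn, S2_P1dup = "g1dup")
    }
    nd <- if (s <= 2L) nDecoys %/% 2L else 0L
    if (nd > 0L) {
      dids <- sprintf("S%d_D%d", s, seq_len(nd))
      decs <- setNames(vapply(seq_len(nd), function(i)
        paste(sample(AA20, 80L, TRUE), collapse = ""), ""), dids)
      prots <- c(prots, decs)
      gn <- c(gn, setNames(paste0("dg", seq_len(nd)), dids))
    }
    proteomes[[sprintf("S%d", s)]] <- prots
    genes[[sprintf("S%d", s)]] <- gn
  }
  truth <- do.call(rbind, lapply(2:nSpecies, function(s) {
    keep <- seq_len(nAncestors)
    if (s == 3L) keep <- setdiff(keep, 2L)
    # b-side group membership (seed or inparalog, order irrelevant)
    membersB <- sprintf("S%d_P%d", s, keep)
    if (s == 2L) membersB[keep == 1L] <- "S2_P1;S2_P1dup"
    data.frame(species = sprintf("S%d", s), ancestor = keep,
               seed_a = sprintf("S1_P%d", keep),
               members_b = membersB,
               relationship = ifelse(s == 2L & keep == 1L,
                                     "one-to-many", "one-to-one"),
               stringsAsFactors = FALSE)
  }))
  expCons <- vapply(seq_len(nAncestors), function(k)
    sum(vapply(2:nSpecies, function(s) !(s == 3L && k == 2L), TRUE)), 0L)
  names(expCons) <- sprintf("S1_P%d", seq_len(nAncestors))
  list(proteomes = proteomes, genes = genes, truth = truth,
       expectedConservation = expCons)
}

# first substring window of `prot` (length w) occurring in exactly
# `target` of `corpus`; scans deterministically left to right
.pickPeptide <- function(prot, corpus, w = 10L, target = 1L,
                         from = 2L) {
  for (s in from:(nchar(prot) - w + 1L)) {
    pep <- substr(prot, s, s + w - 1L)
    hits <- sum(vapply(corpus, function(p)
      grepl(pep, p, fixed = TRUE), TRUE))
    if (hits == target) return(pep)
  }
  stop("no peptide window with required multiplicity")
}

#' Generate MS and Ribo-seq evidence tables for a fixture catalog
#'
#' Samples peptides from the planted proteins of a [generateLocusSet()]
#' truth table -- including a peptide shared between a RefProt and its
#' isoform (expected RefProt-only assignment), two unique peptides for
#' the uORF protein across two pseudo-studies (expected tier "high"),
#' an ambiguous peptide shared by two novel proteins (assigned to
#' none), and a unique peptide for the ncRNA ORF -- and Ribo-seq
#' detections across two pseudo-studies with p-values straddling the
#' detection cutoff. Expected MS/TE scores are derived from the
#' planting design, not from running the assignment.
#'
#' @param seed integer seed.
#' @param truth truth table from [generateLocusSet()].
#' @param outDir output directory.
#' @return list with \code{paths} (peptides, riboseq) and
#'   \code{expected} (data.frame: orf_id, ms_score, te_score,
#'   unique_peptides, tier).
#' @export
generateEvidenceTables <- function(seed, truth, outDir = tempfile("evid")) {
  set.seed(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  corpus <- truth$protein
  row1 <- function(suffix) {
    i <- grep(paste0("_", suffix, "$"), truth$orf_id)
    if (length(i)) truth[i[1L], ] else NULL
  }
  uorf <- row1("uORF"); u3 <- row1("u3ORF"); nc <- row1("ncORF")
  isoA <- row1("ISO_A")
  pep <- list(); exp <- list()
  addPep <- function(study, p, psm) pep[[length(pep) + 1L]] <<- data.frame(
    study_id = study, peptide = p, psm_count = psm, fdr = 1e-5,
    stringsAsFactors = FALSE)

  refRow <- truth[truth$category == "RefProt", ][1L, ]
  addPep("MS1", .pickPeptide(refRow$protein, corpus, 12L, 1L, from = 10L), 3L)
  exp[[length(exp) + 1L]] <- data.frame(orf_id = refRow$orf_id, ms_score = 1L,
    te_score = 0L, unique_peptides = 1L, tier = "supported",
    stringsAsFactors = FALSE)

  if (!is.null(uorf)) {
    p1 <- .pickPeptide(uorf$protein, corpus, 10L, 1L, from = 17L)
    p2 <- .pickPeptide(uorf$protein, corpus, 10L, 1L, from = 20L)
    stopifnot(p1 != p2)
    addPep("MS1", p1, 2L); addPep("MS2", p2, 1L)
    if (!is.null(u3)) # the planted shared 10-mer: residues 6..15 of both
      addPep("MS1", substr(uorf$protein, 6L, 15L), 1L)
    exp[[length(exp) + 1L]] <- data.frame(orf_id = uorf$orf_id,
      ms_score = 2L, te_score = 2L, unique_peptides = 2L, tier = "high",
      stringsAsFactors = FALSE)
    if (!is.null(u3))
      exp[[length(exp) + 1L]] <- data.frame(orf_id = u3$orf_id,
        ms_score = 0L, te_score = 0L, unique_peptides = 0L,
        tier = "predicted", stringsAsFactors = FALSE)
  }
  if (!is.null(isoA)) {
    # peptide from the truncation isoform's shared C-terminal region:
    # occurs in the isoform AND its parent RefProt -> RefProt only
    sharedPep <- .pickPeptide(isoA$protein, corpus, 12L, 2L,
                              from = nchar(isoA$protein) - 30L)
    addPep("MS1", sharedPep, 2L)
    parent <- truth[truth$gene == isoA$gene & truth$category == "RefProt", ]
    exp[[length(exp) + 1L]] <- data.frame(orf_id = isoA$orf_id,
      ms_score = 0L, te_score = 0L, unique_peptides = 0L,
      tier = "predicted", stringsAsFactors = FALSE)
    if (nrow(parent) && parent$orf_id[1L] != refRow$orf_id)
      exp[[length(exp) + 1L]] <- data.frame(orf_id = parent$orf_id[1L],
        ms_score = 1L, te_score = 0L, unique_peptides = 1L,
        tier = "supported", stringsAsFactors = FALSE)
  }
  if (!is.null(nc)) {
    addPep("MS2", .pickPeptide(nc$protein, corpus, 10L, 1L, from = 5L), 4L)
    exp[[length(exp) + 1L]] <- data.frame(orf_id = nc$orf_id, ms_score = 1L,
      te_score = 1L, unique_peptides = 1L, tier = "supported",
      stringsAsFactors = FALSE)
  }

  # Ribo-seq detections keyed by genomic blocks
  splitKey <- function(key) {
    p <- strsplit(key, ":", fixed = TRUE)[[1L]]
    list(contig = p[1L], strand = p[2L], blocks = p[3L])
  }
  det <- list()
  addDet <- function(study, key, pval, rc) {
    k <- splitKey(key)
    det[[length(det) + 1L]] <<- data.frame(study_id = study,
      contig = k$contig, strand = k$strand, blocks = k$blocks,
      p_value = pval, readcount = rc, stringsAsFactors = FALSE)
  }
  alt <- row1("altORF")
  if (!is.null(uorf)) { addDet("RS1", uorf$block_key, 0.001, 120L)
                        addDet("RS2", uorf$block_key, 0.005, 80L) }
  if (!is.null(alt)) {
    addDet("RS1", alt$block_key, 0.5, 15L)    # fails the 0.01 cutoff
    addDet("RS2", alt$block_key, 0.002, 60L)
    exp[[length(exp) + 1L]] <- data.frame(orf_id = alt$orf_id, ms_score = 0L,
      te_score = 1L, unique_peptides = 0L, tier = "supported",
      stringsAsFactors = FALSE)
  }
  if (!is.null(nc)) { addDet("RS1", nc$block_key, 0.004, 40L)
                      addDet("RS1", nc$block_key, 0.008, 35L) }

  paths <- list(peptides = file.path(outDir, "peptides.tsv"),
                riboseq = file.path(outDir, "riboseq.tsv"))
  utils::write.table(do.call(rbind, pep), paths$peptides, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, det), paths$riboseq, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths, expected = do.call(rbind, exp))
}
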