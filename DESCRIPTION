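Package: Orfeome
Title: Polycistronic ORF Annotation with Isoform Classification and
    Evidence Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enumerates every ATG-initiated open reading frame of at least
    30 codons in all three frames of every transcript of a merged
    transcript annotation, under a polycistronic model that allows several
    ORFs per transcript. Predicted products are partitioned into known
    reference proteins, novel isoforms of known coding sequences, and
    novel alternative proteins using an exact-match filter against
    reference protein sets followed by a two-argument sequence-similarity
    filter. Each protein is annotated with translation-initiation context
    motifs (simplified Kozak and high-efficiency initiation motifs),
    molecular weight and isoelectric point, and its localization within
    the transcript (5'UTR, CDS, 3'UTR or ncRNA). Cross-species orthologs
    and within-species paralogs are inferred with a reciprocal-best-hit
    approach gated by a bit-score and query-coverage filter, yielding a
    per-protein conservation score. Externally produced mass-spectrometry
    peptide tables and ribosome-profiling detection tables are ingested
    and summarized into unique-peptide MS scores and per-study translation
    scores. Catalogs are exported as TSV, BED12 and FASTA. A deterministic
    synthetic-data generator produces toy genomes, paired annotation
    dialects, reference proteomes and evidence tables with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: SequenceAnnotation, Proteomics, RiboSeq, Alignment, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
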