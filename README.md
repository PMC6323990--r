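# Orfeome

Polycistronic ORF annotation for eukaryotic transcriptomes: enumerate
every ATG-initiated open reading frame, classify the hidden proteome,
and score it with conservation, translation and mass-spectrometry
evidence.

## What it does and for whom

Conventional annotations allow one coding sequence (CDS) per
transcript, hiding the many additional proteins translated from
upstream ORFs, 3'UTR ORFs, overlapping reading frames and "non-coding"
RNAs. `Orfeome` is for proteogenomics researchers who want a complete,
reproducible catalog of this coding potential:

1. **Prediction** — two source annotations (GTF and GFF3 dialects) are
   merged into one exhaustive transcriptome; every transcript is
   translated *in silico* in three frames; every ATG-initiated ORF with
   ≥ 30 codons (protein ≥ 30 aa, stop excluded) becomes a candidate.
2. **Classification** — products exactly matching a known protein set
   are **RefProts**; unannotated products similar to a same-gene
   RefProt are **novel isoforms** (`II_` accessions); the rest are
   **alternative proteins** (`IP_` accessions), so that
   `AltProts = ORFeome − RefProts − Isoforms` exactly. The similarity
   filter has two arguments: (a) ≥ 80 % identity over ≥ 50 % of the
   candidate length (Smith–Waterman local alignment), or (b) an
   identical genomic start- or stop-codon coordinate plus a stringent
   PAM-matrix local alignment scoring ≥ 100 over ≥ 20 % of the
   candidate length.
3. **Annotation** — localization within the transcript (5'UTR / CDS /
   3'UTR / ncRNA), simplified Kozak context `RNNATGG`, high-efficiency
   initiation motif `RYMRMVAUGGC`, length, molecular weight and
   isoelectric point.
4. **Evidence** — reciprocal-best-hit orthology with a significance
   filter at bit score ≥ 40 over ≥ 50 % query coverage, giving a
   conservation score (number of species with an ortholog); ingestion
   of external Ribo-seq detection tables (TE score = number of
   detecting studies) and MS peptide tables with uniqueness-aware
   assignment under strict RefProt priority (MS score = sum of unique
   peptides per study).

Catalogs are exported as TSV, BED12 and FASTA (protein or DNA). A
deterministic synthetic-data generator (`generateLocusSet()`,
`generateProteomes()`, `generateEvidenceTables()`) produces every input
with planted ground truth, and is the basis of the validation suite.

## Worked example

```r
library(Orfeome)

fx <- generateLocusSet(7, "fixture")          # toy genome + annotations
catalog <- runBuild(fx$paths$genome,
  annotations = list(
    list(path = fx$paths$annotA, dialect = "gtf",  tag = "annotA"),
    list(path = fx$paths$annotB, dialect = "gff3", tag = "annotB")),
  knownProteins = list(
    list(path = fx$paths$knownA,   source = "annotA"),
    list(path = fx$paths$knownB,   source = "annotB"),
    list(path = fx$paths$external, source = "external")),
  outDir = "out")
#> parsed 8 transcript(s), 7 mRNA, from fixture/annotA.gtf
#> parsed 9 transcript(s), 6 mRNA, from fixture/annotB.gff3
#> enumerated 23 ORF candidate(s) on 17 transcript(s)
#> classified catalog: Total 13 / Ref 7 / II_ 2 / IP_ 4

ev <- generateEvidenceTables(7, fx$truth, "evidence")
catalog <- runEvidence(catalog, ev$paths$peptides, ev$paths$riboseq, "out")
read.delim("out/catalog.tsv")[, c(1, 2, 6, 7, 13, 14, 15)]
```

```
 accession category localization length_aa ms_score te_score      tier
 II_000001  Isoform        ncRNA        61        0        0 predicted
 II_000002  Isoform        ncRNA       100        0        0 predicted
 IP_000001  AltProt         5UTR        30        2        2      high
 IP_000002  AltProt         3UTR        32        0        0 predicted
 IP_000003  AltProt          CDS        34        0        1 supported
 IP_000004  AltProt        ncRNA        40        1        1 supported
  REFA_G01  RefProt          CDS        80        1        0 supported
  ...
    SP_G07  RefProt          CDS        90        0        0 predicted
```

Reading the output: the 17 merged transcripts yield 23 ORF candidates
that deduplicate into 13 protein entries — 7 known proteins (RefProts,
one of them matched only in the external protein set, hence the
`SP_` accession), 2 novel isoforms of known CDSs and 4 alternative
proteins. `IP_000001` is a 30-aa upstream-ORF product located in a
5'UTR: two unique peptides across two MS studies (MS score 2) and
detections in two Ribo-seq studies (TE score 2) put it in the `high`
confidence tier, the two-unique-peptide criterion for a confidently
detected novel protein. `IP_000003` overlaps a CDS in a shifted reading
frame and is supported by one Ribo-seq study only.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/orfannot.R` (subcommands `build`, `evidence`,
`fixtures`).

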