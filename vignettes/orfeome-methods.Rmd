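---
title: "Polycistronic ORF annotation: models, parameters and design choices"
author: "Orfeome maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polycistronic ORF annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Orfeome)
```

## The problem

Standard genome annotations enforce one coding sequence (CDS) per
transcript. A growing body of proteomics and ribosome-profiling evidence
shows that eukaryotic transcripts are frequently polycistronic: they
carry additional translated open reading frames (ORFs) in 5' and 3'
untranslated regions, in alternative reading frames overlapping the
annotated CDS, and on transcripts annotated as non-coding. `Orfeome`
annotates this hidden proteome. It enumerates every ATG-initiated ORF of
at least 30 codons in all three frames of every transcript of a merged
annotation, classifies the predicted products, annotates their
properties, and aggregates cross-species conservation,
ribosome-profiling and mass-spectrometry evidence into per-protein
scores.

## Transcriptome assembly

Two source annotations (a GTF-style and a GFF3-style dialect, e.g. a
RefSeq-like and an Ensembl-like release) are parsed into transcript
models and merged into one exhaustive transcriptome. Each transcript
keeps its source tag so downstream users can restrict results to either
source. Since the two dialects disagree on identifiers, "the same
transcript" is defined structurally: identical contig, strand and exact
exon boundary chain. This is the only dialect-neutral criterion; we make
no claim that it reproduces any particular external count of shared
transcripts.

Genes are reconciled across sources by name where names are shared, and
by same-strand genomic overlap otherwise (a union-find over both
relations). The classification filter below needs this reconciled
"same gene" notion, because a novel product must be compared with the
reference proteins *of its own gene*.

Internally all ranges are `GRanges`/`IRanges` (1-based, closed), the
single convention of the Bioconductor ecosystem; GTF/GFF3 and BED
conventions are converted at the file boundary only. Annotated CDS
intervals are stored in transcript coordinates without the stop codon
(GTF files already exclude it; GFF3 CDS features include it and are
trimmed by 3 nt on ingest, with a warning if the first CDS segment's
phase is non-zero). For localization purposes the "CDS region" includes
the stop codon, so a 3'UTR starts immediately after it.

## ORF enumeration

For every transcript the spliced sequence is scanned in three frames.
An ORF starts at an ATG, ends at the first in-frame stop (TAA, TAG,
TGA) and must encode at least `minCodons = 30` amino acids; the stop
codon is not counted, so the boundary case is a 30-aa product.
Transcripts may contain undefined bases: codons containing N translate
to X and never terminate an ORF — only exact stop codons do. ORFs
running off the 3' end without a stop are excluded by default (their
product is undefined); `includeStopless = TRUE` reports them with
`has_stop = FALSE`.

Two enumeration modes are provided because "all possible ORFs" is
ambiguous when several ATGs share one stop. The default
`longest_per_stop` reports the 5'-most qualifying ATG per (frame, stop)
pair, matching how CDSs are conventionally enumerated and keeping the
catalog non-redundant; `all_starts` reports every qualifying ATG. The
test suite checks `all_starts` against a brute-force scan over every
(position, frame) pair on 200 seeded random transcripts.

Candidates are mapped to genomic blocks (maximal genomically contiguous
runs in transcript order), and products are deduplicated on the pair
(protein sequence, genomic blocks): the same product encoded by three
splice isoforms at one locus is one entry with three transcript
associations, while an identical peptide encoded at two loci stays two
entries. Accessions are assigned in a deterministic order — contig,
genomic start, strand, protein sequence — so reruns are reproducible.

## Classification

The catalog is partitioned into three exclusive categories:

* **RefProt** — the protein exactly matches (full length) a record of
  the known-protein index, built from the protein sets of both source
  annotations plus an optional external curated set. When several
  sources match, the accession follows a fixed priority (first
  annotation > second annotation > external).
* **Isoform (II_ accessions)** — an unannotated product similar to a
  reference protein of the same reconciled gene, by either argument of
  the similarity filter below.
* **AltProt (IP_ accessions)** — everything else, so the subtraction
  identity `|AltProt| = |total| − |RefProt| − |Isoform|` holds exactly.

The similarity filter has two arguments, evaluated against each
same-gene RefProt:

* **Argument A**: a Smith–Waterman local alignment (match +5, mismatch
  −4, gap open 10, extend 0.5) shows ≥ 80 % identity over an aligned
  span covering ≥ 50 % of the candidate's length.
* **Argument B**: the candidate shares the exact genomic coordinate of
  the start codon's first base or the stop codon's last base with the
  RefProt (same contig and strand), and a local alignment under a
  stringent short-diagonal PAM matrix scores ≥ 100 over ≥ 20 % of the
  candidate's length.

Three genuinely open choices were fixed as follows. First, the span
thresholds are measured against the *candidate's* length: a short novel
product must remain classifiable against a long reference protein.
Second, the stringent-matrix score threshold is applied as a *minimum*:
a maximum-score ceiling would label dissimilar sequences isoforms,
contradicting the filter's purpose; `scoreBDirection = "max"` restores
the ceiling reading for anyone wanting it. Third, PAM30 is used as the
stringent matrix — the shortest-diagonal PAM matrix shipped with
Biostrings — with the matrix name exposed as a parameter. External
curated proteins without transcript coordinates participate only in
exact RefProt matching, not in same-gene comparisons, unless a gene
mapping is supplied.

## Protein features

Each entry is annotated with length, average molecular mass (sum of
average residue masses plus one water; monoisotopic masses via a flag),
isoelectric point, and two initiation-context motifs. The pI is the
unique zero of the Henderson–Hasselbalch net-charge curve over the
N-terminus, C-terminus and D/E/C/Y/H/K/R side chains, found by bisection
on [0, 14] to 0.001 pH units; the pKa set is the common EMBOSS-style
default (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
R 12.5, Y 10.1) and is replaceable. No numeric parity with any external
web resource is claimed, since those resources do not publish their
tables.

The motifs are IUPAC-degenerate windows anchored on the initiator ATG:
the simplified Kozak motif `RNNATGG` (3 nt upstream, 1 downstream) and
the high-efficiency initiation motif `RYMRMVAUGGC` (6 upstream, 2
downstream; U ≡ T). A window truncated by a transcript end scores
`FALSE` rather than partially matching. A product shared by several
transcripts is flagged when the motif matches on *any* associated
transcript. Both matchers are validated against a brute-force IUPAC
regex oracle, exhaustively for all 4^7 Kozak windows.

## Orthology and conservation

Homology uses local alignment (BLOSUM62, gap open 11 / extend 1) with
Karlin–Altschul bit scores, bits = (λS − ln K)/ln 2 with the standard
gapped values λ = 0.267, K = 0.041. A directed comparison is
significant at ≥ 40 bits with the aligned span covering ≥ 50 % of the
query. Ortholog groups are seeded by reciprocal best hits between two
species (ties broken lexicographically); same-species sequences scoring
at least their seed member's seed score join as inparalogs, giving the
one-to-one / one-to-many / many-to-one / many-to-many relationships.
This is a reciprocal-best-hit approximation of the InParanoid family of
methods; bootstrap confidence values are omitted. Paralogs are
significant within-species pairs excluding same-gene comparisons. The
conservation score of a protein is the number of species with at least
one ortholog group containing it — several groups in one species still
count once. No acceleration heuristics are used; the implementation
targets desk-scale proteomes.

## Evidence ingestion and scores

The package consumes tables produced by external MS search pipelines
and ribosome-profiling ORF detectors; it performs no spectrum or read
processing, and upstream FDR filtering is assumed already applied.
Peptides map to proteins by exact substring (I and L distinguished by
default, a flag equates them). Assignment is uniqueness-aware with
strict RefProt priority: a peptide matching any RefProt is assigned
only to the matching RefProt(s); a peptide matching no RefProt and
exactly one novel entry is that entry's unique peptide; a peptide
matching several novel entries is ambiguous and assigned to none — a
strict reading of "unique". The MS score is the sum over studies of the
study's distinct unique peptides for the protein (a per-study-maximum
reading is possible but the summation reading is implemented). The TE
score is the number of distinct studies with at least one detection of
the ORF (matched by exact genomic blocks or accession) passing the
p-value cutoff, default 0.01. Confidence tiers: `high` = novel entry
with ≥ 2 cumulative unique peptides; `supported` = any MS, translation
or conservation evidence; `predicted` = none.

## The synthetic-data generator

`generateLocusSet()` emulates every pipeline input at desk scale: a toy
genome (two contigs, multi-exon genes on both strands), the same loci
written in both annotation dialects with different identifiers,
reference protein FASTA files per source plus an external-only set, and
a truth table. Eight gene roles plant one instance each of: a 5'UTR
uORF (with a favourable Kozak context), a minus-strand 3'UTR ORF, a
CDS-overlapping ORF in a shifted frame, a truncation isoform spliced
from an intron-resident ATG exon onto the C-terminal 60 % of its
parent's CDS (satisfying argument A), an anchored isoform sharing only
its C-terminal quarter and the stop codon (satisfying argument B and
not A), an ncRNA ORF spanning a splice junction, an mRNA whose protein
exists only in the external set, and a single-annotation gene. The
default sizes (CDS 70–120 codons, UTRs 110 nt, introns 100–400 nt) are
chosen once as representative of compact eukaryotic gene models and
small enough that the full suite runs in seconds.

The planting is exact by construction: rejection sampling removes every
ATG that is not a planted ORF start, including ATGs formed across codon
or splice junctions, so the enumerated catalog equals the truth table
in both enumeration modes. This exactness is what the recovery tests
rely on; the price is that fixture transcripts are unrealistic in one
respect (no internal methionines, no near-threshold decoy ORFs). What
passing tests show is therefore that the machinery is correct on
planted ground truth, not that category proportions on real genomes are
reproduced — those depend on annotation releases and are out of scope.
Other idealizations: no sequencing errors or soft-masked repeats, clean
single-gene loci, and evidence tables with known assignment outcomes
(including a deliberately shared RefProt/isoform peptide and a
deliberately ambiguous two-AltProt peptide).

`generateProteomes()` mutates a common ancestor set per species at a
configurable divergence (default 10 % per residue), plants one
duplication (an expected one-to-many group), drops one ancestor from
the third species (an expected conservation deficit), and appends 50
random decoys that must join no group. `generateEvidenceTables()`
derives its expected MS/TE scores from the planting design, not by
running the assignment code, keeping truth independent of the code
under test.

## Numerical and degenerate-input choices

* Alignment raw scores ≤ 0 are reported as "no alignment" with zero
  coverage and identity.
* The bisection for pI relies on the strict monotonicity of the charge
  curve; the root is unique, so no restarts are needed.
* Reciprocal-best-hit ties are broken lexicographically on subject
  identifier, making group seeds deterministic.
* Empty inputs (no transcripts, empty proteomes, empty evidence
  tables, empty catalogs) yield structurally valid empty outputs, not
  errors; missing files fail loudly before any work is done.
* Duplicate contig identifiers, mixed-strand transcripts and
  non-amino-acid reference records are hard errors; unknown-parent
  GFF3 exons and non-multiple-of-3 CDSs degrade with warnings.

## Problem sizes used in the validation suite

The test and acceptance runs use the 8-gene seed-7 locus set
(~13 planted ORFs, genome ~8 kb), 200 random transcripts of
300–3,000 nt for the enumeration oracle, 50 random pairs of ≤ 60-aa
proteins for the alignment oracle, exhaustive 4^7 Kozak windows plus
10,000 random 11-mers for the motif oracle, and 3-species proteomes of
6 ancestors with 50 decoys for orthology. These sizes were chosen as
the smallest at which every code path (multi-exon, both strands, both
dialects, every category and every evidence rule) is exercised.

## Known limitations

* Non-ATG initiation and ORFs shorter than 30 codons are deliberately
  excluded (both configurable only down to the enumeration threshold).
* Functional-domain, GO and pathway prediction are out of scope; the
  TSV export reserves an empty `domains` column.
* Ortholog inference is quadratic all-vs-all local alignment; it is
  not intended for full mammalian proteomes.
* Classification thresholds (80 %/50 %, score 100/20 %, 40 bits/50 %)
  are exposed as parameters but their defaults are fixed conventions of
  the method, not fitted values; sensitivity to them is not analysed
  here.
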