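---
title: "ribostar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribostar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostar)
```

This vignette explains the models and conventions behind each analysis
step, the parameters that matter, and the choices made where more than one
reasonable design existed. The companion README shows the worked example;
here we focus on *why* the package behaves as it does.

## Coordinate model

Everything internal is **0-based half-open**, on both genome and
transcript. GTF input (1-based inclusive) is converted on read; BED input
is native. Transcript coordinates always run 5'→3' regardless of genomic
strand, so ORF scanning, P-site arithmetic and quantification never branch
on strand: strand is resolved once, inside `genome_to_transcript()` /
`transcript_to_genome()`, which are exact inverses on every exonic base
(verified exhaustively in the tests on random multi-exon models of both
strands).

A transcript's annotated ORF (aORF) is taken from **its own CDS
annotation**, per isoform, never a gene-level consensus: ORF categories are
positional relationships on one transcript. The stored aORF interval always
*includes* the stop codon. Because Gencode-style GTFs exclude the stop from
CDS records, the default `gencode` dialect appends `stop_codon` features to
the CDS span; the `generic` dialect takes CDS rows as-is. A CDS whose
spliced length is not a positive multiple of 3 cannot be a codon-exact
aORF; the transcript is kept but its CDS is dropped with a warning, leaving
it eligible only for `unannotated` ORFs.

## ORF enumeration and the seven categories

An ORF is any AUG paired with the *nearest* downstream in-frame stop codon;
AUGs with no in-frame stop before the transcript end emit nothing, since an
open-ended interval is not a complete ORF. The scanner is a per-frame
linear pass; the test suite holds it against an independent O(L²) all-pairs
oracle on 1,000 random sequences (lengths 30–3,000 nt, GC 0.25–0.75).

Numerical/edge conventions:

* **Length includes the stop codon** (start of AUG through end of stop), so
  every ORF length is a multiple of 3 and at least 6 nt, and the minimal
  `AUGUAA` ORF is valid. The 300-nt sORF cutoff is applied to this
  inclusive length; whether the conventional threshold counts the stop
  codon is genuinely ambiguous, so the cutoff is exposed as
  `sorf_threshold` rather than hard-coded.
* **Ambiguous bases:** codons containing N never match AUG or a stop. This
  is conservative — it can only suppress ORFs, never fabricate them.
* **Start-codon policy is AUG-only**; near-cognate starts are out of scope.

Categorization is a fixed cascade evaluated in order: no CDS →
`unannotated`; identical interval → `annotated`; same stop → `truncated` /
`extended` by start side; any remaining overlap ≥ 1 nt → `internal`;
otherwise `uorf` / `dorf`. The ordering makes the seven classes a
*partition*: same-stop cases are resolved before overlap, so
upstream/downstream ORFs never touch the aORF, and `internal` is exactly
the overlapping-without-shared-stop class (off-frame, or in-frame ORFs
terminating at an off-frame stop planted within the aORF — impossible for
in-frame stops, which would have terminated the aORF earlier). An in-frame
ORF wholly upstream of the aORF that does not share its stop is classed
`uorf`; nothing in the category definitions distinguishes it from an
off-frame one.

## P-site offsets and signal tracks

The offset estimator is the classic start-codon metagene: initiating
ribosomes protect fragments whose 5' ends sit a characteristic distance
upstream of the AUG, so for each read length the mode of the distance
distribution identifies the offset. Choices:

* **Statistic = mode**, ties broken toward the smaller offset; this is
  deterministic and robust to a minority of mis-placed reads, which is all
  the estimator needs under the initiation-peak assumption.
* **Window = 40 nt** upstream of (and including) the start codon, i.e.
  distances 0 ≤ d ≤ 40 enter the tally, additionally bounded by d < read
  length because a P-site cannot lie outside the read. 40 nt generously
  covers one footprint plus placement jitter while excluding most
  elongation signal.
* **Minimum support = 10 reads** per length; lengths below it are omitted
  rather than reported on noise. Both parameters are arguments, not
  constants.

Track construction adds one count at `five_prime + offset(L)` per read.
Reads of lengths without an offset are skipped, P-sites past the 3' end are
dropped; both tallies are attached as attributes so the conservation
identity (track sum = retained reads) is checkable, and the tests assert it
on every fixture. Denoised footprint tracks produced by external tools can
be quantified identically by passing them as a `denoised` signal source;
the package does not denoise.

Genomic alignments are accepted as data frames of aligned spans and
converted with `genomic_reads_to_transcript()`: the 5' end is the leftmost
aligned base on plus-strand models and the rightmost on minus-strand
models, and a read is kept only when its terminal bases are exonic and
their transcript distance equals the aligned length minus one — which
admits reads spliced exactly at annotated junctions and rejects everything
else. Decoding BAM/CIGAR itself is left to the alignment ecosystem; the
exchange formats here are the transcript-space TSV and genomic span
tables.

## Quantification

RPKM uses the library size actually contributing to the quantified signal
(the track's retained reads, or the supplied count table's total), not raw
sequencing depth — the two differ by the filtered/unmappable fraction,
which should not silently rescale TE. Both are overridable. TE divides
Ribo-seq RPKM over the ORF by RNA-seq RPKM over its *transcript*
(transcript-level RNA abundance is the natural denominator when counts are
supplied per transcript); where the RNA RPKM is zero TE is `NA`, never 0 or
infinity. A read contributes to an ORF iff its P-site falls inside
`[start, end)` — the convention the track construction itself implies.
There are no pseudocounts anywhere by default.

## Hotspots, elements, intersections

The hotspot unit is a **20-nt bin along the precursor** — the full
unspliced gene span, introns included, binned from the 5' end in
transcription orientation with the final partial bin retained. The count is
the number of **distinct RBP names** (pooling peak callers and samples;
`distinct_by = c("rbp", "sample")` switches the key) with ≥ 1 nt overlap,
so it is invariant to duplicated peak records — a necessity when the same
interaction appears once per caller. Strand-matched sites only; `.` matches
both. The implementation bins interval overlaps arithmetically and is
tested against a literal per-base union oracle on 50 seeded fixtures.

Element assignment resolves multi-isoform ambiguity with an explicit
priority (default CDS > 3'UTR > 5'UTR > lncRNA exon > other exon > intron >
intergenic): coding annotation outranks non-coding, exon outranks intron.
Transcripts without a CDS contribute `lncRNA_exon` when their biotype looks
long-non-coding and `other_exon` otherwise. Intersections with
variant/modification tracks use the half-open convention (abutting
intervals do not overlap), widen zero-width point records to 1 nt, and
ignore strand, since variant positions are not stranded annotations.
Interval machinery is delegated to `GenomicRanges`/`IRanges`; the tests
hold it against a quadratic all-vs-all oracle at 10³ × 10³ records.

## Read filters

"Above Q20 in 80 % of bases" is implemented as *strictly* greater than the
quality threshold and *at least* the fraction: a 10-base read with exactly
8 passing bases passes, all-Q20 reads fail. The inequality senses are
genuinely ambiguous in common usage, so both thresholds are parameters and
the boundary behavior is pinned by tests. The length filter keeps reads of
≥ 13 nt. Duplicate collapsing keys on the sequence alone (no UMI handling),
keeps the first occurrence's id and qualities, and preserves input order;
multiplicities always sum to the input count. All filters are idempotent
and mutually order-independent.

## The synthetic-data generator

The generator exists so that every result in this package can be checked
against a truth that was *constructed*, not re-computed. Transcript
sequences are assembled from planted `AUG…stop` elements over a restricted
alphabet: ORF bodies use only {A, C, G} (no U, hence no internal starts or
stops in any frame), spacers are C-runs, planted stops are UAA/UAG, and the
base following every planted AUG is confined to {C, G}, which provably
prevents stop codons from arising in windows that straddle planted
elements. Every AUG on a built transcript is therefore deliberate, and the
ground-truth ORF table — including the category of each ORF — follows from
the construction alone. The default transcriptome (12 transcripts, ~60 %
coding, 1–3 exons, alternating strands, random intronic/intergenic filler)
always contains at least one instance of each of the seven categories.

Footprints are placed on annotated ORF codons (3-nt periodic) with a 5×
initiation peak at the start codon — the enrichment real libraries show and
the reason the metagene mode identifies the offset — with true offsets
{28→12, 29→13}, 5 % uniformly placed noise reads, and per-ORF signal
proportional to TE × RNA abundance × length, so quantified TE ratios
recover their targets (the leading pair is 2 vs 1 at equal RNA counts)
within multinomial sampling error; at the default 10⁴ reads that error is a
few percent. CLIP sites (200 records, 12 RBPs, mixed strands including
records that must be excluded) come with a hotspot truth computed base by
base, independently of the package's binning arithmetic. The FASTQ
generator draws unique sequences with geometric multiplicities (expected
~1.7 copies), 15 % low-quality reads and lengths 8–40 nt, recording the
exact duplication spectrum.

What the generator does **not** emulate: sequencing errors, untemplated
additions, fragment-length distributions beyond two read lengths, biased
nucleotide composition (real transcripts contain Us outside ORFs),
incomplete or wrong annotations, multi-mapping, or peak-caller artifacts.
Passing tests therefore demonstrate that the *logic* is exact under clean
inputs, not that the estimators are robust to every pathology of real
libraries — robustness claims would need real benchmarks.

## Problem sizes and determinism

The validation suite runs the scanner oracle on 1,000 random sequences up
to 3,000 nt, offset recovery on 100 seeded replicates at 120
reads/length with 20 % noise, hotspot oracles on 50 seeded site draws, and
the intersection oracle at 10³ × 10³ records — sizes at which the
brute-force oracles are still exact and fast. All randomness flows from
explicit seeds; regenerating any fixture with the same `fixture_spec`
yields byte-identical files.

## Known limitations

* No GFF3, no polycistronic (multi-CDS) transcripts, no annotation
  merging: one CDS span per transcript, from the GTF given.
* Translated-vs-untranslated calls (3-nt periodicity tests), peak calling,
  motif/structure discovery, liftOver and differential TE testing are out
  of scope; the package consumes or emits their inputs/outputs instead.
* RNA-seq quantification is count-table-in: the package does not estimate
  transcript abundance from RNA-seq alignments.
* TE compares RPKMs within one condition pair; no shrinkage, no
  replicate-aware inference.
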