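Package: ribostar
Title: Translatome Annotation and RBP-Binding Site Profiling from Ribo-Seq and CLIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating the translational landscape of transcriptomes
    and profiling RNA-binding-protein (RBP) occupancy. Enumerates every candidate
    open reading frame (ORF) on spliced transcript models and classifies each
    into one of seven positional categories relative to the annotated CDS
    (annotated, truncated, extended, internal, upstream, downstream,
    unannotated), flags small ORFs, infers per-read-length ribosome P-site
    offsets from footprint alignments around annotated start codons, builds
    per-nucleotide P-site signal tracks, and quantifies translation efficiency
    (Ribo-seq/RNA-seq RPKM ratio) and translation density per ORF. For CLIP-seq
    data it computes distinct-RBP binding hotspots in 20-nt bins along gene
    precursors, assigns binding sites to genomic elements, intersects sites
    with variant and modification tracks, and applies standard read quality,
    length and PCR-duplicate filters. A deterministic simulator generates
    mini genomes, annotations, alignments and peak sets with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
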