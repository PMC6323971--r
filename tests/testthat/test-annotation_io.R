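test_that("GTF coordinates are converted to 0-based half-open on read", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t90\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_name "G1";'),
    paste0("chr1\tsrc\tCDS\t10\t39\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_name "G1";'),
    paste0("chr1\tsrc\tstop_codon\t40\t42\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_name "G1";')), gtf)
  models <- parse_gtf(gtf, dialect = "gencode")
  m <- models[["t1"]]
  expect_equal(unname(m$exons[1, ]), c(0L, 90L))
  expect_equal(m$cds, c(9L, 42L))   # stop codon appended under gencode
  expect_equal(diff(cds_transcript_interval(m)), 33L)
  # generic dialect treats CDS rows as-is and ignores stop_codon
  m2 <- parse_gtf(gtf, dialect = "generic")[["t1"]]
  expect_equal(m2$cds, c(9L, 39L))
})

test_that("transcripts without CDS or with a broken CDS are handled", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t60\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "nc1";'),
    paste0("chr1\tsrc\texon\t101\t160\t.\t+\t.\t",
           'gene_id "g2"; transcript_id "bad1";'),
    paste0("chr1\tsrc\tCDS\t110\t120\t.\t+\t.\t",
           'gene_id "g2"; transcript_id "bad1";')), gtf)
  expect_warning(models <- parse_gtf(gtf, dialect = "generic"),
                 "not a multiple of 3")
  expect_null(models[["nc1"]]$cds)
  expect_null(models[["bad1"]]$cds)  # 11-nt CDS dropped, transcript kept
})

test_that("malformed GTF lines raise errors naming the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "# a comment line",
    paste0("chr1\tsrc\texon\t1\t60\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    "chr1\tsrc\texon\t61\t90\t.\t+\t."), gtf)
  expect_error(parse_gtf(gtf), "line 3")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t60\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    'chr1\tsrc\texon\t61\t90\t.\t+\t.\tgene_id "g1";'), gtf)
  expect_error(parse_gtf(gtf), "transcript_id at line 2")
})

test_that("spliced sequence extraction respects exon structure and strand", {
  genome <- Biostrings::DNAStringSet(c(chrA = "ATGCCCAAATTT", chrB = "CATCAT"))
  plus <- transcript_model("p", "chrA", "+", rbind(c(0, 3), c(6, 9)))
  expect_equal(extract_sequence(plus, genome), "AUGAAA")
  minus <- transcript_model("m", "chrB", "-", rbind(c(0, 6)))
  expect_equal(extract_sequence(minus, genome), "AUGAUG")
  expect_equal(extract_sequence(minus, genome, alphabet = "dna"), "ATGATG")
  # minus-strand extraction is the reverse complement of the plus extraction
  plus_same <- transcript_model("p2", "chrB", "+", rbind(c(0, 6)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(extract_sequence(plus_same, genome, "dna"))))
  expect_equal(extract_sequence(minus, genome, "dna"), rc)
  far <- transcript_model("f", "chrB", "+", rbind(c(0, 99)))
  expect_error(extract_sequence(far, genome), "exceeds")
  lost <- transcript_model("l", "chrZ", "+", rbind(c(0, 3)))
  expect_error(extract_sequence(lost, genome), "missing")
})

test_that("genome/transcript mapping follows the strand convention", {
  plus <- transcript_model("p", "c", "+", rbind(c(10, 20)))
  expect_equal(genome_to_transcript(plus, 10), 0L)
  expect_equal(genome_to_transcript(plus, 25), NA_integer_)
  minus <- transcript_model("m", "c", "-", rbind(c(10, 20)))
  expect_equal(genome_to_transcript(minus, 19), 0L)
  expect_equal(genome_to_transcript(minus, 10), 9L)
  expect_error(transcript_to_genome(minus, 10), "out of range")
})

test_that("genome<->transcript round trip is the identity on exonic bases", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_model(paste0("t", i))
    gpos <- unlist(lapply(seq_len(nrow(m$exons)), function(k)
      seq.int(m$exons[k, 1], m$exons[k, 2] - 1L)))
    tpos <- genome_to_transcript(m, gpos)
    expect_false(anyNA(tpos))
    expect_setequal(tpos, seq.int(0L, transcript_length(m) - 1L))
    expect_equal(transcript_to_genome(m, tpos), gpos)
    # intronic and flanking positions are absent, not errors
    introns <- setdiff(seq.int(min(gpos) - 1L, max(gpos) + 1L), gpos)
    expect_true(all(is.na(genome_to_transcript(m, introns))))
  }
})

test_that("parse -> write -> parse round trip preserves the models", {
  fx <- fixture_cache()
  gtf2 <- tempfile(fileext = ".gtf")
  write_gtf(fx$tx$models, gtf2, dialect = "gencode")
  reparsed <- parse_gtf(gtf2, dialect = "gencode")
  expect_identical(reparsed, fx$tx$models)
})

test_that("parser agrees with rtracklayer on the fixture annotation", {
  skip_if_not_installed("rtracklayer")
  fx <- fixture_cache()
  gr <- rtracklayer::import(fx$tx$gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  for (id in names(fx$tx$models)) {
    m <- fx$tx$models[[id]]
    theirs <- ex[ex$transcript_id == id]
    ord <- order(BiocGenerics::start(theirs))
    expect_equal(BiocGenerics::start(theirs)[ord] - 1L,
                 unname(m$exons[, 1]), info = id)
    expect_equal(BiocGenerics::end(theirs)[ord], unname(m$exons[, 2]),
                 info = id)
  }
})
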