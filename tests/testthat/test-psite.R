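# a tiny hand-built transcriptome for offset arithmetic:
# one plus-strand coding transcript, start codon at transcript position 100
psite_models <- function(start_codon = 100L, tlen = 400L) {
  genome_len <- tlen
  m <- transcript_model("tx1", "chrP", "+", rbind(c(0L, genome_len)),
                        cds = c(start_codon, start_codon + 90L))
  nc <- transcript_model("nc1", "chrP", "+", rbind(c(0L, 200L)))
  list(tx1 = m, nc1 = nc)
}

test_that("offsets are the per-length mode of start-codon 5' distances", {
  models <- psite_models()
  reads <- data.frame(
    transcript_id = "tx1",
    five_prime = c(rep(88L, 20), rep(87L, 5), rep(87L, 0)),
    read_length = 28L)
  off <- infer_psite_offsets(reads, models)
  expect_equal(off$offsets[["28"]], 12L)
  expect_equal(off$support[["28"]], 25L)
  # ties break toward the smaller offset
  tie <- data.frame(transcript_id = "tx1",
                    five_prime = c(rep(88L, 10), rep(87L, 10)),
                    read_length = 28L)
  expect_equal(infer_psite_offsets(tie, models)$offsets[["28"]], 12L)
  # support below the minimum omits the length
  few <- data.frame(transcript_id = "tx1", five_prime = rep(88L, 9),
                    read_length = 28L)
  expect_length(infer_psite_offsets(few, models)$offsets, 0L)
  expect_length(infer_psite_offsets(few, models,
                                    min_support = 5L)$offsets, 1L)
})

test_that("metagene window and read-length bounds restrict the distances", {
  models <- psite_models()
  # d = 60 is outside the default 40-nt window; d = 30 >= read length 28
  reads <- data.frame(transcript_id = "tx1",
                      five_prime = c(rep(40L, 20), rep(70L, 20), rep(88L, 20)),
                      read_length = 28L)
  off <- infer_psite_offsets(reads, models)
  expect_equal(off$offsets[["28"]], 12L)
  expect_equal(off$support[["28"]], 20L)
  wide <- infer_psite_offsets(reads, models, window = 60L)
  expect_equal(wide$support[["28"]], 20L)  # d=60 passes window, fails d < L
})

test_that("reads on non-coding transcripts yield an empty offset table", {
  models <- psite_models()
  reads <- data.frame(transcript_id = "nc1", five_prime = rep(50L, 30),
                      read_length = 28L)
  off <- infer_psite_offsets(reads, models)
  expect_length(off$offsets, 0L)
  expect_error(infer_psite_offsets(reads, list(nc1 = models$nc1)),
               "no annotated CDS")
  empty <- reads[0, ]
  expect_length(infer_psite_offsets(empty, models)$offsets, 0L)
})

test_that("offset inference is invariant under coordinate translation", {
  set.seed(31)
  for (shift in c(0L, 7L, 23L)) {
    models <- psite_models(start_codon = 100L + shift)
    reads <- data.frame(
      transcript_id = "tx1",
      five_prime = 100L + shift - 12L + sample(c(0L, 0L, 0L, -3L), 50,
                                               replace = TRUE),
      read_length = 28L)
    off <- infer_psite_offsets(reads, models)
    expect_equal(off$offsets[["28"]], 12L, info = paste("shift", shift))
  }
})

test_that("P-site tracks add one count per retained read at 5' + offset", {
  models <- psite_models()
  off <- structure(list(offsets = c("28" = 12L), support = c("28" = 1L)),
                   class = "psite_offsets")
  reads <- data.frame(transcript_id = "tx1", five_prime = c(88L, 88L, 50L),
                      read_length = 28L)
  tracks <- build_psite_tracks(reads, off, models)
  expect_equal(tracks$tx1[101], 2)          # two reads, same P-site
  expect_equal(tracks$tx1[63], 1)
  expect_equal(sum(tracks$tx1), 3)
  expect_equal(sum(tracks$nc1), 0)
  expect_equal(attr(tracks, "n_retained"), 3L)
  # unknown lengths are skipped, out-of-bounds P-sites dropped, both counted
  mixed <- data.frame(transcript_id = "tx1",
                      five_prime = c(88L, 88L, 395L),
                      read_length = c(28L, 31L, 28L))
  tr2 <- build_psite_tracks(mixed, off, models)
  expect_equal(attr(tr2, "n_skipped_length"), 1L)
  expect_equal(attr(tr2, "n_dropped_out_of_bounds"), 1L)
  expect_equal(sum(unlist(tr2)), attr(tr2, "n_retained"))
  expect_error(build_psite_tracks(reads, structure(
    list(offsets = integer(0), support = integer(0)),
    class = "psite_offsets"), models), "empty")
})

test_that("genomic alignments convert to transcript space strand-aware", {
  # two-exon plus and minus models over the same exons
  ex <- rbind(c(10L, 20L), c(30L, 40L))
  plus <- transcript_model("p", "chrG", "+", ex)
  minus <- transcript_model("m", "chrG", "-", ex)
  reads <- data.frame(chrom = "chrG",
                      start = c(12L, 18L, 25L, 12L),
                      end = c(17L, 33L, 35L, 45L),
                      read_length = c(5L, 5L, 10L, 33L))
  conv_p <- genomic_reads_to_transcript(reads, list(p = plus))
  # read 1: fully exonic; read 2: spliced exactly at the junction
  expect_equal(conv_p$five_prime, c(2L, 8L))
  expect_equal(conv_p$read_length, c(5L, 5L))
  conv_m <- genomic_reads_to_transcript(reads, list(m = minus))
  # on minus models the 5' end is the rightmost aligned base
  expect_equal(conv_m$five_prime, c(20L - 1L - 16L + 10L, 10L - 3L))
  # intron-spanning (read 3) and out-of-model (read 4) reads are dropped
  expect_equal(attr(conv_p, "n_placed"), 2L)
})

test_that("simulated footprints round-trip through the full P-site path", {
  fx <- fixture_cache()
  rs <- make_riboseq(fx$tx, fx$spec)
  off <- infer_psite_offsets(rs$reads, fx$tx$models)
  expect_equal(off$offsets[c("28", "29")], c("28" = 12L, "29" = 13L))
  tracks <- build_psite_tracks(rs$reads, off, fx$tx$models)
  expect_equal(sum(unlist(tracks)), attr(tracks, "n_retained"))
  expect_equal(attr(tracks, "n_retained") +
                 attr(tracks, "n_skipped_length") +
                 attr(tracks, "n_dropped_out_of_bounds"), nrow(rs$reads))
})
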