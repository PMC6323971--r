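mk_sites <- function(chrom, start, end, strand = "+", rbp,
                     method = "Piranha", sample = "HeLa") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = paste0("peak", seq_along(start)), score = "0",
             strand = strand, rbp = rbp, method = method, sample = sample,
             stringsAsFactors = FALSE)
}

test_that("hotspot bins count distinct proteins, not peaks", {
  gene <- list(gene_id = "g", chrom = "chr1", start = 100L, end = 200L,
               strand = "+")
  three <- mk_sites("chr1", c(100, 105, 110), c(115, 118, 119),
                    rbp = c("A", "B", "C"))
  hs <- compute_hotspots(three, gene)
  expect_equal(hs$n_rbp[1], 3L)
  # five peaks from one protein still count once
  five <- mk_sites("chr1", rep(102, 5), rep(114, 5), rbp = "A",
                   method = c("Piranha", "CIMS", "CITS", "PARalyzer",
                              "eCLIP"))
  expect_equal(compute_hotspots(five, gene)$n_rbp[1], 1L)
  # unless distinctness is keyed on (rbp, sample)
  five$sample <- c("HeLa", "HeLa", "K562", "K562", "brain")
  expect_equal(compute_hotspots(five, gene,
                                distinct_by = c("rbp", "sample"))$n_rbp[1], 3L)
})

test_that("hotspot binning is 5'-anchored, strand-matched and clipped", {
  minus_gene <- list(gene_id = "g", chrom = "chr1", start = 100L, end = 161L,
                     strand = "-")
  # a site covering the gene's genomically-last base sits in bin 0 (5' end)
  s <- mk_sites("chr1", 158, 161, strand = "-", rbp = "A")
  hs <- compute_hotspots(s, minus_gene)
  expect_equal(nrow(hs), 4L)              # 61 nt -> 3 full bins + partial
  expect_equal(hs$bin_end[4], 61L)        # final partial bin retained
  expect_equal(hs$n_rbp, c(1L, 0L, 0L, 0L))
  # wrong strand is excluded, "." matches both
  expect_equal(sum(compute_hotspots(
    mk_sites("chr1", 158, 161, strand = "+", rbp = "A"),
    minus_gene)$n_rbp), 0L)
  expect_equal(compute_hotspots(
    mk_sites("chr1", 158, 161, strand = ".", rbp = "A"),
    minus_gene)$n_rbp[1], 1L)
  # other chromosomes are skipped with a tally
  off <- compute_hotspots(mk_sites("chr2", 110, 120, rbp = "A"), minus_gene)
  expect_equal(sum(off$n_rbp), 0L)
  expect_equal(attr(off, "n_skipped_chrom"), 1L)
})

test_that("hotspot counts match the per-base oracle and ignore duplicates", {
  fx <- fixture_cache()
  for (s in 1:6) {
    cl <- make_clip(fx$tx, fixture_spec(seed = 100L + s))
    hs <- compute_hotspots(cl$sites, cl$gene)
    expect_equal(hs$n_rbp, brute_force_hotspots(cl$sites, cl$gene),
                 info = paste("clip fixture", s))
    expect_equal(hs$n_rbp, cl$truth_hotspots$n_rbp)
    dup <- rbind(cl$sites, cl$sites[sample(nrow(cl$sites), 50), ])
    expect_equal(compute_hotspots(dup, cl$gene)$n_rbp, hs$n_rbp)
    expect_true(all(hs$n_rbp <= length(unique(cl$sites$rbp))))
  }
})

test_that("element assignment follows the priority over all isoforms", {
  # coding isoform: exons [0,100) + [200,300), CDS span [30,232), 102 nt
  coding <- transcript_model("cod", "chr1", "+",
                             rbind(c(0L, 100L), c(200L, 300L)),
                             cds = c(30L, 232L))
  lnc <- transcript_model("lnc", "chr1", "+", rbind(c(400L, 500L)),
                          biotype = "lncRNA")
  other <- transcript_model("oth", "chr1", "+", rbind(c(600L, 700L)),
                            biotype = "processed_pseudogene")
  models <- list(cod = coding, lnc = lnc, oth = other)
  sites <- mk_sites("chr1",
                    start = c(40, 5, 250, 120, 420, 620, 900, 95),
                    end = c(60, 20, 280, 150, 440, 640, 950, 132),
                    rbp = "X")
  labels <- assign_elements(sites, models)
  expect_equal(labels, c("CDS", "5'UTR", "3'UTR", "intron", "lncRNA_exon",
                         "other_exon", "intergenic", "CDS"))
  # the straddling site (95..132) hits CDS and intron; CDS outranks intron;
  # reversing the priority flips the label
  rev_priority <- rev(ELEMENT_PRIORITY)
  expect_equal(assign_elements(sites[8, , drop = FALSE], models,
                               priority = rev_priority), "intron")
  # strand mismatch makes a site intergenic
  minus_site <- mk_sites("chr1", 40, 60, strand = "-", rbp = "X")
  expect_equal(assign_elements(minus_site, models), "intergenic")
  expect_equal(assign_elements(mk_sites("chr1", 40, 60, strand = ".",
                                        rbp = "X"), models), "CDS")
})

test_that("intersections match the quadratic oracle with half-open touches", {
  feats <- function(chrom, start, end, kind = "SNV") {
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), name = "f", score = "0", strand = ".",
               kind = kind, stringsAsFactors = FALSE)
  }
  site <- mk_sites("chr1", 95, 105, rbp = "A")
  expect_equal(nrow(intersect_tracks(site, feats("chr1", 100, 101))), 1L)
  # zero-width point record is widened to 1 nt
  expect_equal(nrow(intersect_tracks(site, feats("chr1", 100, 100))), 1L)
  # abutting half-open intervals do not overlap
  expect_equal(nrow(intersect_tracks(site, feats("chr1", 105, 110))), 0L)
  expect_equal(nrow(intersect_tracks(site, feats("chr1", 90, 95))), 0L)
  expect_equal(nrow(intersect_tracks(site, feats("chr2", 100, 101))), 0L)
  set.seed(61)
  sites <- mk_sites(sample(c("chr1", "chr2"), 300, TRUE),
                    start = s <- sample(0:5000, 300, TRUE),
                    end = s + sample(10:40, 300, TRUE),
                    rbp = sample(LETTERS[1:5], 300, TRUE))
  fs <- sample(0:5000, 400, TRUE)
  features <- feats(sample(c("chr1", "chr2"), 400, TRUE), fs,
                    fs + sample(0:20, 400, TRUE),
                    kind = sample(c("SNV", "modification", "editing"), 400,
                                  TRUE))
  got <- intersect_tracks(sites, features)
  oracle <- brute_force_overlaps(sites, features)
  expect_equal(nrow(got), nrow(oracle))
  expect_setequal(paste(got$site_name, got$feature_start),
                  paste(sites$name[oracle[, 1]], features$start[oracle[, 2]]))
  expect_true(all(got$overlap_nt >= 1L))
})

test_that("BED reading enforces format and preserves extra columns", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test",
               "chr1\t10\t20\tp1\t0\t+\tRBP1\tPiranha\tHeLa",
               "chr1\t30\t45\tp2\t0\t-\tRBP2\tCIMS\tK562"), bed)
  sites <- read_binding_sites(bed)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$start, c(10L, 30L))
  expect_equal(sites$rbp, c("RBP1", "RBP2"))
  writeLines(c("chr1\t10\t20\tp1\t0\t+\tRBP1\tPiranha\tHeLa",
               "chr1\tten\t20\tp2\t0\t+\tRBP2\tPiranha\tHeLa"), bed)
  expect_error(read_binding_sites(bed), "line 2")
  writeLines("chr1\t10\t20\tp1\t0", bed)
  expect_error(read_binding_sites(bed), "line 1")
})
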