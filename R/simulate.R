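#' Specification for the synthetic fixture generator
#'
#' Bundles every parameter of the deterministic mini-dataset generator. The
#' same spec (same seed) always reproduces byte-identical files.
#'
#' @param seed Integer RNG seed.
#' @param n_transcripts Number of transcripts in the mini-transcriptome; the
#'   first two are fixed designs that together exhibit all seven ORF
#'   categories.
#' @param coding_fraction Fraction of the remaining random transcripts that
#'   carry an annotated CDS.
#' @param psite_offsets Named integer vector mapping read length to the true
#'   5'-end-to-P-site offset used when simulating footprints.
#' @param noise_fraction Fraction of footprint reads placed uniformly at
#'   random rather than on ORF codons.
#' @param n_reads Number of simulated footprint reads.
#' @param init_weight Relative ribosome occupancy of the start codon versus
#'   any elongation codon; emulates the initiation peak of real profiles.
#' @param te Recycled vector of target translation efficiencies assigned to
#'   the annotated ORFs in transcript order; the default starts with the
#'   2-vs-1 pair at equal RNA abundance.
#' @param rna_count RNA-seq read count given to every transcript.
#' @param n_binding_sites,n_rbps CLIP fixture: number of binding-site records
#'   and of distinct RBP names.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, n_transcripts = 12L,
                         coding_fraction = 0.6,
                         psite_offsets = c("28" = 12L, "29" = 13L),
                         noise_fraction = 0.05, n_reads = 10000L,
                         init_weight = 5, te = c(2, 1, 0.5, 4, 1.5),
                         rna_count = 500, n_binding_sites = 200L,
                         n_rbps = 12L) {
  stopifnot(n_transcripts >= 0L, coding_fraction >= 0, coding_fraction <= 1,
            noise_fraction >= 0, noise_fraction < 1, n_reads >= 0L,
            init_weight > 0, all(te > 0), rna_count > 0,
            n_binding_sites >= 0L, n_rbps >= 1L)
  lens <- suppressWarnings(as.integer(names(psite_offsets)))
  if (length(psite_offsets) == 0L || anyNA(lens) ||
      any(psite_offsets < 0L | psite_offsets >= lens))
    stop("psite_offsets must be named by read length with 0 <= offset < length")
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 coding_fraction = coding_fraction,
                 psite_offsets = psite_offsets,
                 noise_fraction = noise_fraction, n_reads = n_reads,
                 init_weight = init_weight, te = te, rna_count = rna_count,
                 n_binding_sites = n_binding_sites, n_rbps = n_rbps),
            class = "fixture_spec")
}

# --- sequence construction kit ---------------------------------------------
# ORF bodies use only {A, C, G} so they contain no start or stop codon in any
# frame; inter-ORF spacers are plain C runs. Every AUG in a built transcript
# is therefore planted deliberately and the ground-truth ORF table is exact.
# The single base following a planted AUG is restricted to {C, G}: together
# with using UAA/UAG stops only, this prevents any stop codon from arising in
# a reading-frame window that straddles a planted element.

rand_codons <- function(n, first_cg = FALSE) {
  if (n == 0L) return("")
  codons <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G"), 3L, replace = TRUE), collapse = ""), "")
  if (first_cg) substr(codons[1L], 1L, 1L) <- sample(c("C", "G"), 1L)
  paste(codons, collapse = "")
}

cspacer <- function(n) strrep("C", n)

# Build one transcript sequence with planted ORFs whose coordinates and
# categories are known by construction. Returns list(seq, cds, truth).
build_transcript_sequence <- function(coding, with_uorf = FALSE,
                                      with_ext = FALSE, with_internal = FALSE,
                                      with_trunc = FALSE, with_dorf = FALSE,
                                      n_unann = 1L) {
  parts <- character(0); cur <- 0L
  truth <- list()
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    cur <<- cur + nchar(s)
  }
  plant <- function(n_codons, category, stop_codon = "UAA") {
    s0 <- cur
    add(paste0("AUG", rand_codons(n_codons, first_cg = TRUE), stop_codon))
    truth[[length(truth) + 1L]] <<- c(start = s0, end = cur)
    names(truth)[length(truth)] <<- category
    invisible(c(s0, cur))
  }
  if (!coding) {
    add(cspacer(sample(10:30, 1L)))
    for (i in seq_len(n_unann)) {
      plant(sample(2:30, 1L), "unannotated")
      add(cspacer(sample(5:25, 1L)))
    }
    if (n_unann == 0L) add(cspacer(sample(30:80, 1L)))
    return(list(seq = paste(parts, collapse = ""), cds = NULL,
                truth = truth))
  }
  add(cspacer(sample(16:30, 1L)))
  if (with_uorf) {
    plant(sample(1:8, 1L), "uorf")
    add(cspacer(sample(4:20, 1L)))
  }
  ext_start <- NA_integer_
  if (with_ext) {
    ext_start <- cur
    add(paste0("AUG", rand_codons(sample(1:10, 1L), first_cg = TRUE)))
  }
  a_start <- cur
  add("AUG")
  add(rand_codons(sample(2:10, 1L), first_cg = TRUE))
  if (with_internal) {
    shift <- sample(1:2, 1L)
    add(paste(sample(c("A", "C", "G"), shift, replace = TRUE), collapse = ""))
    plant(sample(1:6, 1L), "internal")
    pad <- (3L - shift) %% 3L
    if (pad > 0L)
      add(paste(sample(c("A", "C", "G"), pad, replace = TRUE), collapse = ""))
    add(rand_codons(sample(1:8, 1L)))
  }
  tr_start <- NA_integer_
  if (with_trunc) {
    tr_start <- cur
    add("AUG")
    add(rand_codons(sample(1:8, 1L), first_cg = TRUE))
  } else {
    add(rand_codons(sample(1:8, 1L)))
  }
  add("UAA")
  a_end <- cur
  truth[[length(truth) + 1L]] <- c(start = a_start, end = a_end)
  names(truth)[length(truth)] <- "annotated"
  if (with_ext) {
    truth[[length(truth) + 1L]] <- c(start = ext_start, end = a_end)
    names(truth)[length(truth)] <- "extended"
  }
  if (with_trunc) {
    truth[[length(truth) + 1L]] <- c(start = tr_start, end = a_end)
    names(truth)[length(truth)] <- "truncated"
  }
  add(cspacer(sample(5:20, 1L)))
  if (with_dorf) {
    plant(sample(1:10, 1L), "dorf")
    add(cspacer(sample(3:10, 1L)))
  }
  list(seq = paste(parts, collapse = ""), cds = c(a_start, a_end),
       truth = truth)
}

rand_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split a transcript into exon pieces and embed it on a chromosome string
# builder; returns the exon coordinate matrix
split_points <- function(tlen, n_exons, min_exon = 20L) {
  if (n_exons == 1L || tlen < n_exons * min_exon) return(integer(0))
  for (try in 1:20) {
    cuts <- sort(sample(seq.int(min_exon, tlen - min_exon), n_exons - 1L))
    if (all(diff(c(0L, cuts, tlen)) >= min_exon)) return(cuts)
  }
  integer(0)
}

#' Generate a deterministic mini-transcriptome with known ORF ground truth
#'
#' Builds a small genome FASTA and gencode-dialect GTF whose transcripts
#' contain, by construction, at least one ORF of each of the seven
#' categories, and returns the exact table of every ORF present. Transcript
#' sequences are assembled from planted AUG...stop elements over a restricted
#' alphabet so that no unplanned start or stop codon can occur; the truth
#' table is therefore derived from the construction itself, independently of
#' the package's scanner. Transcripts alternate strand and may be split into
#' up to three exons with random intronic and intergenic filler.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param dir Output directory (created if needed); defaults to a fresh
#'   temporary directory.
#' @return List with \code{dir}, \code{genome_path}, \code{gtf_path},
#'   \code{genome} (\code{DNAStringSet}), \code{models} (as re-read through
#'   \code{\link{parse_gtf}}) and \code{truth} (the ground-truth ORF table
#'   with \code{transcript_id}, \code{gene_id}, \code{start}, \code{end},
#'   \code{frame}, \code{category}, \code{length_nt}, \code{is_sorf}).
#' @export
make_transcriptome <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(dir)) dir <- tempfile("ribostar_fixture_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_transcripts
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      plans[[i]] <- build_transcript_sequence(
        coding = TRUE, with_uorf = TRUE, with_ext = TRUE,
        with_internal = TRUE, with_trunc = TRUE, with_dorf = TRUE)
    } else if (i == 2L) {
      plans[[i]] <- build_transcript_sequence(coding = FALSE, n_unann = 1L)
    } else if (stats::runif(1L) < spec$coding_fraction) {
      plans[[i]] <- build_transcript_sequence(
        coding = TRUE,
        with_uorf = stats::runif(1L) < 0.5,
        with_ext = stats::runif(1L) < 0.3,
        with_internal = stats::runif(1L) < 0.5,
        with_trunc = stats::runif(1L) < 0.5,
        with_dorf = stats::runif(1L) < 0.5)
    } else {
      plans[[i]] <- build_transcript_sequence(coding = FALSE,
                                              n_unann = sample(0:2, 1L))
    }
  }
  chrom_of <- function(i) paste0("chr", (i - 1L) %/% 3L + 1L)
  chrom_parts <- list()
  chrom_len <- integer(0)
  models <- list()
  truth_rows <- list()
  for (i in seq_len(n)) {
    plan <- plans[[i]]
    tid <- sprintf("TX%03d", i)
    gid <- sprintf("G%03d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    chrom <- chrom_of(i)
    if (is.null(chrom_parts[[chrom]])) {
      chrom_parts[[chrom]] <- list()
      chrom_len[chrom] <- 0L
    }
    append_chrom <- function(s) {
      chrom_parts[[chrom]][[length(chrom_parts[[chrom]]) + 1L]] <<- s
      chrom_len[chrom] <<- chrom_len[chrom] + nchar(s)
    }
    append_chrom(rand_dna(sample(50:150, 1L)))
    tseq <- plan$seq
    tlen <- nchar(tseq)
    dna <- chartr("U", "T", tseq)
    cuts <- split_points(tlen, sample(1:3, 1L))
    bounds <- c(0L, cuts, tlen)
    pieces <- substring(dna, bounds[-length(bounds)] + 1L, bounds[-1L])
    if (strand == "-")
      pieces <- rev(vapply(pieces, function(p)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
        "", USE.NAMES = FALSE))
    ex <- matrix(0L, nrow = length(pieces), ncol = 2L)
    for (k in seq_along(pieces)) {
      if (k > 1L) append_chrom(rand_dna(sample(30:80, 1L)))
      ex[k, 1L] <- chrom_len[chrom]
      append_chrom(pieces[k])
      ex[k, 2L] <- chrom_len[chrom]
    }
    model <- transcript_model(tid, chrom, strand, ex,
                              gene_id = gid, gene_name = gid,
                              biotype = if (is.null(plan$cds)) "lncRNA"
                                        else "protein_coding")
    if (!is.null(plan$cds)) {
      g1 <- transcript_to_genome(model, plan$cds[1L])
      g2 <- transcript_to_genome(model, plan$cds[2L] - 1L)
      model <- transcript_model(tid, chrom, strand, ex,
                                cds = c(min(g1, g2), max(g1, g2) + 1L),
                                gene_id = gid, gene_name = gid,
                                biotype = "protein_coding")
    }
    models[[tid]] <- model
    if (length(plan$truth) > 0L) {
      starts <- vapply(plan$truth, `[[`, 0L, "start")
      ends <- vapply(plan$truth, `[[`, 0L, "end")
      truth_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid, start = starts, end = ends,
        frame = starts %% 3L, category = names(plan$truth),
        length_nt = ends - starts, stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  # pad chromosome ends so no exon abuts the boundary
  genome <- Biostrings::DNAStringSet(vapply(
    names(chrom_parts), function(ch)
      paste(c(unlist(chrom_parts[[ch]]), rand_dna(50L)), collapse = ""),
    "", USE.NAMES = TRUE))
  if (length(genome) == 0L)
    genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(200L)))
  genome_path <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "annotation.gtf")
  Biostrings::writeXStringSet(genome, genome_path, width = 70L)
  write_gtf(models, gtf_path, dialect = "gencode")
  truth <- if (length(truth_rows) > 0L)
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE))) else NULL
  if (is.null(truth))
    truth <- data.frame(transcript_id = character(0), gene_id = character(0),
                        start = integer(0), end = integer(0),
                        frame = integer(0), category = character(0),
                        length_nt = integer(0), stringsAsFactors = FALSE)
  truth$is_sorf <- truth$length_nt < 300L
  truth <- truth[order(truth$transcript_id, truth$start, truth$end), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(dir = dir, genome_path = genome_path, gtf_path = gtf_path,
       genome = read_genome(genome_path),
       models = parse_gtf(gtf_path, dialect = "gencode"), truth = truth)
}

#' Simulate ribosome footprint alignments with known offsets and TE
#'
#' Places footprint reads on the annotated ORFs of a fixture transcriptome.
#' Each annotated ORF receives signal proportional to its target translation
#' efficiency times its RNA abundance and length, so the quantified TE ratios
#' recover the targets up to sampling noise. P-sites sit on codon starts
#' (3-nt periodic) with an elevated initiation peak at the start codon
#' (weight \code{spec$init_weight}); the read 5' end is the P-site minus the
#' true per-length offset. A \code{noise_fraction} of reads is placed
#' uniformly at random across all transcripts. RNA-seq counts
#' (\code{spec$rna_count} per transcript) are written alongside.
#'
#' @param txome Output of \code{\link{make_transcriptome}}.
#' @param spec The same \code{\link{fixture_spec}}.
#' @return List with \code{reads} (transcript-space alignment table),
#'   \code{alignments_path}, \code{rna_counts_path}, \code{rna_counts}
#'   (named vector) and \code{truth}: list with the true \code{offsets},
#'   per-ORF target \code{te} and realized signal \code{orf_counts} (named by
#'   transcript).
#' @export
make_riboseq <- function(txome, spec = fixture_spec()) {
  set.seed(spec$seed + 1001L)
  models <- txome$models
  tlen <- vapply(models, transcript_length, integer(1L))
  coding <- Filter(function(m) !is.null(m$cds), models)
  if (length(coding) == 0L) stop("fixture transcriptome has no coding transcript")
  aorf <- lapply(coding, cds_transcript_interval)
  te <- rep(spec$te, length.out = length(coding))
  names(te) <- names(coding)
  rna_counts <- stats::setNames(rep(spec$rna_count, length(models)),
                                names(models))
  orf_len <- vapply(aorf, function(x) x[2L] - x[1L], integer(1L))
  rna_rpkm_prop <- rna_counts[names(coding)] / tlen[names(coding)]
  w <- te * rna_rpkm_prop * orf_len
  lens <- as.integer(names(spec$psite_offsets))
  n_signal <- round(spec$n_reads * (1 - spec$noise_fraction))
  n_noise <- spec$n_reads - n_signal
  orf_counts <- stats::setNames(integer(length(coding)), names(coding))
  reads_list <- list()
  if (n_signal > 0L) {
    pick <- sample(names(coding), n_signal, replace = TRUE, prob = w)
    cnt <- table(factor(pick, levels = names(coding)))
    orf_counts[] <- as.integer(cnt)
    for (id in names(coding)) {
      k <- orf_counts[[id]]
      if (k == 0L) next
      n_codons <- orf_len[[id]] %/% 3L - 1L  # exclude the stop codon
      codon_w <- c(spec$init_weight, rep(1, n_codons - 1L))
      codon <- sample.int(n_codons, k, replace = TRUE, prob = codon_w) - 1L
      L <- sample(lens, k, replace = TRUE)
      psite <- aorf[[id]][1L] + 3L * codon
      reads_list[[id]] <- data.frame(
        transcript_id = id,
        five_prime = psite - spec$psite_offsets[as.character(L)],
        read_length = L, stringsAsFactors = FALSE)
    }
  }
  if (n_noise > 0L) {
    tid <- sample(names(models), n_noise, replace = TRUE, prob = tlen)
    L <- sample(lens, n_noise, replace = TRUE)
    five <- floor(stats::runif(n_noise) * tlen[tid])
    reads_list[["noise"]] <- data.frame(
      transcript_id = tid, five_prime = as.integer(five), read_length = L,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, c(reads_list, list(make.row.names = FALSE)))
  if (is.null(reads))
    reads <- data.frame(transcript_id = character(0), five_prime = integer(0),
                        read_length = integer(0), stringsAsFactors = FALSE)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  alignments_path <- file.path(txome$dir, "riboseq_alignments.tsv")
  write_alignments(reads, alignments_path)
  rna_counts_path <- file.path(txome$dir, "rna_counts.tsv")
  utils::write.table(
    data.frame(transcript_id = names(rna_counts), count = rna_counts),
    rna_counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads = reads, alignments_path = alignments_path,
       rna_counts_path = rna_counts_path, rna_counts = rna_counts,
       truth = list(offsets = spec$psite_offsets, te = te,
                    orf_counts = orf_counts))
}

#' Simulate a start-codon metagene read set
#'
#' Places reads with their 5' ends exactly \code{offset} nt upstream of
#' annotated start codons (one draw per read over the coding transcripts),
#' with a fraction of uniformly placed noise reads. Used to validate offset
#' recovery by \code{\link{infer_psite_offsets}}.
#'
#' @param models Named list of \code{transcript_model} objects.
#' @param offsets Named integer vector mapping read length to true offset.
#' @param n_per_length Reads per read length (signal plus noise).
#' @param noise_fraction Fraction of uniformly placed reads.
#' @return Transcript-space read table.
#' @export
simulate_metagene_reads <- function(models, offsets, n_per_length = 100L,
                                    noise_fraction = 0.05) {
  coding <- Filter(function(m) !is.null(m$cds), models)
  if (length(coding) == 0L) stop("no coding transcript models")
  starts <- vapply(coding, function(m) cds_transcript_interval(m)[1L],
                   integer(1L))
  tlen <- vapply(models, transcript_length, integer(1L))
  out <- list()
  for (L in as.integer(names(offsets))) {
    off <- offsets[[as.character(L)]]
    eligible <- names(starts)[starts - off >= 0L]
    n_noise <- round(n_per_length * noise_fraction)
    n_sig <- n_per_length - n_noise
    tid <- sample(eligible, n_sig, replace = TRUE)
    sig <- data.frame(transcript_id = tid,
                      five_prime = starts[tid] - off,
                      read_length = L, stringsAsFactors = FALSE)
    noi <- if (n_noise > 0L) {
      ntid <- sample(names(models), n_noise, replace = TRUE, prob = tlen)
      data.frame(transcript_id = ntid,
                 five_prime = as.integer(floor(stats::runif(n_noise) *
                                                 tlen[ntid])),
                 read_length = L, stringsAsFactors = FALSE)
    }
    out[[as.character(L)]] <- rbind(sig, noi)
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Simulate CLIP binding sites and crosstalk features with hotspot truth
#'
#' Draws binding-site records for \code{spec$n_rbps} RBPs around the fixture
#' gene with the widest genomic span, plus a feature track mixing miRNA
#' target sites, modification/editing sites and point variants. The true
#' 20-nt hotspot profile is computed base by base from the drawn sites
#' (independent of the package's binning arithmetic). Site strands are
#' mostly the gene strand, with a minority of unstranded and opposite-strand
#' records; the latter must not contribute to hotspot counts.
#'
#' @param txome Output of \code{\link{make_transcriptome}}.
#' @param spec The same \code{\link{fixture_spec}}.
#' @return List with \code{sites}, \code{features} (data frames),
#'   \code{sites_path}, \code{features_path}, \code{gene} (precursor
#'   descriptor) and \code{truth_hotspots}.
#' @export
make_clip <- function(txome, spec = fixture_spec()) {
  set.seed(spec$seed + 2002L)
  models <- txome$models
  span <- vapply(models, function(m)
    max(m$exons[, 2L]) - min(m$exons[, 1L]), integer(1L))
  m <- models[[which.max(span)]]
  gene <- list(gene_id = m$gene_id, chrom = m$chrom,
               start = min(m$exons[, 1L]), end = max(m$exons[, 2L]),
               strand = m$strand)
  glen <- gene$end - gene$start
  n <- spec$n_binding_sites
  width <- sample(10:40, n, replace = TRUE)
  start <- sample(seq.int(gene$start - 50L, gene$end + 10L), n,
                  replace = TRUE)
  strand <- sample(c(gene$strand, ".", setdiff(c("+", "-"), gene$strand)),
                   n, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  sites <- data.frame(
    chrom = gene$chrom, start = start, end = start + width,
    name = sprintf("peak%04d", seq_len(n)), score = "0", strand = strand,
    rbp = sample(sprintf("RBP%02d", seq_len(spec$n_rbps)), n, replace = TRUE),
    method = sample(c("Piranha", "PARalyzer", "CIMS", "CITS", "eCLIP"), n,
                    replace = TRUE),
    sample = sample(c("HeLa", "HEK293", "brain"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  # ground truth: per-base distinct-RBP union, 20-nt bins anchored 5'
  usable <- sites[sites$strand %in% c(gene$strand, "."), , drop = FALSE]
  n_bins <- ceiling(glen / 20L)
  truth <- integer(n_bins)
  for (b in seq_len(n_bins) - 1L) {
    offs <- seq.int(20L * b, min(20L * b + 19L, glen - 1L))
    gpos <- if (gene$strand == "-") gene$end - 1L - offs else gene$start + offs
    hit <- character(0)
    for (p in gpos)
      hit <- c(hit, usable$rbp[usable$start <= p & usable$end > p])
    truth[b + 1L] <- length(unique(hit))
  }
  truth_hotspots <- data.frame(
    gene_id = gene$gene_id, bin_index = seq_len(n_bins) - 1L,
    n_rbp = truth, stringsAsFactors = FALSE)
  n_feat <- 120L
  kind <- sample(c("miRNA_target", "modification", "editing", "SNV", "GWAS",
                   "somatic"), n_feat, replace = TRUE)
  fstart <- sample(seq.int(gene$start - 100L, gene$end + 100L), n_feat,
                   replace = TRUE)
  fwidth <- ifelse(kind %in% c("SNV", "GWAS", "somatic"), 1L,
                   sample(2:20, n_feat, replace = TRUE))
  features <- data.frame(
    chrom = gene$chrom, start = fstart, end = fstart + fwidth,
    name = sprintf("feat%04d", seq_len(n_feat)), score = "0", strand = ".",
    kind = kind, stringsAsFactors = FALSE)
  sites_path <- file.path(txome$dir, "clip_sites.bed")
  features_path <- file.path(txome$dir, "crosstalk_features.bed")
  utils::write.table(sites, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(features, features_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(sites = sites, features = features, sites_path = sites_path,
       features_path = features_path, gene = gene,
       truth_hotspots = truth_hotspots)
}

#' Simulate a FASTQ file with a known duplication spectrum
#'
#' Draws unique read sequences with geometric multiplicities, shuffles the
#' expanded reads, and writes them as FASTQ. A fraction of reads is given
#' low-quality bases and some reads are shorter than the conventional 13-nt
#' cutoff, so all three preprocessing filters have work to do.
#'
#' @param spec A \code{\link{fixture_spec}} (only the seed is used).
#' @param n_reads Total reads to emit.
#' @param dir Output directory; defaults to a fresh temporary directory.
#' @return List with \code{path}, \code{reads} (the table as written) and
#'   \code{truth}: \code{data.frame(sequence, count)} — the duplication
#'   spectrum.
#' @export
make_fastq <- function(spec = fixture_spec(), n_reads = 10000L, dir = NULL) {
  set.seed(spec$seed + 3003L)
  if (is.null(dir)) dir <- tempfile("ribostar_fastq_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- sample(8:40, n_reads, replace = TRUE)
  seqs <- vapply(lens, rand_dna, "")
  dup <- duplicated(seqs)
  seqs <- seqs[!dup]; lens <- lens[!dup]
  m <- 1L + stats::rgeom(length(seqs), 0.6)
  cum <- cumsum(m)
  k <- which(cum >= n_reads)[1L]
  seqs <- seqs[seq_len(k)]; lens <- lens[seq_len(k)]
  counts <- m[seq_len(k)]
  counts[k] <- counts[k] - (cum[k] - n_reads)
  if (counts[k] == 0L) {
    seqs <- seqs[-k]; lens <- lens[-k]; counts <- counts[-k]
  }
  lowq <- stats::runif(length(seqs)) < 0.15
  quals <- vapply(seq_along(seqs), function(i) {
    score <- if (lowq[i]) sample(3:20, lens[i], replace = TRUE)
             else sample(25:40, lens[i], replace = TRUE)
    intToUtf8(score + 33L)
  }, "")
  total <- sum(counts)
  order_idx <- sample.int(total)
  expand <- rep(seq_along(seqs), counts)[order_idx]
  reads <- data.frame(
    read_id = sprintf("read%05d", seq_len(total)),
    sequence = seqs[expand], quality = quals[expand],
    stringsAsFactors = FALSE)
  attr(reads, "phred_offset") <- 33L
  path <- file.path(dir, "reads.fastq")
  write_fastq(reads, path)
  list(path = path, reads = reads,
       truth = data.frame(sequence = seqs, count = counts,
                          stringsAsFactors = FALSE))
}
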