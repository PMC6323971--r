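# Independent brute-force oracles and small random-input generators.
# These deliberately re-derive results by the most literal method available
# (all-pairs scans, per-base unions) so they share no code path with the
# package implementations they check.

# O(L^2) ORF oracle: every (AUG, stop) pair, keeping the nearest in-frame stop
brute_force_orfs <- function(sequence) {
  seq <- chartr("T", "U", toupper(sequence))
  n <- nchar(seq)
  codon_at <- function(i) substr(seq, i + 1L, i + 3L)
  starts <- integer(0); ends <- integer(0)
  for (i in 0:max(0L, n - 3L)) {
    if (codon_at(i) != "AUG") next
    best <- NA_integer_
    if (i + 3L <= n - 3L) for (j in seq(i + 3L, n - 3L, by = 3L)) {
      if (codon_at(j) %in% c("UAA", "UAG", "UGA")) { best <- j; break }
    }
    if (!is.na(best)) { starts <- c(starts, i); ends <- c(ends, best + 3L) }
  }
  ord <- order(starts, ends)
  data.frame(start = starts[ord], end = ends[ord])
}

random_rna <- function(len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# random multi-exon transcript model on a synthetic chromosome
random_model <- function(id = "TX", chrom = "chrT", n_exons = NULL,
                         strand = NULL) {
  if (is.null(n_exons)) n_exons <- sample(2:5, 1L)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  widths <- sample(5:60, n_exons, replace = TRUE)
  gaps <- sample(1:40, n_exons, replace = TRUE)
  starts <- cumsum(gaps + c(0L, widths[-n_exons]))
  transcript_model(id, chrom, strand,
                   cbind(starts, starts + widths))
}

# per-base distinct-RBP union per bin, in 5'->3' precursor orientation
brute_force_hotspots <- function(sites, gene, bin_width = 20L) {
  glen <- gene$end - gene$start
  ok <- sites$chrom == gene$chrom &
    (sites$strand == gene$strand | sites$strand == ".")
  s <- sites[ok, , drop = FALSE]
  n_bins <- ceiling(glen / bin_width)
  vapply(seq_len(n_bins) - 1L, function(b) {
    offs <- seq.int(bin_width * b, min(bin_width * (b + 1L), glen) - 1L)
    gpos <- if (gene$strand == "-") gene$end - 1L - offs
            else gene$start + offs
    rbps <- character(0)
    for (p in gpos)
      rbps <- c(rbps, s$rbp[s$start <= p & s$end > p])
    length(unique(rbps))
  }, integer(1L))
}

# quadratic all-vs-all interval overlap oracle (point features widened first)
brute_force_overlaps <- function(sites, features) {
  f <- features
  pt <- f$end == f$start
  f$end[pt] <- f$end[pt] + 1L
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(nrow(sites))) {
    hit <- which(f$chrom == sites$chrom[i] &
                   f$start < sites$end[i] & f$end > sites$start[i])
    if (length(hit) > 0L)
      pairs <- rbind(pairs, cbind(i, hit))
  }
  pairs
}

# shared tiny fixture, built once per test run
fixture_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 42L)
      tx <- make_transcriptome(spec)
      cache <<- list(spec = spec, tx = tx)
    }
    cache
  }
})
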