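#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count / (length_nt/1000 * library_size/1e6)}.
#'
#' @param count Read count(s) on the feature (vectorized).
#' @param length_nt Feature length(s) in nucleotides; must be positive.
#' @param library_size Total mapped reads in the library; must be positive.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, length_nt, library_size) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (length_nt / 1000 * library_size / 1e6)
}

#' Translation efficiency
#'
#' TE is the ratio of Ribo-seq RPKM to RNA-seq RPKM over a feature. It is
#' undefined (\code{NA}, never 0 or Inf) where the RNA RPKM is zero.
#'
#' @param ribo_rpkm,rna_rpkm Non-negative numeric vectors.
#' @return Numeric vector of TE values with \code{NA} where
#'   \code{rna_rpkm == 0}.
#' @export
translation_efficiency <- function(ribo_rpkm, rna_rpkm) {
  if (any(ribo_rpkm < 0, na.rm = TRUE) || any(rna_rpkm < 0, na.rm = TRUE))
    stop("RPKM inputs must be non-negative")
  te <- ribo_rpkm / rna_rpkm
  te[rna_rpkm == 0] <- NA_real_
  te
}

#' Translation density of an ORF
#'
#' The summed footprint signal on the ORF divided by the ORF length in nt;
#' computed identically for raw and denoised tracks.
#'
#' @param track Numeric per-nucleotide signal vector for the ORF's transcript.
#' @param start,end ORF interval in 0-based half-open transcript coordinates.
#' @return Signal per nucleotide (numeric scalar).
#' @export
translation_density <- function(track, start, end) {
  if (start < 0L || end > length(track) || end <= start)
    stop("ORF interval [", start, ", ", end, ") outside track bounds [0, ",
         length(track), ")")
  sum(track[(start + 1L):end]) / (end - start)
}

#' Quantify translation per ORF across conditions
#'
#' For every ORF and condition, counts the footprint signal whose P-site falls
#' inside the ORF, computes Ribo-seq RPKM over the ORF and RNA-seq RPKM over
#' its transcript, and derives translation efficiency and translation density.
#' When a condition supplies both a raw and a denoised track, one record per
#' signal source is emitted.
#'
#' @param orfs ORF table from \code{\link{scan_transcriptome}}.
#' @param models Named list of \code{transcript_model} objects (for
#'   transcript lengths).
#' @param ribo_tracks Named list (one element per condition). Each element is
#'   either a track list as returned by \code{\link{build_psite_tracks}}
#'   (taken as \code{raw}) or a named list of such track lists keyed by signal
#'   source (\code{raw}, \code{denoised}).
#' @param rna_counts Named list (one element per condition) of named numeric
#'   vectors: RNA-seq read counts per transcript.
#' @param ribo_library_size,rna_library_size Optional named numeric vectors of
#'   library sizes per condition; by default the number of reads contributing
#'   to the respective track or count table.
#' @param pseudocount Additive pseudocount applied to both ribo and RNA
#'   counts before RPKM, for exploratory use only; 0 (off) by default.
#' @return \code{data.frame} with one row per ORF x condition x signal source:
#'   \code{orf_id}, \code{condition}, \code{signal_source}, \code{ribo_count},
#'   \code{rna_count}, \code{ribo_rpkm}, \code{rna_rpkm}, \code{te},
#'   \code{density}.
#' @export
quantify <- function(orfs, models, ribo_tracks, rna_counts,
                     ribo_library_size = NULL, rna_library_size = NULL,
                     pseudocount = 0) {
  conditions <- names(ribo_tracks)
  if (is.null(conditions) || any(!nzchar(conditions)))
    stop("ribo_tracks must be a named list keyed by condition")
  if (anyDuplicated(conditions))
    stop("duplicated condition label: ",
         paste(unique(conditions[duplicated(conditions)]), collapse = ", "))
  unmatched <- c(setdiff(conditions, names(rna_counts)),
                 setdiff(names(rna_counts), conditions))
  if (length(unmatched) > 0L)
    stop("condition labels do not match between ribo_tracks and rna_counts: ",
         paste(unique(unmatched), collapse = ", "))
  tlen <- vapply(models, transcript_length, integer(1L))
  records <- list()
  for (cond in conditions) {
    sources <- ribo_tracks[[cond]]
    if (!is.list(sources[[1L]])) sources <- list(raw = sources)
    rna <- rna_counts[[cond]]
    rna_lib <- if (!is.null(rna_library_size)) rna_library_size[[cond]]
               else sum(rna)
    for (src in names(sources)) {
      tracks <- sources[[src]]
      ribo_lib <- if (!is.null(ribo_library_size)) ribo_library_size[[cond]]
                  else sum(vapply(tracks, sum, numeric(1L)))
      ribo_count <- mapply(function(tid, s, e) {
        if (!tid %in% names(tracks)) return(0)
        sum(tracks[[tid]][(s + 1L):e])
      }, orfs$transcript_id, orfs$start, orfs$end)
      rna_count <- ifelse(orfs$transcript_id %in% names(rna),
                          rna[orfs$transcript_id], 0)
      ribo_rpkm <- rpkm(ribo_count + pseudocount, orfs$length_nt, ribo_lib)
      rna_rpkm <- rpkm(rna_count + pseudocount, tlen[orfs$transcript_id],
                       rna_lib)
      records[[paste(cond, src)]] <- data.frame(
        orf_id = orfs$orf_id, condition = cond, signal_source = src,
        ribo_count = as.numeric(ribo_count), rna_count = as.numeric(rna_count),
        ribo_rpkm = ribo_rpkm, rna_rpkm = rna_rpkm,
        te = translation_efficiency(ribo_rpkm, rna_rpkm),
        density = as.numeric(ribo_count) / orfs$length_nt,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, c(records, list(make.row.names = FALSE)))
}

#' Write a quantification table to TSV (undefined TE written as NA)
#' @param quant Output of \code{\link{quantify}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_quant <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
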