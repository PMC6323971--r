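#' Read transcript-space alignments from a TSV file
#'
#' The simple tabular alignment format has three columns:
#' \code{transcript_id}, \code{five_prime} (0-based transcript offset of the
#' read 5' end) and \code{read_length} (nt).
#'
#' @param path Path to the TSV (with header).
#' @return \code{data.frame} of aligned reads.
#' @export
read_alignments <- function(path) {
  reads <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  required <- c("transcript_id", "five_prime", "read_length")
  if (!all(required %in% names(reads)))
    stop("alignment TSV must have columns: ", paste(required, collapse = ", "))
  reads
}

#' Write transcript-space alignments to TSV
#' @param reads \code{data.frame} with \code{transcript_id},
#'   \code{five_prime}, \code{read_length}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignments <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert genomic alignments to transcript space
#'
#' Places genomic read alignments onto transcript models. The read 5' end in
#' transcript orientation is the leftmost aligned base for plus-strand models
#' and the rightmost for minus-strand models. A read is kept on a transcript
#' only when both of its terminal bases are exonic and their transcript
#' distance equals \code{read length - 1}, i.e. the read is fully exonic or
#' spliced exactly at the model's junctions; other reads are dropped and
#' counted. A read compatible with several models yields one record each.
#'
#' @param reads \code{data.frame} with columns \code{chrom}, \code{start}
#'   (0-based leftmost aligned base), \code{end} (one past the rightmost),
#'   optionally \code{read_length} (number of aligned bases; defaults to
#'   \code{end - start}, which is only correct for unspliced reads) and
#'   optionally \code{strand}, which must then match the model strand.
#' @param models Named list of \code{transcript_model} objects.
#' @return \code{data.frame} with \code{transcript_id}, \code{five_prime},
#'   \code{read_length}; attributes \code{n_input} and \code{n_placed} record
#'   how many input reads there were and how many placements were emitted.
#' @export
genomic_reads_to_transcript <- function(reads, models) {
  pieces <- lapply(models, function(m) {
    sel <- reads$chrom == m$chrom
    if (!is.null(reads$strand)) sel <- sel & reads$strand == m$strand
    r <- reads[sel, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    tl <- genome_to_transcript(m, r$start)
    tr <- genome_to_transcript(m, r$end - 1L)
    len <- if (!is.null(r$read_length)) r$read_length else r$end - r$start
    five <- if (m$strand == "+") tl else tr
    three <- if (m$strand == "+") tr else tl
    ok <- !is.na(five) & !is.na(three) & (three - five) == (len - 1L)
    if (!any(ok)) return(NULL)
    data.frame(transcript_id = m$transcript_id, five_prime = five[ok],
               read_length = len[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), five_prime = integer(0),
                      read_length = integer(0), stringsAsFactors = FALSE)
  attr(out, "n_input") <- nrow(reads)
  attr(out, "n_placed") <- nrow(out)
  out
}

#' Infer per-read-length P-site offsets from start-codon metagenes
#'
#' For every footprint read whose 5' end lies within \code{window} nt upstream
#' of (or exactly at) an annotated start codon, the 5' distance
#' \code{d = start_codon_position - five_prime} is recorded. The P-site offset
#' for each read length L is the mode of these distances restricted to
#' \code{0 <= d < L}; ties are broken toward the smaller offset, and read
#' lengths supported by fewer than \code{min_support} reads are omitted.
#'
#' @param reads \code{data.frame} of transcript-space reads (see
#'   \code{\link{read_alignments}}).
#' @param models Named list of \code{transcript_model} objects; at least one
#'   must carry an annotated CDS.
#' @param window Metagene window in nt upstream of the start codon (default
#'   40).
#' @param min_support Minimum reads per length (default 10).
#' @return An object of class \code{psite_offsets}: list with integer vectors
#'   \code{offsets} and \code{support}, both named by read length.
#' @export
infer_psite_offsets <- function(reads, models, window = 40L,
                                min_support = 10L) {
  has_cds <- vapply(models, function(m) !is.null(m$cds), logical(1L))
  if (!any(has_cds)) stop("no annotated CDS among the transcript models")
  starts <- vapply(models[has_cds],
                   function(m) cds_transcript_interval(m)[1L], integer(1L))
  empty <- structure(list(offsets = integer(0), support = integer(0)),
                     class = "psite_offsets")
  if (nrow(reads) == 0L) return(empty)
  s <- starts[reads$transcript_id]
  d <- s - reads$five_prime
  keep <- !is.na(d) & d >= 0L & d <= window & d < reads$read_length
  if (!any(keep)) return(empty)
  d <- d[keep]; len <- reads$read_length[keep]
  offsets <- integer(0); support <- integer(0)
  for (L in sort(unique(len))) {
    dL <- d[len == L]
    if (length(dL) < min_support) next
    counts <- table(dL)
    mode_d <- min(as.integer(names(counts)[counts == max(counts)]))
    offsets[as.character(L)] <- mode_d
    support[as.character(L)] <- length(dL)
  }
  structure(list(offsets = offsets, support = support),
            class = "psite_offsets")
}

#' @export
print.psite_offsets <- function(x, ...) {
  cat("<psite_offsets>\n")
  if (length(x$offsets) == 0L) {
    cat("  (empty)\n")
  } else {
    for (L in names(x$offsets))
      cat(sprintf("  length %s nt: offset %d (%d reads)\n", L,
                  x$offsets[[L]], x$support[[L]]))
  }
  invisible(x)
}

#' Build per-transcript P-site signal tracks
#'
#' Each read of length L with an inferred offset contributes one count at
#' transcript position \code{five_prime + offset(L)}. Reads of lengths without
#' an offset entry are skipped; reads whose P-site would fall beyond the
#' transcript 3' end are dropped. Both tallies are attached as attributes.
#' The sum over all tracks equals the number of retained reads.
#'
#' @param reads Transcript-space reads.
#' @param offsets A \code{psite_offsets} object (must be non-empty).
#' @param models Named list of \code{transcript_model} objects; one track is
#'   produced per model, zero-filled where no reads land.
#' @return Named list of numeric vectors (class \code{signal_tracks}) with
#'   attributes \code{source = "psite"}, \code{n_retained},
#'   \code{n_skipped_length}, \code{n_dropped_out_of_bounds}.
#' @export
build_psite_tracks <- function(reads, offsets, models) {
  if (length(offsets$offsets) == 0L) stop("empty P-site offset table")
  tlen <- vapply(models, transcript_length, integer(1L))
  off <- offsets$offsets[as.character(reads$read_length)]
  known_tx <- reads$transcript_id %in% names(models)
  usable <- !is.na(off) & known_tx
  n_skipped <- sum(!usable)
  p <- reads$five_prime[usable] + off[usable]
  tx <- reads$transcript_id[usable]
  inb <- p >= 0L & p < tlen[tx]
  n_oob <- sum(!inb)
  p <- p[inb]; tx <- tx[inb]
  tracks <- lapply(names(models), function(id) {
    v <- numeric(tlen[[id]])
    sel <- tx == id
    if (any(sel)) {
      tab <- tabulate(p[sel] + 1L, nbins = tlen[[id]])
      v <- as.numeric(tab)
    }
    v
  })
  names(tracks) <- names(models)
  structure(tracks, class = "signal_tracks", source = "psite",
            n_retained = length(p), n_skipped_length = n_skipped,
            n_dropped_out_of_bounds = n_oob)
}
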