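#' Enumerate all candidate ORFs on a transcript sequence
#'
#' Scans the spliced sequence 5' to 3' and pairs every AUG with the nearest
#' downstream in-frame stop codon (UAA, UAG or UGA). AUGs without an in-frame
#' stop before the transcript end emit nothing. ORF intervals include the stop
#' codon, so every ORF length is a multiple of 3 and at least 6 nt. Codons
#' containing ambiguous bases (N) never match a start or stop.
#'
#' @param sequence Single character string over the RNA alphabet (T is
#'   tolerated and read as U).
#' @param transcript_id Identifier carried into the output.
#' @return \code{data.frame} with columns \code{transcript_id}, \code{start},
#'   \code{end} (0-based half-open transcript coordinates), \code{frame}
#'   (\code{start mod 3}) and \code{length_nt}, sorted by start then end.
#' @export
enumerate_orfs <- function(sequence, transcript_id = "transcript") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("Tt", "Uu", toupper(sequence))
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      length_nt = integer(0), stringsAsFactors = FALSE)
  if (nchar(seq) < 6L) return(empty)
  find_all <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  aug <- find_all("AUG")
  stops <- sort(c(find_all("UAA"), find_all("UAG"), find_all("UGA")))
  if (length(aug) == 0L || length(stops) == 0L) return(empty)
  out_start <- integer(0); out_end <- integer(0)
  for (f in 0:2) {
    s_f <- aug[aug %% 3L == f]
    t_f <- stops[stops %% 3L == f]
    if (length(s_f) == 0L || length(t_f) == 0L) next
    # index of first in-frame stop at or after start + 3
    idx <- findInterval(s_f + 2L, t_f) + 1L
    ok <- idx <= length(t_f)
    out_start <- c(out_start, s_f[ok])
    out_end <- c(out_end, t_f[idx[ok]] + 3L)
  }
  if (length(out_start) == 0L) return(empty)
  ord <- order(out_start, out_end)
  data.frame(transcript_id = transcript_id, start = out_start[ord],
             end = out_end[ord], frame = out_start[ord] %% 3L,
             length_nt = (out_end - out_start)[ord], stringsAsFactors = FALSE)
}

#' The seven ORF categories
#'
#' Positional classes of a candidate ORF relative to the transcript's
#' annotated ORF (aORF): \code{annotated} (identical to the aORF),
#' \code{truncated}/\code{extended} (same stop codon, start downstream/
#' upstream of the aORF start), \code{internal} (overlapping the aORF without
#' sharing its stop, necessarily off-frame or differently terminated),
#' \code{uorf}/\code{dorf} (entirely upstream/downstream of the aORF) and
#' \code{unannotated} (any ORF on a transcript without a reference CDS).
#'
#' @export
ORF_CATEGORIES <- c("annotated", "truncated", "extended", "internal",
                    "uorf", "dorf", "unannotated")

#' Categorize enumerated ORFs against a transcript's annotated ORF
#'
#' Applies a fixed decision cascade so that the seven categories of
#' \code{\link{ORF_CATEGORIES}} partition the enumeration output:
#' no annotated CDS on the transcript -> \code{unannotated}; identical
#' interval -> \code{annotated}; shared stop codon -> \code{truncated} or
#' \code{extended} by start side; any remaining overlap of at least 1 nt ->
#' \code{internal}; otherwise \code{uorf} or \code{dorf} by position.
#' Upstream and downstream ORFs therefore never overlap the aORF.
#'
#' @param orfs Output of \code{\link{enumerate_orfs}} for this transcript.
#' @param model The matching \code{\link{transcript_model}}.
#' @return Character vector of categories, one per ORF row.
#' @export
categorize_orfs <- function(orfs, model) {
  n <- nrow(orfs)
  if (n == 0L) return(character(0))
  tlen <- transcript_length(model)
  if (any(orfs$start < 0L | orfs$end > tlen))
    stop("ORF out of transcript bounds on ", model$transcript_id)
  aorf <- cds_transcript_interval(model)
  if (is.null(aorf)) return(rep("unannotated", n))
  s <- orfs$start; e <- orfs$end
  out <- character(n)
  same_stop <- e == aorf[2L]
  out[same_stop & s == aorf[1L]] <- "annotated"
  out[same_stop & s > aorf[1L]] <- "truncated"
  out[same_stop & s < aorf[1L]] <- "extended"
  rest <- !same_stop
  overlap <- rest & s < aorf[2L] & e > aorf[1L]
  out[overlap] <- "internal"
  out[rest & e <= aorf[1L]] <- "uorf"
  out[rest & s >= aorf[2L]] <- "dorf"
  out
}

#' Enumerate and categorize ORFs across a transcriptome
#'
#' Runs \code{\link{enumerate_orfs}} and \code{\link{categorize_orfs}} on
#' every transcript model and flags small ORFs (sORFs), i.e. ORFs shorter
#' than \code{sorf_threshold} nucleotides (stop codon included).
#'
#' @param models Named list of \code{transcript_model} objects.
#' @param genome A \code{DNAStringSet} genome (see \code{\link{read_genome}}).
#' @param sorf_threshold sORF length cutoff in nt; the conventional value is
#'   300.
#' @param verbose Report per-category counts with \code{message()}.
#' @return \code{data.frame} with columns \code{orf_id}, \code{transcript_id},
#'   \code{gene_id}, \code{start}, \code{end}, \code{frame}, \code{category},
#'   \code{length_nt}, \code{is_sorf}.
#' @export
scan_transcriptome <- function(models, genome, sorf_threshold = 300L,
                               verbose = TRUE) {
  per_tx <- lapply(models, function(m) {
    orfs <- enumerate_orfs(extract_sequence(m, genome), m$transcript_id)
    orfs$category <- categorize_orfs(orfs, m)
    orfs$gene_id <- rep(m$gene_id, nrow(orfs))
    orfs
  })
  out <- if (length(per_tx) > 0L)
    do.call(rbind, c(per_tx, list(make.row.names = FALSE))) else NULL
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(orf_id = character(0), transcript_id = character(0),
                      gene_id = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      category = character(0), length_nt = integer(0),
                      is_sorf = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  out$is_sorf <- out$length_nt < sorf_threshold
  out$orf_id <- sprintf("%s:%d-%d:%s", out$transcript_id, out$start, out$end,
                        out$category)
  out <- out[, c("orf_id", "transcript_id", "gene_id", "start", "end",
                 "frame", "category", "length_nt", "is_sorf")]
  if (verbose) {
    counts <- table(factor(out$category, levels = ORF_CATEGORIES))
    message("scan_transcriptome: ", nrow(out), " ORFs (",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", "), ")")
  }
  out
}

#' Write an ORF table to TSV
#' @param orfs Output of \code{\link{scan_transcriptome}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_orfs <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ORF table written by \code{\link{write_orfs}}
#' @param path Path to the TSV.
#' @return \code{data.frame} of ORFs.
#' @export
read_orfs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
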