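#' Read a FASTQ file into a read table
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @param phred_offset Phred encoding offset, 33 (default) or 64; stored as an
#'   attribute and used by \code{\link{quality_filter}}.
#' @return \code{data.frame} with columns \code{read_id}, \code{sequence},
#'   \code{quality} (the raw quality string).
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  reads <- data.frame(
    read_id = if (is.null(names(x))) paste0("read", seq_along(x))
              else sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(reads, "phred_offset") <- phred_offset
  reads
}

#' Write a read table to FASTQ
#'
#' @param reads Read table (see \code{\link{read_fastq}}); an optional
#'   \code{count} column from \code{\link{collapse_duplicates}} is appended to
#'   the read id as \code{ id:count=N}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$read_id
  if (!is.null(reads$count)) ids <- sprintf("%s:count=%d", ids, reads$count)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

phred_offset_of <- function(reads, default = 33L) {
  off <- attr(reads, "phred_offset")
  if (is.null(off)) default else off
}

#' Filter reads on per-base quality
#'
#' A read passes when the fraction of its bases with a Phred quality score
#' strictly above \code{q} is at least \code{fraction} (defaults: above Q20
#' in 80 percent of the nucleotides). A 10-base read with exactly 8 bases
#' above Q20 therefore passes; a read whose bases are all exactly Q20 fails.
#'
#' @param reads Read table (see \code{\link{read_fastq}}).
#' @param q Quality threshold (strict inequality).
#' @param fraction Minimum passing-base fraction (non-strict inequality).
#' @param phred_offset Phred encoding offset; defaults to the table's
#'   attribute or 33.
#' @return The passing subset of \code{reads}.
#' @export
quality_filter <- function(reads, q = 20L, fraction = 0.80,
                           phred_offset = phred_offset_of(reads)) {
  if (nrow(reads) == 0L) return(reads)
  if (any(nchar(reads$quality) != nchar(reads$sequence)))
    stop("quality and sequence lengths differ at read ",
         reads$read_id[which(nchar(reads$quality) !=
                               nchar(reads$sequence))[1L]])
  pass <- vapply(reads$quality, function(qs) {
    scores <- utf8ToInt(qs) - phred_offset
    mean(scores > q) >= fraction
  }, logical(1L), USE.NAMES = FALSE)
  keep_attrs(reads[pass, , drop = FALSE], reads)
}

#' Filter reads on minimum length
#'
#' Retains reads of at least \code{min_len} nucleotides (reads shorter than
#' 13 nt after adaptor trimming are conventionally discarded).
#'
#' @param reads Read table.
#' @param min_len Minimum length in nt.
#' @return The passing subset of \code{reads}.
#' @export
length_filter <- function(reads, min_len = 13L) {
  keep_attrs(reads[nchar(reads$sequence) >= min_len, , drop = FALSE], reads)
}

#' Collapse exact duplicate reads
#'
#' Keeps one representative per distinct sequence (the first occurrence's id
#' and qualities, input order preserved) and records the multiplicity, so
#' that PCR duplicates contribute a single record. The multiplicities sum to
#' the input read count.
#'
#' @param reads Read table.
#' @return The unique subset of \code{reads} with an added integer
#'   \code{count} column.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0L) {
    reads$count <- integer(0)
    return(reads)
  }
  first <- !duplicated(reads$sequence)
  out <- reads[first, , drop = FALSE]
  out$count <- tabulate(match(reads$sequence, out$sequence), nbins = nrow(out))
  keep_attrs(out, reads)
}

keep_attrs <- function(subset, original) {
  attr(subset, "phred_offset") <- attr(original, "phred_offset")
  rownames(subset) <- NULL
  subset
}
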