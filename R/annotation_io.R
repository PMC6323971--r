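#' Read a genome FASTA file
#'
#' Loads chromosome sequences into a \code{DNAStringSet}. Sequence names are
#' truncated at the first whitespace so that GTF \code{seqname} fields match
#' FASTA headers carrying a description.
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(Biostrings::width(genome) == 0L))
    stop("zero-length sequence in genome FASTA: ",
         paste(names(genome)[Biostrings::width(genome) == 0L], collapse = ", "))
  genome
}

#' Construct a transcript model
#'
#' A transcript model is the coordinate backbone of the package: the ordered
#' exon structure of one isoform plus, optionally, the genomic span of its
#' annotated ORF (aORF). All internal coordinates are 0-based half-open;
#' transcript coordinates always run 5' to 3' regardless of genomic strand.
#'
#' @param transcript_id,gene_id,gene_name Identifiers; \code{gene_id} and
#'   \code{gene_name} default to \code{transcript_id}.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column integer matrix (start, end) of genomic exon
#'   intervals, 0-based half-open. Rows may be given in any order; they are
#'   sorted by genomic start and must not overlap.
#' @param cds Optional integer pair \code{c(start, end)}: the genomic span from
#'   the first to one past the last base of the annotated ORF (stop codon
#'   included). Must lie within the exon union and have a spliced length that
#'   is a positive multiple of 3.
#' @param biotype Optional transcript biotype string (e.g. from the GTF
#'   \code{transcript_type} attribute); used for element assignment.
#' @return An object of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, cds = NULL,
                             gene_id = transcript_id, gene_name = gene_id,
                             biotype = NA_character_) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in transcript ", transcript_id)
  model <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_name = gene_name, chrom = chrom, strand = strand,
         exons = exons, cds = NULL, biotype = biotype),
    class = "transcript_model")
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    stopifnot(length(cds) == 2L, cds[2L] > cds[1L])
    splen <- spliced_overlap_length(exons, cds[1L], cds[2L])
    if (splen == 0L || splen %% 3L != 0L)
      stop("CDS spliced length ", splen, " is not a positive multiple of 3 (",
           transcript_id, ")")
    model$cds <- cds
    # both endpoints must be exonic so the transcript-space interval is defined
    ends <- genome_to_transcript(model, c(cds[1L], cds[2L] - 1L))
    if (anyNA(ends)) stop("CDS endpoints fall outside exons (", transcript_id, ")")
  }
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s\n", x$transcript_id,
              x$gene_name, x$chrom,
              paste0(min(x$exons[, 1L]), "-", max(x$exons[, 2L])), x$strand))
  cat(sprintf("  %d exon(s), spliced length %d nt, %s\n", nrow(x$exons),
              transcript_length(x),
              if (is.null(x$cds)) "no annotated CDS"
              else sprintf("CDS %d-%d", x$cds[1L], x$cds[2L])))
  invisible(x)
}

# spliced (exonic) length of a genomic interval [start, end) on an exon matrix
spliced_overlap_length <- function(exons, start, end) {
  sum(pmax(0L, pmin(exons[, 2L], end) - pmax(exons[, 1L], start)))
}

#' Spliced length of a transcript
#' @param model A \code{transcript_model}.
#' @return Integer number of exonic nucleotides.
#' @export
transcript_length <- function(model) {
  sum(model$exons[, 2L] - model$exons[, 1L])
}

#' Map genomic positions to transcript coordinates
#'
#' Transcript coordinates are 0-based offsets counted from the transcript 5'
#' end; on minus-strand models offset 0 is the genomically rightmost exonic
#' base. Intronic or out-of-model positions map to \code{NA} (an absent
#' result is a value, not an error).
#'
#' @param model A \code{transcript_model}.
#' @param genomic_position Integer vector of 0-based genomic positions.
#' @return Integer vector of transcript offsets, \code{NA} where non-exonic.
#' @export
genome_to_transcript <- function(model, genomic_position) {
  gpos <- as.integer(genomic_position)
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  idx <- findInterval(gpos, ex[, 1L])
  ok <- idx >= 1L & gpos < ex[pmax(idx, 1L), 2L] & gpos >= 0L
  plus_off <- rep(NA_integer_, length(gpos))
  plus_off[ok] <- before[idx[ok]] + gpos[ok] - ex[idx[ok], 1L]
  if (model$strand == "-") transcript_length(model) - 1L - plus_off else plus_off
}

#' Map transcript offsets back to genomic positions
#'
#' Inverse of \code{\link{genome_to_transcript}}; the round trip is the
#' identity on every exonic base.
#'
#' @param model A \code{transcript_model}.
#' @param transcript_position Integer vector of 0-based transcript offsets.
#' @return Integer vector of 0-based genomic positions.
#' @export
transcript_to_genome <- function(model, transcript_position) {
  tpos <- as.integer(transcript_position)
  tlen <- transcript_length(model)
  if (any(tpos < 0L | tpos >= tlen))
    stop("transcript position out of range [0, ", tlen, ")")
  plus_off <- if (model$strand == "-") tlen - 1L - tpos else tpos
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  idx <- findInterval(plus_off, before)
  ex[idx, 1L] + plus_off - before[idx]
}

#' Project a transcript interval onto the genome
#'
#' Splits a 0-based half-open transcript interval into the genomic blocks it
#' occupies (one block per exon crossed), returned in genomic order.
#'
#' @param model A \code{transcript_model}.
#' @param start,end Transcript interval, 0-based half-open.
#' @return Integer matrix with columns \code{start}, \code{end}.
#' @export
transcript_interval_to_genome <- function(model, start, end) {
  stopifnot(end > start, start >= 0L, end <= transcript_length(model))
  gpos <- sort(transcript_to_genome(model, seq.int(start, end - 1L)))
  breaks <- which(diff(gpos) != 1L)
  bstart <- gpos[c(1L, breaks + 1L)]
  bend <- gpos[c(breaks, length(gpos))] + 1L
  cbind(start = bstart, end = bend)
}

#' Transcript-space interval of the annotated ORF
#'
#' @param model A \code{transcript_model} with a CDS.
#' @return Integer pair \code{c(start, end)}, 0-based half-open in transcript
#'   coordinates (stop codon included), or \code{NULL} when the model has no
#'   annotated CDS.
#' @export
cds_transcript_interval <- function(model) {
  if (is.null(model$cds)) return(NULL)
  t1 <- genome_to_transcript(model, model$cds[1L])
  t2 <- genome_to_transcript(model, model$cds[2L] - 1L)
  c(min(t1, t2), max(t1, t2) + 1L)
}

#' Extract the spliced transcript sequence
#'
#' Concatenates exon sequences in genomic order, reverse-complements for
#' minus-strand models, and reports the result 5' to 3' in the RNA alphabet
#' (T transcribed to U) by default.
#'
#' @param model A \code{transcript_model}.
#' @param genome A named \code{DNAStringSet} (see \code{\link{read_genome}}).
#' @param alphabet \code{"rna"} (default) or \code{"dna"}.
#' @return A single character string of length \code{transcript_length(model)}.
#' @export
extract_sequence <- function(model, genome, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " missing from genome")
  chrom <- genome[[model$chrom]]
  if (max(model$exons[, 2L]) > length(chrom))
    stop("exon exceeds length of chromosome ", model$chrom, " (",
         model$transcript_id, ")")
  pieces <- Biostrings::DNAStringSet(
    chrom, start = model$exons[, 1L] + 1L, end = model$exons[, 2L])
  spliced <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (model$strand == "-") spliced <- Biostrings::reverseComplement(spliced)
  out <- toupper(as.character(spliced))
  if (alphabet == "rna") chartr("T", "U", out) else out
}

#' Extract spliced sequences for a set of transcript models
#'
#' @param models A named list of \code{transcript_model} objects.
#' @inheritParams extract_sequence
#' @return Named character vector, one sequence per transcript.
#' @export
extract_sequences <- function(models, genome, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  vapply(models, extract_sequence, character(1L),
         genome = genome, alphabet = alphabet)
}

# ---- GTF I/O ---------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, ' "([^"]*)"')
  hit <- regexpr(pat, attrs)
  out <- rep(NA_character_, length(attrs))
  out[hit > 0L] <- sub(pat, "\\1", regmatches(attrs, hit))
  out
}

#' Parse a GTF annotation into transcript models
#'
#' Reads \code{exon}, \code{CDS} and (gencode dialect) \code{stop_codon}
#' features and assembles one \code{\link{transcript_model}} per
#' \code{transcript_id}. GTF 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention on read.
#'
#' The \code{gencode} dialect follows Gencode conventions where CDS records
#' exclude the stop codon: \code{stop_codon} features are appended to the CDS
#' span so that the stored aORF interval always includes its stop codon. The
#' \code{generic} dialect uses CDS lines as-is.
#'
#' Transcripts whose merged CDS has a spliced length that is not a positive
#' multiple of 3 are kept, but their CDS is dropped with a warning, leaving
#' them eligible only for unannotated ORFs.
#'
#' @param path Path to a GTF file.
#' @param dialect \code{"gencode"} (default) or \code{"generic"}.
#' @return Named list of \code{transcript_model} objects (names are
#'   transcript ids, in order of first appearance).
#' @export
parse_gtf <- function(path, dialect = c("gencode", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF: expected 9 tab-separated fields at line ",
         lineno[which(nf != 9L)[1L]])
  tab <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L),
    lineno = lineno, stringsAsFactors = FALSE)
  used <- tab$feature %in% c("exon", "CDS", "stop_codon")
  tab <- tab[used, , drop = FALSE]
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  if (anyNA(tab$start) || anyNA(tab$end))
    stop("malformed GTF: non-numeric coordinate at line ",
         tab$lineno[which(is.na(tab$start) | is.na(tab$end))[1L]])
  tid <- gtf_attr(tab$attrs, "transcript_id")
  if (anyNA(tid))
    stop("malformed GTF attributes: missing transcript_id at line ",
         tab$lineno[which(is.na(tid))[1L]])
  gid <- gtf_attr(tab$attrs, "gene_id")
  gname <- gtf_attr(tab$attrs, "gene_name")
  btype <- gtf_attr(tab$attrs, "transcript_type")
  # 1-based inclusive -> 0-based half-open
  tab$start <- tab$start - 1L
  models <- list()
  for (id in unique(tid)) {
    rows <- tab[tid == id, , drop = FALSE]
    exr <- rows[rows$feature == "exon", , drop = FALSE]
    if (nrow(exr) == 0L)
      stop("transcript ", id, " has CDS but no exon features")
    cds_feats <- if (dialect == "gencode") c("CDS", "stop_codon") else "CDS"
    cdr <- rows[rows$feature %in% cds_feats, , drop = FALSE]
    cds <- if (nrow(cdr[cdr$feature == "CDS", , drop = FALSE]) > 0L)
      c(min(cdr$start), max(cdr$end)) else NULL
    exons <- cbind(exr$start, exr$end)
    if (!is.null(cds)) {
      splen <- spliced_overlap_length(
        exons[order(exons[, 1L]), , drop = FALSE], cds[1L], cds[2L])
      if (splen %% 3L != 0L || splen == 0L) {
        warning("transcript ", id, ": CDS spliced length ", splen,
                " is not a multiple of 3; dropping CDS annotation",
                call. = FALSE)
        cds <- NULL
      }
    }
    i1 <- which(tid == id)[1L]
    models[[id]] <- transcript_model(
      transcript_id = id, chrom = rows$chrom[1L], strand = rows$strand[1L],
      exons = exons, cds = cds,
      gene_id = if (is.na(gid[i1])) id else gid[i1],
      gene_name = if (is.na(gname[i1])) id else gname[i1],
      biotype = btype[i1])
  }
  models
}

#' Write transcript models to a GTF file
#'
#' Emits \code{exon}, \code{CDS} and (gencode dialect) \code{stop_codon}
#' features, converting back to 1-based inclusive coordinates.
#' \code{parse_gtf(write_gtf(models))} reproduces the models.
#'
#' @param models Named list of \code{transcript_model} objects.
#' @param path Output path.
#' @param dialect \code{"gencode"} (stop codon written as a separate
#'   \code{stop_codon} feature, excluded from CDS records) or \code{"generic"}
#'   (CDS records cover the full aORF including its stop).
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(models, path, dialect = c("gencode", "generic")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(m, feature, gstart, gend)
    sprintf(paste0("%s\tribostar\t%s\t%d\t%d\t.\t%s\t.\t",
                   'gene_id "%s"; transcript_id "%s"; gene_name "%s";%s'),
            m$chrom, feature, gstart + 1L, gend, m$strand,
            m$gene_id, m$transcript_id, m$gene_name,
            if (is.na(m$biotype)) "" else
              sprintf(' transcript_type "%s";', m$biotype))
  for (m in models) {
    for (i in seq_len(nrow(m$exons)))
      writeLines(fmt(m, "exon", m$exons[i, 1L], m$exons[i, 2L]), con)
    if (!is.null(m$cds)) {
      ct <- cds_transcript_interval(m)
      if (dialect == "gencode") {
        body <- transcript_interval_to_genome(m, ct[1L], ct[2L] - 3L)
        stopc <- transcript_interval_to_genome(m, ct[2L] - 3L, ct[2L])
        for (i in seq_len(nrow(body)))
          writeLines(fmt(m, "CDS", body[i, 1L], body[i, 2L]), con)
        for (i in seq_len(nrow(stopc)))
          writeLines(fmt(m, "stop_codon", stopc[i, 1L], stopc[i, 2L]), con)
      } else {
        blocks <- transcript_interval_to_genome(m, ct[1L], ct[2L])
        for (i in seq_len(nrow(blocks)))
          writeLines(fmt(m, "CDS", blocks[i, 1L], blocks[i, 2L]), con)
      }
    }
  }
  invisible(path)
}
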