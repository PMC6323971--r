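#' Read a BED6(+) file
#'
#' Parses BED with the native 0-based half-open convention. At least six
#' columns are required; extra columns can be named via \code{extra_cols}.
#'
#' @param path Path to the BED file.
#' @param extra_cols Character vector naming columns after the sixth.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand} and any extras.
#' @export
read_bed <- function(path, extra_cols = character(0)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  cols <- c("chrom", "start", "end", "name", "score", "strand", extra_cols)
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols), stringsAsFactors = FALSE)
    out$start <- integer(0); out$end <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < length(cols)))
    stop("malformed BED: expected at least ", length(cols),
         " fields at line ", lineno[which(nf < length(cols))[1L]])
  out <- as.data.frame(lapply(seq_along(cols), function(i)
    vapply(fields, `[[`, "", i)), stringsAsFactors = FALSE)
  names(out) <- cols
  start <- suppressWarnings(as.integer(out$start))
  end <- suppressWarnings(as.integer(out$end))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0L)
    stop("malformed BED: bad coordinates at line ", lineno[bad[1L]])
  out$start <- start; out$end <- end
  out
}

#' Read RBP binding sites from BED6+3
#'
#' Binding sites are BED6 records with three extra columns: \code{rbp}
#' (protein name), \code{method} (peak-calling label) and \code{sample}.
#'
#' @param path Path to the BED6+3 file.
#' @return \code{data.frame} of binding sites.
#' @export
read_binding_sites <- function(path) {
  read_bed(path, extra_cols = c("rbp", "method", "sample"))
}

#' Read crosstalk/variation features from BED6+1
#'
#' Feature tracks (miRNA target sites, RNA modification sites, editing sites,
#' SNVs, GWAS and somatic variants) are BED6 records with a seventh
#' \code{kind} column.
#'
#' @param path Path to the BED6+1 file.
#' @return \code{data.frame} of features.
#' @export
read_features <- function(path) {
  read_bed(path, extra_cols = "kind")
}

#' RBP-binding hotspots along a gene precursor
#'
#' Partitions the unspliced gene span (the precursor, introns included) into
#' consecutive 20-nt bins anchored at the gene 5' end in transcription
#' orientation (the final partial bin is retained) and counts, per bin, the
#' number of DISTINCT RBPs with at least one binding site overlapping the bin
#' by >= 1 nt. Peaks are pooled across methods and samples by default, so
#' duplicated site records never inflate a count. Only strand-matched sites
#' are used (site strand \code{"."} matches both); sites on another
#' chromosome are skipped and tallied.
#'
#' @param sites Binding-site \code{data.frame}
#'   (see \code{\link{read_binding_sites}}).
#' @param gene List with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open precursor span) and \code{strand}.
#' @param bin_width Bin width in nt (default 20).
#' @param distinct_by \code{"rbp"} (default) or \code{c("rbp", "sample")}:
#'   the key defining a distinct binder.
#' @return \code{data.frame} with \code{gene_id}, \code{bin_index} (0-based),
#'   \code{bin_start}, \code{bin_end} (precursor offsets, 5' anchored) and
#'   \code{n_rbp}; attribute \code{n_skipped_chrom} counts skipped sites.
#' @export
compute_hotspots <- function(sites, gene, bin_width = 20L,
                             distinct_by = "rbp") {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(gene)))
  glen <- gene$end - gene$start
  n_bins <- ceiling(glen / bin_width)
  prof <- data.frame(
    gene_id = gene$gene_id, bin_index = seq_len(n_bins) - 1L,
    bin_start = (seq_len(n_bins) - 1L) * bin_width,
    bin_end = pmin(seq_len(n_bins) * bin_width, glen),
    n_rbp = 0L, stringsAsFactors = FALSE)
  on_chrom <- sites$chrom == gene$chrom
  n_skipped <- sum(!on_chrom)
  s <- sites[on_chrom & (sites$strand == gene$strand | sites$strand == "."),
             , drop = FALSE]
  # clip to the precursor, then express in 5'->3' precursor offsets
  lo_g <- pmax(s$start, gene$start)
  hi_g <- pmin(s$end, gene$end)
  ok <- hi_g > lo_g
  s <- s[ok, , drop = FALSE]; lo_g <- lo_g[ok]; hi_g <- hi_g[ok]
  if (nrow(s) > 0L) {
    if (gene$strand == "-") {
      lo <- gene$end - hi_g
      hi <- gene$end - lo_g
    } else {
      lo <- lo_g - gene$start
      hi <- hi_g - gene$start
    }
    key <- do.call(paste, c(unname(s[distinct_by]), list(sep = "\r")))
    b0 <- lo %/% bin_width
    b1 <- (hi - 1L) %/% bin_width
    reps <- b1 - b0 + 1L
    bins <- unlist(mapply(seq.int, b0, b1, SIMPLIFY = FALSE))
    keys <- rep(key, reps)
    pairs <- unique(data.frame(bin = bins, key = keys,
                               stringsAsFactors = FALSE))
    counts <- table(factor(pairs$bin, levels = prof$bin_index))
    prof$n_rbp <- as.integer(counts)
  }
  attr(prof, "bin_width") <- bin_width
  attr(prof, "n_skipped_chrom") <- n_skipped
  prof
}

#' Default genomic-element priority for site assignment
#' @export
ELEMENT_PRIORITY <- c("CDS", "3'UTR", "5'UTR", "lncRNA_exon", "other_exon",
                      "intron", "intergenic")

# decompose a set of transcript models into labeled genomic element intervals
element_table <- function(models) {
  pieces <- lapply(models, function(m) {
    ex <- m$exons
    rows <- list()
    if (nrow(ex) > 1L) {
      introns <- cbind(ex[-nrow(ex), 2L], ex[-1L, 1L], deparse.level = 0)
      rows$intron <- introns[introns[, 2L] > introns[, 1L], , drop = FALSE]
    }
    if (!is.null(m$cds)) {
      cs <- m$cds
      cds_blk <- cbind(pmax(ex[, 1L], cs[1L]), pmin(ex[, 2L], cs[2L]))
      rows$CDS <- cds_blk[cds_blk[, 2L] > cds_blk[, 1L], , drop = FALSE]
      left <- cbind(ex[, 1L], pmin(ex[, 2L], cs[1L]))
      left <- left[left[, 2L] > left[, 1L], , drop = FALSE]
      right <- cbind(pmax(ex[, 1L], cs[2L]), ex[, 2L])
      right <- right[right[, 2L] > right[, 1L], , drop = FALSE]
      if (m$strand == "+") {
        rows[["5'UTR"]] <- left; rows[["3'UTR"]] <- right
      } else {
        rows[["3'UTR"]] <- left; rows[["5'UTR"]] <- right
      }
    } else {
      label <- if (!is.na(m$biotype) &&
                   grepl("lnc|linc|antisense|non_?coding", m$biotype,
                         ignore.case = TRUE)) "lncRNA_exon" else "other_exon"
      rows[[label]] <- ex
    }
    rows <- rows[vapply(rows, nrow, integer(1L)) > 0L]
    if (length(rows) == 0L) return(NULL)
    data.frame(chrom = m$chrom, strand = m$strand,
               start = unlist(lapply(rows, `[`, , 1L), use.names = FALSE),
               end = unlist(lapply(rows, `[`, , 2L), use.names = FALSE),
               label = rep(names(rows), vapply(rows, nrow, integer(1L))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Assign binding sites to genomic elements
#'
#' Labels each site with the highest-priority annotation element it overlaps
#' by >= 1 nt across all transcript models (strand-matched; site strand
#' \code{"."} overlaps both strands). Sites overlapping nothing are
#' \code{"intergenic"}. With several isoforms the priority list makes the
#' assignment deterministic, e.g. a site in one isoform's 3'UTR and another's
#' intron is a 3'UTR site under the default priority.
#'
#' @param sites Binding-site \code{data.frame}.
#' @param models Named list of \code{transcript_model} objects.
#' @param priority Character vector ordering the element labels from the
#'   default \code{\link{ELEMENT_PRIORITY}}.
#' @return Character vector of element labels, one per site.
#' @export
assign_elements <- function(sites, models, priority = ELEMENT_PRIORITY) {
  stopifnot(all(c("CDS", "intron", "intergenic") %in% priority))
  n <- nrow(sites)
  out <- rep("intergenic", n)
  elems <- element_table(models)
  if (is.null(elems) || n == 0L) return(out)
  sgr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(sites$start + 1L, sites$end),
    strand = ifelse(sites$strand == ".", "*", sites$strand))
  egr <- GenomicRanges::GRanges(
    elems$chrom, IRanges::IRanges(elems$start + 1L, elems$end),
    strand = elems$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(sgr, egr))
  if (length(hits) > 0L) {
    rank <- match(elems$label[S4Vectors::subjectHits(hits)], priority)
    best <- tapply(rank, S4Vectors::queryHits(hits), min)
    out[as.integer(names(best))] <- priority[as.integer(best)]
  }
  out
}

#' Intersect binding sites with crosstalk and variation tracks
#'
#' Reports every (site, feature) pair that overlaps by at least one
#' nucleotide under the half-open convention (features that merely abut a
#' site produce no pair). Zero-width records (point features such as SNVs
#' given with \code{end == start}) are treated as 1-nt intervals. Strand is
#' ignored: variant and modification tracks annotate genomic positions.
#'
#' @param sites Binding-site \code{data.frame}
#'   (see \code{\link{read_binding_sites}}).
#' @param features Feature \code{data.frame} (see \code{\link{read_features}});
#'   the \code{kind} column carries labels such as \code{miRNA_target},
#'   \code{modification}, \code{editing}, \code{SNV}, \code{GWAS},
#'   \code{somatic}.
#' @return \code{data.frame} with one row per overlapping pair, carrying the
#'   site columns prefixed \code{site_} and the feature columns prefixed
#'   \code{feature_}, plus \code{overlap_nt}.
#' @export
intersect_tracks <- function(sites, features) {
  f <- features
  pt <- f$end == f$start
  f$end[pt] <- f$end[pt] + 1L
  empty <- function() {
    out <- data.frame(site_index = integer(0), feature_index = integer(0))
    out
  }
  if (nrow(sites) == 0L || nrow(f) == 0L) {
    res <- empty()
  } else {
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$start + 1L,
                                                   sites$end))
    fgr <- GenomicRanges::GRanges(f$chrom,
                                  IRanges::IRanges(f$start + 1L, f$end))
    # disjoint chromosome sets are a legitimate no-overlap case, not a
    # user-facing condition
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(sgr, fgr, ignore.strand = TRUE))
    res <- data.frame(site_index = S4Vectors::queryHits(hits),
                      feature_index = S4Vectors::subjectHits(hits))
  }
  si <- sites[res$site_index, , drop = FALSE]
  fi <- f[res$feature_index, , drop = FALSE]
  names(si) <- paste0("site_", names(si))
  names(fi) <- paste0("feature_", names(fi))
  out <- cbind(si, fi, row.names = NULL)
  out$overlap_nt <- if (nrow(out) > 0L)
    pmin(si$site_end, fi$feature_end) - pmax(si$site_start, fi$feature_start)
  else integer(0)
  out
}
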