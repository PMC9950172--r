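#' Junction count table
#'
#' Split-read counts per (chrom, donor, acceptor, strand, sample). The intron
#' interval convention is 0-based half-open: \code{donor_pos} is the genomic
#' coordinate of the first intronic base and \code{acceptor_pos} is one past
#' the last intronic base.
#'
#' @param df data.frame with columns \code{chrom}, \code{donor_pos},
#'   \code{acceptor_pos}, \code{strand}, \code{sample}, \code{count}.
#' @return an object of class \code{junction_counts}.
#' @export
junction_counts <- function(df) {
  required <- c("chrom", "donor_pos", "acceptor_pos", "strand", "sample", "count")
  .check(all(required %in% names(df)), "junction table needs columns: %s",
         paste(required, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df)) {
    .check(all(df$donor_pos < df$acceptor_pos), "donor_pos must be < acceptor_pos")
    .check(all(df$count >= 0), "counts must be non-negative")
  }
  # collapse duplicate keys
  key <- paste(df$chrom, df$donor_pos, df$acceptor_pos, df$strand, df$sample)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(count ~ chrom + donor_pos + acceptor_pos + strand + sample,
                            data = df, FUN = sum)
    df <- agg
  }
  df <- df[order(df$sample, df$chrom, df$donor_pos, df$acceptor_pos),
           required, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("junction_counts", "data.frame")
  df
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d junction-sample rows, %d sample(s)\n",
              nrow(x), length(unique(x$sample))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Extract splice junctions from spliced alignments
#'
#' Reads a SAM (or BAM) file of spliced RNA alignments and counts, per sample,
#' the split reads supporting each exon-exon junction: every N operation in a
#' primary, non-duplicate alignment's CIGAR contributes one junction
#' observation, so a read spanning two introns contributes two observations.
#' Unmapped, secondary and duplicate records are skipped.
#'
#' @param sam_file path to a SAM or BAM file with \code{@SQ} header lines.
#' @param sample sample identifier attached to the counts.
#' @param min_mapq minimum mapping quality; default 0 (no filter).
#' @return a \code{\link{junction_counts}} table.
#' @export
extract_junctions <- function(sam_file, sample, min_mapq = 0) {
  bam <- sam_file
  if (grepl("\\.sam$", sam_file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_file, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  jx <- unlist(GenomicAlignments::junctions(gal))   # introns, 1-based inclusive
  if (length(jx) == 0) {
    return(junction_counts(data.frame(chrom = character(0), donor_pos = integer(0),
                                      acceptor_pos = integer(0), strand = character(0),
                                      sample = character(0), count = integer(0))))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(jx)),
    donor_pos = GenomicRanges::start(jx) - 1L,
    acceptor_pos = GenomicRanges::end(jx),
    strand = "+",
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df[c("chrom", "donor_pos", "acceptor_pos", "strand")],
                          FUN = sum)
  agg$sample <- sample
  junction_counts(agg)
}

#' Read a junction-count TSV
#'
#' @param path TSV with header columns \code{chrom}, \code{donor_pos},
#'   \code{acceptor_pos}, \code{strand}, \code{sample}, \code{count}.
#' @return a \code{\link{junction_counts}} table.
#' @export
read_junction_tsv <- function(path) {
  junction_counts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a junction-count table to TSV
#' @param jc a \code{\link{junction_counts}} table.
#' @param path output path.
#' @export
write_junction_tsv <- function(jc, path) {
  utils::write.table(as.data.frame(jc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Acceptor usage ratios at one donor
#'
#' For the split reads leaving a given donor in one sample, reports the
#' percentage of reads supporting each acceptor:
#' \code{100 * count(acceptor) / total count at the donor}, rounded half-up to
#' one decimal. This is the statistic that distinguishes balanced use of two
#' competing acceptors (e.g. 45\% vs 55\%) from an allele-driven shift.
#'
#' @param jc a \code{\link{junction_counts}} table.
#' @param chrom,donor_pos donor identity (first intronic base, 0-based).
#' @param sample sample to evaluate.
#' @return data.frame with columns \code{acceptor_pos}, \code{count},
#'   \code{percent}; zero coverage at the donor returns a zero-row frame with
#'   attribute \code{status = "no coverage"}.
#' @export
donor_usage_ratios <- function(jc, chrom, donor_pos, sample) {
  sub <- jc[jc$chrom == chrom & jc$donor_pos == donor_pos &
              jc$sample == sample & jc$count > 0, , drop = FALSE]
  if (nrow(sub) == 0 || sum(sub$count) == 0) {
    out <- data.frame(acceptor_pos = integer(0), count = integer(0),
                      percent = numeric(0))
    attr(out, "status") <- "no coverage"
    return(out)
  }
  out <- data.frame(acceptor_pos = sub$acceptor_pos, count = sub$count)
  out <- out[order(out$acceptor_pos), , drop = FALSE]
  out$percent <- round_half_up(100 * out$count / sum(out$count), 1)
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}

#' Read a junction catalog from BED
#'
#' The catalog lists known exon-exon junctions as intron intervals. BED is
#' 0-based half-open, matching the package's junction convention directly.
#'
#' @param path BED file (chrom, start, end, then optional columns).
#' @return data.frame with columns \code{chrom}, \code{donor_pos},
#'   \code{acceptor_pos}.
#' @export
read_junction_catalog <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             donor_pos = GenomicRanges::start(gr) - 1L,
             acceptor_pos = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Detect junctions absent from a reference catalog
#'
#' Flags junctions observed in one sample with at least \code{min_reads}
#' supporting split reads whose exact coordinates are missing from the
#' reference catalog — the signature of an aberrant splicing event such as a
#' variant-created donor. For each flagged junction the usage fraction at its
#' donor (and acceptor) is reported.
#'
#' @param jc a \code{\link{junction_counts}} table.
#' @param catalog data.frame with columns \code{chrom}, \code{donor_pos},
#'   \code{acceptor_pos} (e.g. from \code{\link{read_junction_catalog}}).
#' @param sample sample to scan.
#' @param min_reads minimum split-read support (default 3).
#' @param slop coordinate tolerance in nt for the catalog match; default 0
#'   (exact matching, since absence from a deep multi-tissue catalog is a
#'   categorical call).
#' @return data.frame with columns \code{chrom}, \code{donor_pos},
#'   \code{acceptor_pos}, \code{count}, \code{fraction_at_donor},
#'   \code{fraction_at_acceptor} (percent, one decimal).
#' @export
detect_novel_junctions <- function(jc, catalog, sample, min_reads = 3, slop = 0) {
  .check(min_reads >= 1, "min_reads must be >= 1")
  if (nrow(catalog) == 0) {
    warning("empty junction catalog: every junction will be flagged as novel")
  }
  sub <- jc[jc$sample == sample & jc$count >= min_reads, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(chrom = character(0), donor_pos = integer(0),
                      acceptor_pos = integer(0), count = integer(0),
                      fraction_at_donor = numeric(0),
                      fraction_at_acceptor = numeric(0)))
  }
  known <- vapply(seq_len(nrow(sub)), function(i) {
    any(catalog$chrom == sub$chrom[i] &
          abs(catalog$donor_pos - sub$donor_pos[i]) <= slop &
          abs(catalog$acceptor_pos - sub$acceptor_pos[i]) <= slop)
  }, logical(1))
  nov <- sub[!known, , drop = FALSE]
  all_s <- jc[jc$sample == sample, , drop = FALSE]
  frac <- function(i, by) {
    tot <- sum(all_s$count[all_s$chrom == nov$chrom[i] & all_s[[by]] == nov[[by]][i]])
    round_half_up(100 * nov$count[i] / tot, 1)
  }
  out <- data.frame(chrom = nov$chrom, donor_pos = nov$donor_pos,
                    acceptor_pos = nov$acceptor_pos, count = nov$count,
                    stringsAsFactors = FALSE)
  out$fraction_at_donor <- vapply(seq_len(nrow(nov)), frac, numeric(1), by = "donor_pos")
  out$fraction_at_acceptor <- vapply(seq_len(nrow(nov)), frac, numeric(1), by = "acceptor_pos")
  rownames(out) <- NULL
  out
}
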