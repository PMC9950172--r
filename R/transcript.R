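#' Transcript model
#'
#' Exon/CDS structure of one transcript on a genome sequence, the substrate on
#' which coding consequences and splice junctions are defined. Genomic exon
#' intervals are 0-based half-open; transcript and CDS coordinates are 1-based.
#'
#' @param tx_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons data.frame with integer columns \code{start}, \code{end}
#'   (0-based half-open genomic intervals, sorted ascending, non-overlapping).
#' @param cds_start,cds_end CDS bounds in transcript coordinates (1-based,
#'   inclusive); CDS length must be >= 3 and a multiple of 3.
#' @param genome named character vector (or single string) of chromosome
#'   sequence(s); required for sequence-dependent operations.
#' @return an object of class \code{transcript_model}.
#' @export
transcript_model <- function(tx_id, chrom, strand, exons, cds_start, cds_end,
                             genome = NULL) {
  .check(strand %in% c("+", "-"), "strand must be '+' or '-'")
  exons <- as.data.frame(exons)
  .check(all(c("start", "end") %in% names(exons)), "exons needs start/end columns")
  .check(all(exons$end > exons$start), "exons must be non-empty intervals")
  if (nrow(exons) > 1) {
    .check(all(diff(exons$start) > 0) && all(utils::head(exons$end, -1) <= exons$start[-1]),
           "exons must be sorted and non-overlapping")
  }
  tx_len <- sum(exons$end - exons$start)
  .check(cds_start >= 1 && cds_end <= tx_len && cds_end - cds_start + 1 >= 3,
         "CDS bounds out of range or too short")
  .check((cds_end - cds_start + 1) %% 3 == 0, "CDS length must be a multiple of 3")
  if (!is.null(genome)) {
    if (is.null(names(genome)) && length(genome) == 1L) names(genome) <- chrom
    .check(chrom %in% names(genome), "genome lacks chromosome '%s'", chrom)
    .check(nchar(genome[[chrom]]) >= max(exons$end),
           "genome sequence shorter than exon span")
  }
  structure(list(tx_id = tx_id, chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end, genome = genome),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s): %d exon(s), length %d nt, CDS %d..%d\n",
              x$tx_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start), x$cds_start, x$cds_end))
  invisible(x)
}

# exon order in transcript (5'->3') direction
.tx_exon_order <- function(tx) {
  if (tx$strand == "+") seq_len(nrow(tx$exons)) else rev(seq_len(nrow(tx$exons)))
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcript (5' to 3') order, reverse
#' complementing for minus-strand models.
#'
#' @param tx a \code{\link{transcript_model}} with a genome sequence.
#' @return character string of length equal to the summed exon lengths.
#' @export
spliced_seq <- function(tx) {
  .check(!is.null(tx$genome), "transcript_model has no genome sequence")
  g <- tx$genome[[tx$chrom]]
  pieces <- vapply(.tx_exon_order(tx), function(i) {
    s <- substr(g, tx$exons$start[i] + 1L, tx$exons$end[i])
    if (tx$strand == "-") .revcomp(s) else s
  }, character(1))
  .check_dna(paste(pieces, collapse = ""), "spliced sequence")
}

#' CDS sequence of a transcript model
#' @param tx a \code{\link{transcript_model}} with genome sequence.
#' @return character string of the coding sequence.
#' @export
cds_seq <- function(tx) substr(spliced_seq(tx), tx$cds_start, tx$cds_end)

#' Map a genomic position onto transcript coordinates
#'
#' @param tx a \code{\link{transcript_model}}.
#' @param gpos0 0-based genomic position of a base.
#' @return 1-based transcript position, or \code{NA} for intronic/outside.
#' @export
genomic_to_tx <- function(tx, gpos0) {
  gpos0 <- as.integer(gpos0)
  vapply(gpos0, function(p) {
    off <- 0L
    for (i in .tx_exon_order(tx)) {
      w <- tx$exons$end[i] - tx$exons$start[i]
      if (p >= tx$exons$start[i] && p < tx$exons$end[i]) {
        within <- if (tx$strand == "+") p - tx$exons$start[i] else tx$exons$end[i] - 1L - p
        return(as.integer(off + within + 1L))
      }
      off <- off + w
    }
    NA_integer_
  }, integer(1))
}

#' Map a transcript position onto the genome
#' @param tx a \code{\link{transcript_model}}.
#' @param tpos 1-based transcript position.
#' @return 0-based genomic position of the base.
#' @export
tx_to_genomic <- function(tx, tpos) {
  tpos <- as.integer(tpos)
  vapply(tpos, function(p) {
    .check(p >= 1, "transcript position must be >= 1")
    off <- 0L
    for (i in .tx_exon_order(tx)) {
      w <- tx$exons$end[i] - tx$exons$start[i]
      if (p <= off + w) {
        within <- p - off - 1L
        return(as.integer(if (tx$strand == "+") tx$exons$start[i] + within
               else tx$exons$end[i] - 1L - within))
      }
      off <- off + w
    }
    stop("transcript position beyond transcript end", call. = FALSE)
  }, integer(1))
}

# CDS-relative c. coordinate string for an exonic transcript position
.c_from_tx <- function(tx, tpos) {
  ifelse(tpos < tx$cds_start, paste0("-", tx$cds_start - tpos),
         ifelse(tpos > tx$cds_end, paste0("*", tpos - tx$cds_end),
                as.character(tpos - tx$cds_start + 1L)))
}

# Locate a genomic base relative to the exon structure (transcript strand).
# Returns list(region, tpos, c_label, exon_index, offset):
#   region "exonic": tpos set; "intronic": offset > 0 from the nearer boundary,
#   side "donor" (after an exon end, c.<E>+k) or "acceptor" (before an exon
#   start, c.<S>-k); "outside" beyond the transcript span.
.locate_genomic <- function(tx, gpos0) {
  tpos <- genomic_to_tx(tx, gpos0)
  if (!is.na(tpos)) {
    return(list(region = "exonic", tpos = tpos, c_label = .c_from_tx(tx, tpos)))
  }
  if (gpos0 < min(tx$exons$start) || gpos0 >= max(tx$exons$end)) {
    return(list(region = "outside"))
  }
  ord <- .tx_exon_order(tx)
  n <- length(ord)
  for (k in seq_len(n - 1)) {
    up <- ord[k]; down <- ord[k + 1]           # upstream/downstream in tx order
    if (tx$strand == "+") {
      in_intron <- gpos0 >= tx$exons$end[up] && gpos0 < tx$exons$start[down]
      d_don <- gpos0 - tx$exons$end[up] + 1L
      d_acc <- tx$exons$start[down] - gpos0
    } else {
      in_intron <- gpos0 >= tx$exons$end[down] && gpos0 < tx$exons$start[up]
      d_don <- tx$exons$start[up] - 1L - gpos0 + 1L
      d_acc <- gpos0 - tx$exons$end[down] + 1L + 0L
    }
    if (in_intron) {
      up_end_t <- sum(tx$exons$end[ord[seq_len(k)]] - tx$exons$start[ord[seq_len(k)]])
      if (d_don <= d_acc) {
        lab <- paste0(.c_from_tx(tx, up_end_t), "+", d_don)
        return(list(region = "intronic", side = "donor", offset = d_don,
                    intron_index = k, c_label = lab))
      } else {
        lab <- paste0(.c_from_tx(tx, up_end_t + 1L), "-", d_acc)
        return(list(region = "intronic", side = "acceptor", offset = d_acc,
                    intron_index = k, c_label = lab))
      }
    }
  }
  list(region = "outside")
}

#' Read transcript models from GTF and FASTA
#'
#' Imports exon and CDS features of each transcript from a GTF file and binds
#' them to genome sequences from a FASTA file.
#'
#' @param gtf_file path to a GTF with \code{exon} and \code{CDS} features
#'   carrying \code{transcript_id} attributes.
#' @param fasta_file path to the genome FASTA.
#' @return named list of \code{\link{transcript_model}} objects.
#' @export
read_transcript_gtf <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  dna <- Biostrings::readDNAStringSet(fasta_file)
  names(dna) <- sub("\\s.*$", "", names(dna))
  genome <- stats::setNames(as.character(dna), names(dna))
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  out <- list()
  for (txid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == txid]
    e <- e[order(GenomicRanges::start(e))]
    strand <- as.character(GenomicRanges::strand(e))[1]
    exons <- data.frame(start = GenomicRanges::start(e) - 1L,
                        end = GenomicRanges::end(e))
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    cc <- cds[cds$transcript_id == txid]
    .check(length(cc) > 0, "transcript %s has no CDS features", txid)
    tmp <- structure(list(tx_id = txid, chrom = chrom, strand = strand,
                          exons = exons, genome = genome),
                     class = "transcript_model")
    cpos0 <- c(GenomicRanges::start(cc) - 1L, GenomicRanges::end(cc) - 1L)
    tpos <- genomic_to_tx(tmp, cpos0)
    out[[txid]] <- transcript_model(txid, chrom, strand, exons,
                                    cds_start = min(tpos), cds_end = max(tpos),
                                    genome = genome)
  }
  out
}
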