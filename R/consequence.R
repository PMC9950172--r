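#' Codon index of a CDS nucleotide position
#'
#' @param n 1-based coding-DNA (c.) nucleotide position.
#' @return 1-based codon (residue) index: \code{floor((n - 1) / 3) + 1}.
#' @export
#' @examples
#' cds_position_to_codon(1570)  # 524
#' cds_position_to_codon(58)    # 20
cds_position_to_codon <- function(n) {
  .check(all(n >= 1), "CDS position must be >= 1")
  as.integer(floor((n - 1) / 3) + 1)
}

#' Normalize a deletion within its repeat context
#'
#' A deletion inside a homopolymer or short tandem repeat has several
#' equivalent representations that all produce the same mutated sequence.
#' \code{vcf_left} slides the deleted window maximally to the left (the VCF
#' convention); \code{hgvs_right} slides it maximally to the right (the HGVS
#' 3' rule on the given strand's sequence).
#'
#' @param seq reference sequence (character string, ACGT).
#' @param del_start 1-based position of the first deleted base in \code{seq}.
#' @param del_len deletion length in nt.
#' @param mode \code{"vcf_left"} or \code{"hgvs_right"}.
#' @return integer: the normalized 1-based \code{del_start}; deleting
#'   \code{del_len} bases there yields the same sequence as the input
#'   representation.
#' @export
normalize_deletion <- function(seq, del_start, del_len,
                               mode = c("vcf_left", "hgvs_right")) {
  mode <- match.arg(mode)
  seq <- .check_dna(seq)
  n <- nchar(seq)
  .check(del_start >= 1 && del_len >= 1 && del_start + del_len - 1 <= n,
         "deletion outside sequence bounds")
  b <- strsplit(seq, "")[[1]]
  s <- del_start
  if (mode == "vcf_left") {
    # shifting left by one is allowed when the base entering the window on the
    # right equals the base leaving it on the left
    while (s > 1 && b[s - 1] == b[s + del_len - 1]) s <- s - 1L
  } else {
    while (s + del_len - 1 < n && b[s] == b[s + del_len]) s <- s + 1L
  }
  as.integer(s)
}

# apply a deletion to a sequence
.delete_seq <- function(seq, del_start, del_len) {
  paste0(substr(seq, 1, del_start - 1),
         substr(seq, del_start + del_len, nchar(seq)))
}

.AA1 <- Biostrings::GENETIC_CODE
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

# translate an in-frame nucleotide string into one-letter AAs (string),
# keeping '*' for stops; trailing partial codon dropped
.translate <- function(nt) {
  nt <- substr(nt, 1, floor(nchar(nt) / 3) * 3)
  if (nchar(nt) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

.fmt_aa <- function(aa, style) {
  if (style == "one_letter") aa else unname(.AA3[aa])
}

#' Predict the protein consequence of a CDS deletion
#'
#' Deletes \code{del_len} nucleotides starting at CDS position
#' \code{cds_del_start}, then determines the consequence. In-frame deletions
#' (length divisible by 3) are reported as such. Frameshifts are translated in
#' the shifted frame from the first affected codon through the transcript 3'
#' end (reading into the 3' UTR) until a stop codon; the protein change is
#' reported in the HGVS \code{RefAA<pos>AltAAfs*N} style where the first
#' altered residue counts as 1 and N is the new stop position. When the
#' shifted frame reaches the transcript end without a stop, the consequence is
#' tagged \code{fs_no_stop}. A frameshift whose first altered codon is itself
#' a stop is a nonsense change.
#'
#' @param tx a \code{\link{transcript_model}} with genome sequence.
#' @param cds_del_start 1-based CDS position of the first deleted base.
#' @param del_len deletion length in nt (must lie fully inside the CDS).
#' @param hgvs_style \code{"one_letter"} (\code{L524Tfs*3}) or
#'   \code{"three_letter"} (\code{Leu524Thrfs*3}).
#' @return a \code{coding_consequence} list: \code{hgvs_c}, \code{hgvs_p},
#'   \code{kind}, \code{first_altered_residue}, \code{stop_offset}.
#' @export
predict_frameshift <- function(tx, cds_del_start, del_len,
                               hgvs_style = c("one_letter", "three_letter")) {
  hgvs_style <- match.arg(hgvs_style)
  cds_len <- tx$cds_end - tx$cds_start + 1L
  .check(cds_del_start >= 1 && del_len >= 1,
         "deletion start and length must be positive")
  .check(cds_del_start + del_len - 1 <= cds_len,
         "deletion crosses the CDS 3' boundary; CDS/UTR-spanning deletions are unsupported")
  full <- spliced_seq(tx)
  ref_orf <- substr(full, tx$cds_start, nchar(full))     # CDS + 3' UTR
  hgvs_c <- if (del_len == 1) sprintf("c.%ddel", cds_del_start) else
    sprintf("c.%d_%ddel", cds_del_start, cds_del_start + del_len - 1)

  if (del_len %% 3 == 0) {
    cons <- list(hgvs_c = hgvs_c, hgvs_p = NA_character_,
                 kind = "inframe_deletion",
                 first_altered_residue = cds_position_to_codon(cds_del_start),
                 stop_offset = NA_integer_)
    class(cons) <- "coding_consequence"
    return(cons)
  }

  mut_orf <- .delete_seq(ref_orf, cds_del_start, del_len)
  .fs_consequence(substr(ref_orf, 1, cds_len), mut_orf, hgvs_c, hgvs_style)
}

# Shared shifted-frame consequence: compare the reference protein against the
# translation of the mutated open reading frame (which runs into the 3' UTR),
# find the first altered residue and the new stop (HGVS fs*N rule).
.fs_consequence <- function(ref_cds, mut_orf, hgvs_c, hgvs_style) {
  ref_aa <- strsplit(.translate(ref_cds), "")[[1]]
  mut_aa <- strsplit(.translate(mut_orf), "")[[1]]

  m <- min(length(ref_aa), length(mut_aa))
  diffs <- which(ref_aa[seq_len(m)] != mut_aa[seq_len(m)])
  first_alt <- if (length(diffs)) diffs[1] else m + 1L
  .check(first_alt <= length(mut_aa),
         "mutant protein identical over its whole length; no altered residue")

  stop_rel <- which(mut_aa[first_alt:length(mut_aa)] == "*")
  ref_sym <- if (first_alt <= length(ref_aa)) .fmt_aa(ref_aa[first_alt], hgvs_style)
             else .fmt_aa(mut_aa[first_alt], hgvs_style)
  alt_sym <- .fmt_aa(mut_aa[first_alt], hgvs_style)

  if (length(stop_rel) && stop_rel[1] == 1L) {
    cons <- list(hgvs_c = hgvs_c,
                 hgvs_p = sprintf("p.%s%d%s", ref_sym, first_alt,
                                  if (hgvs_style == "one_letter") "*" else "Ter"),
                 kind = "nonsense", first_altered_residue = first_alt,
                 stop_offset = NA_integer_)
  } else if (length(stop_rel)) {
    cons <- list(hgvs_c = hgvs_c,
                 hgvs_p = sprintf("p.%s%d%sfs*%d", ref_sym, first_alt, alt_sym,
                                  stop_rel[1]),
                 kind = "frameshift", first_altered_residue = first_alt,
                 stop_offset = as.integer(stop_rel[1]))
  } else {
    cons <- list(hgvs_c = hgvs_c,
                 hgvs_p = sprintf("p.%s%d%sfs*?", ref_sym, first_alt, alt_sym),
                 kind = "fs_no_stop", first_altered_residue = first_alt,
                 stop_offset = NA_integer_)
  }
  class(cons) <- "coding_consequence"
  cons
}

#' Consequence of an aberrant transcript retaining intronic sequence
#'
#' Models the transcript produced when a disrupted donor is replaced by a
#' cryptic donor \code{extension} nt downstream inside the intron: the first
#' \code{extension} intronic bases are retained in the mRNA. An extension not
#' divisible by 3 shifts the frame of every downstream codon; the consequence
#' is computed exactly like a coding frameshift (first altered residue, new
#' stop, fs*N name).
#'
#' @param tx a \code{\link{transcript_model}} with genome sequence.
#' @param intron_index which intron (1-based in transcript order) gains the
#'   retained sequence.
#' @param extension number of retained intronic nt (> 0).
#' @param hgvs_style \code{"one_letter"} or \code{"three_letter"}.
#' @return a \code{coding_consequence}.
#' @export
predict_exon_extension <- function(tx, intron_index, extension,
                                   hgvs_style = c("one_letter", "three_letter")) {
  hgvs_style <- match.arg(hgvs_style)
  .check(extension >= 1, "extension must be >= 1 nt")
  ord <- .tx_exon_order(tx)
  .check(intron_index >= 1 && intron_index < nrow(tx$exons),
         "intron_index out of range")
  up <- ord[intron_index]
  g <- tx$genome[[tx$chrom]]
  retained <- if (tx$strand == "+") {
    substr(g, tx$exons$end[up] + 1L, tx$exons$end[up] + extension)
  } else {
    .revcomp(substr(g, tx$exons$start[up] - extension + 1L, tx$exons$start[up]))
  }
  full <- spliced_seq(tx)
  up_end_t <- sum(vapply(seq_len(intron_index), function(k) {
    tx$exons$end[ord[k]] - tx$exons$start[ord[k]]
  }, numeric(1)))
  mut_full <- paste0(substr(full, 1, up_end_t), retained,
                     substr(full, up_end_t + 1L, nchar(full)))
  cds_len <- tx$cds_end - tx$cds_start + 1L
  ref_cds <- substr(full, tx$cds_start, tx$cds_end)
  mut_orf <- substr(mut_full, tx$cds_start, nchar(mut_full))
  hgvs_c <- sprintf("c.%s_%sins%s",
                    .c_from_tx(tx, up_end_t), .c_from_tx(tx, up_end_t + 1L),
                    retained)
  if (extension %% 3 == 0) {
    cons <- list(hgvs_c = hgvs_c, hgvs_p = NA_character_,
                 kind = "inframe_insertion",
                 first_altered_residue = cds_position_to_codon(
                   min(up_end_t - tx$cds_start + 2L, cds_len)),
                 stop_offset = NA_integer_)
    class(cons) <- "coding_consequence"
    return(cons)
  }
  .fs_consequence(ref_cds, mut_orf, hgvs_c, hgvs_style)
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("coding_consequence: %s %s %s\n", x$kind, x$hgvs_c,
              ifelse(is.na(x$hgvs_p), "", x$hgvs_p)))
  invisible(x)
}

#' Classify a variant against the splice sites of a transcript
#'
#' Maps a genomic deletion or substitution onto a transcript model and decides
#' whether it disrupts a splice site. Deletions are first normalized by the
#' HGVS 3' rule on the transcript strand, so e.g. a G deletion anywhere inside
#' a GGG run spanning an exon/intron boundary is assigned to the canonical
#' intronic +1 position. Variants touching intronic positions +1/+2 after an
#' exon are donor disruptions; positions -1/-2 before an exon are acceptor
#' region hits; intronic variants beyond 25 nt of any exon are
#' \code{deep_intronic}; everything else is returned as \code{exonic} or
#' \code{intronic_near_exon} for downstream handling.
#'
#' @param tx a \code{\link{transcript_model}} with genome sequence.
#' @param pos 1-based genomic position (VCF convention: for a deletion, the
#'   position of the base preceding the deleted bases when \code{ref}/
#'   \code{alt} use the anchor-base style, otherwise the first deleted base —
#'   see \code{del_start0}/\code{del_len} for the explicit interface).
#' @param del_start0 0-based genomic position of the first deleted base
#'   (explicit deletion interface).
#' @param del_len number of deleted bases (0 for a substitution at \code{pos}).
#' @return a \code{coding_consequence} list with \code{kind} one of
#'   \code{splice_donor_disruption}, \code{splice_acceptor_region},
#'   \code{exonic}, \code{intronic_near_exon}, \code{deep_intronic}, and
#'   \code{hgvs_c} in \code{c.<pos>+k}/\code{c.<pos>-k} notation.
#' @export
classify_splice_site_variant <- function(tx, pos = NULL, del_start0 = NULL,
                                         del_len = 1L) {
  .check(!is.null(tx$genome), "transcript_model has no genome sequence")
  if (is.null(del_start0)) {
    .check(!is.null(pos), "either pos or del_start0 is required")
    del_start0 <- pos - 1L
  }
  g <- tx$genome[[tx$chrom]]
  is_del <- del_len >= 1L

  if (is_del) {
    # HGVS right-normalization in transcript-strand space: genomic right for
    # '+' transcripts, genomic left for '-' transcripts
    if (tx$strand == "+") {
      s <- normalize_deletion(g, del_start0 + 1L, del_len, "hgvs_right")
      del_start0 <- s - 1L
    } else {
      s <- normalize_deletion(g, del_start0 + 1L, del_len, "vcf_left")
      del_start0 <- s - 1L
    }
    touched <- del_start0 + seq_len(del_len) - 1L
  } else {
    touched <- del_start0
  }

  locs <- lapply(touched, function(p) .locate_genomic(tx, p))
  regions <- vapply(locs, function(l) l$region, character(1))

  suffix <- if (is_del) "del" else ""
  pick <- function(kind, loc) {
    cons <- list(hgvs_c = paste0("c.", loc$c_label, suffix),
                 hgvs_p = NA_character_, kind = kind,
                 first_altered_residue = NA_integer_, stop_offset = NA_integer_)
    class(cons) <- "coding_consequence"
    cons
  }

  # transcript-strand 3'-most touched base determines the reported position;
  # donor/acceptor calls use the most splice-proximal touched base
  for (i in seq_along(locs)) {
    l <- locs[[i]]
    if (l$region == "intronic" && l$side == "donor" && l$offset <= 2) {
      return(pick("splice_donor_disruption", l))
    }
    if (l$region == "intronic" && l$side == "acceptor" && l$offset <= 2) {
      return(pick("splice_acceptor_region", l))
    }
  }
  if (any(regions == "exonic")) {
    l <- locs[[which(regions == "exonic")[if (tx$strand == "+") sum(regions == "exonic") else 1L]]]
    return(pick("exonic", l))
  }
  if (any(regions == "intronic")) {
    l <- locs[[which(regions == "intronic")[1]]]
    if (l$offset > 25) return(pick("deep_intronic", l))
    return(pick("intronic_near_exon", l))
  }
  cons <- list(hgvs_c = NA_character_, hgvs_p = NA_character_,
               kind = "deep_intronic", first_altered_residue = NA_integer_,
               stop_offset = NA_integer_)
  class(cons) <- "coding_consequence"
  cons
}
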