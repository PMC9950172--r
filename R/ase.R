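#' Allele count at one site in one assay
#'
#' @param ref_count,alt_count non-negative integer read counts supporting the
#'   reference and alternate allele.
#' @param sample sample identifier.
#' @param assay \code{"DNA"} or \code{"RNA"}.
#' @param site site identifier.
#' @return an \code{allele_count} list.
#' @export
allele_count <- function(ref_count, alt_count, sample = "sample",
                         assay = c("DNA", "RNA"), site = "site") {
  assay <- match.arg(assay)
  .check(ref_count >= 0 && alt_count >= 0 &&
           ref_count == floor(ref_count) && alt_count == floor(alt_count),
         "allele counts must be non-negative integers")
  structure(list(sample = sample, assay = assay, site = site,
                 ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count)),
            class = "allele_count")
}

#' Variant allele fraction
#'
#' @param ref_count,alt_count read counts (or a single \code{allele_count}
#'   object passed as \code{ref_count}).
#' @return list with \code{fraction} (alt / total) and \code{percent}
#'   (rounded half-up to one decimal); zero depth yields
#'   \code{status = "no coverage"} with \code{NA} values.
#' @export
#' @examples
#' vaf(67, 29)$percent  # 30.2
#' vaf(19, 25)$percent  # 56.8
vaf <- function(ref_count, alt_count = NULL) {
  if (inherits(ref_count, "allele_count")) {
    ac <- ref_count
    ref_count <- ac$ref_count
    alt_count <- ac$alt_count
  }
  depth <- ref_count + alt_count
  if (depth == 0) {
    return(list(fraction = NA_real_, percent = NA_real_, status = "no coverage"))
  }
  f <- alt_count / depth
  list(fraction = f, percent = round_half_up(100 * f, 1), status = "ok")
}

#' Classify zygosity / mosaicism from allele counts
#'
#' Formalizes the by-inspection call of germline heterozygosity versus
#' post-zygotic mosaicism as an exact two-sided binomial test of the alternate
#' count against p = 0.5. A site compatible with 0.5 is heterozygous; a site
#' rejecting 0.5 with a VAF inside the mosaic band is mosaic; VAFs at the
#' homozygous extremes give homozygous calls; anything else (including depth
#' below \code{min_depth}) is indeterminate.
#'
#' @param ref_count,alt_count read counts (or one \code{allele_count} object).
#' @param alpha two-sided significance level for the test vs 0.5 (default 0.05).
#' @param mosaic_band VAF band \code{c(lod, upper)} for a mosaic call after
#'   rejecting 0.5; default \code{c(0.05, 0.35)}.
#' @param min_depth minimum depth for any call (default 20).
#' @return a \code{zygosity_call} list: \code{call}, \code{vaf},
#'   \code{vaf_percent}, \code{binomial_p}, \code{depth}.
#' @export
#' @examples
#' classify_zygosity(19, 25)$call  # heterozygous
#' classify_zygosity(67, 29)$call  # mosaic
classify_zygosity <- function(ref_count, alt_count = NULL, alpha = 0.05,
                              mosaic_band = c(0.05, 0.35), min_depth = 20) {
  if (inherits(ref_count, "allele_count")) {
    ac <- ref_count
    ref_count <- ac$ref_count
    alt_count <- ac$alt_count
  }
  depth <- ref_count + alt_count
  lod <- mosaic_band[1]
  if (depth < min_depth) {
    call <- "indeterminate"
    p <- NA_real_
    f <- if (depth > 0) alt_count / depth else NA_real_
  } else {
    f <- alt_count / depth
    p <- stats::binom.test(alt_count, depth, p = 0.5,
                           alternative = "two.sided")$p.value
    call <- if (p >= alpha) {
      "heterozygous"
    } else if (f <= lod) {
      "homozygous_ref"
    } else if (f >= 1 - lod) {
      "homozygous_alt"
    } else if (f >= lod && f <= mosaic_band[2]) {
      "mosaic"
    } else {
      "indeterminate"
    }
  }
  structure(list(call = call, vaf = f,
                 vaf_percent = if (is.na(f)) NA_real_ else round_half_up(100 * f, 1),
                 binomial_p = p, depth = depth),
            class = "zygosity_call")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat(sprintf("zygosity_call: %s (VAF %s%%, depth %d, binomial p = %s)\n",
              x$call, format(x$vaf_percent), x$depth,
              format(signif(x$binomial_p, 3))))
  invisible(x)
}

#' DNA-versus-RNA allelic imbalance test
#'
#' One-sided Fisher exact test of the 2x2 table
#' \code{rbind(c(dna_ref, dna_alt), c(rna_ref, rna_alt))} with the alternative
#' that the alternate-allele fraction is lower in RNA than in DNA — the
#' expected signature of degradation of the mutant transcript (e.g. by
#' nonsense-mediated decay). Any zero table margin makes the test
#' uninformative and returns p = 1 with a degenerate-table note.
#'
#' @param dna,rna \code{allele_count} objects, or numeric \code{c(ref, alt)}
#'   pairs.
#' @return list with \code{odds_ratio} (conditional MLE), \code{p_one_sided},
#'   \code{table} and \code{note}.
#' @export
#' @examples
#' allelic_imbalance_test(c(19, 25), c(93, 45))$p_one_sided
allelic_imbalance_test <- function(dna, rna) {
  as_pair <- function(x) {
    if (inherits(x, "allele_count")) c(x$ref_count, x$alt_count) else as.numeric(x)
  }
  d <- as_pair(dna)
  r <- as_pair(rna)
  .check(sum(d) > 0 && sum(r) > 0, "both assays need positive depth")
  tab <- rbind(DNA = c(ref = d[1], alt = d[2]), RNA = c(ref = r[1], alt = r[2]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_one_sided = 1, table = tab,
                note = "degenerate table"))
  }
  # OR = (dna_ref * rna_alt) / (dna_alt * rna_ref); RNA depleted for alt
  # means OR < 1, i.e. alternative = "less"
  ft <- stats::fisher.test(tab, alternative = "less")
  list(odds_ratio = unname(ft$estimate), p_one_sided = ft$p.value,
       table = tab, note = "")
}

#' Genotype RNA reads at a variant site from spliced alignments
#'
#' Counts RNA reads carrying the exact reference or alternate allele at a
#' site. A read must span the whole allele interval with aligned (M) bases;
#' reads matching neither allele exactly are counted as ambiguous and excluded
#' from both counts.
#'
#' @param sam_file SAM/BAM of RNA alignments.
#' @param chrom chromosome.
#' @param pos 1-based position of the first allele base.
#' @param ref,alt allele strings (VCF style; for deletions the shared anchor
#'   base plus deleted bases in \code{ref}).
#' @param sample sample id for the returned \code{allele_count}.
#' @return list with \code{counts} (an RNA \code{allele_count}) and
#'   \code{ambiguous} (integer).
#' @export
count_rna_alleles <- function(sam_file, chrom, pos, ref, alt, sample = "sample") {
  bam <- sam_file
  if (grepl("\\.sam$", sam_file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_file, destination = tempfile(),
                            overwrite = TRUE, indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("pos", "cigar", "seq"),
                                   which = GenomicRanges::GRanges(
                                     chrom, IRanges::IRanges(pos, pos + nchar(ref) - 1L)))
  recs <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_ref <- 0L; n_alt <- 0L; n_amb <- 0L
  for (i in seq_along(recs$pos)) {
    obs <- .read_allele_at(recs$pos[i], recs$cigar[i], as.character(recs$seq[i]),
                           pos, nchar(ref))
    if (is.null(obs)) next
    if (obs$spans && obs$allele == ref) n_ref <- n_ref + 1L
    else if (obs$matches_alt_del && nchar(alt) == 1L && nchar(ref) > 1L) n_alt <- n_alt + 1L
    else if (obs$spans && obs$allele == alt) n_alt <- n_alt + 1L
    else if (obs$spans || obs$matches_alt_del) n_amb <- n_amb + 1L
  }
  list(counts = allele_count(n_ref, n_alt, sample = sample, assay = "RNA",
                             site = paste0(chrom, ":", pos)),
       ambiguous = n_amb)
}

# Walk a CIGAR to recover the read bases over [site_pos, site_pos+len) and
# whether the read carries a deletion exactly covering the non-anchor bases.
.read_allele_at <- function(read_pos, cigar, seq, site_pos, ref_len) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  gpos <- read_pos          # 1-based genomic
  qpos <- 1L                # 1-based in read
  allele <- character(0)
  covered <- 0L
  del_hit <- FALSE
  target <- site_pos:(site_pos + ref_len - 1L)
  for (tk in toks) {
    n <- as.integer(sub("[A-Z=]$", "", tk))
    op <- sub("^\\d+", "", tk)
    if (op %in% c("M", "=", "X")) {
      hit <- intersect(target, gpos:(gpos + n - 1L))
      if (length(hit)) {
        allele <- c(allele, substring(seq, qpos + hit - gpos, qpos + hit - gpos))
        covered <- covered + length(hit)
      }
      gpos <- gpos + n; qpos <- qpos + n
    } else if (op %in% c("D", "N")) {
      if (op == "D" && ref_len > 1L && gpos == site_pos + 1L && n == ref_len - 1L) {
        del_hit <- TRUE
      }
      gpos <- gpos + n
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + n
    }
  }
  list(spans = covered == ref_len, allele = paste(allele, collapse = ""),
       matches_alt_del = del_hit && covered >= 1L)
}

#' Read an allele-count TSV
#'
#' @param path TSV with columns \code{sample}, \code{assay}, \code{site},
#'   \code{ref_count}, \code{alt_count}.
#' @return data.frame of allele counts.
#' @export
read_allele_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("sample", "assay", "site", "ref_count", "alt_count") %in% names(df)),
         "allele-count TSV needs sample/assay/site/ref_count/alt_count columns")
  df
}
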