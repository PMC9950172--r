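#' Simulation configuration for a synthetic trio study
#'
#' Defines the conditions of the synthetic study on which the whole pipeline
#' is exercised: a trio with planted background variants and one de novo
#' loss-of-function variant (germline heterozygous or mosaic at fraction f),
#' binomially sampled read depths, a donor with two competing acceptors at
#' configurable usage fractions, an optional aberrant donor creating a novel
#' junction in the proband only, and RNA allele counts depleted for the
#' alternate allele as under nonsense-mediated decay.
#'
#' The synthetic locus is one plus-strand transcript of five exons whose first
#' exon holds 57 coding nt and ends in a GG/GTAAGT boundary, so the exonic GG
#' plus the intronic +1 G form a GGG homopolymer across the donor; a cryptic
#' donor sits 4 nt into intron 1, so its use inserts 4 intronic nt into the
#' mRNA and shifts the frame from residue 20. The exon 3 donor splices to a
#' long and a short acceptor of exon 4 (21 nt apart).
#'
#' @param seed integer RNG seed; every simulated artifact is reproducible
#'   from it.
#' @param n_background_variants number of Mendelian-consistent background
#'   variants (default 100).
#' @param variant_type planted de novo variant: \code{"donor_deletion"} (a G
#'   deleted from the GGG run at the exon 1 donor) or \code{"cds_deletion"}
#'   (a 2-nt deletion inside exon 4 at CDS position \code{cds_del_start}).
#' @param de_novo_spec \code{"germline_het"}, \code{"mosaic"}, or
#'   \code{"none"}; mosaic uses \code{mosaic_fraction}.
#' @param mosaic_fraction post-zygotic fraction f in (0, 0.5] (default 0.30,
#'   the blood-mosaicism regime).
#' @param cds_del_start CDS position of the planted exonic deletion
#'   (default 281, 7 bp upstream of the short exon 4 acceptor; used when \code{variant_type = "cds_deletion"}).
#' @param depth_dna,depth_rna mean read depths (defaults 96 and 100; the
#'   germline-het regime observed in practice is ~44x DNA / ~138x RNA and can
#'   be set explicitly).
#' @param nmd_factor multiplicative survival of alternate-allele RNA reads in
#'   \[0,1\] (default 0.5; 1 = no decay, 0 = complete degradation).
#' @param usage_parent,usage_proband usage fractions (short, long acceptor)
#'   at the exon 3 donor; parents default to c(0.45, 0.55). The proband
#'   default is c(0.38, 0.62) for the exonic-deletion study (the deletion sits
#'   in the long acceptor's pyrimidine-tract side) and c(0.45, 0.55)
#'   otherwise.
#' @param aberrant_fraction fraction of exon 1 donor reads using the cryptic
#'   donor in the proband (default 0.13 for the donor-deletion study, 0
#'   otherwise).
#' @param n_junction_reads split reads per sample at the exon 3 donor
#'   (default 2000).
#' @param n_exon1_reads split reads per sample at the exon 1 donor
#'   (default 100).
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_background_variants = 100L,
                              variant_type = c("donor_deletion", "cds_deletion"),
                              de_novo_spec = c("mosaic", "germline_het", "none"),
                              mosaic_fraction = 0.30,
                              cds_del_start = 281L,
                              depth_dna = 96, depth_rna = 100,
                              nmd_factor = 0.5,
                              usage_parent = c(0.45, 0.55),
                              usage_proband = NULL,
                              aberrant_fraction = NULL,
                              n_junction_reads = 2000L,
                              n_exon1_reads = 100L) {
  variant_type <- match.arg(variant_type)
  de_novo_spec <- match.arg(de_novo_spec)
  if (de_novo_spec == "mosaic") {
    .check(mosaic_fraction > 0 && mosaic_fraction <= 0.5,
           "mosaic fraction must lie in (0, 0.5]")
  }
  .check(nmd_factor >= 0 && nmd_factor <= 1, "nmd_factor must lie in [0,1]")
  .check(abs(sum(usage_parent) - 1) < 1e-9, "usage fractions must sum to 1")
  if (is.null(usage_proband)) {
    usage_proband <- if (variant_type == "cds_deletion") c(0.38, 0.62) else usage_parent
  }
  .check(abs(sum(usage_proband) - 1) < 1e-9, "usage fractions must sum to 1")
  if (is.null(aberrant_fraction)) {
    aberrant_fraction <- if (variant_type == "donor_deletion") 0.13 else 0
  }
  .check(aberrant_fraction >= 0 && aberrant_fraction < 1,
         "aberrant_fraction must lie in [0,1)")
  structure(list(seed = as.integer(seed),
                 n_background_variants = as.integer(n_background_variants),
                 variant_type = variant_type, de_novo_spec = de_novo_spec,
                 mosaic_fraction = mosaic_fraction,
                 cds_del_start = as.integer(cds_del_start),
                 depth_dna = depth_dna, depth_rna = depth_rna,
                 nmd_factor = nmd_factor,
                 usage_parent = usage_parent, usage_proband = usage_proband,
                 aberrant_fraction = aberrant_fraction,
                 n_junction_reads = as.integer(n_junction_reads),
                 n_exon1_reads = as.integer(n_exon1_reads)),
            class = "simulation_config")
}

# Fixed layout of the synthetic locus (0-based half-open genomic intervals)
.LOCUS <- list(
  chrom = "chrS",
  exon_starts = c(100L, 457L, 877L, 1267L, 1717L),
  exon_ends   = c(157L, 577L, 967L, 1417L, 2058L),
  cds_start = 1L, cds_end = 558L,
  short_acceptor_offset = 21L,   # short exon 4 acceptor, 21 nt inside
  cryptic_donor_offset = 4L      # cryptic donor 4 nt into intron 1
)

#' Build the synthetic locus: genome, transcript model and junction catalog
#'
#' Deterministic given the seed. The genome is random ACGT with canonical
#' GT..AG intron boundaries (pyrimidine-rich acceptor tracts), an ATG at the
#' CDS start, a stop at the CDS end, the GG|GTAAGT exon 1 donor homopolymer,
#' and an AG dinucleotide ahead of the short exon 4 acceptor.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{tx} (a \code{\link{transcript_model}}),
#'   \code{genome}, \code{catalog} (known-junction data.frame including both
#'   exon 4 acceptors), \code{aberrant_junction}, and \code{donors}
#'   (landmark coordinates).
#' @export
build_locus <- function(config) {
  set.seed(config$seed + 1000L)
  L <- .LOCUS
  glen <- max(L$exon_ends) + 100L
  g <- sample(.DNA_BASES, glen, replace = TRUE)

  exon_starts <- L$exon_starts; exon_ends <- L$exon_ends
  set_seq <- function(pos0, s) {
    b <- strsplit(s, "")[[1]]
    g[pos0 + seq_along(b)] <<- b      # pos0 is 0-based; vector is 1-based
  }
  # intron boundaries: GTAAGT donors, pyrimidine tract + AG acceptors
  for (i in 1:4) {
    set_seq(exon_ends[i], "GTAAGT")
    tract <- paste(sample(c("C", "T"), 14, replace = TRUE), collapse = "")
    set_seq(exon_starts[i + 1] - 16L, paste0(tract, "AG"))
  }
  set_seq(exon_starts[1], "ATG")
  # GGG homopolymer across the exon 1 donor: c.56 G, c.57 G, +1 G (of GTAAGT);
  # the base before the run must not extend it
  set_seq(exon_ends[1] - 3L, "AGG")
  # short exon 4 acceptor: AG immediately before it, pyrimidines upstream
  sa <- exon_starts[4] + L$short_acceptor_offset
  set_seq(sa - 16L, paste0(paste(sample(c("C", "T"), 14, replace = TRUE),
                                 collapse = ""), "AG"))
  # stop codon at CDS end, and no premature stop in the reference frame
  cds_tx <- L$cds_start:L$cds_end
  tmp_tx <- transcript_model("TXS", L$chrom, "+",
                             data.frame(start = exon_starts, end = exon_ends),
                             L$cds_start, L$cds_end,
                             stats::setNames(paste(g, collapse = ""), L$chrom))
  gpos_cds <- tx_to_genomic(tmp_tx, cds_tx)
  codons <- split(gpos_cds, rep(seq_len(length(cds_tx) / 3), each = 3))
  for (k in seq_along(codons)) {
    cd <- paste(g[codons[[k]] + 1L], collapse = "")
    if (k < length(codons) && cd %in% c("TAA", "TAG", "TGA")) {
      g[codons[[k]][1] + 1L] <- "C"
    }
  }
  g[codons[[length(codons)]] + 1L] <- c("T", "A", "A")

  genome <- stats::setNames(paste(g, collapse = ""), L$chrom)
  tx <- transcript_model("TXS", L$chrom, "+",
                         data.frame(start = exon_starts, end = exon_ends),
                         L$cds_start, L$cds_end, genome)
  catalog <- data.frame(
    chrom = L$chrom,
    donor_pos = c(exon_ends[1:4], exon_ends[3]),
    acceptor_pos = c(exon_starts[2:5], sa),
    stringsAsFactors = FALSE
  )
  list(tx = tx, genome = genome, catalog = catalog,
       aberrant_junction = c(donor_pos = exon_ends[1] + L$cryptic_donor_offset,
                             acceptor_pos = exon_starts[2]),
       donors = list(exon1_donor = exon_ends[1], exon3_donor = exon_ends[3],
                     acceptor_long = exon_starts[4], acceptor_short = sa))
}

# VCF-style (anchored, left-aligned) representation of a deletion
.vcf_deletion <- function(genome_seq, del_start0, del_len) {
  s <- normalize_deletion(genome_seq, del_start0 + 1L, del_len, "vcf_left")
  anchor <- s - 1L
  list(pos = anchor,
       ref = substr(genome_seq, anchor, anchor + del_len),
       alt = substr(genome_seq, anchor, anchor))
}

#' Simulate a trio variant set with one planted de novo variant
#'
#' Background variants are drawn with population allele frequencies and
#' Mendelian-consistent trio genotypes (parents from Hardy-Weinberg at the
#' population frequency, proband inheriting one allele from each); read
#' depths are Poisson around \code{depth_dna} with binomial allele counts.
#' The planted de novo variant has homozygous-reference parents with zero
#' alternate reads and a proband alternate fraction of 0.5 (germline het) or
#' the mosaic fraction f.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param locus optional prebuilt \code{\link{build_locus}} result.
#' @return list with \code{trio} (an \code{\link{annotated_trio}}) and
#'   \code{truth} (one-row data.frame describing the planted variant, or
#'   zero rows when \code{de_novo_spec = "none"}).
#' @export
simulate_trio <- function(config, locus = NULL) {
  if (is.null(locus)) locus <- build_locus(config)
  set.seed(config$seed + 2000L)
  n <- config$n_background_variants
  genes <- sprintf("BG%02d", 1:30)
  gene_inh <- sample(.INHERITANCE_MODES, 30, replace = TRUE,
                     prob = c(0.3, 0.4, 0.1, 0.2))
  gene_pen <- ifelse(gene_inh == "AD", stats::runif(30) < 0.5, FALSE)

  rows <- list()
  if (n > 0) {
    gi <- sample.int(30, n, replace = TRUE)
    af <- ifelse(stats::runif(n) < 0.3, stats::runif(n, 0.01, 0.5),
                 stats::runif(n, 1e-5, 0.01))
    status <- sample(c("none", "VUS", "benign", "likely_benign",
                       "benign_conflicting", "risk_factor", "pathogenic"),
                     n, replace = TRUE,
                     prob = c(0.45, 0.2, 0.1, 0.1, 0.05, 0.03, 0.07))
    draw_gt <- function(p) {           # HWE genotype as allele pair
      c(stats::rbinom(1, 1, p), stats::rbinom(1, 1, p))
    }
    for (i in seq_len(n)) {
      mo <- draw_gt(af[i]); fa <- draw_gt(af[i])
      pro <- c(sample(mo, 1), sample(fa, 1))
      fmt <- function(a) paste(sort(a), collapse = "/")
      counts <- function(a) {
        dp <- max(stats::rpois(1, config$depth_dna), 8L)
        alt <- stats::rbinom(1, dp, sum(a) / 2)
        c(dp - alt, alt)
      }
      cp <- counts(pro); cm <- counts(mo); cf <- counts(fa)
      rows[[i]] <- data.frame(
        chrom = "chrB", pos = 1000L + i * 97L,
        ref = sample(.DNA_BASES, 1),
        alt = NA_character_, gene = genes[gi[i]],
        gene_inheritance = gene_inh[gi[i]],
        penetrance_complete_pediatric = gene_pen[gi[i]],
        population_af = af[i], clinvar_status = status[i],
        gt_proband = fmt(pro), gt_mother = fmt(mo), gt_father = fmt(fa),
        pro_ref = cp[1], pro_alt = cp[2], mo_ref = cm[1], mo_alt = cm[2],
        fa_ref = cf[1], fa_alt = cf[2], stringsAsFactors = FALSE
      )
      rows[[i]]$alt <- sample(setdiff(.DNA_BASES, rows[[i]]$ref), 1)
    }
  }

  truth <- data.frame()
  if (config$de_novo_spec != "none") {
    L <- .LOCUS
    if (config$variant_type == "donor_deletion") {
      # delete one G of the GGG run; plant the 3'-most representation (+1)
      del_start0 <- locus$donors$exon1_donor
      del_len <- 1L
      cds_del_start <- NA_integer_
    } else {
      tpos <- config$cds_del_start + locus$tx$cds_start - 1L
      del_start0 <- tx_to_genomic(locus$tx, tpos)
      del_len <- 2L
      cds_del_start <- config$cds_del_start
    }
    rep_vcf <- .vcf_deletion(locus$genome[[L$chrom]], del_start0, del_len)
    p_true <- if (config$de_novo_spec == "mosaic") config$mosaic_fraction else 0.5
    dp <- round(config$depth_dna)
    alt <- stats::rbinom(1, dp, p_true)
    dpm <- max(stats::rpois(1, config$depth_dna), 10L)
    dpf <- max(stats::rpois(1, config$depth_dna), 10L)
    planted <- data.frame(
      chrom = L$chrom, pos = rep_vcf$pos, ref = rep_vcf$ref, alt = rep_vcf$alt,
      gene = "GENE_TXS", gene_inheritance = "unknown",
      penetrance_complete_pediatric = FALSE,
      population_af = NA_real_, clinvar_status = "none",
      gt_proband = "0/1", gt_mother = "0/0", gt_father = "0/0",
      pro_ref = dp - alt, pro_alt = alt,
      mo_ref = dpm, mo_alt = 0L, fa_ref = dpf, fa_alt = 0L,
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1]] <- planted
    truth <- data.frame(
      variant_id = paste(L$chrom, rep_vcf$pos, rep_vcf$ref, rep_vcf$alt, sep = ":"),
      chrom = L$chrom, vcf_pos = rep_vcf$pos,
      del_start0 = del_start0, del_len = del_len,
      cds_del_start = cds_del_start,
      variant_type = config$variant_type,
      mode = config$de_novo_spec, true_fraction = p_true,
      stringsAsFactors = FALSE
    )
  }
  trio_df <- do.call(rbind, rows)
  if (is.null(trio_df)) {
    trio_df <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          gene = character(0), gene_inheritance = character(0),
                          penetrance_complete_pediatric = logical(0),
                          population_af = numeric(0), clinvar_status = character(0),
                          gt_proband = character(0), gt_mother = character(0),
                          gt_father = character(0),
                          pro_ref = integer(0), pro_alt = integer(0),
                          mo_ref = integer(0), mo_alt = integer(0),
                          fa_ref = integer(0), fa_alt = integer(0))
  }
  list(trio = annotated_trio(trio_df), truth = truth)
}

#' Simulate split junction reads for one sample
#'
#' Draws multinomial junction observations per donor from the configured
#' usage fractions: at the exon 3 donor between the short and long exon 4
#' acceptors, and at the exon 1 donor between the canonical junction and (in
#' the proband, when configured) the cryptic-donor aberrant junction.
#' Optionally emits a SAM file with one spliced read (30M..N..30M) per
#' observation, whose CIGARs reproduce the sampled junctions exactly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param sample one of \code{"proband"}, \code{"mother"}, \code{"father"}.
#' @param locus optional prebuilt \code{\link{build_locus}} result.
#' @param out_sam optional path; when given, a SAM file is written.
#' @return a \code{\link{junction_counts}} table (invisibly also the SAM path
#'   as attribute \code{"sam"} when written).
#' @export
simulate_junction_reads <- function(config, sample = c("proband", "mother", "father"),
                                    locus = NULL, out_sam = NULL) {
  sample <- match.arg(sample)
  if (is.null(locus)) locus <- build_locus(config)
  set.seed(config$seed + 3000L + match(sample, c("proband", "mother", "father")))
  d <- locus$donors
  usage <- if (sample == "proband") config$usage_proband else config$usage_parent
  n3 <- stats::rmultinom(1, config$n_junction_reads, usage)[, 1]
  ab_frac <- if (sample == "proband") config$aberrant_fraction else 0
  n1 <- stats::rmultinom(1, config$n_exon1_reads, c(1 - ab_frac, ab_frac))[, 1]

  df <- data.frame(
    chrom = .LOCUS$chrom,
    donor_pos = c(d$exon3_donor, d$exon3_donor, d$exon1_donor,
                  locus$aberrant_junction[["donor_pos"]]),
    acceptor_pos = c(d$acceptor_short, d$acceptor_long,
                     .LOCUS$exon_starts[2], locus$aberrant_junction[["acceptor_pos"]]),
    strand = "+", sample = sample,
    count = c(n3[1], n3[2], n1[1], n1[2]),
    stringsAsFactors = FALSE
  )
  df <- df[df$count > 0, , drop = FALSE]
  jc <- junction_counts(df)
  if (!is.null(out_sam)) {
    .write_junction_sam(jc, locus, out_sam)
    attr(jc, "sam") <- out_sam
  }
  jc
}

# one SAM record per junction observation: 30M <intron> N 30M, MAPQ 60
.write_junction_sam <- function(jc, locus, path) {
  g <- locus$genome[[.LOCUS$chrom]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", .LOCUS$chrom, nchar(g))), con)
  rid <- 0L
  for (i in seq_len(nrow(jc))) {
    dp <- jc$donor_pos[i]; ap <- jc$acceptor_pos[i]
    pos1 <- dp - 30L + 1L                     # 1-based leftmost aligned base
    cigar <- sprintf("30M%dN30M", ap - dp)
    seqs <- paste0(substr(g, dp - 30L + 1L, dp), substr(g, ap + 1L, ap + 30L))
    for (k in seq_len(jc$count[i])) {
      rid <- rid + 1L
      writeLines(paste(sprintf("r%06d", rid), 0, .LOCUS$chrom, pos1, 60, cigar,
                       "*", 0, 0, seqs, strrep("I", nchar(seqs)),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Simulate DNA and RNA allele counts at the planted site
#'
#' DNA alternate reads are Binomial(depth_dna, p) with p = 0.5 for a germline
#' het or the mosaic fraction f. RNA reads model per-read survival of the
#' alternate transcript at rate \code{nmd_factor}: alternate reads are
#' Binomial(depth_rna, p_rna) with
#' \code{p_rna = p * nmd / (1 - p + p * nmd)}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param p true alternate-allele fraction; defaults from the config's
#'   de novo spec.
#' @return list of two \code{allele_count} objects, \code{dna} and \code{rna}.
#' @export
simulate_allele_reads <- function(config, p = NULL) {
  if (is.null(p)) {
    .check(config$de_novo_spec != "none", "no planted variant in this config")
    p <- if (config$de_novo_spec == "mosaic") config$mosaic_fraction else 0.5
  }
  set.seed(config$seed + 4000L)
  dp_d <- round(config$depth_dna)
  alt_d <- stats::rbinom(1, dp_d, p)
  nmd <- config$nmd_factor
  p_rna <- p * nmd / (1 - p + p * nmd)
  dp_r <- round(config$depth_rna)
  alt_r <- stats::rbinom(1, dp_r, p_rna)
  list(dna = allele_count(dp_d - alt_d, alt_d, "proband", "DNA", "planted"),
       rna = allele_count(dp_r - alt_r, alt_r, "proband", "RNA", "planted"))
}

#' Simulate a complete synthetic trio study
#'
#' Bundles every artifact the pipeline consumes: the locus (transcript model
#' + genome + junction catalog), the trio variant table with its truth table,
#' per-sample junction counts, and DNA/RNA allele counts at the planted site.
#' Byte-identical across runs for a fixed config.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{synthetic_study} list.
#' @export
simulate_study <- function(config) {
  locus <- build_locus(config)
  tv <- simulate_trio(config, locus)
  jc <- do.call(rbind, lapply(c("proband", "mother", "father"), function(s) {
    as.data.frame(simulate_junction_reads(config, s, locus))
  }))
  jc <- junction_counts(jc)
  reads <- if (config$de_novo_spec != "none") simulate_allele_reads(config) else NULL
  structure(list(config = config, locus = locus, trio = tv$trio,
                 truth = tv$truth, junctions = jc, reads = reads),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study (seed %d): %d variant(s), planted: %s %s\n",
              x$config$seed, nrow(x$trio),
              x$config$variant_type, x$config$de_novo_spec))
  invisible(x)
}
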