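# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (hand-rolled codon table, CIGAR
# walk, hypergeometric/binomial enumeration, per-rule set operations) and
# never call the code paths they verify.

# --- translation oracle: standard genetic code, codon-by-codon lookup -------
.ORACLE_BASES <- c("T", "C", "A", "G")
.ORACLE_AA <- strsplit(paste0(
  "FFLLSSSSYY**CC*W",   # TTT..TGG
  "LLLLPPPPHHQQRRRR",   # CTT..CGG
  "IIIMTTTTNNKKSSRR",   # ATT..AGG
  "VVVVAAAADDEEGGGG"),  # GTT..GGG
  "")[[1]]
oracle_codon_to_aa <- function(codon) {
  b <- match(strsplit(codon, "")[[1]], .ORACLE_BASES) - 1L
  .ORACLE_AA[b[1] * 16 + b[2] * 4 + b[3] + 1L]
}
oracle_translate <- function(nt) {
  nt <- substr(nt, 1, floor(nchar(nt) / 3) * 3)
  n <- nchar(nt) / 3
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    oracle_codon_to_aa(substr(nt, 3 * i - 2, 3 * i))
  }, character(1))
}

# mutate-and-translate frameshift oracle: delete del_len nt at CDS position
# del_start from the ORF (CDS + 3' UTR), translate both, compare residues
oracle_frameshift <- function(cds, utr3, del_start, del_len) {
  orf <- paste0(cds, utr3)
  mut <- paste0(substr(orf, 1, del_start - 1),
                substr(orf, del_start + del_len, nchar(orf)))
  ref_aa <- oracle_translate(cds)
  mut_aa <- oracle_translate(mut)
  m <- min(length(ref_aa), length(mut_aa))
  diffs <- which(ref_aa[seq_len(m)] != mut_aa[seq_len(m)])
  first_alt <- if (length(diffs)) diffs[1] else m + 1L
  stops <- which(mut_aa == "*")
  stops <- stops[stops >= first_alt]
  list(first_altered_residue = first_alt,
       stop_offset = if (length(stops)) stops[1] - first_alt + 1L else NA_integer_,
       stop_at_first = length(stops) > 0 && stops[1] == first_alt)
}

# --- CIGAR junction oracle: manual walk over the reference space -----------
oracle_cigar_junctions <- function(pos0, cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  g <- pos0
  out <- list()
  for (tk in toks) {
    n <- as.integer(sub("[A-Z=]$", "", tk))
    op <- sub("^\\d+", "", tk)
    if (op %in% c("M", "=", "X", "D")) g <- g + n
    if (op == "N") {
      out[[length(out) + 1]] <- c(donor = g, acceptor = g + n)
      g <- g + n
    }
  }
  out
}

# --- exact-test oracles -----------------------------------------------------
# one-sided Fisher p (alternative: OR < 1) by hypergeometric tail enumeration
oracle_fisher_less <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  dens <- function(k) exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  sum(vapply(lo:a, dens, numeric(1)))
}

# two-sided exact binomial p vs p0 = 0.5: sum of all outcome probabilities
# not exceeding the observed one (the minlike convention)
oracle_binom_two_sided <- function(x, n) {
  dens <- vapply(0:n, function(k) exp(lchoose(n, k) - n * log(2)), numeric(1))
  obs <- dens[x + 1]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# --- cascade oracle: rules as independent set operations composed in order --
oracle_cascade <- function(trio) {
  af <- ifelse(is.na(trio$population_af), 0, trio$population_af)
  has_alt <- function(g) !is.na(g) & grepl("1", g)
  het <- function(g) !is.na(g) & g %in% c("0/1", "1/0")
  hom <- function(g) !is.na(g) & g == "1/1"

  rule <- rep("none", nrow(trio))
  thr <- ifelse(trio$gene_inheritance == "AR", 0.05, 0.01)
  rule[rule == "none" & af >= thr] <- "i_frequency"
  rule[rule == "none" & af >= 0.01 & af <= 0.05 &
         trio$clinvar_status %in% c("benign", "likely_benign")] <- "ii_borderline_benign"
  rule[rule == "none" &
         trio$clinvar_status %in% c("risk_factor", "histocompatibility")] <- "iii_clinvar_category"

  dn <- rep(FALSE, nrow(trio))
  for (i in seq_len(nrow(trio))) {
    modp <- trio$mo_ref[i] + trio$mo_alt[i]
    fadp <- trio$fa_ref[i] + trio$fa_alt[i]
    dn[i] <- !is.na(trio$pro_alt[i]) && trio$pro_alt[i] > 0 &&
      !is.na(modp) && !is.na(fadp) && modp >= 10 && fadp >= 10 &&
      trio$mo_alt[i] <= 1 && trio$fa_alt[i] <= 1 &&
      !has_alt(trio$gt_mother[i]) && !has_alt(trio$gt_father[i])
  }

  rule[rule == "none" & trio$gene_inheritance == "AD" &
         trio$penetrance_complete_pediatric & het(trio$gt_proband) &
         (has_alt(trio$gt_mother) | has_alt(trio$gt_father))] <- "iv_inherited_dominant"

  cls <- rep("none", nrow(trio))
  for (g in unique(trio$gene)) {
    idx <- which(trio$gene == g & rule == "none")
    if (!length(idx)) next
    ar <- trio$gene_inheritance[idx] == "AR"
    hets <- idx[ar & het(trio$gt_proband[idx])]
    orig <- ifelse(has_alt(trio$gt_mother[hets]) & has_alt(trio$gt_father[hets]),
                   "ambiguous",
                   ifelse(has_alt(trio$gt_mother[hets]), "mother",
                          ifelse(has_alt(trio$gt_father[hets]), "father", "neither")))
    trans_pair <- length(hets) >= 2 && any(orig == "mother") && any(orig == "father")
    both_amb <- length(hets) >= 2 && sum(orig == "ambiguous") >= 2
    for (k in seq_along(hets)) {
      i <- hets[k]
      if (trans_pair && orig[k] %in% c("mother", "father")) {
        cls[i] <- "compound_het"
      } else if (trans_pair && orig[k] == "ambiguous") {
        # retained, phase unknown
      } else if (both_amb && orig[k] == "ambiguous") {
        cls[i] <- "compound_het"
      } else if (!dn[i]) {
        rule[i] <- "v_unpaired_recessive"
      }
    }
    cls[idx[ar & hom(trio$gt_proband[idx]) & rule[idx] == "none"]] <- "homozygous_recessive"
  }
  cls[dn & rule == "none"] <- "de_novo"   # de novo outranks the other classes
  data.frame(variant_id = trio$variant_id, retained = rule == "none",
             rule_fired = rule, candidate_class = ifelse(rule == "none", cls, "none"),
             stringsAsFactors = FALSE)
}

# --- small constructors shared across tests --------------------------------
# one-row annotated_trio builder with sensible defaults
make_variant <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                         gene = "G1", inh = "AD", pen = FALSE, af = NA,
                         clinvar = "none",
                         gt_pro = "0/1", gt_mo = "0/0", gt_fa = "0/0",
                         pro = c(20, 20), mo = c(30, 0), fa = c(30, 0)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             gene_inheritance = inh, penetrance_complete_pediatric = pen,
             population_af = af, clinvar_status = clinvar,
             gt_proband = gt_pro, gt_mother = gt_mo, gt_father = gt_fa,
             pro_ref = pro[1], pro_alt = pro[2], mo_ref = mo[1], mo_alt = mo[2],
             fa_ref = fa[1], fa_alt = fa[2], stringsAsFactors = FALSE)
}

# single-exon plus-strand transcript whose genome is flank + CDS + 3' UTR
make_simple_tx <- function(cds, utr3 = "", flank = 10) {
  pad <- strrep("A", flank)
  genome <- paste0(pad, cds, utr3, pad)
  transcript_model("tx", "c1", "+",
                   data.frame(start = flank, end = flank + nchar(cds) + nchar(utr3)),
                   cds_start = 1, cds_end = nchar(cds),
                   genome = c(c1 = genome))
}

# random CDS: ATG + random non-stop codons + TAA
random_cds <- function(n_codons) {
  codons <- c()
  while (length(codons) < n_codons - 2) {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (!cd %in% c("TAA", "TAG", "TGA")) codons <- c(codons, cd)
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# the six-variant toy set: one variant removed by each rule i-v plus one
# de novo survivor
make_toy_cascade_set <- function() {
  rbind(
    make_variant(pos = 100, gene = "GAR", inh = "AR", af = 0.06,
                 gt_pro = "0/1", gt_mo = "0/1", pro = c(20, 20), mo = c(20, 20)),
    make_variant(pos = 200, gene = "GAR3", inh = "AR", af = 0.03,
                 clinvar = "likely_benign", gt_pro = "0/1", gt_mo = "0/1",
                 mo = c(20, 20)),
    make_variant(pos = 300, gene = "GAD2", inh = "AD", af = 0.001,
                 clinvar = "risk_factor", gt_pro = "0/1", gt_fa = "0/1",
                 fa = c(20, 20)),
    make_variant(pos = 400, gene = "GADP", inh = "AD", pen = TRUE, af = 0.001,
                 gt_pro = "0/1", gt_fa = "0/1", fa = c(20, 20)),
    make_variant(pos = 500, gene = "GAR2", inh = "AR", af = 0.001,
                 gt_pro = "0/1", gt_mo = "0/1", mo = c(20, 20)),
    make_variant(pos = 600, gene = "GNEW", inh = "unknown", af = NA,
                 gt_pro = "0/1", pro = c(19, 25), mo = c(30, 0), fa = c(30, 0))
  )
}
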