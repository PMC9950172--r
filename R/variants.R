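#' Annotated trio variant table
#'
#' Builds the variant container consumed by the filter cascade: one row per
#' biallelic variant with trio genotypes, per-sample allele counts and the
#' annotations the cascade rules read (gene, inheritance mode, population
#' allele frequency, ClinVar status, pediatric-penetrance flag).
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{gene}, \code{gene_inheritance} (one of
#'   \code{AD}, \code{AR}, \code{AD_AR}, \code{unknown}),
#'   \code{penetrance_complete_pediatric} (logical), \code{population_af}
#'   (fraction in \[0,1\], \code{NA} treated as 0), \code{clinvar_status},
#'   genotype columns \code{gt_proband}, \code{gt_mother}, \code{gt_father}
#'   ("0/0", "0/1", "1/1", or \code{NA}), and allele-count columns
#'   \code{pro_ref}, \code{pro_alt}, \code{mo_ref}, \code{mo_alt},
#'   \code{fa_ref}, \code{fa_alt} (\code{NA} allowed for missing data).
#' @param mother_affected,father_affected logical pedigree flags; both default
#'   to \code{FALSE} (unaffected parents, the configuration of a classic
#'   affected-child trio).
#' @return an object of class \code{annotated_trio} (a data.frame with a
#'   \code{variant_id} column and pedigree attributes).
#' @export
annotated_trio <- function(variants, mother_affected = FALSE, father_affected = FALSE) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "gene_inheritance",
                "penetrance_complete_pediatric", "population_af", "clinvar_status",
                "gt_proband", "gt_mother", "gt_father",
                "pro_ref", "pro_alt", "mo_ref", "mo_alt", "fa_ref", "fa_alt")
  missing_cols <- setdiff(required, names(variants))
  .check(length(missing_cols) == 0L, "missing columns: %s",
         paste(missing_cols, collapse = ", "))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(v) > 0) {
    .check(all(v$pos >= 1), "pos must be >= 1 (VCF convention)")
    .check(all(v$ref != v$alt), "ref must differ from alt")
    af <- v$population_af
    .check(all(is.na(af) | (af >= 0 & af <= 1)),
           "population_af must lie in [0,1] (or NA for absent)")
    bad_inh <- setdiff(unique(v$gene_inheritance), .INHERITANCE_MODES)
    .check(length(bad_inh) == 0L,
           "unknown gene_inheritance token(s) %s; valid: %s",
           paste(bad_inh, collapse = ","), paste(.INHERITANCE_MODES, collapse = ","))
    bad_cln <- setdiff(unique(v$clinvar_status), .CLINVAR_STATUSES)
    .check(length(bad_cln) == 0L,
           "unknown clinvar_status token(s) %s; valid: %s",
           paste(bad_cln, collapse = ","), paste(.CLINVAR_STATUSES, collapse = ","))
  }
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  attr(v, "mother_affected") <- isTRUE(mother_affected)
  attr(v, "father_affected") <- isTRUE(father_affected)
  class(v) <- c("annotated_trio", "data.frame")
  v
}

.INHERITANCE_MODES <- c("AD", "AR", "AD_AR", "unknown")
.CLINVAR_STATUSES <- c("none", "benign", "likely_benign", "benign_conflicting",
                       "risk_factor", "histocompatibility", "pathogenic",
                       "likely_pathogenic", "VUS")

#' @export
print.annotated_trio <- function(x, ...) {
  cat(sprintf("annotated_trio: %d variant(s), %d gene(s)\n",
              nrow(x), length(unique(x$gene))))
  cat(sprintf("  parents affected: mother=%s father=%s\n",
              attr(x, "mother_affected"), attr(x, "father_affected")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# population_af with the missing-equals-absent-from-population convention
.af0 <- function(af) ifelse(is.na(af), 0, af)

.gt_has_alt <- function(gt) !is.na(gt) & grepl("1", gt, fixed = TRUE)
.gt_is_het <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0")
.gt_is_homalt <- function(gt) !is.na(gt) & gt %in% c("1/1", "1|1")

#' Rule i: population-frequency filter
#'
#' Removes variants whose population allele frequency is at or above the
#' inheritance-mode threshold: 0.05 for autosomal-recessive genes and 0.01 for
#' autosomal-dominant genes. Genes annotated both AD and AR, and genes of
#' unknown inheritance, use the stricter AD threshold. A frequency below the
#' threshold passes (strict inequality); missing frequencies count as 0.
#'
#' @param trio an \code{\link{annotated_trio}}.
#' @return logical vector, \code{TRUE} where rule i removes the variant.
#' @export
apply_frequency_filter <- function(trio) {
  af <- trio$population_af
  .check(all(is.na(af) | (af >= 0 & af <= 1)), "population_af must lie in [0,1]")
  af <- .af0(af)
  thr <- ifelse(trio$gene_inheritance == "AR", 0.05, 0.01)
  af >= thr
}

#' Rules ii and iii: ClinVar-based filters
#'
#' Rule ii removes variants in the borderline frequency band \[0.01, 0.05\]
#' annotated benign or likely benign without conflicting interpretations;
#' a benign call with conflicts is retained. Rule iii removes variants
#' annotated as a risk factor or histocompatibility allele at any frequency.
#'
#' @param trio an \code{\link{annotated_trio}}.
#' @return data.frame with logical columns \code{rule_ii} and \code{rule_iii}.
#' @export
apply_clinvar_filters <- function(trio) {
  status <- trio$clinvar_status
  bad <- setdiff(unique(status), .CLINVAR_STATUSES)
  .check(length(bad) == 0L, "unknown clinvar_status token(s) %s; valid: %s",
         paste(bad, collapse = ","), paste(.CLINVAR_STATUSES, collapse = ","))
  af <- .af0(trio$population_af)
  data.frame(
    rule_ii  = af >= 0.01 & af <= 0.05 & status %in% c("benign", "likely_benign"),
    rule_iii = status %in% c("risk_factor", "histocompatibility")
  )
}

#' De novo status from trio allele counts
#'
#' A variant is called de novo when the proband carries alternate-supporting
#' reads while both parents are adequately covered and essentially free of the
#' alternate allele. Parents with depth below \code{min_depth}, or with missing
#' counts, cannot exclude inheritance and yield \code{"unresolvable"}.
#'
#' @param trio an \code{\link{annotated_trio}}.
#' @param min_depth minimum parental depth to exclude inheritance (default 10).
#' @param max_parent_alt maximum tolerated parental alternate reads (default 1,
#'   allowing for a stray error read at high depth).
#' @return character vector with values \code{"de_novo"}, \code{"not_de_novo"},
#'   or \code{"unresolvable"}.
#' @export
detect_de_novo <- function(trio, min_depth = 10, max_parent_alt = 1) {
  pro_alt <- trio$pro_alt
  mo_dp <- trio$mo_ref + trio$mo_alt
  fa_dp <- trio$fa_ref + trio$fa_alt
  out <- rep("not_de_novo", nrow(trio))
  carries <- !is.na(pro_alt) & pro_alt > 0
  parents_missing <- is.na(mo_dp) | is.na(fa_dp)
  parents_shallow <- !parents_missing & (mo_dp < min_depth | fa_dp < min_depth)
  parents_clean <- !parents_missing & !parents_shallow &
    trio$mo_alt <= max_parent_alt & trio$fa_alt <= max_parent_alt &
    !.gt_has_alt(trio$gt_mother) & !.gt_has_alt(trio$gt_father)
  out[carries & (parents_missing | parents_shallow)] <- "unresolvable"
  out[carries & parents_clean] <- "de_novo"
  out
}

# Parental origin of a proband-het variant, from parent genotypes.
# "mother"/"father" when exactly one parent carries it, "neither" (de novo
# configuration), or "ambiguous" when both parents carry it (phase unknown).
.parental_origin <- function(trio) {
  mo <- .gt_has_alt(trio$gt_mother)
  fa <- .gt_has_alt(trio$gt_father)
  ifelse(mo & fa, "ambiguous",
         ifelse(mo, "mother", ifelse(fa, "father", "neither")))
}

#' Rules iv and v: trio inheritance filters within one gene
#'
#' Rule iv removes proband-heterozygous variants inherited from an unaffected
#' parent in autosomal-dominant genes with complete penetrance in the
#' pediatric age. Rule v removes a lone proband-heterozygous variant in an
#' autosomal-recessive gene unless it is de novo; two or more proband hets in
#' an AR gene with opposite parental origin are retained as a compound
#' heterozygote, and a homozygous-alternate proband in an AR gene is retained
#' as homozygous recessive. When two AR hets are present in both parents the
#' phase cannot be resolved and both are retained with a \code{phase_unknown}
#' note rather than dropped.
#'
#' @param gene_trio an \code{\link{annotated_trio}} restricted to one gene.
#' @param de_novo_status character vector from \code{\link{detect_de_novo}}
#'   aligned with \code{gene_trio} rows; computed if missing.
#' @return data.frame with columns \code{rule_iv}, \code{rule_v} (logical),
#'   \code{candidate_class} and \code{note}.
#' @export
apply_inheritance_filters <- function(gene_trio, de_novo_status = NULL) {
  .check(length(unique(gene_trio$gene)) <= 1L,
         "apply_inheritance_filters expects variants of a single gene")
  n <- nrow(gene_trio)
  if (is.null(de_novo_status)) de_novo_status <- detect_de_novo(gene_trio)
  mo_aff <- isTRUE(attr(gene_trio, "mother_affected"))
  fa_aff <- isTRUE(attr(gene_trio, "father_affected"))

  het <- .gt_is_het(gene_trio$gt_proband)
  homalt <- .gt_is_homalt(gene_trio$gt_proband)
  inh <- gene_trio$gene_inheritance
  origin <- .parental_origin(gene_trio)

  rule_iv <- inh == "AD" & gene_trio$penetrance_complete_pediatric & het &
    ((origin %in% c("mother", "ambiguous") & !mo_aff) |
     (origin %in% c("father", "ambiguous") & !fa_aff))

  candidate <- rep("none", n)
  note <- rep("", n)
  rule_v <- rep(FALSE, n)

  ar <- inh == "AR" & !rule_iv
  candidate[ar & homalt] <- "homozygous_recessive"

  ar_het <- which(ar & het)
  if (length(ar_het) > 0) {
    orig <- origin[ar_het]
    dn <- de_novo_status[ar_het] == "de_novo"
    if (length(ar_het) >= 2 && any(orig == "mother") && any(orig == "father")) {
      in_trans <- orig %in% c("mother", "father")
      candidate[ar_het[in_trans]] <- "compound_het"
      rule_v[ar_het[!in_trans & !dn & orig != "ambiguous"]] <- TRUE
      # ambiguous-origin hets alongside a resolved trans pair stay retained
      note[ar_het[orig == "ambiguous"]] <- "phase_unknown"
    } else if (length(ar_het) >= 2 && sum(orig == "ambiguous") >= 2) {
      # two hets, both transmissible from either parent: phase unresolvable
      candidate[ar_het[orig == "ambiguous"]] <- "compound_het"
      note[ar_het[orig == "ambiguous"]] <- "phase_unknown"
      # hets with a resolved single-parent origin still lack a trans partner
      rule_v[ar_het[orig != "ambiguous" & !dn]] <- TRUE
    } else {
      # lone het (or hets all on one haplotype side): rule v unless de novo
      rule_v[ar_het[!dn]] <- TRUE
    }
  }

  candidate[de_novo_status == "de_novo" & !rule_iv & !rule_v] <- "de_novo"
  data.frame(rule_iv = rule_iv, rule_v = rule_v,
             candidate_class = candidate, note = note,
             stringsAsFactors = FALSE)
}

#' Run the five-rule filter cascade over a trio variant set
#'
#' Applies the removal rules in order: (i) population-frequency threshold by
#' inheritance mode, (ii) borderline-frequency benign/likely-benign without
#' conflicts, (iii) ClinVar risk factor or histocompatibility allele, (iv)
#' dominant-gene heterozygotes inherited from an unaffected parent, (v) lone
#' recessive-gene heterozygotes without a second rare variant. The first rule
#' that removes a variant is recorded; survivors are classified as de novo,
#' homozygous recessive or compound heterozygous. Output rows are sorted by
#' (chrom, pos) and the cascade is deterministic.
#'
#' @param trio an \code{\link{annotated_trio}}.
#' @param min_depth,max_parent_alt de novo calling thresholds, see
#'   \code{\link{detect_de_novo}}.
#' @return a \code{filter_decisions} data.frame with columns
#'   \code{variant_id}, \code{chrom}, \code{pos}, \code{gene},
#'   \code{retained}, \code{rule_fired} (one of \code{i_frequency},
#'   \code{ii_borderline_benign}, \code{iii_clinvar_category},
#'   \code{iv_inherited_dominant}, \code{v_unpaired_recessive}, \code{none}),
#'   \code{candidate_class}, \code{de_novo_status} and \code{note}.
#' @export
run_cascade <- function(trio, min_depth = 10, max_parent_alt = 1) {
  .check(inherits(trio, "annotated_trio"), "run_cascade expects an annotated_trio")
  n <- nrow(trio)
  dec <- data.frame(
    variant_id = trio$variant_id %||% character(0),
    chrom = trio$chrom, pos = trio$pos, gene = trio$gene,
    retained = rep(TRUE, n), rule_fired = rep("none", n),
    candidate_class = rep("none", n),
    de_novo_status = rep("not_de_novo", n),
    note = rep("", n), stringsAsFactors = FALSE
  )
  if (n == 0) {
    class(dec) <- c("filter_decisions", "data.frame")
    return(dec)
  }

  dec$de_novo_status <- detect_de_novo(trio, min_depth, max_parent_alt)

  rm_i <- apply_frequency_filter(trio)
  dec$rule_fired[rm_i] <- "i_frequency"

  cl <- apply_clinvar_filters(trio)
  hit_ii <- cl$rule_ii & dec$rule_fired == "none"
  dec$rule_fired[hit_ii] <- "ii_borderline_benign"
  hit_iii <- cl$rule_iii & dec$rule_fired == "none"
  dec$rule_fired[hit_iii] <- "iii_clinvar_category"

  # rules iv/v act per gene on the survivors of i-iii
  alive <- dec$rule_fired == "none"
  for (g in unique(trio$gene[alive])) {
    idx <- which(alive & trio$gene == g)
    sub <- trio[idx, , drop = FALSE]
    attr(sub, "mother_affected") <- attr(trio, "mother_affected")
    attr(sub, "father_affected") <- attr(trio, "father_affected")
    class(sub) <- class(trio)
    res <- apply_inheritance_filters(sub, dec$de_novo_status[idx])
    dec$rule_fired[idx[res$rule_iv]] <- "iv_inherited_dominant"
    dec$rule_fired[idx[res$rule_v & !res$rule_iv]] <- "v_unpaired_recessive"
    keep <- !res$rule_iv & !res$rule_v
    dec$candidate_class[idx[keep]] <- res$candidate_class[keep]
    dec$note[idx[keep]] <- res$note[keep]
  }

  dec$retained <- dec$rule_fired == "none"
  dec$candidate_class[!dec$retained] <- "none"
  ord <- order(dec$chrom, dec$pos)
  dec <- dec[ord, , drop = FALSE]
  rownames(dec) <- NULL
  class(dec) <- c("filter_decisions", "data.frame")
  dec
}

#' @export
print.filter_decisions <- function(x, ...) {
  cat(sprintf("filter_decisions: %d variant(s), %d retained\n",
              nrow(x), sum(x$retained)))
  if (nrow(x) > 0) {
    tab <- table(x$rule_fired)
    cat("  rules fired:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cls <- table(x$candidate_class[x$retained])
    if (length(cls)) {
      cat("  candidate classes:",
          paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
    }
  }
  invisible(x)
}
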