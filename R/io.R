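#' Write a trio variant table as VCF 4.2
#'
#' Emits one biallelic record per row with annotations in INFO (keys
#' \code{GENE}, \code{AF_POP}, \code{INHERITANCE}, \code{CLNSIG} and the flag
#' \code{PENETRANCE_PED}) and per-sample \code{GT:AD} genotypes for proband,
#' mother and father.
#'
#' @param trio an \code{\link{annotated_trio}}.
#' @param path output VCF path.
#' @param sample_names names of the three samples, proband first.
#' @param seed optional integer recorded as a \code{##simulation_seed} header
#'   line for provenance.
#' @return the path, invisibly.
#' @export
write_trio_vcf <- function(trio, path,
                           sample_names = c("proband", "mother", "father"),
                           seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(seed)) sprintf("##simulation_seed=%d", seed),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF_POP,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=INHERITANCE,Number=1,Type=String,Description=\"Gene inheritance mode\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar status\">",
    "##INFO=<ID=PENETRANCE_PED,Number=0,Type=Flag,Description=\"Complete penetrance in pediatric age\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  writeLines(hdr, con)
  fmt_ad <- function(r, a) sprintf("%s,%s", ifelse(is.na(r), ".", r),
                                   ifelse(is.na(a), ".", a))
  for (i in seq_len(nrow(trio))) {
    info <- sprintf("GENE=%s;AF_POP=%s;INHERITANCE=%s;CLNSIG=%s%s",
                    trio$gene[i],
                    ifelse(is.na(trio$population_af[i]), ".",
                           format(trio$population_af[i], digits = 6)),
                    trio$gene_inheritance[i], trio$clinvar_status[i],
                    ifelse(trio$penetrance_complete_pediatric[i],
                           ";PENETRANCE_PED", ""))
    gt <- function(g) ifelse(is.na(g), "./.", g)
    writeLines(paste(trio$chrom[i], trio$pos[i], trio$variant_id[i],
                     trio$ref[i], trio$alt[i], ".", "PASS", info, "GT:AD",
                     paste0(gt(trio$gt_proband[i]), ":",
                            fmt_ad(trio$pro_ref[i], trio$pro_alt[i])),
                     paste0(gt(trio$gt_mother[i]), ":",
                            fmt_ad(trio$mo_ref[i], trio$mo_alt[i])),
                     paste0(gt(trio$gt_father[i]), ":",
                            fmt_ad(trio$fa_ref[i], trio$fa_alt[i])),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write the three-line trio sample sheet
#' @param path output TSV path.
#' @param sample_names samples, proband first.
#' @param affected logical affected flags aligned with \code{sample_names}.
#' @export
write_sample_sheet <- function(path,
                               sample_names = c("proband", "mother", "father"),
                               affected = c(TRUE, FALSE, FALSE)) {
  utils::write.table(
    data.frame(sample_id = sample_names,
               role = c("proband", "mother", "father"),
               affected = affected),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated trio VCF and sample sheet
#'
#' Parses a VCF 4.2 via vcfR, splits multi-allelic records into biallelic
#' ones, reads annotations from configurable INFO keys and trio roles from
#' the sample sheet.
#'
#' @param vcf_path VCF path.
#' @param pedigree_path sample-sheet TSV (\code{sample_id}, \code{role},
#'   \code{affected}); when \code{NULL}, samples are assumed to be in
#'   proband/mother/father order with unaffected parents.
#' @param info_keys named character vector mapping the fields \code{gene},
#'   \code{af}, \code{inheritance}, \code{clinvar}, \code{penetrance} to INFO
#'   keys.
#' @return an \code{\link{annotated_trio}}.
#' @export
read_trio_vcf <- function(vcf_path, pedigree_path = NULL,
                          info_keys = c(gene = "GENE", af = "AF_POP",
                                        inheritance = "INHERITANCE",
                                        clinvar = "CLNSIG",
                                        penetrance = "PENETRANCE_PED")) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)

  roles <- c(proband = samples[1], mother = samples[2], father = samples[3])
  mo_aff <- FALSE; fa_aff <- FALSE
  if (!is.null(pedigree_path)) {
    ped <- utils::read.delim(pedigree_path, stringsAsFactors = FALSE)
    .check(all(c("sample_id", "role", "affected") %in% names(ped)),
           "sample sheet needs sample_id/role/affected columns")
    .check(all(c("proband", "mother", "father") %in% ped$role),
           "sample sheet must declare proband, mother and father")
    roles <- stats::setNames(ped$sample_id[match(c("proband", "mother", "father"),
                                                 ped$role)],
                             c("proband", "mother", "father"))
    mo_aff <- isTRUE(as.logical(ped$affected[ped$role == "mother"]))
    fa_aff <- isTRUE(as.logical(ped$affected[ped$role == "father"]))
  }
  .check(all(roles %in% samples), "pedigree samples not all present in VCF")

  info_get <- function(key, rec_info) {
    m <- regmatches(rec_info, regexpr(paste0("(^|;)", key, "=[^;]*"), rec_info))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i]
    for (ai in seq_along(alts)) {
      split_gt <- function(s) {
        g <- gt[i, s]
        if (is.na(g) || g %in% c("./.", ".")) return(NA_character_)
        al <- strsplit(gsub("\\|", "/", g), "/")[[1]]
        # recode this alternate allele to 1, everything else to 0
        paste(sort(ifelse(al == as.character(ai), "1", "0")), collapse = "/")
      }
      split_ad <- function(s) {
        a <- ad[i, s]
        if (is.na(a)) return(c(NA_integer_, NA_integer_))
        parts <- suppressWarnings(as.integer(strsplit(a, ",")[[1]]))
        c(parts[1], parts[ai + 1L])
      }
      adp <- split_ad(roles[["proband"]])
      adm <- split_ad(roles[["mother"]])
      adf <- split_ad(roles[["father"]])
      af_raw <- info_get(info_keys[["af"]], info)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[ai],
        gene = info_get(info_keys[["gene"]], info) %||% NA_character_,
        gene_inheritance = info_get(info_keys[["inheritance"]], info),
        penetrance_complete_pediatric =
          grepl(paste0("(^|;)", info_keys[["penetrance"]], "(;|$|=)"), info),
        population_af = if (is.na(af_raw) || af_raw == ".") NA_real_
                        else as.numeric(af_raw),
        clinvar_status = info_get(info_keys[["clinvar"]], info),
        gt_proband = split_gt(roles[["proband"]]),
        gt_mother = split_gt(roles[["mother"]]),
        gt_father = split_gt(roles[["father"]]),
        pro_ref = adp[1], pro_alt = adp[2],
        mo_ref = adm[1], mo_alt = adm[2],
        fa_ref = adf[1], fa_alt = adf[2],
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  df$gene_inheritance[is.na(df$gene_inheritance)] <- "unknown"
  df$clinvar_status[is.na(df$clinvar_status)] <- "none"
  annotated_trio(df, mother_affected = mo_aff, father_affected = fa_aff)
}

#' Write filter decisions to TSV
#' @param decisions a \code{filter_decisions} data.frame.
#' @param path output path.
#' @export
write_decisions_tsv <- function(decisions, path) {
  utils::write.table(as.data.frame(decisions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
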