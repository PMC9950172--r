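#' Run the integrated prioritization pipeline
#'
#' Orchestrates the stages end to end: trio filter cascade, consequence
#' prediction on the transcript model, RNA junction analysis (acceptor usage
#' ratios at the study donors and novel-junction detection against the
#' catalog), allele-specific expression (zygosity/mosaicism call and
#' DNA-versus-RNA imbalance test), and splice-site delta scoring under the
#' WMM and MM1 models trained on the catalog's site windows. Candidates are
#' ranked by (de novo, loss-of-function consequence, RNA support count).
#' Stages are independent: removing an evidence source (e.g. running with no
#' RNA inputs) marks its fields "not assessed" without changing the others.
#'
#' @param study a \code{synthetic_study} from \code{\link{simulate_study}},
#'   or any list with components \code{trio} (an
#'   \code{\link{annotated_trio}}), \code{locus} (with \code{tx},
#'   \code{genome}, \code{catalog}, \code{donors}), and optionally
#'   \code{junctions} (a \code{\link{junction_counts}} table) and
#'   \code{reads} (list with \code{dna}/\code{rna} \code{allele_count}s).
#' @param alpha significance level for the binomial and Fisher tests.
#' @param min_reads novel-junction read support threshold.
#' @param min_depth,max_parent_alt de novo calling thresholds.
#' @return an \code{evidence_report}: ranked \code{candidates} data.frame,
#'   per-candidate \code{evidence} list, full \code{decisions}, and the
#'   \code{thresholds} echoed for provenance.
#' @export
run_pipeline <- function(study, alpha = 0.05, min_reads = 3,
                         min_depth = 10, max_parent_alt = 1) {
  .check(!is.null(study$trio), "study has no trio variant table")
  decisions <- run_cascade(study$trio, min_depth, max_parent_alt)
  retained <- decisions[decisions$retained, , drop = FALSE]
  tx <- study$locus$tx
  genome_seq <- study$locus$genome[[tx$chrom]]
  have_rna <- !is.null(study$junctions)
  have_reads <- !is.null(study$reads)

  evidence <- list()
  rank_rows <- list()
  for (i in seq_len(nrow(retained))) {
    vid <- retained$variant_id[i]
    row <- study$trio[study$trio$variant_id == vid, , drop = FALSE]
    ev <- list(filter = as.list(retained[i, c("rule_fired", "candidate_class",
                                              "de_novo_status", "note")]))

    # --- consequence (only variants on the modeled transcript's chromosome)
    cons <- NULL
    splice_cls <- NULL
    on_tx <- row$chrom == tx$chrom
    if (on_tx) {
      del_len <- nchar(row$ref) - nchar(row$alt)
      if (del_len > 0) {
        del_start0 <- row$pos            # anchor at pos => first deleted base
        splice_cls <- classify_splice_site_variant(tx, del_start0 = del_start0,
                                                   del_len = del_len)
        if (splice_cls$kind == "exonic") {
          s <- normalize_deletion(genome_seq, del_start0 + 1L, del_len, "hgvs_right")
          tpos <- genomic_to_tx(tx, s - 1L)
          if (!is.na(tpos) && tpos >= tx$cds_start &&
              tpos + del_len - 1L <= tx$cds_end) {
            cons <- predict_frameshift(tx, tpos - tx$cds_start + 1L, del_len)
          }
        } else {
          cons <- splice_cls
        }
      }
    }
    ev$consequence <- if (is.null(cons)) "not assessed" else unclass(cons)

    # --- DNA zygosity / mosaicism
    zyg <- classify_zygosity(row$pro_ref, row$pro_alt, alpha = alpha)
    ev$zygosity <- unclass(zyg)

    # --- RNA junction evidence
    novel <- NULL
    usage <- NULL
    aberrant_cons <- NULL
    if (have_rna && on_tx) {
      d <- study$locus$donors
      usage <- lapply(c("proband", "mother", "father"), function(s) {
        donor_usage_ratios(study$junctions, tx$chrom, d$exon3_donor, s)
      })
      names(usage) <- c("proband", "mother", "father")
      novel <- detect_novel_junctions(study$junctions, study$locus$catalog,
                                      "proband", min_reads = min_reads)
      # aberrant transcript consequence: novel junction sharing the canonical
      # acceptor but with a shifted donor = cryptic-donor exon extension
      if (nrow(novel) > 0 && !is.null(splice_cls) &&
          splice_cls$kind == "splice_donor_disruption") {
        ext <- novel$donor_pos[1] - d$exon1_donor
        if (ext > 0) aberrant_cons <- predict_exon_extension(tx, 1L, ext)
      }
      ev$usage_ratios <- lapply(usage, function(u) {
        if (attr(u, "status") == "no coverage") "no coverage" else u
      })
      ev$novel_junctions <- novel
      ev$aberrant_transcript <- if (is.null(aberrant_cons)) "none"
                                else unclass(aberrant_cons)
    } else {
      ev$usage_ratios <- "not assessed"
      ev$novel_junctions <- "not assessed"
      ev$aberrant_transcript <- "not assessed"
    }

    # --- DNA vs RNA allelic imbalance
    imb <- NULL
    if (have_reads && on_tx) {
      imb <- allelic_imbalance_test(study$reads$dna, study$reads$rna)
      ev$allelic_imbalance <- imb[c("odds_ratio", "p_one_sided", "note")]
      ev$rna_vaf_percent <- vaf(study$reads$rna)$percent
    } else {
      ev$allelic_imbalance <- "not assessed"
    }

    # --- splice-site delta scores under WMM and MM1
    deltas <- NULL
    if (on_tx && !is.null(splice_cls) &&
        splice_cls$kind %in% c("splice_donor_disruption", "exonic")) {
      deltas <- .pipeline_delta_scores(study, row, splice_cls)
    }
    ev$delta_scores <- if (is.null(deltas)) "not assessed" else deltas

    # --- informational ACMG-style tags (not scored)
    is_lof <- !is.null(cons) &&
      cons$kind %in% c("frameshift", "nonsense", "fs_no_stop",
                       "splice_donor_disruption")
    is_dn <- retained$de_novo_status[i] == "de_novo"
    ev$tags <- list(PVS1_like = is_lof, PS2_like = is_dn,
                    PM2_like = is.na(row$population_af) || row$population_af == 0)

    rna_support <- sum(c(
      !is.null(novel) && nrow(novel) > 0,
      !is.null(imb) && imb$p_one_sided < alpha,
      !is.null(usage) && .usage_shifted(usage)
    ))
    evidence[[vid]] <- ev
    rank_rows[[vid]] <- data.frame(
      variant_id = vid, gene = row$gene,
      candidate_class = retained$candidate_class[i],
      de_novo = is_dn, lof = is_lof, rna_support = rna_support,
      stringsAsFactors = FALSE
    )
  }

  candidates <- if (length(rank_rows)) do.call(rbind, rank_rows) else
    data.frame(variant_id = character(0), gene = character(0),
               candidate_class = character(0), de_novo = logical(0),
               lof = logical(0), rna_support = integer(0))
  ord <- order(-candidates$de_novo, -candidates$lof, -candidates$rna_support,
               candidates$variant_id)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL

  structure(list(schema_version = "1.0",
                 thresholds = list(alpha = alpha, min_reads = min_reads,
                                   min_depth = min_depth,
                                   max_parent_alt = max_parent_alt),
                 decisions = decisions, candidates = candidates,
                 evidence = evidence),
            class = "evidence_report")
}

# proband usage at the two competing acceptors differs from the parents'
# beyond a 3-point tolerance
.usage_shifted <- function(usage) {
  p <- usage$proband; m <- usage$mother
  if (!is.data.frame(p) || !is.data.frame(m) || nrow(p) == 0 || nrow(m) == 0) {
    return(FALSE)
  }
  shared <- intersect(p$acceptor_pos, m$acceptor_pos)
  if (length(shared) == 0) return(FALSE)
  any(abs(p$percent[match(shared, p$acceptor_pos)] -
            m$percent[match(shared, m$acceptor_pos)]) > 3)
}

# Train WMM + MM1 on the catalog's site windows and score ref vs alt windows
# around the planted deletion (donor 9-mers for donor variants, acceptor
# 23-mers for exonic deletions near an acceptor).
.pipeline_delta_scores <- function(study, row, splice_cls) {
  tx <- study$locus$tx
  g <- study$locus$genome[[tx$chrom]]
  del_len <- nchar(row$ref) - nchar(row$alt)
  del_start0 <- row$pos
  mut_g <- .delete_seq(g, del_start0 + 1L, del_len)

  if (splice_cls$kind == "splice_donor_disruption") {
    site_type <- "donor_5ss"
    donors <- unique(study$locus$catalog$donor_pos)
    train <- vapply(donors, function(dp) substr(g, dp - 2L, dp + 6L), character(1))
    ref_w <- .donor_window(g, study$locus$donors$exon1_donor)
    alt_w <- substr(mut_g, study$locus$donors$exon1_donor - 2L,
                    study$locus$donors$exon1_donor + 6L)
  } else {
    site_type <- "acceptor_3ss"
    accs <- unique(study$locus$catalog$acceptor_pos)
    train <- vapply(accs, function(ap) substr(g, ap - 19L, ap + 3L), character(1))
    ap <- study$locus$donors$acceptor_short
    if (del_start0 + del_len > ap - 20L && del_start0 < ap) {
      ref_w <- substr(g, ap - 19L, ap + 3L)
      ap_mut <- ap - del_len          # acceptor slides left by the deletion
      alt_w <- substr(mut_g, ap_mut - 19L, ap_mut + 3L)
    } else {
      return(NULL)                    # deletion does not touch a scored window
    }
  }
  models <- list(train_model(train, site_type, "WMM"),
                 train_model(train, site_type, "MM1"))
  call <- splice_weakening_call(models, ref_w, alt_w)
  list(site_type = site_type, ref_window = ref_w, alt_window = alt_w,
       deltas = as.list(call$deltas), splice_weakening = call$splice_weakening)
}

# donor 9-mer: last 3 exonic + first 6 intronic bases, donor_pos = first
# intronic base (0-based)
.donor_window <- function(genome_seq, donor_pos) {
  substr(genome_seq, donor_pos - 2L, donor_pos + 6L)
}

#' @export
print.evidence_report <- function(x, ...) {
  cat(sprintf("evidence_report (schema %s): %d candidate(s) of %d variant(s)\n",
              x$schema_version, nrow(x$candidates), nrow(x$decisions)))
  if (nrow(x$candidates)) print.data.frame(x$candidates)
  invisible(x)
}

#' Write an evidence report as JSON and TSV
#'
#' @param report an \code{evidence_report}.
#' @param dir output directory (created if needed); writes
#'   \code{evidence_report.json}, \code{candidates.tsv} and
#'   \code{decisions.tsv}.
#' @return the directory, invisibly.
#' @export
write_evidence_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(schema_version = report$schema_version,
         thresholds = report$thresholds,
         candidates = report$candidates,
         evidence = report$evidence),
    file.path(dir, "evidence_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_decisions_tsv(report$decisions, file.path(dir, "decisions.tsv"))
  invisible(dir)
}
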