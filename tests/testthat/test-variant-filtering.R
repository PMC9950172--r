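test_that("frequency filter applies inheritance-specific thresholds strictly", {
  t_ar <- annotated_trio(make_variant(inh = "AR", af = 0.06))
  expect_true(apply_frequency_filter(t_ar))

  t_ad0 <- annotated_trio(make_variant(inh = "AD", af = 0))
  expect_false(apply_frequency_filter(t_ad0))

  # boundary: strictly below the threshold passes, at the threshold is removed
  expect_false(apply_frequency_filter(annotated_trio(make_variant(inh = "AD", af = 0.009999))))
  expect_true(apply_frequency_filter(annotated_trio(make_variant(inh = "AD", af = 0.01))))
  expect_false(apply_frequency_filter(annotated_trio(make_variant(inh = "AR", af = 0.049))))
  expect_true(apply_frequency_filter(annotated_trio(make_variant(inh = "AR", af = 0.05))))

  # AD_AR and unknown inheritance use the stricter dominant threshold
  expect_true(apply_frequency_filter(annotated_trio(make_variant(inh = "AD_AR", af = 0.02))))
  expect_true(apply_frequency_filter(annotated_trio(make_variant(inh = "unknown", af = 0.02))))

  # missing frequency counts as absent from the population
  expect_false(apply_frequency_filter(annotated_trio(make_variant(inh = "AR", af = NA))))

  expect_error(annotated_trio(make_variant(af = 1.2)), "population_af")
})

test_that("ClinVar filters remove borderline benign and risk-factor variants", {
  cl <- function(af, status) {
    apply_clinvar_filters(annotated_trio(make_variant(inh = "AR", af = af,
                                                      clinvar = status)))
  }
  expect_true(cl(0.03, "likely_benign")$rule_ii)
  expect_true(cl(0.01, "benign")$rule_ii)
  expect_true(cl(0.05, "benign")$rule_ii)
  expect_false(cl(0.005, "benign")$rule_ii)      # below the borderline band
  expect_false(cl(0.03, "benign_conflicting")$rule_ii)  # conflicts: retained
  expect_true(cl(0.0, "risk_factor")$rule_iii)
  expect_true(cl(0.2, "histocompatibility")$rule_iii)
  expect_false(cl(0.0, "pathogenic")$rule_iii)
  expect_error(annotated_trio(make_variant(clinvar = "bogus")), "benign")
})

test_that("de novo detection requires a covered, alternate-free parental pair", {
  dn <- function(...) detect_de_novo(annotated_trio(make_variant(...)))
  expect_equal(dn(pro = c(19, 25), mo = c(30, 0), fa = c(30, 0)), "de_novo")
  expect_equal(dn(pro = c(40, 0), mo = c(30, 0), fa = c(30, 0)), "not_de_novo")
  expect_equal(dn(pro = c(19, 25), mo = c(5, 0), fa = c(30, 0)), "unresolvable")
  expect_equal(dn(pro = c(19, 25), mo = c(NA, NA), fa = c(30, 0)), "unresolvable")
  # one stray parental alt read is tolerated, two are not
  expect_equal(dn(pro = c(19, 25), mo = c(30, 1), fa = c(30, 0)), "de_novo")
  expect_equal(dn(pro = c(19, 25), mo = c(30, 2), fa = c(30, 0)), "not_de_novo")
  # a parent genotyped as a carrier blocks the call even with clean counts
  expect_equal(dn(pro = c(19, 25), gt_fa = "0/1"), "not_de_novo")
})

test_that("inheritance filters handle dominant transmission and recessive pairing", {
  # rule iv: AD complete-penetrance gene, het inherited from unaffected father
  v <- annotated_trio(make_variant(inh = "AD", pen = TRUE, gt_pro = "0/1",
                                   gt_fa = "0/1", fa = c(20, 20)))
  expect_true(apply_inheritance_filters(v)$rule_iv)
  # without the penetrance flag the variant survives rule iv
  v2 <- annotated_trio(make_variant(inh = "AD", pen = FALSE, gt_pro = "0/1",
                                    gt_fa = "0/1", fa = c(20, 20)))
  expect_false(apply_inheritance_filters(v2)$rule_iv)
  # an affected carrier parent does not trigger rule iv
  v3 <- annotated_trio(make_variant(inh = "AD", pen = TRUE, gt_pro = "0/1",
                                    gt_fa = "0/1", fa = c(20, 20)),
                       father_affected = TRUE)
  expect_false(apply_inheritance_filters(v3)$rule_iv)

  # rule v: lone AR het inherited from a parent is removed ...
  lone <- annotated_trio(make_variant(inh = "AR", gt_pro = "0/1",
                                      gt_mo = "0/1", mo = c(20, 20)))
  expect_true(apply_inheritance_filters(lone)$rule_v)
  # ... unless it is de novo
  dn <- annotated_trio(make_variant(inh = "AR", gt_pro = "0/1",
                                    pro = c(19, 25)))
  expect_false(apply_inheritance_filters(dn)$rule_v)

  # compound het: two AR hets with opposite parental origin both retained
  ch <- annotated_trio(rbind(
    make_variant(pos = 10, gene = "GAR", inh = "AR", gt_pro = "0/1",
                 gt_mo = "0/1", mo = c(20, 20)),
    make_variant(pos = 20, gene = "GAR", inh = "AR", gt_pro = "0/1",
                 gt_fa = "0/1", fa = c(20, 20))))
  res <- apply_inheritance_filters(ch)
  expect_false(any(res$rule_v))
  expect_equal(res$candidate_class, c("compound_het", "compound_het"))

  # homozygous recessive proband
  hr <- annotated_trio(make_variant(inh = "AR", gt_pro = "1/1", gt_mo = "0/1",
                                    gt_fa = "0/1", pro = c(0, 40),
                                    mo = c(20, 20), fa = c(20, 20)))
  expect_equal(apply_inheritance_filters(hr)$candidate_class, "homozygous_recessive")

  # phase unresolvable: both hets carried by both parents -> retained + note
  pu <- annotated_trio(rbind(
    make_variant(pos = 10, gene = "GAR", inh = "AR", gt_pro = "0/1",
                 gt_mo = "0/1", gt_fa = "0/1", mo = c(20, 20), fa = c(20, 20)),
    make_variant(pos = 20, gene = "GAR", inh = "AR", gt_pro = "0/1",
                 gt_mo = "0/1", gt_fa = "0/1", mo = c(20, 20), fa = c(20, 20))))
  res <- apply_inheritance_filters(pu)
  expect_false(any(res$rule_v))
  expect_true(all(res$note == "phase_unknown"))
})

test_that("the six-variant toy set fires each rule once and keeps the de novo", {
  dec <- run_cascade(annotated_trio(make_toy_cascade_set()))
  expect_equal(sum(dec$retained), 1L)
  expect_setequal(dec$rule_fired,
                  c("i_frequency", "ii_borderline_benign", "iii_clinvar_category",
                    "iv_inherited_dominant", "v_unpaired_recessive", "none"))
  surv <- dec[dec$retained, ]
  expect_equal(surv$gene, "GNEW")
  expect_equal(surv$candidate_class, "de_novo")
})

test_that("cascade handles empty input and preserves (chrom, pos) order", {
  empty <- annotated_trio(make_variant()[0, ])
  expect_equal(nrow(run_cascade(empty)), 0L)

  shuffled <- make_toy_cascade_set()[c(4, 1, 6, 3, 5, 2), ]
  dec <- run_cascade(annotated_trio(shuffled))
  expect_equal(dec$pos, sort(dec$pos))
})

# random annotated trio generator for the property checks
random_trio_df <- function(n) {
  genes <- sprintf("G%02d", 1:8)
  inh <- sample(c("AD", "AR", "AD_AR", "unknown"), 8, replace = TRUE)
  pen <- sample(c(TRUE, FALSE), 8, replace = TRUE)
  gi <- sample.int(8, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    gts <- c("0/0", "0/1", "1/1")
    gm <- sample(gts, 1, prob = c(0.6, 0.3, 0.1))
    gf <- sample(gts, 1, prob = c(0.6, 0.3, 0.1))
    gp <- sample(gts, 1, prob = c(0.3, 0.6, 0.1))
    cnt <- function(g, dn_zero = FALSE) {
      dp <- sample(c(5, 15, 40), 1, prob = c(0.1, 0.3, 0.6))
      alt <- round(dp * c(`0/0` = 0, `0/1` = 0.5, `1/1` = 1)[g])
      c(dp - alt, alt)
    }
    make_variant(pos = i * 13, gene = genes[gi[i]], inh = inh[gi[i]],
                 pen = pen[gi[i]],
                 af = sample(c(NA, 0.001, 0.011, 0.03, 0.06), 1),
                 clinvar = sample(c("none", "VUS", "benign", "likely_benign",
                                    "benign_conflicting", "risk_factor"), 1),
                 gt_pro = gp, gt_mo = gm, gt_fa = gf,
                 pro = cnt(gp), mo = cnt(gm), fa = cnt(gf))
  }))
}

test_that("cascade equals the per-rule set-operation oracle on random sets", {
  set.seed(42)
  for (trial in 1:15) {
    df <- random_trio_df(sample(c(5, 30, 120, 200), 1))
    trio <- annotated_trio(df)
    dec <- run_cascade(trio)
    ora <- oracle_cascade(trio)
    m <- match(dec$variant_id, ora$variant_id)
    expect_equal(dec$retained, ora$retained[m])
    expect_equal(dec$rule_fired, ora$rule_fired[m])
    expect_equal(dec$candidate_class, ora$candidate_class[m])
  }
})

test_that("cascade is deterministic, rule-exclusive and af-monotone", {
  set.seed(99)
  df <- random_trio_df(80)
  trio <- annotated_trio(df)
  d1 <- run_cascade(trio)
  d2 <- run_cascade(trio)
  expect_identical(d1, d2)

  # exactly one rule per removed variant; none for retained
  expect_true(all((d1$rule_fired == "none") == d1$retained))

  # lowering any retained variant's frequency never flips it to removed
  kept <- d1$variant_id[d1$retained]
  df2 <- df
  df2$population_af <- pmax(0, ifelse(is.na(df2$population_af), NA,
                                      df2$population_af / 10))
  d3 <- run_cascade(annotated_trio(df2))
  expect_true(all(kept %in% d3$variant_id[d3$retained]))
})
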