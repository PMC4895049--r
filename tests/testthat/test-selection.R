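# Branch-length transform, PBS combination, outlier calling and the
# enrichment tests.

test_that("branch length transform and its edge cases", {
  expect_equal(branch_length_T(0), 0)
  expect_equal(branch_length_T(0.5), -log(0.5))
  expect_equal(round(branch_length_T(0.5), 4), 0.6931)
  expect_equal(round(branch_length_T(0.09), 4), 0.0943)
  expect_equal(branch_length_T(-0.1), 0)           # clamped
  expect_warning(expect_equal(branch_length_T(1), Inf), "infinite")
  expect_error(branch_length_T(1.2), "above 1")
})

test_that("PBS combines branch lengths and is additive", {
  t_ab <- branch_length_T(0.2); t_ac <- branch_length_T(0.2)
  t_bc <- branch_length_T(0.05)
  expect_equal(pbs(t_ab, t_ac, t_bc),
               (0.22314355 + 0.22314355 - 0.05129329) / 2,
               tolerance = 1e-7)
  expect_equal(pbs(0.4, 0.4, 0.4), 0.2)            # symmetric trio
  expect_equal(pbs(0.1, 0.1, 0.5), -0.15)          # negative, unclamped
  # pbs_A + pbs_B = t_ab exactly, over random trios
  set.seed(2)
  for (i in 1:50) {
    tt <- runif(3, 0, 2)
    expect_equal(pbs(tt[1], tt[2], tt[3]) + pbs(tt[1], tt[3], tt[2]),
                 tt[1], tolerance = 1e-12)
  }
})

test_that("pbs_scan matches a by-hand window computation", {
  ds <- simulate_cohort(ecotype_scenario(0.1, 1), scenario_layout(0.1),
                        five_pop_samples(6), seed = 6)
  tab <- suppressWarnings(pbs_scan(ds, c("B1", "B2", "C"),
                                   window_bp = 50000, step_bp = 50000))
  st <- as_site_table(ds)
  w <- tab[3, c("chrom", "start", "end")]
  f_ab <- window_fst(st, "B1", "B2", w)$fst
  f_ac <- window_fst(st, "B1", "C", w)$fst
  f_bc <- window_fst(st, "B2", "C", w)$fst
  tt <- function(f) -log(1 - max(f, 0))
  expect_equal(tab$pbs_focal[3],
               (tt(f_ab) + tt(f_ac) - tt(f_bc)) / 2, tolerance = 1e-12)
  expect_equal(tab$pbs_focal + tab$pbs_sister, tab$t_ab,
               tolerance = 1e-12)
})

test_that("a sweep in the outgroup population leaves the focal branch flat", {
  ds <- simulate_cohort(ecotype_scenario(0.2, 1), scenario_layout(0.2),
                        five_pop_samples(8), seed = 13)
  reg <- list(chrom = "chr2", start = 100000, end = 150000)
  ds <- spike_sweep(ds, reg, "C", 0.5)
  tab <- suppressWarnings(pbs_scan(ds, c("B1", "B2", "C")))
  in_reg <- tab$chrom == "chr2" & tab$start < 150000 & tab$end > 100000
  thr99 <- quantile(tab$pbs_focal[tab$eligible], 0.99, na.rm = TRUE)
  expect_lt(max(tab$pbs_focal[in_reg]), thr99)
  # but the outgroup branch itself is elevated there
  expect_gt(max(tab$pbs_out[in_reg]),
            quantile(tab$pbs_out[tab$eligible], 0.99, na.rm = TRUE))
})

test_that("outlier_call takes the k-th largest with ties included", {
  rec <- data.frame(pbs_focal = c(100:1) / 10)
  oc <- suppressWarnings(outlier_call(rec, percentile = 99.9))
  expect_equal(nrow(oc$outliers), 1)
  set.seed(1)
  rec2 <- data.frame(pbs_focal = sample(c(1:9990 / 100, rep(99.91, 10))))
  oc2 <- outlier_call(rec2, percentile = 99.9)
  expect_equal(nrow(oc2$outliers), 10)
  expect_equal(oc2$threshold, 99.91)
  # ties at the threshold are all returned
  rec3 <- data.frame(pbs_focal = c(rep(5, 20), 1:1980 / 1000))
  oc3 <- outlier_call(rec3, percentile = 99.9)
  expect_equal(nrow(oc3$outliers), 20)
  # degenerate all-equal input returns everything
  rec4 <- data.frame(pbs_focal = rep(1, 50))
  expect_equal(nrow(suppressWarnings(
    outlier_call(rec4, 99.9))$outliers), 50)
  # percentile 0 returns all features
  expect_equal(nrow(suppressWarnings(
    outlier_call(rec, 0))$outliers), 100)
  expect_error(outlier_call(rec[0, , drop = FALSE], 99.9))
})

test_that("top_fst_snps keeps the top fraction with ties", {
  snps <- data.frame(fst = c(1:1000) / 1000)
  expect_equal(nrow(top_fst_snps(snps)), 10)
  expect_equal(nrow(top_fst_snps(snps, fraction = 1)), 1000)
  tied <- data.frame(fst = c(rep(0.99, 25), 1:975 / 10000))
  expect_equal(nrow(top_fst_snps(tied, 0.01)), 25)
  expect_error(top_fst_snps(data.frame(fst = numeric(0))), "no SNPs")
})

test_that("category-bin residuals match hand-computed Pearson residuals", {
  # 2 categories x 2 bins: obs (30, 70) and (10, 90), n = 200
  snps <- data.frame(
    fst = c(rep(0.05, 100), rep(0.95, 100)),
    category = c(rep("exon", 30), rep("intergenic", 70),
                 rep("exon", 10), rep("intergenic", 90)))
  et <- category_bin_chisq(snps, bins = c(0, 0.5, 1))
  # margins: 40 exon / 160 intergenic, 100 per bin -> E(exon, bin) = 20
  expect_equal(unname(et$expected["exon", ]), c(20, 20))
  expect_equal(unname(et$residuals["exon", 1]), (30 - 20) / sqrt(20))
  expect_equal(unname(et$residuals["intergenic", 2]), (90 - 80) / sqrt(80))
  # observed sums are preserved
  expect_equal(sum(et$observed), 200)
  # cross-check the statistic against stats::chisq.test on the same table
  ct <- suppressWarnings(stats::chisq.test(et$observed, correct = FALSE))
  expect_equal(et$chisq, unname(ct$statistic))
  expect_equal(et$residuals, ct$residuals, ignore_attr = TRUE)
})

test_that("enrichment flags respect Bonferroni and expected-count rules", {
  # observed equal to expected: no residuals, no flags
  snps <- data.frame(fst = rep(c(0.05, 0.95), each = 50),
                     category = rep(c("exon", "intergenic"), 50))
  et <- category_bin_chisq(snps, bins = c(0, 0.5, 1))
  expect_true(all(abs(et$residuals) < 1e-12))
  expect_false(any(et$significant))
  # per-cell alpha is alpha / cells tested
  expect_equal(et$alpha_cell, 0.05 / sum(!et$unreliable))
  # tiny expected counts are excluded from testing
  snps2 <- data.frame(fst = c(rep(0.05, 99), 0.95),
                      category = c(rep("intergenic", 99), "exon"))
  et2 <- category_bin_chisq(snps2, bins = c(0, 0.5, 1))
  expect_true(any(et2$unreliable))
  expect_false(any(et2$significant & et2$unreliable))
})

test_that("Fisher term enrichment matches the hypergeometric tail", {
  bg <- paste0("g", 1:100)
  ann <- data.frame(gene = c(paste0("g", 1:18)),
                    term = c(rep("T1", 18)))
  out <- paste0("g", c(1:8, 50, 51))      # 8 of 10 outliers in T1
  res <- fisher_term_enrichment(out, ann, bg)
  # 2x2: a=8 outliers in term, b=2 out, c=10 in-term non-outlier, d=80
  expect_equal(res$p_value, oracle_fisher_greater(8, 2, 10, 80),
               tolerance = 1e-9)
  expect_equal(res$p_bonferroni, min(1, res$p_value * nrow(res)))
  # a term covering every gene is uninformative
  all_ann <- data.frame(gene = bg, term = "ALL")
  expect_equal(fisher_term_enrichment(out, all_ann, bg)$p_value, 1)
  # empty outlier set gives an empty table
  expect_equal(nrow(fisher_term_enrichment(character(0), ann, bg)), 0)
  expect_error(fisher_term_enrichment("zzz", ann, bg), "subset")
})
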