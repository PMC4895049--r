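# Ancestral assignment, mutation classification, derived-count partitions,
# Ts/Tv and the derived-mutation clock.

test_that("mutation classification follows the purine/pyrimidine rule", {
  expect_identical(classify_mutation("A", "G"), "transition")
  expect_identical(classify_mutation("C", "T"), "transition")
  expect_identical(classify_mutation("A", "T"), "transversion")
  expect_identical(classify_mutation("G", "C"), "transversion")
  # symmetric in its arguments
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in setdiff(bases, a))
    expect_identical(classify_mutation(a, b), classify_mutation(b, a))
  expect_error(classify_mutation("A", "A"), "differ")
  expect_error(classify_mutation("A", "N"), "A, C, G or T")
})

test_that("ancestral assignment requires an observed ingroup allele", {
  geno <- matrix(c(0L, 1L, 2L), nrow = 3, ncol = 2)
  st <- toy_site_table(geno, c("A", "A"), ref = "A", alt = "G", anc = NA)
  outg <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     allele = c("A", "G", "T"))
  res <- assign_ancestral(st, outg)
  expect_identical(res$sites$sites$anc, c("A", "G", NA))
  expect_equal(res$report$inferable, 2)
  expect_equal(res$report$percent, 100 * 2 / 3)
  # all-unknown outgroup gives zero coverage
  outg$allele <- NA_character_
  expect_equal(assign_ancestral(st, outg)$report$percent, 0)
})

test_that("derived-count partition identity holds by construction", {
  dc <- derived_counts(ti_fixed = 11176, ti_within = 1608,
                       tv_fixed = 7120, tv_within = 421, mixed = 6)
  expect_identical(dc$ti_total, 11176 + 1608)
  expect_identical(dc$tv_total, 7120 + 421 + 6)
  expect_error(derived_counts(ti_fixed = -1), ">= 0")
})

test_that("derived counts on a constructed 9-genotype panel match enumeration", {
  # 4 third-codon sites over 9 individuals:
  #  s1: A->T transversion fixed (all hom derived)
  #  s2: A->C transversion fixed
  #  s3: A->T transversion segregating at freq 6/18
  #  s4: A->G transition segregating at freq 2/18 (above the 0.1 cutoff)
  #  s5: A->G transition segregating at 1/18 (below cutoff, dropped)
  geno <- rbind(rep(2L, 9),
                rep(2L, 9),
                c(2L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  st <- toy_site_table(geno, rep("P", 9),
                       alt = c("T", "C", "T", "G", "G"),
                       third_codon = TRUE)
  dc <- count_derived_by_class(st)
  expect_equal(dc$tv_fixed, 2)
  expect_equal(dc$tv_within, 1)
  expect_equal(dc$ti_within, 1)
  expect_equal(dc$ti_fixed, 0)
  expect_equal(dc$nonmissing_sites, 5)

  # a site with missing data in any panel individual is masked out
  geno2 <- geno
  geno2[3, 9] <- NA_integer_
  st2 <- toy_site_table(geno2, rep("P", 9),
                        alt = c("T", "C", "T", "G", "G"),
                        third_codon = TRUE)
  expect_equal(count_derived_by_class(st2)$tv_within, 0)

  # all-ancestral input gives zero counts
  st0 <- toy_site_table(matrix(0L, 2, 9), rep("P", 9), third_codon = TRUE)
  expect_equal(count_derived_by_class(st0)$ti_total +
                 count_derived_by_class(st0)$tv_total, 0)
})

test_that("minor-frequency mode differs from derived-frequency mode", {
  # derived freq 17/18 (> 0.9): derived mode keeps it, minor mode drops it
  geno <- rbind(c(rep(2L, 8), 1L))
  st <- toy_site_table(geno, rep("P", 9), alt = "T", third_codon = TRUE)
  expect_equal(count_derived_by_class(st)$tv_within, 1)
  expect_equal(count_derived_by_class(st, freq_type = "minor")$tv_within, 0)
})

test_that("Ts/Tv handles scope, mixed-site convention and errors", {
  dc <- derived_counts(ti_fixed = 11176, ti_within = 1608,
                       tv_fixed = 7120, tv_within = 421, mixed = 6)
  expect_equal(round(estimate_tstv(dc), 1), 3.8)
  expect_equal(round(estimate_tstv(dc, include_mixed = TRUE), 1), 3.8)
  expect_equal(estimate_tstv(dc, include_mixed = TRUE), 1614 / 427)
  expect_equal(estimate_tstv(derived_counts(ti_within = 100,
                                            tv_within = 100)), 1.0)
  expect_error(estimate_tstv(derived_counts(ti_within = 5)), "zero")
})

test_that("shared derived fractions count carrier overlap", {
  # 3 sites derived in i1; i2 carries 2 of them; i3 none
  geno <- rbind(c(2L, 1L, 0L),
                c(1L, 2L, 0L),
                c(1L, 0L, 0L))
  st <- toy_site_table(geno, rep("P", 3), third_codon = TRUE,
                       alt = "T")
  expect_equal(shared_derived_fraction(st, "i1", "i2", maf_cutoff = 0),
               2 / 3)
  expect_equal(shared_derived_fraction(st, "i1", "i1", maf_cutoff = 0), 1)
  expect_equal(shared_derived_fraction(st, "i1", "i3", maf_cutoff = 0), 0)
  expect_error(shared_derived_fraction(st, "i3", "i1", maf_cutoff = 0),
               "no derived")
})

test_that("the TMRCA formula scales as derived_count / (L * class rate)", {
  est <- estimate_tmrca(124, "transversion", L = 3127876,
                        mu_total = 9.10e-10, tstv = 3.8)
  expect_equal(est$years, 124 / (3127876 * 9.10e-10 / 4.8))
  # doubling L halves the age
  est2 <- estimate_tmrca(124, "transversion", L = 2 * 3127876,
                         mu_total = 9.10e-10, tstv = 3.8)
  expect_equal(est2$years, est$years / 2)
  expect_equal(estimate_tmrca(0, "combined", L = 1e6,
                              mu_total = 1e-9)$years, 0)
  # class rates partition the total rate
  ti <- estimate_tmrca(1, "transition", 1, 1e-9, tstv = 3.8)$years
  tv <- estimate_tmrca(1, "transversion", 1, 1e-9, tstv = 3.8)$years
  expect_equal(1 / ti + 1 / tv, 1e-9)
  # rate HPD: larger rate gives younger bound, endpoints ordered
  est3 <- estimate_tmrca(124, "transversion", 3127876, 9.10e-10,
                         mu_hpd = c(6.68e-10, 1.18e-9), tstv = 3.8)
  expect_lt(est3$interval_years[1], est3$years)
  expect_gt(est3$interval_years[2], est3$years)
  expect_error(estimate_tmrca(1, "transversion", 0, 1e-9, tstv = 3.8))
})
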