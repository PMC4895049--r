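# FST / Dxy / pi arithmetic, ratio-of-sums aggregation, and the window
# scan's alignment and correlation machinery.

test_that("site FST components match direct formula evaluation", {
  cc <- site_fst_components(0.5, 20, 0.25, 20)
  expect_equal(cc$numerator, 0.0625 - 0.25 / 19 - 0.1875 / 19)
  expect_equal(round(cc$numerator, 6), 0.039474)
  expect_equal(cc$denominator, 0.5)
  expect_equal(round(cc$numerator / cc$denominator, 4), 0.0789)

  fixed <- site_fst_components(1, 50, 0, 50)
  expect_equal(fixed$numerator, 1)
  expect_equal(fixed$denominator, 1)

  eq <- site_fst_components(0.3, 1000, 0.3, 1000)
  expect_equal(eq$numerator, -2 * 0.3 * 0.7 / 999)
  expect_error(site_fst_components(0.5, 1, 0.5, 20))
})

test_that("site Dxy is symmetric, bounded and matches arithmetic", {
  expect_equal(site_dxy(0.3, 0.6), 0.3 * 0.4 + 0.6 * 0.7)
  expect_equal(site_dxy(0.3, 0.6), 0.54)
  expect_equal(site_dxy(1, 0), 1)
  expect_equal(site_dxy(0.5, 0.5), 0.5)
  expect_equal(site_dxy(0, 0), 0)
  set.seed(1)
  p1 <- runif(200); p2 <- runif(200)
  expect_equal(site_dxy(p1, p2), site_dxy(p2, p1))
  expect_true(all(site_dxy(p1, p2) >= 0 & site_dxy(p1, p2) <= 1))
})

test_that("window FST ratio-of-sums matches the brute-force oracle", {
  set.seed(7)
  n <- 100
  geno_a <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  geno_b <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  storage.mode(geno_a) <- storage.mode(geno_b) <- "integer"
  st <- toy_site_table(cbind(geno_a, geno_b), rep(c("A", "B"), each = 10))
  w <- data.frame(chrom = "chr1", start = 0, end = 2000)
  got <- window_fst(st, "A", "B", w)
  want <- oracle_fst_window(rowMeans(geno_a) / 2, rep(20, n),
                            rowMeans(geno_b) / 2, rep(20, n))
  expect_equal(got$fst_num, unname(want["num"]), tolerance = 1e-12)
  expect_equal(got$fst_den, unname(want["den"]), tolerance = 1e-12)
  expect_equal(got$fst, unname(want["fst"]), tolerance = 1e-12)
  expect_lte(got$fst, 1)
})

test_that("all fixed differences give window FST 1; no variation flags NA", {
  geno <- rbind(c(2L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L))
  st <- toy_site_table(geno, c("A", "A", "B", "B"))
  w <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_equal(window_fst(st, "A", "B", w)$fst, 1)
  st0 <- toy_site_table(matrix(0L, 2, 4), c("A", "A", "B", "B"))
  expect_true(is.na(window_fst(st0, "A", "B", w)$fst))
})

test_that("pooled half-windows reproduce the full window by sum additivity", {
  set.seed(11)
  geno <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  storage.mode(geno) <- "integer"
  st <- toy_site_table(geno, rep(c("A", "B"), each = 4),
                       pos = sort(sample.int(50000, 60)) - 1L)
  full <- window_fst(st, "A", "B",
                     data.frame(chrom = "chr1", start = 0, end = 50000))
  halves <- window_fst(st, "A", "B",
                       data.frame(chrom = "chr1", start = c(0, 25000),
                                  end = c(25000, 50000)))
  expect_equal(sum(halves$fst_num), full$fst_num, tolerance = 1e-12)
  expect_equal(sum(halves$fst_den), full$fst_den, tolerance = 1e-12)
  expect_equal(sum(halves$fst_num) / sum(halves$fst_den), full$fst,
               tolerance = 1e-12)
})

test_that("window pi matches the unbiased per-site formula", {
  # one site at p = 0.5 over n = 10 sampled alleles (5 diploids)
  geno <- rbind(c(1L, 1L, 1L, 1L, 1L))
  st <- toy_site_table(geno, rep("A", 5))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(window_pi(st, "A", w)$pi, 0.5 * (10 / 9) / 1000)
  expect_equal(round(window_pi(st, "A", w)$pi, 6), 5.56e-4)
  # monomorphic window
  st0 <- toy_site_table(matrix(2L, 1, 5), rep("A", 5))
  expect_equal(window_pi(st0, "A", w)$pi, 0)
  expect_error(window_pi(st, "A",
                         data.frame(chrom = "chr1", start = 0, end = 0)),
               "zero covered")
})

test_that("the pi estimator is unbiased under binomial resampling", {
  set.seed(3)
  p <- 0.3; n_al <- 20
  h <- replicate(1000, {
    d <- rbinom(1, n_al, p)
    ph <- d / n_al
    2 * ph * (1 - ph) * n_al / (n_al - 1)
  })
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - 2 * p * (1 - p)), 2 * se)
})

test_that("landscape scan aligns tables and handles eligibility", {
  ds <- simulate_cohort(ecotype_scenario(0.1, 1), scenario_layout(0.1),
                        five_pop_samples(6), seed = 4)
  tabs <- landscape_scan(ds, list(c("B1", "B2"), c("B1", "C"),
                                  c("B1", "B2")),
                         window_bp = 50000)
  expect_identical(tabs[[1]][c("chrom", "start", "end")],
                   tabs[[2]][c("chrom", "start", "end")])
  # identical comparisons give identical tables
  expect_identical(tabs[[1]], tabs[[3]])
  expect_true(all(tabs[[1]]$eligible))
  expect_true(all(tabs[[1]]$fst <= 1, na.rm = TRUE))
  expect_true(all(tabs[[1]]$dxy >= 0 & tabs[[1]]$pi_pop1 >= 0,
                  na.rm = TRUE))
})

test_that("rank correlations: self-correlation 1, independent tables ~0", {
  set.seed(5)
  w <- data.frame(chrom = "chr1", start = 0:199 * 1000,
                  end = 1:200 * 1000)
  t1 <- cbind(w, fst = runif(200))
  t2 <- cbind(w, fst = runif(200))
  rho <- landscape_correlations(list(a = t1, b = t2), "fst")
  expect_equal(unname(diag(rho)), c(1, 1))
  expect_equal(rho, t(rho))
  expect_lt(abs(rho["a:fst", "b:fst"]), 0.2)
  rho_self <- landscape_correlations(list(a = t1, b = t1), "fst")
  expect_equal(unname(rho_self["a:fst", "b:fst"]), 1)
  expect_error(landscape_correlations(list(a = t1[1:5, ], b = t2[1:5, ]),
                                      "fst"), "aligned windows")
})

test_that("shared low-diversity regions induce positive FST correlations", {
  # common ancestral diversity profile drives both comparisons
  set.seed(8)
  w <- data.frame(chrom = "chr1", start = 0:99 * 1000, end = 1:100 * 1000)
  base <- runif(100, 0.05, 0.6)
  t1 <- cbind(w, fst = base + rnorm(100, 0, 0.05))
  t2 <- cbind(w, fst = base + rnorm(100, 0, 0.05))
  rho <- landscape_correlations(list(a = t1, b = t2), "fst")
  expect_gt(rho["a:fst", "b:fst"], 0.5)
})
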