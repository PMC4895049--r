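# Simulator: model construction, determinism, neutral expectations,
# sweep spiking arithmetic, and file round-trips.

test_that("the five-ecotype scenario has the required structure", {
  m <- ecotype_scenario(scale = 1, seed = 7)
  expect_s3_class(m, "demographic_model")
  expect_setequal(leaf_populations(m), c("RES", "TRA", "B1", "B2", "C"))
  bottl <- m$epochs[m$epochs$ne < 1000, ]
  expect_gte(nrow(bottl), 3)
  expect_true(all(bottl$ne >= 2))
  expect_identical(m$pulses$source, "RES")
  expect_identical(m$pulses$dest, "TRA")
  # identical calls give identical models
  expect_identical(ecotype_scenario(1, 7), ecotype_scenario(1, 7))
  expect_error(ecotype_scenario(scale = -1), "positive")
})

test_that("model validation enforces pulse and epoch bounds", {
  base <- ecotype_scenario()
  ok <- base
  ok$pulses$fraction <- 0.1
  expect_silent(validate_model(ok))
  bad <- base
  bad$pulses$fraction <- 1.5
  expect_error(validate_model(bad), "fraction")
  bad2 <- base
  bad2$epochs$ne[1] <- 1
  expect_error(validate_model(bad2), "Ne >= 2")
  expect_error(genome_layout("chr1", 0), "length_bp > 0")
})

test_that("simulation is deterministic under a fixed seed", {
  m <- neutral_model()
  lay <- genome_layout("chr1", 2e5)
  d1 <- simulate_cohort(m, lay, c(A = 5), seed = 42)
  d2 <- simulate_cohort(m, lay, c(A = 5), seed = 42)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$geno, d2$geno)
  d3 <- simulate_cohort(m, lay, c(A = 5), seed = 43)
  expect_false(identical(d1$sites, d3$sites))
})

test_that("simulate_cohort rejects bad inputs", {
  m <- neutral_model()
  lay <- genome_layout("chr1", 1e5)
  expect_error(simulate_cohort(m, lay, c(Z = 5), seed = 1), "populations")
  empty <- structure(data.frame(chrom = character(),
                                length_bp = numeric()),
                     class = c("genome_layout", "data.frame"))
  expect_error(simulate_cohort(m, empty, c(A = 2), seed = 1),
               "zero-length")
})

test_that("nucleotide diversity matches the 4*Ne*mu neutral expectation", {
  m <- neutral_model(ne = 10000, mu = 1e-8)
  lay <- genome_layout("chr1", 5e5)
  pis <- vapply(1:6, function(s) {
    st <- as_site_table(simulate_cohort(m, lay, c(A = 10), seed = s))
    window_pi(st, "A", data.frame(chrom = "chr1", start = 0, end = 5e5))$pi
  }, numeric(1))
  expect_lt(abs(mean(pis) - 4e-4) / 4e-4, 0.10)
})

test_that("a pair split zero generations ago shows no differentiation", {
  m <- pair_model(t_split = 0)
  lay <- genome_layout("chr1", 5e5)
  st <- as_site_table(simulate_cohort(m, lay, c(A = 10, B = 10), seed = 5))
  w <- data.frame(chrom = "chr1", start = 0, end = 5e5)
  f <- window_fst(st, "A", "B", w)
  expect_lt(abs(f$fst), 0.02)
})

test_that("spike_sweep displaces frequencies by p + shift*(1-p)", {
  geno <- matrix(0L, nrow = 3, ncol = 5)
  geno[1, 1] <- 2L                      # p = 0.2
  geno[2, ] <- c(2L, 2L, 0L, 0L, 0L)    # p = 0.4
  st <- toy_site_table(geno, rep("A", 5))
  ds <- structure(list(layout = genome_layout("chr1", 100),
                       panel = st$panel, sites = st$sites, geno = st$geno,
                       annotations = annotate_layout(genome_layout("chr1", 100)),
                       truth = list(model = NULL, seed = 1,
                                    sweeps = ecoscan:::empty_sweep_table())),
                  class = "sim_dataset")
  reg <- list(chrom = "chr1", start = 0, end = 100)

  sw <- spike_sweep(ds, reg, "A", 0.5)
  p <- rowSums(sw$geno) / 10
  expect_equal(p[1], 0.2 + 0.5 * 0.8)   # 0.6
  expect_equal(p[2], 0.4 + 0.5 * 0.6)   # 0.7
  expect_equal(p[3], 0.5)               # 0 + 0.5

  expect_identical(spike_sweep(ds, reg, "A", 0)$geno, ds$geno)
  fixed <- spike_sweep(ds, reg, "A", 1)
  expect_true(all(rowSums(fixed$geno) == 10))
  expect_equal(nrow(fixed$truth$sweeps), 1L)

  expect_error(spike_sweep(ds, list(chrom = "chr1", start = 5, end = 5),
                           "A", 0.5), "empty")
  expect_error(spike_sweep(ds, reg, "Z", 0.5), "unknown")
})

test_that("written datasets round-trip losslessly through the reader", {
  m <- ecotype_scenario(0.1, 1)
  ds <- simulate_cohort(m, scenario_layout(0.1), five_pop_samples(3),
                        seed = 11)
  dir <- withr::local_tempdir()
  files <- write_dataset(ds, dir)
  expect_true(all(file.exists(files)))
  st1 <- as_site_table(ds)
  st2 <- read_cohort(dir)
  cols <- c("chrom", "pos", "ref", "alt", "anc", "category", "third_codon")
  expect_equal(st2$sites[cols], st1$sites[cols],
               ignore_attr = TRUE)
  expect_identical(unname(st2$geno), unname(st1$geno))
  # AA tag present for every polarizable site
  vcf_lines <- readLines(gzfile(file.path(dir, "cohort.vcf.gz")))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_equal(sum(grepl("AA=[ACGT]", body)), sum(!is.na(ds$sites$anc)))
})

test_that("a dataset with zero variants writes a header-only VCF", {
  m <- neutral_model()
  lay <- genome_layout("chr1", 1e5)
  ds <- simulate_cohort(m, lay, c(A = 2), seed = 1)
  ds$sites <- ds$sites[0, , drop = FALSE]
  ds$geno <- ds$geno[0, , drop = FALSE]
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  st <- read_cohort(dir)
  expect_equal(nrow(st$sites), 0L)
  lines <- readLines(gzfile(file.path(dir, "cohort.vcf.gz")))
  expect_true(all(startsWith(lines, "#")))
})

test_that("ancestral states can be mislabeled at a configured error rate", {
  m <- neutral_model(ne = 20000, mu = 2e-8)
  lay <- genome_layout("chr1", 2e5)
  ds <- simulate_cohort(m, lay, c(A = 5), seed = 2, anc_error = 0.3)
  frac <- mean(ds$sites$anc != ds$sites$anc_true)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
  ds0 <- simulate_cohort(m, lay, c(A = 5), seed = 2, anc_error = 0)
  expect_true(all(ds0$sites$anc == ds0$sites$anc_true))
})

test_that("third-codon flags follow the annotated exon frame", {
  lay <- genome_layout("chr1", 2e5)
  ann <- annotate_layout(lay)
  ex <- ecoscan:::df0(ann$exon)[1, ]
  pos <- ex$start + 0:8
  flags <- third_codon_flag(rep("chr1", 9), pos, ann)
  expect_identical(flags, rep(c(FALSE, FALSE, TRUE), 3))
  expect_identical(site_category("chr1", ex$start, ann), "exon")
})
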