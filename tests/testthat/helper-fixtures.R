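# Shared fixtures and independent oracles. Oracles are written as plain
# loops from the defining formulas so they stay independent of the
# vectorised implementation paths they check.

# a small hand-built site table: `geno` rows are sites, columns individuals
toy_site_table <- function(geno, panel_pops,
                           chrom = "chr1",
                           pos = seq_len(nrow(geno)) * 10L,
                           ref = "A", alt = "G", anc = "A",
                           category = "intergenic", third_codon = FALSE) {
  n_ind <- ncol(geno)
  panel <- data.frame(individual = paste0("i", seq_len(n_ind)),
                      population = panel_pops,
                      stringsAsFactors = FALSE)
  colnames(geno) <- panel$individual
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, nrow(geno)),
                      alt = rep_len(alt, nrow(geno)),
                      anc = rep_len(anc, nrow(geno)),
                      category = rep_len(category, nrow(geno)),
                      third_codon = rep_len(third_codon, nrow(geno)),
                      stringsAsFactors = FALSE)
  site_table(sites, geno, panel)
}

# one-population constant-size model for neutral checks
neutral_model <- function(ne = 10000, mu = 1e-8) {
  demographic_model("A",
                    data.frame(pop = "A", start_gen = 0, ne = ne),
                    data.frame(child = character(), parent = character(),
                               time_gen = numeric()),
                    mu = mu)
}

# two populations split t generations ago (t = 0 gives a panmictic pair)
pair_model <- function(t_split, ne = 10000, mu = 1e-8) {
  if (t_split <= 0) t_split <- 1e-9
  demographic_model(c("A", "B", "ANC"),
                    rbind(data.frame(pop = "A", start_gen = 0, ne = ne),
                          data.frame(pop = "B", start_gen = 0, ne = ne),
                          data.frame(pop = "ANC", start_gen = t_split,
                                     ne = ne)),
                    data.frame(child = c("A", "B"),
                               parent = c("ANC", "ANC"),
                               time_gen = c(t_split, t_split)),
                    mu = mu)
}

five_pop_samples <- function(n = 10)
  stats::setNames(rep(n, 5), c("RES", "TRA", "B1", "B2", "C"))

adm_layout <- function() genome_layout(paste0("chr", 1:3), rep(1e6, 3))

# --- independent oracles -------------------------------------------------

# Hudson FST components, scalar arithmetic spelt out
oracle_fst_window <- function(p1, n1, p2, n2) {
  num <- 0; den <- 0
  for (i in seq_along(p1)) {
    num <- num + (p1[i] - p2[i])^2 -
      p1[i] * (1 - p1[i]) / (n1[i] - 1) -
      p2[i] * (1 - p2[i]) / (n2[i] - 1)
    den <- den + p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
  }
  c(num = num, den = den, fst = num / den)
}

# D statistic and delete-one jackknife, plain loops
oracle_dstat <- function(p, block_size) {
  abba <- baba <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    abba[i] <- (1 - p[i, 1]) * p[i, 2] * p[i, 3] * (1 - p[i, 4])
    baba[i] <- p[i, 1] * (1 - p[i, 2]) * p[i, 3] * (1 - p[i, 4])
  }
  d <- sum(abba - baba) / sum(abba + baba)
  blk <- (seq_len(nrow(p)) - 1) %/% block_size
  loo <- sapply(unique(blk), function(b)
    sum((abba - baba)[blk != b]) / sum((abba + baba)[blk != b]))
  g <- length(loo)
  list(d = d, se = sqrt((g - 1) / g * sum((loo - mean(loo))^2)))
}

oracle_f3 <- function(p, n_c) {
  x <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    x[i] <- (p[i, 1] - p[i, 2]) * (p[i, 1] - p[i, 3]) -
      p[i, 1] * (1 - p[i, 1]) / (n_c - 1)
  }
  mean(x)
}

# one-sided hypergeometric tail by explicit enumeration
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  num <- 0; den <- 0
  for (x in max(0, k - n):min(k, m)) {
    w <- choose(m, x) * choose(n, k - x)
    den <- den + w
    if (x >= a) num <- num + w
  }
  num / den
}
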