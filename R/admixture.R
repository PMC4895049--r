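# Four-population D-statistic (ABBA-BABA) and three-population f3 test,
# frequency-based, with delete-one block-jackknife standard errors over
# contiguous blocks of SNPs (equal-size blocks make delete-one weights
# uniform).

jackknife_ratio <- function(num, den, block) {
  blocks <- unique(block)
  g <- length(blocks)
  if (g < 2) stop("need at least 2 jackknife blocks")
  tot_n <- sum(num); tot_d <- sum(den)
  if (tot_d == 0) stop("no informative sites (zero denominator)")
  bn <- tapply(num, block, sum)[as.character(blocks)]
  bd <- tapply(den, block, sum)[as.character(blocks)]
  loo <- (tot_n - bn) / (tot_d - bd)
  est <- tot_n / tot_d
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, n_blocks = g)
}

#' ABBA-BABA D-statistic
#'
#' For per-site derived-allele frequencies of populations
#' `(P1, P2, P3, Outgroup)`:
#' `ABBA = (1-p1) p2 p3 (1-p4)`, `BABA = p1 (1-p2) p3 (1-p4)`,
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`, with the standard error from
#' a delete-one block jackknife over contiguous blocks of
#' `block_size_snps` sites. A positive D indicates excess allele sharing
#' between P2 and P3.
#'
#' @param freqs Numeric matrix (sites x 4) of derived-allele frequencies
#'   in the order P1, P2, P3, Outgroup. After polarization the outgroup
#'   column is typically all 0.
#' @param block_size_snps SNPs per jackknife block (default 1000).
#' @return A `dstat_result`: list with `d`, `abba_sum`, `baba_sum`, `se`,
#'   `z`, `n_blocks`, `block_size`, `n_snps`.
#' @export
dstat <- function(freqs, block_size_snps = 1000) {
  freqs <- as.matrix(freqs)
  stopifnot(ncol(freqs) == 4, all(freqs >= 0 & freqs <= 1, na.rm = TRUE))
  ok <- stats::complete.cases(freqs)
  f <- freqs[ok, , drop = FALSE]
  abba <- (1 - f[, 1]) * f[, 2] * f[, 3] * (1 - f[, 4])
  baba <- f[, 1] * (1 - f[, 2]) * f[, 3] * (1 - f[, 4])
  block <- (seq_len(nrow(f)) - 1L) %/% block_size_snps
  jk <- jackknife_ratio(abba - baba, abba + baba, block)
  structure(list(d = jk$estimate, abba_sum = sum(abba),
                 baba_sum = sum(baba), se = jk$se,
                 z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
                 n_blocks = jk$n_blocks, block_size = block_size_snps,
                 n_snps = nrow(f)),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  (ABBA %.1f, BABA %.1f)  SE %.4f  Z %.2f  [%d blocks of %d SNPs]\n",
              x$d, x$abba_sum, x$baba_sum, x$se, x$z, x$n_blocks,
              x$block_size))
  invisible(x)
}

#' Three-population f3 test
#'
#' `f3(Target; A, B)` is the mean over sites of `(c - a)(c - b)` minus the
#' finite-sample correction `c (1 - c) / (n_c - 1)`, where `c` is the
#' target's frequency and `n_c` its sampled allele count. A significantly
#' negative value indicates that the target is admixed between relatives
#' of the two sources. Standard error by delete-one block jackknife.
#'
#' @param freqs Numeric matrix (sites x 3): Target, A, B frequencies.
#' @param n_target Sampled allele count(s) of the target (scalar or
#'   per-site vector; must be >= 2).
#' @param block_size_snps SNPs per jackknife block (default 1000).
#' @param labels Optional population labels `c(target, a, b)`.
#' @return An `f3_result`: list with `f3`, `se`, `z`, `n_blocks`,
#'   `n_snps`, `target`, `source_a`, `source_b`.
#' @export
f3 <- function(freqs, n_target, block_size_snps = 1000,
               labels = c("target", "A", "B")) {
  freqs <- as.matrix(freqs)
  stopifnot(ncol(freqs) == 3, all(n_target >= 2))
  ok <- stats::complete.cases(freqs)
  f <- freqs[ok, , drop = FALSE]
  n_c <- if (length(n_target) == 1) rep(n_target, nrow(f)) else
    n_target[ok]
  x <- (f[, 1] - f[, 2]) * (f[, 1] - f[, 3]) -
    f[, 1] * (1 - f[, 1]) / (n_c - 1)
  block <- (seq_len(nrow(f)) - 1L) %/% block_size_snps
  jk <- jackknife_ratio(x, rep(1, length(x)), block)
  structure(list(f3 = jk$estimate, se = jk$se,
                 z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
                 n_blocks = jk$n_blocks, n_snps = nrow(f),
                 target = labels[1], source_a = labels[2],
                 source_b = labels[3]),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.5f  SE %.5f  Z %.2f  [%d blocks]\n",
              x$target, x$source_a, x$source_b, x$f3, x$se, x$z,
              x$n_blocks))
  invisible(x)
}

# derived-frequency matrix for named populations; outgroup = 0 after
# polarization unless a genotyped outgroup population is named.
freq_matrix <- function(st, pops, outgroup_zero = TRUE) {
  real <- pops[pops %in% st$panel$population]
  pc <- pop_counts(st, unique(real))
  m <- matrix(NA_real_, nrow(st$sites), length(pops),
              dimnames = list(NULL, make.unique(pops)))
  for (i in seq_along(pops)) {
    if (pops[i] %in% colnames(pc$freq)) {
      m[, i] <- pc$freq[, pops[i]]
    } else if (outgroup_zero && pops[i] %in% c("OUTGROUP", "ancestral")) {
      m[, i] <- 0
    } else {
      stop("unknown population label: ", pops[i])
    }
  }
  m
}

#' D-statistics for a list of quartets
#'
#' Runs [dstat()] for each quartet of population labels on polarized
#' derived-allele frequencies; the label `"OUTGROUP"` stands for the fixed
#' ancestral state (frequency 0). No multiple-testing correction is
#' applied; a note records how many quartets were tested.
#'
#' @param dataset A `sim_dataset` or `site_table`.
#' @param quartets List of length-4 character vectors
#'   `(P1, P2, P3, Outgroup)`.
#' @param block_size_snps SNPs per jackknife block (default 1000).
#' @return Data frame with one row per quartet: p1, p2, p3, outgroup, d,
#'   se, z, n_blocks, n_snps; attribute `note` carries the
#'   multiple-testing reminder.
#' @export
dstat_quartets <- function(dataset, quartets, block_size_snps = 1000) {
  st <- if (inherits(dataset, "site_table")) dataset else
    as_site_table(dataset)
  rows <- lapply(quartets, function(q) {
    stopifnot(length(q) == 4, !anyDuplicated(q))
    m <- freq_matrix(st, q)
    res <- dstat(m, block_size_snps)
    data.frame(p1 = q[1], p2 = q[2], p3 = q[3], outgroup = q[4],
               d = res$d, se = res$se, z = res$z,
               n_blocks = res$n_blocks, n_snps = res$n_snps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <- paste0(nrow(out), " quartets tested; Z-scores are ",
                              "reported without multiple-testing correction")
  out
}
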