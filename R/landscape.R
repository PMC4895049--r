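# Differentiation and diversity landscapes. Per-site statistics use sample
# allele frequencies; window values aggregate by ratio-of-sums, with
# monomorphic sites contributing (0, 0) so windows are comparable across
# SNP densities.

#' Hudson method-of-moments FST components for one site
#'
#' `numerator = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`;
#' `denominator = p1(1-p2) + p2(1-p1)`. The numerator is left unclamped so
#' that ratio-of-sums aggregation stays unbiased. Vectorised.
#'
#' @param p1,p2 Sample allele frequencies in `[0, 1]`.
#' @param n1,n2 Sampled allele counts (>= 2).
#' @return List with `numerator` and `denominator`.
#' @export
site_fst_components <- function(p1, n1, p2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

#' Per-site absolute divergence Dxy
#'
#' `p1(1-p2) + p2(1-p1)`; symmetric and bounded in `[0, 1]`. Sites not
#' variable in either population carry frequency 0 and contribute 0.
#'
#' @param p1,p2 Derived (or arbitrary consistent) allele frequencies.
#' @return Numeric vector.
#' @export
site_dxy <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  p1 * (1 - p2) + p2 * (1 - p1)
}

# per-site unbiased heterozygosity 2p(1-p) * n/(n-1)
site_pi <- function(p, n) {
  ifelse(n > 1, 2 * p * (1 - p) * n / (n - 1), 0)
}

# map sites into windows; returns integer window index (NA if none).
# Windows may overlap (sliding), in which case use window_site_list().
window_of <- function(chrom, pos, windows) {
  pts <- gr0(chrom, pos, pos + 1L)
  win <- gr0(windows$chrom, windows$start, windows$end)
  hits <- GenomicRanges::findOverlaps(pts, win, select = "first")
  as.integer(hits)
}

window_site_list <- function(chrom, pos, windows) {
  pts <- gr0(chrom, pos, pos + 1L)
  win <- gr0(windows$chrom, windows$start, windows$end)
  hits <- GenomicRanges::findOverlaps(win, pts)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(windows))))
}

#' Windowed FST by ratio of sums
#'
#' Sums per-site Hudson numerators and denominators over the sites in each
#' window. Windows with zero denominator (no variation in either
#' population) get `NA` and are flagged.
#'
#' @param st A `site_table`.
#' @param pop1,pop2 Population labels.
#' @param windows Data frame with `chrom`, `start`, `end` (may overlap).
#' @return Data frame: windows plus `fst_num`, `fst_den`, `fst`, `n_snps`.
#' @export
window_fst <- function(st, pop1, pop2, windows) {
  pc <- pop_counts(st, c(pop1, pop2))
  ok <- pc$n[, pop1] >= 2 & pc$n[, pop2] >= 2
  comp <- list(numerator = numeric(nrow(st$sites)),
               denominator = numeric(nrow(st$sites)))
  if (any(ok)) {
    cc <- site_fst_components(pc$freq[ok, pop1], pc$n[ok, pop1],
                              pc$freq[ok, pop2], pc$n[ok, pop2])
    comp$numerator[ok] <- cc$numerator
    comp$denominator[ok] <- cc$denominator
  }
  wl <- window_site_list(st$sites$chrom, st$sites$pos, windows)
  out <- windows
  out$fst_num <- vapply(wl, function(i) sum(comp$numerator[i]), numeric(1))
  out$fst_den <- vapply(wl, function(i) sum(comp$denominator[i]), numeric(1))
  out$n_snps <- vapply(wl, length, integer(1))
  out$fst <- ifelse(out$fst_den > 0, out$fst_num / out$fst_den, NA_real_)
  out
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity `2 p (1-p) n/(n-1)` summed over the
#' variant sites of each window and divided by the window's covered length
#' in bp (invariant sites contribute zero heterozygosity but count in the
#' denominator).
#'
#' @param st A `site_table`.
#' @param pop Population label.
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param covered_bp Covered length per window (default: full window
#'   width, appropriate for simulated data).
#' @return Data frame: windows plus `pi` and `n_snps`.
#' @export
window_pi <- function(st, pop, windows,
                      covered_bp = windows$end - windows$start) {
  if (any(covered_bp <= 0)) stop("windows with zero covered bp")
  pc <- pop_counts(st, pop)
  h <- site_pi(pc$freq[, pop], pc$n[, pop])
  h[pc$n[, pop] < 2] <- 0
  wl <- window_site_list(st$sites$chrom, st$sites$pos, windows)
  out <- windows
  out$pi <- vapply(wl, function(i) sum(h[i]), numeric(1)) / covered_bp
  out$n_snps <- vapply(wl, length, integer(1))
  out
}

#' Windowed Dxy
#'
#' Mean per-site Dxy over the window's covered length.
#'
#' @inheritParams window_fst
#' @param covered_bp Covered length per window (default full width).
#' @return Data frame: windows plus `dxy` and `n_snps`.
#' @export
window_dxy <- function(st, pop1, pop2, windows,
                       covered_bp = windows$end - windows$start) {
  pc <- pop_counts(st, c(pop1, pop2))
  p1 <- ifelse(pc$n[, pop1] > 0, pc$freq[, pop1], 0)
  p2 <- ifelse(pc$n[, pop2] > 0, pc$freq[, pop2], 0)
  d <- site_dxy(p1, p2)
  wl <- window_site_list(st$sites$chrom, st$sites$pos, windows)
  out <- windows
  out$dxy <- vapply(wl, function(i) sum(d[i]), numeric(1)) / covered_bp
  out$n_snps <- vapply(wl, length, integer(1))
  out
}

#' Genome-wide differentiation landscape scan
#'
#' For each population pair, applies the window coverage filter and then
#' computes window FST (ratio of sums), Dxy and per-population pi on a
#' shared window grid, so rows align across comparisons.
#'
#' @param dataset A `sim_dataset` (or list with `layout` and a
#'   `site_table`-compatible cohort; see [as_site_table()]).
#' @param comparisons List of length-2 character vectors of population
#'   labels.
#' @param window_bp Window size (one of the supported 50/100/200-kb scales
#'   or any positive size).
#' @param step_bp Step between window starts; default `window_bp` (tiled,
#'   non-overlapping). Use a smaller step for sliding windows.
#' @param min_covered_bp,min_individuals Coverage-filter thresholds
#'   (defaults 10000 bp and 5 individuals).
#' @return Named list of `window_stat` data frames (one per comparison):
#'   chrom, start, end, eligible, fst_num, fst_den, fst, dxy, pi_pop1,
#'   pi_pop2, n_snps. Ineligible windows carry NA statistics.
#' @export
landscape_scan <- function(dataset, comparisons, window_bp = 50000,
                           step_bp = window_bp,
                           min_covered_bp = 10000, min_individuals = 5) {
  st <- as_site_table(dataset)
  windows <- make_windows(dataset$layout, window_bp, step_bp)
  coverage <- cohort_coverage(dataset)
  out <- list()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2)
    eligible <- window_coverage_filter(
      windows, coverage, pops = cmp,
      min_covered_bp = min_covered_bp, min_individuals = min_individuals)
    if (!any(eligible))
      warning("no eligible windows for ", paste(cmp, collapse = " vs "))
    tb <- window_fst(st, cmp[1], cmp[2], windows)
    tb$dxy <- window_dxy(st, cmp[1], cmp[2], windows)$dxy
    tb$pi_pop1 <- window_pi(st, cmp[1], windows)$pi
    tb$pi_pop2 <- window_pi(st, cmp[2], windows)$pi
    tb$eligible <- eligible
    for (col in c("fst", "dxy", "pi_pop1", "pi_pop2"))
      tb[[col]][!eligible] <- NA_real_
    out <- c(out, stats::setNames(list(tb),
                                  paste(cmp, collapse = "_vs_")))
  }
  names(out) <- make.unique(names(out))
  out
}

#' Rank correlations between aligned landscape tables
#'
#' Spearman correlations of windowed statistics across comparisons, over
#' windows present (non-NA) in every table involved in a pair
#' (pairwise-complete).
#'
#' @param tables Named list of aligned window tables ([landscape_scan()]
#'   output).
#' @param statistics Statistics to correlate, subset of
#'   `c("fst", "dxy", "pi_pop1", "pi_pop2")`.
#' @param min_windows Minimum aligned windows required (default 30).
#' @return A symmetric correlation matrix (class `matrix`) with unit
#'   diagonal; labels are `<table>:<statistic>`.
#' @export
landscape_correlations <- function(tables,
                                   statistics = c("fst"),
                                   min_windows = 30) {
  cols <- list()
  for (nm in names(tables)) {
    for (s in statistics) {
      cols[[paste(nm, s, sep = ":")]] <- tables[[nm]][[s]]
    }
  }
  m <- do.call(cbind, cols)
  if (sum(stats::complete.cases(m)) < min_windows)
    stop("fewer than ", min_windows, " aligned windows")
  rho <- stats::cor(m, method = "spearman",
                    use = "pairwise.complete.obs")
  diag(rho) <- 1
  rho
}
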