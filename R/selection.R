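# Population branch statistic (PBS) selection scan and outlier enrichment.
# Window FST values come from the landscape module's ratio-of-sums; small
# negative window FSTs (sampling noise) are clamped to 0 before the log
# transform so branch lengths stay non-negative.

#' Branch-scaled divergence T = -log(1 - FST)
#'
#' Negative FST values are clamped to 0 before the transform. `FST = 1`
#' yields an infinite branch with a warning.
#'
#' @param fst FST values (< 1; vectorised).
#' @return Non-negative branch lengths.
#' @export
branch_length_T <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE)) {
    if (any(fst > 1, na.rm = TRUE)) stop("FST above 1")
    warning("FST = 1 gives an infinite branch length")
  }
  -log(1 - pmax(fst, 0))
}

#' Population branch statistic for the focal population
#'
#' `pbs_A = (t_ab + t_ac - t_bc) / 2` for focal population A against B and
#' C. May be negative (no clamping); `pbs_A + pbs_B = t_ab` by
#' construction.
#'
#' @param t_ab,t_ac,t_bc Branch-scaled divergences (from
#'   [branch_length_T()]).
#' @return PBS values for the focal population.
#' @export
pbs <- function(t_ab, t_ac, t_bc) {
  (t_ab + t_ac - t_bc) / 2
}

#' PBS scan over sliding windows and (optionally) exons
#'
#' Computes window FST for the three population pairs of the trio by ratio
#' of sums, transforms to branch lengths, and combines them into PBS values
#' for each of the three branches. With `features` supplied (e.g. exon
#' intervals), the same computation runs per feature; features with fewer
#' than `min_snps` SNPs are reported but flagged ineligible for percentile
#' ranking.
#'
#' @param dataset A `sim_dataset`.
#' @param trio Character vector of three distinct population labels
#'   `(focal, sister, outgroup-population)`.
#' @param window_bp,step_bp Sliding-window scheme (defaults 50 kb / 10 kb).
#' @param features Optional data frame of intervals (`chrom`, `start`,
#'   `end`) scanned instead of windows.
#' @param min_snps Minimum SNPs per feature for percentile eligibility
#'   (default 2).
#' @param min_covered_bp,min_individuals Window coverage-filter thresholds;
#'   ignored for explicit `features`.
#' @return A `pbs_table` data frame: feature coordinates, `fst_ab`,
#'   `fst_ac`, `fst_bc`, `t_ab`, `t_ac`, `t_bc`, `pbs_focal`,
#'   `pbs_sister`, `pbs_out`, `n_snps`, `eligible`.
#' @export
pbs_scan <- function(dataset, trio, window_bp = 50000, step_bp = 10000,
                     features = NULL, min_snps = 2,
                     min_covered_bp = 10000, min_individuals = 5) {
  stopifnot(length(trio) == 3, !anyDuplicated(trio))
  st <- as_site_table(dataset)
  if (is.null(features)) {
    feats <- make_windows(dataset$layout, window_bp, step_bp)
    eligible <- window_coverage_filter(
      feats, cohort_coverage(dataset), pops = trio,
      min_covered_bp = min_covered_bp, min_individuals = min_individuals)
  } else {
    feats <- as.data.frame(features)[c("chrom", "start", "end")]
    eligible <- rep(TRUE, nrow(feats))
  }
  a <- trio[1]; b <- trio[2]; c_ <- trio[3]
  f_ab <- window_fst(st, a, b, feats)
  f_ac <- window_fst(st, a, c_, feats)
  f_bc <- window_fst(st, b, c_, feats)
  out <- feats
  out$fst_ab <- f_ab$fst; out$fst_ac <- f_ac$fst; out$fst_bc <- f_bc$fst
  # undefined window FST (no variation) means no frequency change: T = 0
  tt <- function(f) ifelse(is.na(f), 0, branch_length_T(pmin(f, 1 - 1e-12)))
  out$t_ab <- tt(out$fst_ab)
  out$t_ac <- tt(out$fst_ac)
  out$t_bc <- tt(out$fst_bc)
  out$pbs_focal <- pbs(out$t_ab, out$t_ac, out$t_bc)
  out$pbs_sister <- pbs(out$t_ab, out$t_bc, out$t_ac)
  out$pbs_out <- pbs(out$t_ac, out$t_bc, out$t_ab)
  out$n_snps <- f_ab$n_snps
  out$eligible <- eligible & out$n_snps >= min_snps
  attr(out, "trio") <- trio
  class(out) <- c("pbs_table", class(out))
  out
}

#' Empirical-percentile outlier call
#'
#' Returns the features whose statistic reaches the k-th largest value,
#' where `k = floor(n * (1 - percentile/100))` (at least 1); ties at the
#' threshold are all included, so the set can exceed the nominal count.
#'
#' @param records A data frame (e.g. [pbs_scan()] output).
#' @param percentile Percentile in `[0, 100)`, typically 99.9 or 99.99.
#' @param column Statistic column (default `"pbs_focal"`).
#' @param use_eligible Restrict ranking to rows flagged `eligible`
#'   (default TRUE when the column exists).
#' @return List with `outliers` (data-frame subset), `threshold` and `n`
#'   (features ranked).
#' @export
outlier_call <- function(records, percentile = 99.9,
                         column = "pbs_focal",
                         use_eligible = !is.null(records$eligible)) {
  stopifnot(percentile >= 0, percentile < 100)
  x <- records[[column]]
  if (is.null(x)) stop("no column ", column)
  keep <- !is.na(x)
  if (use_eligible) keep <- keep & records$eligible
  if (!any(keep)) stop("no rankable features")
  ranked <- records[keep, , drop = FALSE]
  v <- ranked[[column]]
  n <- length(v)
  if (n < 1000 && percentile >= 99.9)
    warning("fewer than 1,000 features; the ", percentile,
            "th percentile is poorly resolved")
  k <- max(1L, floor(n * (1 - percentile / 100)))
  threshold <- sort(v, decreasing = TRUE)[k]
  list(outliers = ranked[v >= threshold, , drop = FALSE],
       threshold = threshold, n = n)
}

#' Top-FST SNP set
#'
#' The highest-FST fraction of SNPs (default 1%), ties at the cutoff
#' included.
#'
#' @param per_site_fst Data frame with at least an `fst` column.
#' @param fraction Fraction of SNPs to keep (default 0.01).
#' @return Data-frame subset of the top SNPs.
#' @export
top_fst_snps <- function(per_site_fst, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- per_site_fst$fst
  if (is.null(x) || length(x) == 0) stop("no SNPs")
  keep <- !is.na(x)
  d <- per_site_fst[keep, , drop = FALSE]
  v <- d$fst
  k <- max(1L, floor(length(v) * fraction))
  threshold <- sort(v, decreasing = TRUE)[k]
  d[v >= threshold, , drop = FALSE]
}

#' Category-by-FST-bin over-representation test
#'
#' Bins SNPs by FST and cross-tabulates against genomic category
#' (exon / intron / flank / intergenic). Expected counts put the
#' background's category proportions in every bin (when `all_snps` is the
#' same set as `snps`, this is the usual test of independence). Pearson
#' residuals `(O - E) / sqrt(E)` are flagged two-sided at
#' `alpha / (cells tested)` (Bonferroni); cells with expected count below
#' 1 are excluded from testing.
#'
#' @param snps SNP set: data frame with `fst` and `category`.
#' @param all_snps Background SNP set defining expected category
#'   proportions (default `snps`).
#' @param bins FST bin edges (default width 0.1 over `[0, 1]`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An `enrichment_table`: list with `observed`, `expected`,
#'   `residuals` (matrices category x bin), `significant` (logical
#'   matrix), `unreliable` (expected < 1), `chisq`, `df`, `alpha_cell`.
#' @export
category_bin_chisq <- function(snps, all_snps = snps,
                               bins = seq(0, 1, by = 0.1),
                               alpha = 0.05) {
  stopifnot(!is.null(snps$fst), !is.null(snps$category),
            !is.null(all_snps$category))
  cats <- c("exon", "flank", "intron", "intergenic")
  cats <- cats[cats %in% unique(c(snps$category, all_snps$category))]
  bin_of <- cut(pmin(pmax(snps$fst, 0), 1), breaks = bins,
                include.lowest = TRUE, right = FALSE)
  obs <- table(factor(snps$category, levels = cats), bin_of)
  obs <- matrix(obs, nrow = length(cats),
                dimnames = list(cats, levels(bin_of)))
  prop <- prop.table(table(factor(all_snps$category, levels = cats)))
  expected <- outer(as.numeric(prop), colSums(obs))
  dimnames(expected) <- dimnames(obs)
  resid <- (obs - expected) / sqrt(expected)
  resid[expected == 0] <- NA_real_
  unreliable <- expected < 1
  testable <- !unreliable & !is.na(resid)
  n_cells <- sum(testable)
  alpha_cell <- alpha / max(1L, n_cells)
  crit <- stats::qnorm(1 - alpha_cell / 2)
  significant <- testable & abs(resid) > crit
  structure(list(observed = obs, expected = expected, residuals = resid,
                 significant = significant, unreliable = unreliable,
                 chisq = sum(resid[testable]^2),
                 df = max(0L, (nrow(obs) - 1L) * ncol(obs)),
                 alpha_cell = alpha_cell),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Category x FST-bin enrichment: chisq =", signif(x$chisq, 4),
      "on", x$df, "df;",
      sum(x$significant), "cells significant at per-cell alpha",
      signif(x$alpha_cell, 3), "\n")
  invisible(x)
}

#' Per-site FST with category annotation
#'
#' Convenience wrapper producing the per-SNP table consumed by
#' [top_fst_snps()] and [category_bin_chisq()].
#'
#' @param st A `site_table`.
#' @param pop1,pop2 Population labels.
#' @return Data frame: chrom, pos, fst (per-site ratio, NA when the
#'   denominator is 0), category.
#' @export
per_site_fst <- function(st, pop1, pop2) {
  pc <- pop_counts(st, c(pop1, pop2))
  ok <- pc$n[, pop1] >= 2 & pc$n[, pop2] >= 2
  fst <- rep(NA_real_, nrow(st$sites))
  cc <- site_fst_components(pc$freq[ok, pop1], pc$n[ok, pop1],
                            pc$freq[ok, pop2], pc$n[ok, pop2])
  fst[ok][cc$denominator > 0] <-
    (cc$numerator / cc$denominator)[cc$denominator > 0]
  data.frame(chrom = st$sites$chrom, pos = st$sites$pos, fst = fst,
             category = st$sites$category, stringsAsFactors = FALSE)
}

#' Fisher exact term enrichment
#'
#' One-sided (over-representation) Fisher's exact test per term on the
#' 2x2 table outlier/non-outlier x in-term/not-in-term, with Bonferroni
#' adjustment over the terms tested. Terms with no annotated genes in the
#' background are skipped.
#'
#' @param outlier_genes Character vector, subset of `background`.
#' @param annotation Data frame with columns `gene`, `term`.
#' @param background Character vector of all genes considered.
#' @return Data frame: term, n_term, n_outlier_in_term, odds_ratio,
#'   p_value, p_bonferroni (sorted by p).
#' @export
fisher_term_enrichment <- function(outlier_genes, annotation, background) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (!all(outlier_genes %in% background))
    stop("outlier genes must be a subset of the background")
  if (length(outlier_genes) == 0)
    return(data.frame(term = character(), n_term = integer(),
                      n_outlier_in_term = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      p_bonferroni = numeric()))
  background <- unique(background)
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    in_term <- unique(ann$gene[ann$term == tm])
    a <- sum(outlier_genes %in% in_term)
    b <- sum(!(outlier_genes %in% in_term))
    cc <- length(setdiff(in_term, outlier_genes))
    d <- length(background) - a - b - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.frame(term = tm, n_term = length(in_term),
               n_outlier_in_term = a,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out[order(out$p_value), , drop = FALSE]
}
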