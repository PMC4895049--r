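# Masking and site-eligibility bookkeeping. A mask_track is the merged
# union of repeat, numt and high-depth intervals, with per-source
# provenance counts attributed in the order repeat -> numt -> depth (a site
# counts for the first source that masks it); the union itself is
# order-invariant.

#' Compile a genome mask from repeat, numt and depth tracks
#'
#' The mask is the union of the repeat intervals, the numt intervals and
#' every site whose total depth exceeds `depth_threshold` (strict `>`,
#' default 200 as for the >200x unmasked-repeat rule). Provenance counts
#' record each source's disjoint contribution in the order
#' repeat -> numt -> depth.
#'
#' @param repeat_track,numt_track Interval tracks: `GRanges` or data frames
#'   with `chrom`, `start`, `end` (0-based half-open). `NULL` for none.
#' @param depth_track Run-length depth track: data frame with `chrom`,
#'   `start`, `end`, `total_depth` (a per-site track is the width-1
#'   special case). `NULL` for none.
#' @param depth_threshold Depth above which a site is masked (strict `>`).
#' @param layout A `genome_layout`; all intervals must fall inside it.
#' @return A `mask_track`: list with `intervals` (merged `GRanges`),
#'   `provenance` (named counts: repeat, numt, high_depth),
#'   `masked_sites` and `genome_length`.
#' @export
compile_mask <- function(repeat_track = NULL, numt_track = NULL,
                         depth_track = NULL, depth_threshold = 200,
                         layout) {
  stopifnot(inherits(layout, "genome_layout"), depth_threshold > 0)
  as_gr <- function(x) {
    if (is.null(x)) return(GenomicRanges::GRanges())
    if (inherits(x, "GRanges")) x else gr0(x$chrom, x$start, x$end)
  }
  rep_gr <- GenomicRanges::reduce(as_gr(repeat_track))
  numt_gr <- GenomicRanges::reduce(as_gr(numt_track))
  depth_gr <- GenomicRanges::GRanges()
  if (!is.null(depth_track) && nrow(depth_track) > 0) {
    hi <- depth_track[depth_track$total_depth > depth_threshold, ,
                      drop = FALSE]
    if (nrow(hi) > 0) depth_gr <- GenomicRanges::reduce(
      gr0(hi$chrom, hi$start, hi$end))
  }
  check_bounds <- function(gr, what) {
    if (length(gr) == 0) return(invisible())
    d <- df0(gr)
    i <- match(d$chrom, layout$chrom)
    if (anyNA(i) || any(d$start < 0) || any(d$end > layout$length_bp[i]))
      stop(what, " interval outside chromosome bounds")
  }
  check_bounds(rep_gr, "repeat"); check_bounds(numt_gr, "numt")
  check_bounds(depth_gr, "depth")

  union_gr <- GenomicRanges::reduce(c(rep_gr, numt_gr, depth_gr))
  w <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))
  prov <- c(
    "repeat" = w(rep_gr),
    numt = w(GenomicRanges::setdiff(numt_gr, rep_gr)),
    high_depth = w(GenomicRanges::setdiff(depth_gr,
                                          GenomicRanges::reduce(
                                            c(rep_gr, numt_gr)))))
  structure(list(intervals = union_gr, provenance = prov,
                 masked_sites = w(union_gr),
                 genome_length = genome_size(layout)),
            class = "mask_track")
}

#' @export
print.mask_track <- function(x, ...) {
  r <- mask_report(x)
  cat(sprintf("Mask: %s of %s sites (%.2f%%)\n",
              format(x$masked_sites, big.mark = ","),
              format(x$genome_length, big.mark = ","),
              r$masked_fraction))
  cat("  provenance:",
      paste(names(x$provenance),
            format(x$provenance, big.mark = ",", trim = TRUE),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Masking report
#'
#' @param mask A `mask_track`.
#' @return List with `masked_sites`, `masked_fraction` (percent of the
#'   genome, full precision; round to 2 decimals for display),
#'   `per_source` counts and `genome_length`.
#' @export
mask_report <- function(mask) {
  stopifnot(inherits(mask, "mask_track"), mask$genome_length > 0)
  list(masked_sites = mask$masked_sites,
       masked_fraction = 100 * mask$masked_sites / mask$genome_length,
       per_source = mask$provenance,
       genome_length = mask$genome_length)
}

#' Variant filter for population-structure analyses
#'
#' Retains autosomal sites genotyped in at least `min_individuals`
#' individuals with a sample minor-allele frequency of at least `min_maf`
#' (inclusive at the boundary; MAF is computed over non-missing alleles).
#'
#' @param st A `site_table`.
#' @param min_individuals Minimum non-missing genotypes (default 40).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @param autosomes Chromosome names counted as autosomal; by default every
#'   chromosome except ones named like X ("X", "chrX").
#' @return The filtered `site_table`.
#' @export
filter_variants_for_structure <- function(st, min_individuals = 40,
                                          min_maf = 0.05,
                                          autosomes = NULL) {
  stopifnot(inherits(st, "site_table"),
            min_individuals >= 0, min_maf >= 0, min_maf <= 0.5)
  if (is.null(autosomes))
    autosomes <- setdiff(unique(st$sites$chrom), c("X", "chrX"))
  n_geno <- rowSums(!is.na(st$geno))
  n_al <- 2 * n_geno
  d <- rowSums(st$geno, na.rm = TRUE)
  maf <- ifelse(n_al > 0, pmin(d, n_al - d) / n_al, 0)
  keep <- st$sites$chrom %in% autosomes &
    n_geno >= min_individuals & maf >= min_maf
  site_table(st$sites[keep, , drop = FALSE],
             st$geno[keep, , drop = FALSE], st$panel)
}

#' Tile or slide windows over a genome layout
#'
#' @param layout A `genome_layout`.
#' @param window_bp Window size in bp.
#' @param step_bp Step between window starts (default `window_bp`,
#'   i.e. non-overlapping tiles).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open);
#'   trailing windows are truncated at the chromosome end.
#' @export
make_windows <- function(layout, window_bp, step_bp = window_bp) {
  stopifnot(window_bp > 0, step_bp > 0)
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    starts <- seq(0, max(0, layout$length_bp[ci] - 1), by = step_bp)
    starts <- starts[starts < layout$length_bp[ci]]
    data.frame(chrom = layout$chrom[ci], start = starts,
               end = pmin(starts + window_bp, layout$length_bp[ci]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Window coverage filter
#'
#' A window is eligible iff, in every population, strictly more than
#' `min_covered_bp` of its bases are covered by at least `min_individuals`
#' genotyped individuals.
#'
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param coverage Run-length coverage track: data frame with `chrom`,
#'   `start`, `end`, `pop`, `n_ind` (bases in the interval genotyped in
#'   `n_ind` individuals of population `pop`).
#' @param pops Populations that must each satisfy the rule (default: all
#'   present in `coverage`).
#' @param min_covered_bp Coverage threshold in bp (strict `>`, default
#'   10000).
#' @param min_individuals Minimum genotyped individuals per covered base
#'   (default 5).
#' @return Logical vector flagging eligible windows.
#' @export
window_coverage_filter <- function(windows, coverage,
                                   pops = unique(coverage$pop),
                                   min_covered_bp = 10000,
                                   min_individuals = 5) {
  stopifnot(all(c("chrom", "start", "end", "pop", "n_ind") %in%
                  names(coverage)))
  win_gr <- gr0(windows$chrom, windows$start, windows$end)
  ok <- matrix(FALSE, nrow(windows), length(pops),
               dimnames = list(NULL, pops))
  for (p in pops) {
    cv <- coverage[coverage$pop == p & coverage$n_ind >= min_individuals, ,
                   drop = FALSE]
    covered <- numeric(nrow(windows))
    if (nrow(cv) > 0) {
      cv_gr <- GenomicRanges::reduce(gr0(cv$chrom, cv$start, cv$end))
      hits <- GenomicRanges::findOverlaps(win_gr, cv_gr)
      if (length(hits) > 0) {
        ov <- GenomicRanges::pintersect(
          win_gr[S4Vectors::queryHits(hits)],
          cv_gr[S4Vectors::subjectHits(hits)])
        wsum <- tapply(GenomicRanges::width(ov),
                       S4Vectors::queryHits(hits), sum)
        covered[as.integer(names(wsum))] <- wsum
      }
    }
    ok[, p] <- covered > min_covered_bp
  }
  rowSums(ok) == length(pops)
}

#' Full-coverage track for a simulated cohort
#'
#' Simulated genotypes are observed everywhere, so each population covers
#' the whole genome with its panel size (per-site missingness, if any, only
#' affects variant sites and is ignored here).
#'
#' @param dataset A `sim_dataset`.
#' @return Coverage data frame as expected by [window_coverage_filter()].
#' @export
cohort_coverage <- function(dataset) {
  pops <- unique(dataset$panel$population)
  do.call(rbind, lapply(pops, function(p) {
    data.frame(chrom = dataset$layout$chrom, start = 0,
               end = dataset$layout$length_bp, pop = p,
               n_ind = sum(dataset$panel$population == p),
               stringsAsFactors = FALSE)
  }))
}
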