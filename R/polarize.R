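# Ancestral-state assignment and the derived-mutation clock: counts of
# derived transitions/transversions at third-codon positions, Ts/Tv,
# shared-derived fractions between individuals, and the TMRCA estimator
# that converts a derived-mutation count into years via a class-specific
# substitution rate.

PURINES <- c("A", "G")

#' Assign ancestral states from an outgroup track
#'
#' The ancestral state of a site is the outgroup consensus allele when that
#' allele matches one of the two alleles observed in the ingroup; anything
#' else (missing outgroup base, or a third state) leaves the site
#' unpolarized. A coverage report counts how much of the queried track was
#' inferable.
#'
#' @param st A `site_table`.
#' @param outgroup Data frame with `chrom`, `pos`, `allele` (single base or
#'   NA), aligned to the same 0-based coordinates.
#' @return List with `sites` (the updated `site_table`) and `report`
#'   (list: `inferable`, `total`, `percent`).
#' @export
assign_ancestral <- function(st, outgroup) {
  stopifnot(inherits(st, "site_table"),
            all(c("chrom", "pos", "allele") %in% names(outgroup)))
  key <- paste(st$sites$chrom, st$sites$pos)
  okey <- paste(outgroup$chrom, outgroup$pos)
  if (anyDuplicated(okey)) stop("duplicated outgroup coordinates")
  og <- outgroup$allele[match(key, okey)]
  anc <- ifelse(!is.na(og) & (og == st$sites$ref | og == st$sites$alt),
                og, NA_character_)
  st$sites$anc <- anc
  list(sites = st,
       report = polarization_coverage(sum(!is.na(anc)), nrow(st$sites)))
}

#' Polarization coverage report
#'
#' @param inferable Number of bases whose ancestral state was inferred.
#' @param total Total bases considered.
#' @return List with `inferable`, `total` and `percent` (full precision;
#'   display-rounded to 1 decimal elsewhere).
#' @export
polarization_coverage <- function(inferable, total) {
  stopifnot(total > 0, inferable >= 0, inferable <= total)
  list(inferable = inferable, total = total,
       percent = 100 * inferable / total)
}

#' Classify a mutation as transition or transversion
#'
#' Transitions exchange bases within the purines or within the pyrimidines;
#' transversions cross between the classes. Vectorised; symmetric in its
#' arguments.
#'
#' @param ancestral,derived Bases in A/C/G/T; must differ pairwise.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_mutation <- function(ancestral, derived) {
  bases <- c("A", "C", "G", "T")
  if (!all(ancestral %in% bases) || !all(derived %in% bases))
    stop("bases must be A, C, G or T")
  if (any(ancestral == derived))
    stop("ancestral and derived bases must differ")
  ifelse((ancestral %in% PURINES) == (derived %in% PURINES),
         "transition", "transversion")
}

#' Construct a derived-mutation count record
#'
#' Per mutation class, counts of fixed-stem mutations (derived in every
#' sampled individual) and within-lineage mutations (segregating or
#' lineage-restricted). Sites capable of both a transversion and a
#' transition (different derived alleles in different lineages) are counted
#' once, in the transversion class total.
#'
#' @param ti_fixed,ti_within Transition counts.
#' @param tv_fixed,tv_within Transversion counts.
#' @param mixed Mixed-state site count (attributed to transversions).
#' @param total_sites,nonmissing_sites Third-codon sites considered and the
#'   subset without missing genotypes.
#' @return A `derived_counts` object; class totals are derived fields:
#'   transitions `ti_fixed + ti_within`, transversions
#'   `tv_fixed + tv_within + mixed`.
#' @export
derived_counts <- function(ti_fixed = 0, ti_within = 0,
                           tv_fixed = 0, tv_within = 0, mixed = 0,
                           total_sites = NA_real_,
                           nonmissing_sites = NA_real_) {
  counts <- c(ti_fixed, ti_within, tv_fixed, tv_within, mixed)
  stopifnot(all(counts >= 0))
  structure(list(ti_fixed = ti_fixed, ti_within = ti_within,
                 tv_fixed = tv_fixed, tv_within = tv_within,
                 mixed = mixed,
                 ti_total = ti_fixed + ti_within,
                 tv_total = tv_fixed + tv_within + mixed,
                 total_sites = total_sites,
                 nonmissing_sites = nonmissing_sites),
            class = "derived_counts")
}

#' @export
print.derived_counts <- function(x, ...) {
  cat("Derived mutations at third-codon positions\n")
  cat(sprintf("  transitions:   %d fixed-stem + %d within-lineage = %d\n",
              x$ti_fixed, x$ti_within, x$ti_total))
  cat(sprintf("  transversions: %d fixed-stem + %d within-lineage + %d mixed = %d\n",
              x$tv_fixed, x$tv_within, x$mixed, x$tv_total))
  if (!is.na(x$nonmissing_sites))
    cat(sprintf("  sites: %s considered, %s without missing data\n",
                format(x$total_sites, big.mark = ","),
                format(x$nonmissing_sites, big.mark = ",")))
  invisible(x)
}

#' Count derived mutations by class at third-codon positions
#'
#' Restricts to polarized third-codon sites, masks sites with missing data
#' in any panel individual, applies the derived-allele-frequency cutoff
#' (default 0.1, guarding against sequencing error; set
#' `freq_type = "minor"` to filter on minor-allele frequency instead), and
#' partitions retained sites into fixed-stem (derived in every individual)
#' and within-lineage mutations of each class. Biallelic sites whose
#' recorded ancestral state equals the ALT allele are repolarized on the
#' fly (dosage flipped), so the counts refer to the annotated ancestral
#' state. Sites listing two ALT alleles of different classes are counted as
#' mixed-state.
#'
#' @param st A `site_table` (any sites; the third-codon restriction is
#'   applied internally).
#' @param individuals Panel subset to analyse (default: all).
#' @param maf_cutoff Frequency cutoff (default 0.1); sites strictly below
#'   it are excluded.
#' @param freq_type `"derived"` (default) or `"minor"`.
#' @return A `derived_counts`.
#' @export
count_derived_by_class <- function(st, individuals = st$panel$individual,
                                   maf_cutoff = 0.1,
                                   freq_type = c("derived", "minor")) {
  stopifnot(inherits(st, "site_table"))
  freq_type <- match.arg(freq_type)
  cols <- match(individuals, st$panel$individual)
  if (anyNA(cols)) stop("unknown individuals in panel subset")
  third <- which(st$sites$third_codon & !is.na(st$sites$anc))
  if (any(st$sites$third_codon & is.na(st$sites$anc)) &&
      length(third) == 0 && sum(st$sites$third_codon) > 0)
    stop("no polarized third-codon sites; run assign_ancestral first")
  total_sites <- sum(st$sites$third_codon)
  g <- st$geno[third, cols, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0
  third <- third[complete]
  g <- g[complete, , drop = FALSE]
  if (length(third) == 0)
    return(derived_counts(total_sites = total_sites, nonmissing_sites = 0))

  # repolarize where the recorded ancestral state is the ALT allele
  anc <- st$sites$anc[third]
  ref <- st$sites$ref[third]
  alt1 <- sub(",.*", "", st$sites$alt[third])
  flip <- anc == alt1
  g[flip, ] <- 2L - g[flip, , drop = FALSE]
  der_base <- ifelse(flip, ref, alt1)

  n_al <- 2L * ncol(g)
  d <- rowSums(g)
  p <- d / n_al
  f <- if (freq_type == "derived") p else pmin(p, 1 - p)
  keep <- d > 0 & f >= maf_cutoff
  g <- g[keep, , drop = FALSE]
  anc <- anc[keep]; der_base <- der_base[keep]
  alt_full <- st$sites$alt[third][keep]
  d <- d[keep]

  if (nrow(g) == 0)
    return(derived_counts(total_sites = total_sites,
                          nonmissing_sites = sum(complete)))
  cls <- classify_mutation(anc, der_base)
  # mixed-state: a second ALT allele of the other class
  alt2 <- ifelse(grepl(",", alt_full), sub(".*,", "", alt_full),
                 NA_character_)
  has2 <- !is.na(alt2) & alt2 != anc
  mixed <- rep(FALSE, length(cls))
  if (any(has2))
    mixed[has2] <- classify_mutation(anc[has2], alt2[has2]) != cls[has2]
  mixed_n <- sum(mixed)
  fixed <- rowSums(g == 2L) == ncol(g)
  use <- !mixed
  derived_counts(
    ti_fixed = sum(cls[use] == "transition" & fixed[use]),
    ti_within = sum(cls[use] == "transition" & !fixed[use]),
    tv_fixed = sum(cls[use] == "transversion" & fixed[use]),
    tv_within = sum(cls[use] == "transversion" & !fixed[use]),
    mixed = mixed_n,
    total_sites = total_sites,
    nonmissing_sites = sum(complete))
}

#' Transition/transversion ratio of derived mutations
#'
#' @param counts A `derived_counts`.
#' @param scope `"within_lineage"` (default; mutations segregating within
#'   the clade) or `"all"` (including fixed-stem mutations).
#' @param include_mixed Count mixed-state sites as capable of both classes
#'   (adds them to both numerator and denominator). Default FALSE.
#' @return The ratio at full precision (round to 1 decimal for display).
#' @export
estimate_tstv <- function(counts, scope = c("within_lineage", "all"),
                          include_mixed = FALSE) {
  stopifnot(inherits(counts, "derived_counts"))
  scope <- match.arg(scope)
  if (scope == "within_lineage") {
    ti <- counts$ti_within
    tv <- counts$tv_within
  } else {
    ti <- counts$ti_total
    tv <- counts$tv_total - counts$mixed
  }
  if (include_mixed) {
    ti <- ti + counts$mixed
    tv <- tv + counts$mixed
  }
  if (tv <= 0) stop("Ts/Tv undefined: zero transversions in scope")
  ti / tv
}

#' Fraction of one individual's derived mutations shared by another
#'
#' Over polarized third-codon sites passing the frequency cutoff, the
#' fraction of sites where `focal` carries at least one derived allele and
#' `other` does too. Sites missing in either individual are skipped.
#'
#' @param st A `site_table`.
#' @param focal,other Individual labels.
#' @param mutation_class `"transversion"`, `"transition"` or `"combined"`.
#' @param maf_cutoff Derived-frequency cutoff applied over the full panel
#'   (default 0.1).
#' @return Fraction in `[0, 1]`; errors if `focal` carries no derived
#'   alleles in scope.
#' @export
shared_derived_fraction <- function(st, focal, other,
                                    mutation_class = c("combined",
                                                       "transversion",
                                                       "transition"),
                                    maf_cutoff = 0.1) {
  stopifnot(inherits(st, "site_table"))
  mutation_class <- match.arg(mutation_class)
  fi <- match(focal, st$panel$individual)
  oi <- match(other, st$panel$individual)
  if (is.na(fi) || is.na(oi)) stop("unknown individual")
  idx <- which(st$sites$third_codon & !is.na(st$sites$anc))
  g <- st$geno[idx, , drop = FALSE]
  n_al <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / pmax(n_al, 1)
  keep <- n_al > 0 & p >= maf_cutoff
  idx <- idx[keep]
  if (mutation_class != "combined") {
    cls <- classify_mutation(st$sites$anc[idx],
                             ifelse(st$sites$anc[idx] == st$sites$alt[idx],
                                    st$sites$ref[idx], st$sites$alt[idx]))
    idx <- idx[cls == mutation_class]
  }
  gf <- st$geno[idx, fi]
  go <- st$geno[idx, oi]
  ok <- !is.na(gf) & !is.na(go)
  focal_der <- ok & gf >= 1L
  if (sum(focal_der) == 0)
    stop("focal individual carries no derived mutations in scope")
  sum(focal_der & go >= 1L) / sum(focal_der)
}

#' TMRCA from accumulated derived mutations
#'
#' Converts a derived-mutation count into a time in years:
#' `years = derived_count / (L * class_rate)`, where the class-specific
#' rate splits the total substitution rate by the Ts/Tv ratio
#' (`mu_total / (1 + tstv)` for transversions,
#' `mu_total * tstv / (1 + tstv)` for transitions, `mu_total` combined).
#' When a highest-posterior-density interval for the rate is supplied the
#' estimate is evaluated at its bounds; a larger rate gives a younger age,
#' so the endpoints swap.
#'
#' @param derived_count Number of derived mutations accumulated.
#' @param mutation_class `"transversion"`, `"transition"` or `"combined"`.
#' @param L Number of sites over which the mutations were counted.
#' @param mu_total Total substitution rate per site per year.
#' @param mu_hpd Optional length-2 numeric, HPD bounds of `mu_total`.
#' @param tstv Ts/Tv ratio (required unless `mutation_class` is
#'   `"combined"`).
#' @return A `tmrca_estimate`: list with `years`, `interval_years`,
#'   `derived_count`, `mutation_class`, `L`, `mu_total`, `tstv`.
#' @export
estimate_tmrca <- function(derived_count,
                           mutation_class = c("transversion", "transition",
                                              "combined"),
                           L, mu_total, mu_hpd = NULL, tstv = NULL) {
  mutation_class <- match.arg(mutation_class)
  stopifnot(derived_count >= 0, L > 0, mu_total > 0)
  if (mutation_class != "combined") {
    if (is.null(tstv) || tstv <= 0)
      stop("a positive Ts/Tv ratio is required for class-specific rates")
  }
  class_rate <- function(mu) switch(mutation_class,
    transversion = mu / (1 + tstv),
    transition = mu * tstv / (1 + tstv),
    combined = mu)
  years <- derived_count / (L * class_rate(mu_total))
  interval <- NULL
  if (!is.null(mu_hpd)) {
    stopifnot(length(mu_hpd) == 2, all(mu_hpd > 0))
    ends <- derived_count / (L * class_rate(sort(mu_hpd)))
    interval <- sort(ends)   # larger rate -> younger age: endpoints swap
  }
  structure(list(years = years, interval_years = interval,
                 derived_count = derived_count,
                 mutation_class = mutation_class, L = L,
                 mu_total = mu_total, tstv = tstv),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA: %.3g years (%d derived %ss over %s sites)\n",
              x$years, x$derived_count, x$mutation_class,
              format(x$L, big.mark = ",")))
  if (!is.null(x$interval_years))
    cat(sprintf("  rate-HPD interval: %.3g - %.3g years\n",
                x$interval_years[1], x$interval_years[2]))
  invisible(x)
}
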