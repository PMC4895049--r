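# Simulated-dataset container, annotation tracks and frequency helpers.
# All interval tracks use the 0-based half-open convention at the interface;
# GRanges objects store them 1-based internally via gr0()/df0().

# 0-based half-open (chrom, start, end) -> GRanges
gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0))
}

# GRanges -> 0-based half-open data frame
df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

empty_sweep_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             pop = character(), shift = numeric(), stringsAsFactors = FALSE)
}

new_sim_dataset <- function(layout, panel, sites, geno, annotations, truth) {
  structure(list(layout = layout, panel = panel, sites = sites,
                 geno = geno, annotations = annotations, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$panel), "diploid individuals in",
      length(unique(x$panel$population)), "populations;",
      nrow(x$sites), "variant sites over",
      format(genome_size(x$layout), big.mark = ","), "bp\n")
  if (nrow(x$truth$sweeps) > 0)
    cat("  spiked sweeps:", nrow(x$truth$sweeps), "\n")
  invisible(x)
}

#' Annotate a genome layout with gene models
#'
#' Lays a deterministic grid of gene models over each chromosome: genes of
#' ten 300-bp exons separated by 1.2-kb introns (13.8 kb per gene), one gene
#' every 150 kb starting at 50 kb, each with a 25-kb flank on both sides.
#' Categories follow the precedence exon > intron > flank > intergenic.
#' Third-codon positions are every third base within an exon on the +
#' strand, i.e. positions `p` with `(p - exon_start) %% 3 == 2`.
#'
#' @param layout A `genome_layout`.
#' @return A list of interval tracks (`gene`, `exon`, `intron`, `flank`),
#'   each a `GRanges`.
#' @export
annotate_layout <- function(layout) {
  genes <- list(); exons <- list()
  n_ex <- 10L; ex_len <- 300L; in_len <- 1200L
  glen <- n_ex * ex_len + (n_ex - 1L) * in_len
  for (ci in seq_len(nrow(layout))) {
    clen <- layout$length_bp[ci]
    gstarts <- seq(50000, by = 150000, length.out = 1000)
    gstarts <- gstarts[gstarts + glen <= clen]
    for (gs in gstarts) {
      genes[[length(genes) + 1L]] <-
        data.frame(chrom = layout$chrom[ci], start = gs, end = gs + glen)
      es <- gs + (seq_len(n_ex) - 1L) * (ex_len + in_len)
      exons[[length(exons) + 1L]] <-
        data.frame(chrom = layout$chrom[ci], start = es, end = es + ex_len)
    }
  }
  if (length(genes) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(gene = empty, exon = empty, intron = empty, flank = empty))
  }
  gene_df <- do.call(rbind, genes)
  exon_df <- do.call(rbind, exons)
  gene_gr <- gr0(gene_df$chrom, gene_df$start, gene_df$end)
  exon_gr <- gr0(exon_df$chrom, exon_df$start, exon_df$end)
  intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)
  flank_df <- data.frame(chrom = rep(gene_df$chrom, 2),
                         start = c(pmax(0, gene_df$start - 25000),
                                   gene_df$end),
                         end = c(gene_df$start, gene_df$end + 25000))
  flank_gr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(gr0(flank_df$chrom, flank_df$start, flank_df$end)),
    gene_gr)
  list(gene = gene_gr, exon = exon_gr, intron = intron_gr, flank = flank_gr)
}

#' Genomic category of sites
#'
#' Assigns each (chrom, pos) one category with precedence
#' exon > intron > flank > intergenic.
#'
#' @param chrom,pos Site coordinates (0-based positions).
#' @param annotations Track list as returned by [annotate_layout()].
#' @return Character vector of categories.
#' @export
site_category <- function(chrom, pos, annotations) {
  pts <- gr0(chrom, pos, pos + 1L)
  cat <- rep("intergenic", length(pos))
  for (lab in c("flank", "intron", "exon")) {
    hit <- IRanges::overlapsAny(pts, annotations[[lab]])
    cat[hit] <- lab
  }
  cat
}

#' Third-codon-position flag
#'
#' TRUE for sites at the third position of a codon under the deterministic
#' + strand gene models of [annotate_layout()].
#'
#' @inheritParams site_category
#' @return Logical vector.
#' @export
third_codon_flag <- function(chrom, pos, annotations) {
  pts <- gr0(chrom, pos, pos + 1L)
  hits <- GenomicRanges::findOverlaps(pts, annotations$exon)
  out <- rep(FALSE, length(pos))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    ex_start0 <- GenomicRanges::start(annotations$exon)[
      S4Vectors::subjectHits(hits)] - 1L
    out[qi] <- (pos[qi] - ex_start0) %% 3L == 2L
  }
  out
}

#' Displace derived-allele frequencies to emulate a selective sweep
#'
#' Shifts the derived-allele frequency of every variant site inside `region`
#' towards fixation in one population: `p' = p + shift * (1 - p)`, realised
#' on genotypes by raising the derived-allele count to `round(p' * n)` in a
#' deterministic individual order (no randomness). The swept region is
#' recorded in the dataset's truth table.
#'
#' @param dataset A `sim_dataset`.
#' @param region List or data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param pop Population label present in the panel.
#' @param shift Displacement in `[0, 1]`; `shift = 1` fixes the derived
#'   allele, `shift = 0` leaves the dataset unchanged.
#' @return The modified `sim_dataset`.
#' @export
spike_sweep <- function(dataset, region, pop, shift) {
  stopifnot(inherits(dataset, "sim_dataset"))
  region <- as.list(region)
  if (is.null(region$chrom) || region$end <= region$start)
    stop("empty or malformed region")
  if (!pop %in% dataset$panel$population) stop("unknown population: ", pop)
  if (!region$chrom %in% dataset$layout$chrom)
    stop("region chromosome not in layout")
  stopifnot(shift >= 0, shift <= 1)
  if (shift == 0) return(dataset)
  idx <- which(dataset$sites$chrom == region$chrom &
                 dataset$sites$pos >= region$start &
                 dataset$sites$pos < region$end)
  cols <- which(dataset$panel$population == pop)
  for (i in idx) {
    g <- dataset$geno[i, cols]
    ok <- !is.na(g)
    n_al <- 2L * sum(ok)
    if (n_al == 0L) next
    d <- sum(g[ok])
    p2 <- d / n_al + shift * (1 - d / n_al)
    add <- as.integer(min(round(p2 * n_al), n_al)) - d
    j <- 1L
    while (add > 0L && j <= length(cols)) {
      if (ok[j] && g[j] < 2L) {
        bump <- min(2L - g[j], add)
        g[j] <- g[j] + as.integer(bump)
        add <- add - bump
      }
      j <- j + 1L
    }
    dataset$geno[i, cols] <- g
  }
  dataset$truth$sweeps <- rbind(
    dataset$truth$sweeps,
    data.frame(chrom = region$chrom, start = region$start, end = region$end,
               pop = pop, shift = shift, stringsAsFactors = FALSE))
  dataset
}

#' Site table: the substrate of all population statistics
#'
#' A `site_table` couples a per-site annotation frame (chrom, pos, ref, alt,
#' anc, category, third_codon) with a derived-allele dosage matrix
#' (sites x individuals, values 0/1/2, NA = missing) and the population
#' panel. Positions are 0-based and strictly increasing within chromosome.
#'
#' @param sites Per-site data frame.
#' @param geno Integer dosage matrix.
#' @param panel Data frame with `individual`, `population`.
#' @return An object of class `site_table`.
#' @export
site_table <- function(sites, geno, panel) {
  stopifnot(nrow(sites) == nrow(geno),
            ncol(geno) == nrow(panel))
  for (col in c("chrom", "pos", "ref", "alt"))
    if (is.null(sites[[col]])) stop("sites lacks column ", col)
  if (is.null(sites$anc)) sites$anc <- NA_character_
  if (is.null(sites$category)) sites$category <- "intergenic"
  if (is.null(sites$third_codon)) sites$third_codon <- FALSE
  ord <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 geno = geno[ord, , drop = FALSE],
                 panel = panel),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("Site table:", nrow(x$sites), "sites x", nrow(x$panel),
      "individuals (", length(unique(x$panel$population)), "populations )\n")
  invisible(x)
}

#' Convert a simulated dataset to a site table
#'
#' Uses the recorded (possibly error-bearing) ancestral states, so dosages
#' stay expressed relative to the true derived allele while `anc` carries
#' what an outgroup would have reported.
#'
#' @param dataset A `sim_dataset`.
#' @return A `site_table`.
#' @export
as_site_table <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  site_table(dataset$sites, dataset$geno, dataset$panel)
}

#' Per-population derived-allele and genotyped-allele counts
#'
#' @param st A `site_table`.
#' @param pops Populations to tabulate (default: all in the panel).
#' @return List with matrices `der` (derived-allele count) and `n`
#'   (non-missing allele count), sites x populations, and `freq = der/n`
#'   (NaN where a population is entirely missing).
#' @export
pop_counts <- function(st, pops = unique(st$panel$population)) {
  der <- matrix(0, nrow(st$sites), length(pops),
                dimnames = list(NULL, pops))
  n <- der
  for (p in pops) {
    cols <- which(st$panel$population == p)
    g <- st$geno[, cols, drop = FALSE]
    der[, p] <- rowSums(g, na.rm = TRUE)
    n[, p] <- 2 * rowSums(!is.na(g))
  }
  list(der = der, n = n, freq = der / n)
}
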