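# File interchange: VCF 4.2 (via vcfR) with an AA INFO tag, BED tracks
# (0-based half-open), popmap and depth TSVs. Writers and the reader
# round-trip a site_table losslessly.

#' Write a simulated dataset to disk
#'
#' Emits `cohort.vcf.gz` (genotypes with the ancestral allele in the INFO
#' `AA` tag), one BED file per annotation category (`exon.bed`,
#' `intron.bed`, `flank.bed`, `gene.bed`; 0-based half-open), a population
#' map `popmap.tsv`, a run-length depth track `depth.tsv` (chrom, start,
#' end, total_depth) and, when sweeps were spiked, `sweeps.tsv`.
#'
#' @param dataset A `sim_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param nominal_depth Per-individual sequencing depth recorded in the
#'   depth track (default 2, summed over individuals).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, out_dir, nominal_depth = 2) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  files <- character(0)

  vcf_path <- file.path(out_dir, "cohort.vcf.gz")
  write_vcf_sites(dataset$sites, dataset$geno, dataset$layout, vcf_path)
  files <- c(files, vcf_path)

  for (lab in c("exon", "intron", "flank", "gene")) {
    p <- file.path(out_dir, paste0(lab, ".bed"))
    write_bed(dataset$annotations[[lab]], p)
    files <- c(files, p)
  }
  pm <- file.path(out_dir, "popmap.tsv")
  utils::write.table(dataset$panel, pm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, pm)

  depth <- data.frame(chrom = dataset$layout$chrom, start = 0L,
                      end = dataset$layout$length_bp,
                      total_depth = nominal_depth * nrow(dataset$panel))
  dp <- file.path(out_dir, "depth.tsv")
  utils::write.table(depth, dp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, dp)

  if (nrow(dataset$truth$sweeps) > 0) {
    sw <- file.path(out_dir, "sweeps.tsv")
    utils::write.table(dataset$truth$sweeps, sw, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, sw)
  }
  invisible(files)
}

# internal: site frame + dosage matrix -> VCF via vcfR
write_vcf_sites <- function(sites, geno, layout, path) {
  n <- nrow(sites)
  meta <- c("##fileformat=VCFv4.2",
            "##source=ecoscan",
            paste0("##contig=<ID=", layout$chrom, ",length=",
                   format(layout$length_bp, scientific = FALSE,
                          trim = TRUE), ">"),
            paste0("##INFO=<ID=AA,Number=1,Type=String,",
                   "Description=\"Ancestral allele\">"),
            paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                   "Description=\"Genotype\">"))
  aa <- ifelse(is.na(sites$anc), "AA=.", paste0("AA=", sites$anc))
  fix <- cbind(CHROM = sites$chrom,
               POS = format(sites$pos + 1L, scientific = FALSE, trim = TRUE),
               ID = rep(".", n), REF = sites$ref, ALT = sites$alt,
               QUAL = rep(".", n), FILTER = rep(".", n), INFO = aa)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", n, ncol(geno), dimnames = dimnames(geno))
  ok <- !is.na(geno)
  gt[ok] <- gt_code[as.character(geno[ok])]
  gt <- cbind(FORMAT = rep("GT", n), gt)
  vcf <- methods::new(methods::getClass("vcfR",
                                        where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr A `GRanges` (or a data frame with `chrom`, `start`, `end`
#'   already in 0-based half-open coordinates).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  df <- if (inherits(gr, "GRanges")) df0(gr) else
    as.data.frame(gr)[c("chrom", "start", "end")]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' @param path BED file (first three columns used; 0-based half-open).
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  df[[1]] <- as.character(df[[1]])
  gr0(df[[1]], df[[2]], df[[3]])
}

#' Read a cohort back into a site table
#'
#' Reads the VCF (+ AA tag), the population map, and the annotation BEDs
#' written by [write_dataset()] and reconstitutes the `site_table`,
#' recomputing categories and third-codon flags from the interval tracks.
#'
#' @param dir Directory written by [write_dataset()], or pass explicit
#'   paths via the other arguments.
#' @param vcf,popmap,exon_bed,intron_bed,flank_bed,gene_bed Optional
#'   explicit paths overriding the defaults under `dir`.
#' @return A `site_table`.
#' @export
read_cohort <- function(dir = NULL,
                        vcf = file.path(dir, "cohort.vcf.gz"),
                        popmap = file.path(dir, "popmap.tsv"),
                        exon_bed = file.path(dir, "exon.bed"),
                        intron_bed = file.path(dir, "intron.bed"),
                        flank_bed = file.path(dir, "flank.bed"),
                        gene_bed = file.path(dir, "gene.bed")) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  panel <- utils::read.table(popmap, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  n <- nrow(v@fix)
  if (n == 0) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        anc = character(), category = character(),
                        third_codon = logical())
    geno <- matrix(integer(0), 0, nrow(panel),
                   dimnames = list(NULL, panel$individual))
    return(site_table(sites, geno, panel))
  }
  aa <- vcfR::extract.info(v, "AA")
  aa[aa == "."] <- NA_character_
  gt <- vcfR::extract.gt(v, "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  dose <- dose[, panel$individual, drop = FALSE]
  ann <- list(exon = read_bed(exon_bed), intron = read_bed(intron_bed),
              flank = read_bed(flank_bed), gene = read_bed(gene_bed))
  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"]) - 1L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      anc = aa,
                      category = site_category(chrom, pos, ann),
                      third_codon = third_codon_flag(chrom, pos, ann),
                      stringsAsFactors = FALSE)
  site_table(sites, dose, panel)
}

#' Read a run-length depth track
#'
#' @param path TSV with columns chrom, start, end, total_depth (0-based
#'   half-open intervals; a per-site track is the width-1 special case).
#' @return Data frame with those columns.
#' @export
read_depth_track <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "total_depth")[seq_along(names(d))]
  d
}

#' Read a stepwise Ne trajectory
#'
#' Two-column TSV (time, Ne), compatible with scaled PSMC text output.
#' Lines starting with `#` are ignored.
#'
#' @param path TSV file.
#' @param marker `"autosome"` or `"x_chromosome"`.
#' @param mu_used,generation_time_years Bookkeeping fields carried on the
#'   trajectory.
#' @return An `ne_trajectory` (see [ne_trajectory()]).
#' @export
read_ne_trajectory <- function(path, marker = "autosome",
                               mu_used = NA_real_,
                               generation_time_years = NA_real_) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
  ne_trajectory(time = d[[1]], ne = d[[2]], marker = marker,
                mu_used = mu_used,
                generation_time_years = generation_time_years)
}
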