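# End-to-end pipeline: simulate (or load) -> mask/filter -> polarize ->
# landscape -> PBS + enrichment -> admixture statistics -> TSV reports.
# Every table is written with a provenance header (config hash + seed) and
# reruns with the same config are byte-identical.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one flat record.
#' Defaults are the study's operating values: depth mask > 200x, derived
#' frequency cutoff 0.1, structure filter >= 40 individuals and MAF >= 5%,
#' window coverage > 10 kb at >= 5 individuals, 50-kb landscape windows,
#' 50-kb/10-kb PBS scheme, outlier percentiles 99.9 / 99.99, top-FST
#' fraction 1%, jackknife blocks of 1,000 SNPs.
#'
#' @param scale Scenario scale factor (default 0.1 for desk runs).
#' @param seed Integer seed driving every random stage.
#' @param out_dir Output directory.
#' @param input_dir Optional directory of a cohort written by
#'   [write_dataset()]; when given, simulation is skipped.
#' @param samples_per_pop Diploid sample size per population (default 10).
#' @param depth_threshold,tmrca_maf,structure_min_individuals,
#'   structure_maf,min_covered_bp,window_min_individuals,window_bp,step_bp,
#'   pbs_window_bp,pbs_step_bp,percentile,percentile_short,top_fraction,
#'   block_size_snps Analysis thresholds; see Details above.
#' @return A validated `run_config`.
#' @export
run_config <- function(scale = 0.1, seed = 1L, out_dir = "ecoscan_out",
                       input_dir = NULL, samples_per_pop = 10,
                       depth_threshold = 200, tmrca_maf = 0.1,
                       structure_min_individuals = 40, structure_maf = 0.05,
                       min_covered_bp = 10000, window_min_individuals = 5,
                       window_bp = 50000, step_bp = window_bp,
                       pbs_window_bp = 50000, pbs_step_bp = 10000,
                       percentile = 99.9, percentile_short = 99.99,
                       top_fraction = 0.01, block_size_snps = 1000) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (scale <= 0) stop("scale must be positive")
    if (depth_threshold <= 0) stop("depth_threshold must be positive")
    if (tmrca_maf < 0 || tmrca_maf > 0.5) stop("tmrca_maf out of range")
    if (structure_maf < 0 || structure_maf > 0.5)
      stop("structure_maf out of range")
    if (percentile < 0 || percentile >= 100)
      stop("percentile must lie in [0, 100)")
    if (percentile_short < 0 || percentile_short >= 100)
      stop("percentile_short must lie in [0, 100)")
    if (top_fraction <= 0 || top_fraction > 1)
      stop("top_fraction must lie in (0, 1]")
    if (block_size_snps < 1) stop("block_size_snps must be >= 1")
    if (window_bp <= 0 || step_bp <= 0 || pbs_window_bp <= 0 ||
        pbs_step_bp <= 0) stop("window sizes must be positive")
  })
  invisible(cfg)
}

serialize_config <- function(cfg, path) {
  keys <- sort(setdiff(names(cfg), "out_dir"))
  lines <- vapply(keys, function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (is.null(v)) "" else
      paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  unname(tools::md5sum(path))
}

write_report <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(c("# ecoscan report",
               paste0("# config_md5=", hash),
               paste0("# seed=", seed)), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: cohort simulation (five-ecotype
#' scenario with a spiked sweep in the focal Antarctic population) or
#' loading, mask compilation and reporting, structure-filter accounting,
#' derived-mutation counts and Ts/Tv, the windowed differentiation
#' landscape with cross-comparison correlations, the PBS scan with
#' percentile outliers and category enrichment, and D-statistic quartets.
#' Each stage's table is written under `config$out_dir` with a provenance
#' header; a rerun with the same config reproduces the tables
#' byte-identically.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the stage objects and output paths.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- serialize_config(config, file.path(config$out_dir, "config.txt"))
  seed <- as.integer(config$seed)
  paths <- character(0)
  emit <- function(df, name) {
    p <- write_report(df, file.path(config$out_dir, name), hash, seed)
    paths[[length(paths) + 1]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dataset <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      st0 <- read_cohort(config$input_dir)
      depth0 <- read_depth_track(file.path(config$input_dir, "depth.tsv"))
      lay <- genome_layout(unique(depth0$chrom),
                           tapply(depth0$end, depth0$chrom, max)[
                             unique(depth0$chrom)])
      ann <- list(
        exon = read_bed(file.path(config$input_dir, "exon.bed")),
        intron = read_bed(file.path(config$input_dir, "intron.bed")),
        flank = read_bed(file.path(config$input_dir, "flank.bed")),
        gene = read_bed(file.path(config$input_dir, "gene.bed")))
      new_sim_dataset(lay, st0$panel, st0$sites, st0$geno, ann,
                      truth = list(model = NULL, seed = seed,
                                   sweeps = empty_sweep_table()))
    } else {
      model <- ecotype_scenario(scale = config$scale, seed = seed)
      layout <- scenario_layout(config$scale)
      pops <- leaf_populations(model)
      ds <- simulate_cohort(
        model, layout,
        samples_per_pop = stats::setNames(
          rep(config$samples_per_pop, length(pops)), pops),
        seed = seed)
      # a sweep-like displacement in the focal Antarctic type for the scan
      ds <- spike_sweep(ds, list(chrom = "chr1", start = 100000,
                                 end = 150000),
                        pop = "B1", shift = 0.5)
      ds
    }
  })
  if (is.null(config$input_dir))
    write_dataset(dataset, file.path(config$out_dir, "data"))
  st <- as_site_table(dataset)

  data_dir <- if (is.null(config$input_dir))
    file.path(config$out_dir, "data") else config$input_dir
  mask <- stage("mask", {
    depth <- read_depth_track(file.path(data_dir, "depth.tsv"))
    compile_mask(depth_track = depth,
                 depth_threshold = config$depth_threshold,
                 layout = dataset$layout)
  })
  rep_m <- mask_report(mask)
  emit(data.frame(masked_sites = rep_m$masked_sites,
                  masked_fraction = rep_m$masked_fraction,
                  t(rep_m$per_source)), "mask_report.tsv")

  stage("structure_filter", {
    kept <- filter_variants_for_structure(
      st, min_individuals = config$structure_min_individuals,
      min_maf = config$structure_maf)
    emit(data.frame(input_sites = nrow(st$sites),
                    retained_sites = nrow(kept$sites),
                    min_individuals = config$structure_min_individuals,
                    min_maf = config$structure_maf),
         "structure_filter.tsv")
  })

  stage("polarize", {
    counts <- count_derived_by_class(st, maf_cutoff = config$tmrca_maf)
    tstv <- if (counts$tv_within > 0)
      estimate_tstv(counts) else NA_real_
    emit(data.frame(ti_fixed = counts$ti_fixed,
                    ti_within = counts$ti_within,
                    tv_fixed = counts$tv_fixed,
                    tv_within = counts$tv_within,
                    mixed = counts$mixed,
                    nonmissing_sites = counts$nonmissing_sites,
                    tstv_within = tstv), "derived_counts.tsv")
  })

  pops <- sort(unique(dataset$panel$population))
  comparisons <- utils::combn(pops, 2, simplify = FALSE)
  tables <- stage("landscape", {
    suppressWarnings(landscape_scan(
      dataset, comparisons, window_bp = config$window_bp,
      step_bp = config$step_bp, min_covered_bp = config$min_covered_bp,
      min_individuals = config$window_min_individuals))
  })
  for (nm in names(tables))
    emit(tables[[nm]], paste0("landscape_", nm, ".tsv"))
  n_win <- nrow(tables[[1]])
  if (length(tables) >= 2 && n_win >= 10) {
    rho <- stage("correlations",
                 landscape_correlations(tables, statistics = "fst",
                                        min_windows = 10))
    emit(data.frame(label = rownames(rho), round(rho, 6)),
         "landscape_correlations.tsv")
  }

  pbs_tab <- stage("pbs", {
    suppressWarnings(pbs_scan(
      dataset, trio = c("B1", "B2", "C"),
      window_bp = config$pbs_window_bp, step_bp = config$pbs_step_bp,
      min_covered_bp = config$min_covered_bp,
      min_individuals = config$window_min_individuals))
  })
  emit(as.data.frame(pbs_tab), "pbs_windows.tsv")
  out_call <- stage("outliers", suppressWarnings(
    outlier_call(pbs_tab, percentile = config$percentile)))
  emit(as.data.frame(out_call$outliers), "pbs_outliers.tsv")

  stage("top_fst", {
    ps <- per_site_fst(st, "B1", "C")
    top <- top_fst_snps(ps[!is.na(ps$fst), ], fraction = config$top_fraction)
    enr <- category_bin_chisq(top, all_snps = ps[!is.na(ps$fst), ])
    emit(top, "top_fst_snps.tsv")
    emit(data.frame(category = rownames(enr$residuals),
                    round(enr$residuals, 4), check.names = FALSE),
         "fst_bin_residuals.tsv")
  })

  dtab <- stage("admixture", {
    quartets <- list(c("B1", "RES", "TRA", "OUTGROUP"),
                     c("B1", "B2", "RES", "OUTGROUP"),
                     c("B1", "B2", "TRA", "OUTGROUP"))
    dstat_quartets(st, quartets,
                   block_size_snps = config$block_size_snps)
  })
  emit(dtab, "dstat.tsv")

  invisible(list(dataset = dataset, mask = mask, landscape = tables,
                 pbs = pbs_tab, outliers = out_call, dstat = dtab,
                 paths = unlist(paths), config_md5 = hash))
}
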