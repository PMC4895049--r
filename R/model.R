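#' Demographic model for a structured-coalescent simulation
#'
#' A `demographic_model` describes a set of populations related by a rooted
#' split tree, piecewise-constant diploid effective sizes, and optional
#' one-off admixture pulses. Times are expressed in generations before the
#' present (backwards in time), so an epoch starting at generation 0 is the
#' most recent one.
#'
#' @param populations Character vector of population labels. Must include
#'   every label used in `epochs`, `splits` and `pulses`; internal (ancestral)
#'   populations are listed here too.
#' @param epochs Data frame with columns `pop`, `start_gen`, `ne`: population
#'   label, epoch start time in generations before present, and diploid
#'   effective size holding from `start_gen` backwards until the next epoch
#'   of the same population begins.
#' @param splits Data frame with columns `child`, `parent`, `time_gen`. Going
#'   backwards in time, all lineages of `child` join `parent` at `time_gen`.
#'   The split relations must form a tree with a single root population.
#' @param pulses Data frame (possibly empty) with columns `source`, `dest`,
#'   `time_gen`, `fraction`: at `time_gen`, a fraction of `dest`'s ancestry
#'   derives from `source` (forward-time direction source -> dest).
#' @param mu Mutation rate per site per generation.
#' @param recomb Recombination rate per site per generation. The simulator
#'   realises it as free recombination between blocks of
#'   approximately `1/(4 * Ne * recomb)`-scaled length (see
#'   [simulate_cohort()]); stored for bookkeeping.
#' @param generation_time_years Generation time in years (> 0).
#'
#' @return An object of class `demographic_model`.
#' @seealso [ecotype_scenario()], [simulate_cohort()]
#' @export
demographic_model <- function(populations, epochs, splits,
                              pulses = NULL, mu, recomb = 1e-8,
                              generation_time_years = 25.7) {
  stopifnot(is.character(populations), length(populations) >= 1,
            !anyDuplicated(populations))
  epochs <- as.data.frame(epochs)
  splits <- as.data.frame(splits)
  if (is.null(pulses)) {
    pulses <- data.frame(source = character(), dest = character(),
                         time_gen = numeric(), fraction = numeric())
  }
  pulses <- as.data.frame(pulses)
  stopifnot(all(c("pop", "start_gen", "ne") %in% names(epochs)),
            all(c("child", "parent", "time_gen") %in% names(splits)))
  if (nrow(pulses) > 0) {
    stopifnot(all(c("source", "dest", "time_gen", "fraction") %in%
                    names(pulses)))
  }
  model <- structure(
    list(populations = populations,
         epochs = epochs[order(epochs$pop, epochs$start_gen), , drop = FALSE],
         splits = splits[order(splits$time_gen), , drop = FALSE],
         pulses = pulses,
         mu = mu, recomb = recomb,
         generation_time_years = generation_time_years),
    class = "demographic_model")
  validate_model(model)
  model
}

#' Validate a demographic model
#'
#' Checks the structural invariants: positive rates, Ne >= 2 everywhere,
#' pulse fractions strictly inside (0, 1), split times strictly ordered along
#' every lineage, and a single root population.
#'
#' @param model A `demographic_model`.
#' @return The model, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  pops <- model$populations
  ep <- model$epochs
  sp <- model$splits
  pu <- model$pulses
  if (model$mu <= 0 || model$recomb <= 0 || model$generation_time_years <= 0)
    stop("mutation rate, recombination rate and generation time must be positive")
  if (!all(ep$pop %in% pops))
    stop("epoch refers to unknown population")
  if (any(ep$ne < 2))
    stop("all epochs must have Ne >= 2 (bottlenecks included)")
  if (any(ep$start_gen < 0))
    stop("epoch start times must be >= 0 generations before present")
  if (nrow(sp) > 0) {
    if (!all(c(sp$child, sp$parent) %in% pops))
      stop("split refers to unknown population")
    if (anyDuplicated(sp$child))
      stop("a population may split into its parent only once")
    # split times strictly increase child -> parent along any lineage
    for (i in seq_len(nrow(sp))) {
      parent <- sp$parent[i]
      j <- match(parent, sp$child)
      if (!is.na(j) && sp$time_gen[j] <= sp$time_gen[i])
        stop("split times must be strictly ordered along each lineage")
    }
    roots <- setdiff(pops, sp$child)
    if (length(roots) != 1)
      stop("split relations must leave exactly one root population, found: ",
           paste(roots, collapse = ", "))
  } else if (length(pops) > 1) {
    stop("multiple populations require split relations joining them")
  }
  if (nrow(pu) > 0) {
    if (!all(c(pu$source, pu$dest) %in% pops))
      stop("pulse refers to unknown population")
    if (any(pu$fraction <= 0 | pu$fraction >= 1))
      stop("pulse fractions must lie strictly inside (0, 1)")
    if (any(pu$time_gen < 0)) stop("pulse times must be >= 0")
  }
  # every population must have an epoch starting at (or before) its origin
  for (p in pops) {
    if (!any(ep$pop == p)) stop("population ", p, " has no Ne epoch")
  }
  invisible(model)
}

root_population <- function(model) {
  setdiff(model$populations, model$splits$child)
}

#' Leaf (sampled) populations of a demographic model
#'
#' @param model A `demographic_model`.
#' @return Character vector of populations that never act as a parent in
#'   the split relations.
#' @export
leaf_populations <- function(model) {
  setdiff(model$populations, model$splits$parent)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", length(x$populations), "populations (",
      paste(leaf_populations(x), collapse = ", "), "at the leaves )\n")
  cat("  splits (generations ago):\n")
  for (i in seq_len(nrow(x$splits)))
    cat(sprintf("    %s -> %s at %g\n", x$splits$child[i],
                x$splits$parent[i], x$splits$time_gen[i]))
  if (nrow(x$pulses) > 0)
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  pulse %s -> %s at %g gen, fraction %.3f\n",
                  x$pulses$source[i], x$pulses$dest[i],
                  x$pulses$time_gen[i], x$pulses$fraction[i]))
  cat(sprintf("  mu = %g /site/gen, recomb = %g, generation time = %g yr\n",
              x$mu, x$recomb, x$generation_time_years))
  invisible(x)
}

#' Genome layout
#'
#' Chromosome names and lengths. All coordinates in the package are 0-based
#' half-open; a chromosome of length L covers positions `[0, L)`.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Integer vector of positive lengths (bp).
#' @return An object of class `genome_layout` (a data frame).
#' @export
genome_layout <- function(chrom, length_bp) {
  stopifnot(length(chrom) == length(length_bp),
            !anyDuplicated(chrom), all(length_bp > 0))
  structure(data.frame(chrom = as.character(chrom),
                       length_bp = as.numeric(length_bp),
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

genome_size <- function(layout) sum(layout$length_bp)

#' Five-ecotype radiation scenario
#'
#' Builds the demographic scenario the package's calibration suite runs on:
#' five ecotype populations descended from a single large ancestor through
#' sequential founder bottlenecks (each with Ne < 1,000) followed by
#' re-expansion, with one directional admixture pulse from a resident-related
#' lineage into the transient ecotype. Two Northern Hemisphere ecotypes
#' (resident, transient) split first; an Antarctic clade then radiates into
#' types B1, B2 and C, with the B1/B2 split youngest.
#'
#' Split times are in generations before present: transient 7,000; the
#' resident / Antarctic-ancestor separation 5,500; type C 1,800; B1/B2 600.
#' Each founder passes through a brief bottleneck (Ne 400-600, roughly 80
#' generations) before expanding to tens of thousands; the drift these
#' epochs accumulate is calibrated so genome-wide pairwise FST spans about
#' 0.1 for the youngest pair to about 0.3 for the Pacific pair. The
#' mutation rate defaults to 2.34e-8 per site per generation and the
#' generation time to 25.7 years.
#'
#' @param scale Positive scale factor for desk-sized runs; it is recorded in
#'   the returned model (attribute `scale`) and interpreted by
#'   [scenario_layout()] and [run_pipeline()] as a multiplier on sequence
#'   length. The demography itself is not rescaled.
#' @param seed Integer seed recorded with the model so that downstream
#'   simulation defaults are reproducible.
#' @return A `demographic_model` with 5 leaf populations (RES, TRA, B1, B2,
#'   C), bottleneck epochs with Ne < 1,000 on every founder lineage, and one
#'   RES -> TRA pulse of fraction 0.10.
#' @export
ecotype_scenario <- function(scale = 1, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a positive number")
  pops <- c("RES", "TRA", "B1", "B2", "C", "ANTB", "ANT", "NOR", "ANC")
  # epochs: (pop, start_gen, ne), ne holds from start_gen backwards in
  # time. Each founder passes a brief bottleneck (Ne < 1,000) right after
  # its origin, then expands; drift totals are calibrated so genome-wide
  # pairwise FST spans roughly 0.1 (B1 vs B2, the youngest pair) to ~0.3
  # (the Pacific pair), the study system's printed range.
  epochs <- rbind(
    data.frame(pop = "TRA", start_gen = 0,    ne = 20000),
    data.frame(pop = "TRA", start_gen = 6920, ne = 500),
    data.frame(pop = "RES", start_gen = 0,    ne = 20000),
    data.frame(pop = "RES", start_gen = 5420, ne = 500),
    data.frame(pop = "C",   start_gen = 0,    ne = 20000),
    data.frame(pop = "C",   start_gen = 1720, ne = 400),
    data.frame(pop = "B1",  start_gen = 0,    ne = 15000),
    data.frame(pop = "B1",  start_gen = 550,  ne = 600),
    data.frame(pop = "B2",  start_gen = 0,    ne = 15000),
    data.frame(pop = "B2",  start_gen = 550,  ne = 600),
    data.frame(pop = "ANTB", start_gen = 600,  ne = 20000),
    data.frame(pop = "ANT",  start_gen = 1800, ne = 20000),
    data.frame(pop = "ANT",  start_gen = 5420, ne = 500),
    data.frame(pop = "NOR",  start_gen = 5500, ne = 15000),
    data.frame(pop = "ANC",  start_gen = 7000, ne = 15000)
  )
  splits <- data.frame(
    child  = c("B1",   "B2",   "C",   "ANTB", "RES", "ANT", "NOR", "TRA"),
    parent = c("ANTB", "ANTB", "ANT", "ANT",  "NOR", "NOR", "ANC", "ANC"),
    time_gen = c(600, 600, 1800, 1800, 5500, 5500, 7000, 7000))
  pulses <- data.frame(source = "RES", dest = "TRA",
                       time_gen = 1000, fraction = 0.10)
  model <- demographic_model(
    populations = pops, epochs = epochs, splits = splits, pulses = pulses,
    mu = 2.34e-8, recomb = 1e-8, generation_time_years = 25.7)
  attr(model, "scale") <- scale
  attr(model, "seed") <- as.integer(seed)
  model
}

#' Calibration fixture: two sisters and a drifted source with one pulse
#'
#' A four-population model built for admixture power checks: sisters P1
#' and P2 split 1,000 generations ago from S, which separated from P3 at
#' 4,000 generations; P3 holds a small long-term size (Ne 2,000), so its
#' branch accrues substantial private drift, and donates one directional
#' pulse into P2 at 500 generations. With the default 10% pulse,
#' [dstat()] on (P1, P2, P3, outgroup) is expected to give Z well above 3
#' on a few megabases; with `pulse_fraction = 0` the quartet is tree-like
#' and D is calibrated around zero.
#'
#' @param pulse_fraction Admixture fraction of the P3 -> P2 pulse; 0
#'   disables it (null model).
#' @return A `demographic_model` with leaves P1, P2, P3.
#' @export
admixture_power_model <- function(pulse_fraction = 0.1) {
  pulses <- if (pulse_fraction > 0)
    data.frame(source = "P3", dest = "P2", time_gen = 500,
               fraction = pulse_fraction) else NULL
  demographic_model(
    populations = c("P1", "P2", "P3", "S", "ANC"),
    epochs = rbind(
      data.frame(pop = "P1", start_gen = 0, ne = 10000),
      data.frame(pop = "P2", start_gen = 0, ne = 10000),
      data.frame(pop = "P3", start_gen = 0, ne = 2000),
      data.frame(pop = "S", start_gen = 1000, ne = 10000),
      data.frame(pop = "ANC", start_gen = 4000, ne = 10000)),
    splits = data.frame(child = c("P1", "P2", "S", "P3"),
                        parent = c("S", "S", "ANC", "ANC"),
                        time_gen = c(1000, 1000, 4000, 4000)),
    pulses = pulses, mu = 2.34e-8)
}

#' Calibration fixture: a clean two-population split
#'
#' Two small populations separated `t_split` generations ago, used for
#' derived-mutation clock recovery: with tiny within-population sizes the
#' private branch length of a sampled individual is dominated by the split
#' time, so the count of its unshared derived mutations divided by
#' `mu * L` recovers `t_split`.
#'
#' @param t_split Split time in generations.
#' @param ne Diploid size of each daughter population.
#' @param ne_anc Ancestral diploid size.
#' @param mu Mutation rate per site per generation.
#' @param generation_time_years Generation time (default 1, so years equal
#'   generations).
#' @return A `demographic_model` with leaves FOC and OTH.
#' @export
split_pair_model <- function(t_split = 20000, ne = 100, ne_anc = 100,
                             mu = 2.34e-8, generation_time_years = 1) {
  demographic_model(
    populations = c("FOC", "OTH", "ANC"),
    epochs = rbind(
      data.frame(pop = "FOC", start_gen = 0, ne = ne),
      data.frame(pop = "OTH", start_gen = 0, ne = ne),
      data.frame(pop = "ANC", start_gen = t_split, ne = ne_anc)),
    splits = data.frame(child = c("FOC", "OTH"), parent = c("ANC", "ANC"),
                        time_gen = c(t_split, t_split)),
    mu = mu, generation_time_years = generation_time_years)
}

#' Genome layout matching a scenario scale
#'
#' The default study genome is 5 chromosomes of 2 Mb; `scale` multiplies the
#' chromosome length (minimum 50 kb per chromosome).
#'
#' @param scale Positive scale factor (default taken from the model if set).
#' @return A `genome_layout`.
#' @export
scenario_layout <- function(scale = 1) {
  stopifnot(is.numeric(scale), scale > 0)
  len <- max(50000, round(2e6 * scale))
  genome_layout(paste0("chr", 1:5), rep(len, 5))
}
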