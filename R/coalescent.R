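# Structured-coalescent engine.
#
# Genealogies are simulated backwards in time for non-recombining blocks
# that are independent of each other (free recombination between blocks,
# none within). Rates are piecewise constant between demographic events
# (epoch boundaries, splits, pulses), so exponential waiting times drawn at
# the current rates are exact.

# Build the sorted event table the engine walks through.
build_event_table <- function(model) {
  ev <- data.frame(time = numeric(), type = character(),
                   a = character(), b = character(), frac = numeric(),
                   stringsAsFactors = FALSE)
  ep <- model$epochs
  boundary <- ep$start_gen > 0
  if (any(boundary)) {
    ev <- rbind(ev, data.frame(time = ep$start_gen[boundary], type = "epoch",
                               a = NA_character_, b = NA_character_,
                               frac = NA_real_))
  }
  pu <- model$pulses
  if (nrow(pu) > 0) {
    ev <- rbind(ev, data.frame(time = pu$time_gen, type = "pulse",
                               a = pu$source, b = pu$dest, frac = pu$fraction))
  }
  sp <- model$splits
  if (nrow(sp) > 0) {
    ev <- rbind(ev, data.frame(time = sp$time_gen, type = "split",
                               a = sp$child, b = sp$parent, frac = NA_real_))
  }
  # at ties, pulses fire before splits so a pulse at a split time still sees
  # the pre-split deme occupancy; epoch markers only refresh rates
  type_rank <- c(epoch = 0, pulse = 1, split = 2)
  ev <- ev[order(ev$time, type_rank[ev$type]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Piecewise-constant Ne lookup: ne_steps is a list (one element per
# population index) of lists with vectors `starts`, `nes`; returns Ne at
# time t (right-continuous backwards in time).
ne_at <- function(ne_steps, p, t) {
  s <- ne_steps[[p]]
  s$nes[max(1L, findInterval(t, s$starts))]
}

# Simulate one marginal genealogy for lineage populations `lin_pop`
# (integer vector of population indices, one per sampled haploid lineage).
# Rates are updated incrementally: a coalescence only changes one
# population's rate, demographic events (few) refresh all of them.
# Returns parent pointers and node times; tips are nodes 1..n.
sim_genealogy <- function(lin_pop, events, ne_steps, n_pops) {
  n <- length(lin_pop)
  parent <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  members <- vector("list", n_pops)
  for (p in seq_len(n_pops)) members[[p]] <- which(lin_pop == p)
  k <- lengths(members)
  nxt <- n + 1L
  time <- 0
  ev_i <- 1L
  n_ev <- length(events$time)
  ev_time <- events$time; ev_type <- events$type
  ev_a <- events$a; ev_b <- events$b; ev_frac <- events$frac
  ne_cur <- vapply(seq_len(n_pops), function(p) ne_at(ne_steps, p, time),
                   numeric(1))
  rate <- k * (k - 1) / 2 / (2 * ne_cur)
  n_active <- n
  while (n_active > 1L) {
    total <- sum(rate)
    t_ev <- if (ev_i <= n_ev) ev_time[ev_i] else Inf
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (time + dt < t_ev) {
      time <- time + dt
      p <- if (n_pops == 1L) 1L else sample.int(n_pops, 1L, prob = rate)
      mem <- members[[p]]
      pair <- if (k[p] == 2L) 1:2 else sample.int(k[p], 2L)
      node <- nxt; nxt <- nxt + 1L
      node_time[node] <- time
      parent[mem[pair]] <- node
      members[[p]] <- c(mem[-pair], node)
      k[p] <- k[p] - 1L
      rate[p] <- k[p] * (k[p] - 1) / 2 / (2 * ne_cur[p])
      n_active <- n_active - 1L
    } else {
      if (!is.finite(t_ev)) stop("genealogy failed to coalesce; model has ",
                                 "disconnected populations")
      time <- t_ev
      type <- ev_type[ev_i]
      if (type == "split") {
        a <- ev_a[ev_i]; b <- ev_b[ev_i]
        members[[b]] <- c(members[[b]], members[[a]])
        members[[a]] <- integer(0)
        k[b] <- k[b] + k[a]; k[a] <- 0L
      } else if (type == "pulse") {
        a <- ev_a[ev_i]; b <- ev_b[ev_i]
        mem <- members[[b]]
        if (length(mem) > 0) {
          mig <- stats::runif(length(mem)) < ev_frac[ev_i]
          if (any(mig)) {
            members[[a]] <- c(members[[a]], mem[mig])
            members[[b]] <- mem[!mig]
            k[a] <- k[a] + sum(mig); k[b] <- k[b] - sum(mig)
          }
        }
      } # epoch markers only refresh the rates
      ne_cur <- vapply(seq_len(n_pops), function(p)
        ne_at(ne_steps, p, time), numeric(1))
      rate <- k * (k - 1) / 2 / (2 * ne_cur)
      ev_i <- ev_i + 1L
    }
  }
  list(parent = parent, node_time = node_time, n_tips = n)
}

# Tips below each node of interest (nodes indexed as in sim_genealogy).
tips_below <- function(tree, nodes) {
  n <- tree$n_tips
  children <- vector("list", 2L * n - 1L)
  for (v in seq_len(2L * n - 2L)) {
    p <- tree$parent[v]
    if (p > 0) children[[p]] <- c(children[[p]], v)
  }
  lapply(nodes, function(v) {
    stack <- v
    tips <- integer(0)
    while (length(stack) > 0) {
      x <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (x <= n) tips <- c(tips, x) else stack <- c(stack, children[[x]])
    }
    sort(tips)
  })
}

# Drop infinite-sites mutations on a genealogy across a block of `len` sites.
# Returns positions (0-based within block) and a carrier matrix
# (sites x lineages, logical).
drop_mutations <- function(tree, len, mu) {
  n_nodes <- 2L * tree$n_tips - 1L
  v <- seq_len(n_nodes - 1L)        # all non-root nodes carry a branch
  blen <- tree$node_time[tree$parent[v]] - tree$node_time[v]
  total <- sum(blen)
  n_mut <- stats::rpois(1L, mu * len * total)
  n_mut <- min(n_mut, len)          # infinite-sites cap at block saturation
  if (n_mut == 0L) {
    return(list(pos = integer(0),
                carriers = matrix(FALSE, 0L, tree$n_tips)))
  }
  branch <- sample(v, n_mut, replace = TRUE, prob = blen)
  pos <- sort(sample.int(len, n_mut, replace = FALSE) - 1L)
  ub <- unique(branch)
  below <- tips_below(tree, ub)
  carriers <- matrix(FALSE, n_mut, tree$n_tips)
  for (i in seq_len(n_mut)) {
    carriers[i, below[[match(branch[i], ub)]]] <- TRUE
  }
  list(pos = pos, carriers = carriers)
}

#' Simulate a multi-population diploid cohort
#'
#' Realises a [demographic_model()] as genotypes over a [genome_layout()]
#' using a structured coalescent: each chromosome is cut into blocks of
#' `block_bp` that recombine freely with each other and not internally; a
#' marginal genealogy is simulated per block and infinite-sites mutations
#' are dropped on it, so the expected nucleotide diversity of a population
#' of constant size Ne is `4 * Ne * mu` per site. Ancestral states are
#' recorded from the simulated root; `anc_error` optionally mislabels them
#' to emulate outgroup polarization error.
#'
#' @param model A validated `demographic_model`.
#' @param layout A `genome_layout`.
#' @param samples_per_pop Named integer vector, diploid individuals sampled
#'   per (leaf) population; names must be populations of the model.
#' @param seed Integer seed; identical inputs give bit-identical datasets.
#' @param block_bp Non-recombining block length in bp (default 10000).
#' @param tstv Transition/transversion ratio used when assigning derived
#'   bases (default 3.8).
#' @param anc_error Probability that the recorded ancestral state is the
#'   derived allele instead (default 0, i.e. exact polarization).
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @return A `sim_dataset`: list with `layout`, `panel` (individual ->
#'   population), `sites` (chrom, pos, ref, alt, anc, anc_true, category,
#'   third_codon), `geno` (sites x individuals derived-allele dosage matrix,
#'   NA = missing), `annotations` (exon/intron/flank/gene interval tracks)
#'   and `truth` (model, seed, sweep regions).
#' @export
simulate_cohort <- function(model, layout, samples_per_pop, seed,
                            block_bp = 10000, tstv = 3.8,
                            anc_error = 0, missing_rate = 0) {
  validate_model(model)
  stopifnot(inherits(layout, "genome_layout"))
  if (genome_size(layout) <= 0) stop("zero-length genome")
  if (is.null(names(samples_per_pop)) ||
      !all(names(samples_per_pop) %in% model$populations))
    stop("samples_per_pop names must be populations of the model")
  stopifnot(all(samples_per_pop >= 1))
  set.seed(as.integer(seed))

  pops <- names(samples_per_pop)
  ind <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(samples_per_pop[[p]]))))
  panel <- data.frame(individual = ind,
                      population = rep(pops, times = unlist(samples_per_pop)),
                      stringsAsFactors = FALSE)
  lin_pop <- rep(panel$population, each = 2L)
  n_ind <- nrow(panel)

  all_pops <- model$populations
  ev_df <- build_event_table(model)
  events <- list(time = ev_df$time, type = ev_df$type,
                 a = match(ev_df$a, all_pops),
                 b = match(ev_df$b, all_pops),
                 frac = ev_df$frac)
  ne_steps <- lapply(all_pops, function(p) {
    d <- model$epochs[model$epochs$pop == p, , drop = FALSE]
    d <- d[order(d$start_gen), , drop = FALSE]
    list(starts = d$start_gen, nes = d$ne)
  })
  lin_pop_idx <- match(lin_pop, all_pops)

  annotations <- annotate_layout(layout)

  chrom_l <- list(); pos_l <- list(); dose_l <- list()
  for (ci in seq_len(nrow(layout))) {
    clen <- layout$length_bp[ci]
    starts <- seq(0, clen - 1, by = block_bp)
    for (bs in starts) {
      len <- min(block_bp, clen - bs)
      tree <- sim_genealogy(lin_pop_idx, events, ne_steps,
                            length(all_pops))
      mut <- drop_mutations(tree, len, model$mu)
      if (length(mut$pos) == 0L) next
      # diploid dosage: lineages 2i-1, 2i belong to individual i
      dose <- mut$carriers[, seq(1L, 2L * n_ind, by = 2L), drop = FALSE] +
        mut$carriers[, seq(2L, 2L * n_ind, by = 2L), drop = FALSE]
      chrom_l[[length(chrom_l) + 1L]] <- rep(layout$chrom[ci],
                                             length(mut$pos))
      pos_l[[length(pos_l) + 1L]] <- mut$pos + bs
      dose_l[[length(dose_l) + 1L]] <- dose
    }
  }
  if (length(pos_l) == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        anc = character(), anc_true = character(),
                        category = character(), third_codon = logical())
    geno <- matrix(integer(0), 0L, n_ind, dimnames = list(NULL, ind))
    return(new_sim_dataset(layout, panel, sites, geno, annotations,
                           truth = list(model = model, seed = seed,
                                        sweeps = empty_sweep_table())))
  }
  chrom <- unlist(chrom_l)
  pos <- unlist(pos_l)
  geno <- do.call(rbind, dose_l)
  storage.mode(geno) <- "integer"
  colnames(geno) <- ind
  n_sites <- length(pos)

  # drop monomorphic-in-sample sites (mutations above the sample MRCA of a
  # block can be carried by every lineage)
  der <- rowSums(geno)
  poly <- der > 0 & der < 2L * n_ind
  chrom <- chrom[poly]; pos <- pos[poly]
  geno <- geno[poly, , drop = FALSE]
  n_sites <- sum(poly)

  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  anc_true <- sample(bases, n_sites, replace = TRUE)
  is_ts <- stats::runif(n_sites) < tstv / (1 + tstv)
  alt <- character(n_sites)
  alt[is_ts] <- transition_of[anc_true[is_ts]]
  if (any(!is_ts)) {
    tv_pick <- ifelse(stats::runif(sum(!is_ts)) < 0.5, 1L, 2L)
    tv_partners <- rbind(A = c("C", "T"), C = c("A", "G"),
                         G = c("C", "T"), T = c("A", "G"))
    alt[!is_ts] <- tv_partners[cbind(match(anc_true[!is_ts], bases),
                                     tv_pick)]
  }
  anc <- anc_true
  if (anc_error > 0) {
    flip <- stats::runif(n_sites) < anc_error
    anc[flip] <- alt[flip]
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_sites * n_ind) < missing_rate,
                   n_sites, n_ind)
    geno[miss] <- NA_integer_
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = anc_true, alt = alt,
                      anc = anc, anc_true = anc_true,
                      stringsAsFactors = FALSE)
  ord <- order(match(sites$chrom, layout$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites$category <- site_category(sites$chrom, sites$pos, annotations)
  sites$third_codon <- third_codon_flag(sites$chrom, sites$pos, annotations)

  new_sim_dataset(layout, panel, sites, geno, annotations,
                  truth = list(model = model, seed = seed,
                               sweeps = empty_sweep_table()))
}
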