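---
title: "Methods and design of ecoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ecoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ecoscan` analyses cohorts of closely related populations that diverged
recently through founder bottlenecks — ecotype radiations of the killer
whale kind. This vignette records the statistical models the package
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic cohorts do and do not emulate, and the design
decisions taken where several defensible choices existed.

## The statistics

### Masking and eligibility

A genome mask is the interval union of a repeat track, a numt track and
all sites whose total sequencing depth exceeds a threshold (strict `>`,
default 200x — depth far above the cohort-wide expectation flags
collapsed, unmasked repeats). Provenance counts attribute each masked site
to the *first* source that masks it, in the order repeat, numt, depth;
this is a reporting convention only, and the union itself is
order-invariant (tested as an idempotence invariant). Masked fractions
are stored at full precision and rounded to two decimals for display.
Because genome-scale tracks cannot be enumerated site by site, the depth
track is consumed in run-length (bedGraph-style) form — chrom, start, end,
total_depth over 0-based half-open intervals — of which a per-site track
is the width-1 special case.

Two eligibility filters recur downstream. The structure filter keeps
autosomal sites genotyped in at least 40 individuals with sample
minor-allele frequency at least 5%; the MAF boundary is inclusive
(removing only frequencies *below* 5%). The window coverage filter admits
a window only when, in *every* population compared, strictly more than
10 kb of it is covered by at least five genotyped individuals.

### The derived-mutation clock

Polarized third-codon sites (the most degenerate codon position, chosen to
minimise the footprint of purifying selection) are classified as derived
transitions or transversions against the ancestral state. Sites with
missing genotypes in any panel individual are masked; a derived-allele
frequency cutoff (default 0.1) guards against sequencing error. Retained
sites partition into fixed-stem mutations (derived allele at frequency 1,
i.e. accumulated on the stem to the clade's common ancestor or reflecting
mispolarization) and within-lineage mutations. Sites carrying derived
alleles of both classes in different lineages are counted once, in the
transversion total; the Ts/Tv ratio is computed from within-lineage counts
excluding those mixed sites by default, with `include_mixed = TRUE`
counting them as capable of both classes — on the package's reference
partition both conventions round to the same value.

The clock converts a derived-mutation count into years as
`years = count / (L * mu_class)`, with `mu_class` splitting a total
substitution rate by the Ts/Tv ratio (`mu/(1+k)` for transversions,
`mu k/(1+k)` for transitions). `L` is an explicit argument, deliberately:
the effective number of sites after missing-data masking is a property of
the data set, not of the estimator, and the published analyses this
mirrors do not always print the value they used. Rate uncertainty is
propagated by evaluating the formula at the bounds of a highest-
posterior-density interval; since a larger rate implies a younger age, the
endpoints swap. Frequency cutoffs can be taken on the derived or on the
minor allele; derived is the default because the counts being filtered are
derived-allele counts.

### Differentiation landscapes

Per-site FST uses the Hudson method-of-moments components

```
num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
den = p1(1-p2) + p2(1-p1)
```

with `n` the sampled allele counts. Windows aggregate by ratio of sums,
which is robust to low-information sites; negative per-site numerators
(sampling noise) are deliberately *not* clamped so the sums stay unbiased.
Monomorphic sites contribute (0, 0). `Dxy = p1(1-p2) + p2(1-p1)` with
absent variation scored as frequency zero, and nucleotide diversity uses
the unbiased per-site heterozygosity `2p(1-p) n/(n-1)` divided by covered
length. Landscape windows are tiled by default (a Manhattan-plot
convention); a step argument produces sliding windows where needed.
Cross-comparison structure is summarised by Spearman rank correlations
over windows present in all tables, pairwise-complete.

### PBS selection scan

Window FST values for the three pairs of a population trio are transformed
by `T = -log(1 - FST)` (small negative window FSTs are clamped to zero
first: branch lengths are non-negative, and such values are sampling
noise) and combined into `PBS_A = (T_AB + T_AC - T_BC)/2`, the
allele-frequency branch length of the focal population. The scan runs on
50-kb windows sliding in 10-kb steps, and on explicit exon intervals where
supplied; features with fewer than 2 SNPs are reported but excluded from
percentile ranking. Windows whose pairwise FST is undefined (no variation)
get `T = 0` rather than an error, since no variation means no measurable
frequency change. Outlier calls take the k-th largest statistic with
`k = floor(n (1 - p/100))`, including all ties at the threshold, so the
call at the 99.9th percentile of 10,000 features returns exactly the top
10 plus ties.

Enrichment of high-FST SNPs works on a category-by-FST-bin table
(category precedence exon > intron > flank > intergenic; a flank is 25 kb
on each side of a gene). Expected counts place the background's category
proportions in every bin — when the tested set *is* the background this
reduces to the classical test of independence, which is how the
chi-square statistic is cross-checked against `stats::chisq.test` in the
test suite. Pearson residuals `(O - E)/sqrt(E)` are flagged two-sided at
`alpha / (cells tested)` (Bonferroni); cells with expected count below 1
are excluded as unreliable. Default bin width is 0.1 over [0, 1],
configurable. Gene-set enrichment is a one-sided Fisher exact test per
term via `stats::fisher.test`, Bonferroni-adjusted over terms; term
databases are user-supplied mappings.

### Admixture statistics

D is frequency-based: `ABBA = (1-p1) p2 p3 (1-p4)`,
`BABA = p1 (1-p2) p3 (1-p4)`, `D = sum(ABBA-BABA)/sum(ABBA+BABA)`. After
polarization the outgroup is the fixed ancestral state (`p4 = 0`); a
genotyped outgroup population can be named instead. f3(Target; A, B) is
the mean of `(c-a)(c-b) - c(1-c)/(n_c - 1)`, the second term being the
finite-sample correction for the target's allele-frequency variance.
Standard errors come from a delete-one jackknife over contiguous blocks of
1,000 SNPs by default; equal-size blocks make delete-one weights uniform,
which is why the weighted variant was not implemented. Quartet batches are
reported without multiple-testing correction, with an explicit note, since
the Z-scores are conventionally read against a fixed |Z| > 3 cutoff.

### X/autosome scaling

With a male-to-female mutation-rate ratio `alpha`, the neutral X rate is
`mu_X = mu_A 2(2+alpha)/(3(1+alpha))`. Inverting gives
`alpha = (4 - 3r)/(3r - 2)` for the observed ratio `r = mu_X/mu_A`, which
is only positive for `r` in the open interval (2/3, 4/3): an observed
ratio outside that band is reported as `"infeasible"` rather than as a
numeric alpha, which is precisely how an X rate far below two-thirds of
the autosomal rate is recognised as biologically unrealistic. Ne
trajectories are step functions evaluated right-continuously with no
interpolation — matching how stepwise demographic reconstructions are
drawn — and the NeX/NeA series reports its minimum, maximum and crossings
of 0.75, the neutral X/autosome expectation under an equal breeding sex
ratio.

## The synthetic cohorts

### Engine

The simulator is a structured coalescent authored in the package: each
chromosome is cut into blocks (default 10 kb) that recombine freely with
one another and not internally; one marginal genealogy is simulated per
block under piecewise-constant diploid sizes with splits and admixture
pulses as point events, and infinite-sites mutations are dropped on the
genealogy at `mu` per site per generation. Between demographic events all
coalescence rates are constant, so exponential waiting times are exact;
events at equal times fire pulses before splits so a pulse at a split
time still sees the pre-split deme occupancy. Expected nucleotide
diversity of a constant-size population is `4 Ne mu`, which the
calibration suite verifies to Monte-Carlo precision. Derived bases are
assigned with a transition:transversion ratio of 3.8 by default, and the
recorded ancestral state can be mislabeled at a configurable error rate
(default 0, so printed-arithmetic tests stay exact).

The block structure is the engine's main approximation: linkage is
complete within a block and absent between blocks, whereas real
chromosomes lie in between. Ten kilobases is conservative (blocks of
independent genealogy in a large recombining population are shorter), and
the admixture calibrations halve it to 5 kb to gain independent loci at
fixed sequence length. The compromises bought by this design are speed —
minutes on one CPU for every suite in the package — and exactness of the
neutral expectations.

### The five-ecotype scenario

`ecotype_scenario()` encodes the study conditions: five leaf populations
(RES, TRA, B1, B2, C) descending from one ancestor (Ne 15,000) through
sequential founder events — transient at 7,000 generations, resident and
the Antarctic ancestor at 5,500, type C at 1,800, B1/B2 at 600 — each
founder passing a brief bottleneck (Ne 400–600 for roughly 80 generations,
all below 1,000) before expanding, plus one directional pulse from the
resident lineage into the transient (fraction 0.10 at 1,000 generations).
The mutation rate is 2.34e-8 per site per generation and the generation
time 25.7 years. Split times in generations are not printed by the source
material, only their qualitative order (sequential bottlenecks, the
Antarctic clade youngest); the values above were chosen once so that the
resulting genome-wide pairwise FST spans roughly 0.1 for the youngest pair
to roughly 0.3 for the Pacific pair, the range the study system reports,
and were not revisited. Annotation tracks are a deterministic grid — one
13.8-kb gene of ten 300-bp exons every 150 kb, 25-kb flanks, third-codon
positions every third exonic base on the + strand — deliberately simple
so category assignment and frame arithmetic are exactly testable.

The default desk genome is 5 chromosomes of 2 Mb with 10 diploids per
population, scaled linearly by the `scale` argument.

### What the cohorts do not emulate

Read-level error, base qualities, genotype likelihoods and low-coverage
uncertainty are out of scope: statistics operate on genotype-derived
frequencies, which the simulator provides exactly. Real annotation
geometry, recombination-rate variation, linked selection and the real
cohort's allele frequencies are not reproduced. Passing calibrations
therefore demonstrate that the estimators recover truth under the stated
demographic structure with exact genotypes — not that they are robust to
genotyping noise, which the source analyses handled with
genotype-likelihood machinery that this package intentionally leaves out.

### Sweep spiking

`spike_sweep()` displaces derived-allele frequencies inside a region
toward fixation, `p' = p + shift (1 - p)`, realised on genotypes by
raising the derived count to `round(p' n)` in a fixed individual order —
deterministic by design, so spiked datasets stay bit-reproducible under
a fixed simulation seed.

## Calibration fixtures and problem sizes

The package pins its stochastic claims to five seeded suites (20
replicates each), sized to give clear power while keeping every suite in
the minutes range:

* Neutral diversity: one population, Ne 10,000, mu 1e-8, 1 Mb, 10
  diploids; mean diversity within 2 standard errors of 4e-4.
* D-statistic null and pulse: `admixture_power_model()` — sisters P1/P2
  (split 1,000 generations), source P3 (split 4,000, long-term Ne 2,000,
  so its branch accrues strong private drift), 3 Mb in 5-kb blocks, 8
  diploids per population, jackknife blocks of 500 SNPs. Null gives
  |Z| < 3 and a 10% pulse gives Z > 3, each in at least 18 of 20
  replicates. The fixture exists because a subtle pulse between
  large, recently split populations is *not* reliably significant at desk
  scales — the five-ecotype scenario's own pulse is checked as a
  direction (sign) effect instead.
* f3: the same fixture at a 30% pulse gives Z < -3.
* Sweep detection: the five-ecotype scenario at half scale, a 0.5
  displacement over 50 kb in B1; the swept window must top the 99.9th
  percentile of the genome-wide PBS distribution.
* Clock recovery: `split_pair_model()` — two populations of Ne 100
  separated 20,000 generations ago, 1 Mb, one diploid each. The count of
  derived alleles private to the focal individual divided by `mu L`
  estimates the private branch length, whose expectation is the split
  time plus two small coalescent offsets (2 Ne within the focal
  population and 2 Ne in the ancestor, 400 generations total here); the
  recovered mean must sit within the 2-standard-error Monte-Carlo band of
  that expectation.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere at the interface;
  conversion to the 1-based closed convention happens once, at the
  GRanges/VCF boundary.
* `FST = 1` produces an infinite branch length with a warning in
  `branch_length_T`; inside `pbs_scan` window FST is capped just below 1
  so a fully fixed window yields a large finite branch instead of
  propagating infinities into percentile ranks.
* Ties: outlier and top-SNP calls include all values tied with the
  threshold, so reported sets can exceed their nominal size; an all-equal
  input returns everything.
* Zero denominators are explicit: window FST with no variation is NA and
  flagged; D with no informative sites and Ts/Tv with zero transversions
  raise errors rather than returning NaN.
* Determinism: identical (model, layout, samples, seed) give bit-identical
  datasets; the pipeline serialises its config, stamps every table with
  the config hash and seed, and reruns byte-identically.

## Known limitations

* No recombination within blocks; linkage disequilibrium decay within a
  window is not modelled.
* The coalescent is neutral; `spike_sweep` imitates only the local
  frequency displacement of a completed or partial sweep, not its
  haplotype structure.
* Genotype uncertainty is absent (see above), so thresholds tuned here
  may be anticonservative on low-coverage data.
* `invert_alpha` treats the scaling formula as exact; it propagates no
  uncertainty in the observed rate ratio.
* The pipeline's input-directory mode re-analyses a written cohort but
  cannot re-simulate from it; truth tables (the demographic model, sweep
  regions) do not round-trip through VCF.
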