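---
title: "Detecting genomic islands of differentiation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic islands of differentiation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`islandscan` detects genomic islands of differentiation between recently
diverged ecotypes — contiguous genomic regions carrying an accumulation of
unusually differentiated SNPs — from multi-population SNP genotype data, and
asks whether those islands show *parallel* differentiation across replicate
habitat contrasts (e.g. two independent lake–stream population pairs). This
vignette explains the statistical machinery, the choices it embodies, and the
limits of what the bundled synthetic data can demonstrate.

## The analysis at a glance

1. **Ingest and filter.** Genotypes from a multi-sample VCF are filtered at
   the genotype level (GQ < 30 or DP < 10 set to missing), the site level
   (QUAL < 30, more than 50% missing genotypes in any population,
   multi-allelic sites, indels and SNPs within 10 bp of an indel, the sex
   chromosome XIX), and for homozygote excess (an exact one-sided
   Hardy–Weinberg test within any population at p < 0.01), which removes
   sites affected by PCR-duplicate artifacts of single-end RAD sequencing.
   A "random-allele" dataset (one gene copy drawn per genotype) is kept for
   analyses that cannot model inbreeding, such as nucleotide diversity.
2. **F-statistics.** Locus-by-locus genotypic AMOVA with an among-individual
   level, so Hardy–Weinberg equilibrium within populations is *not* assumed:
   homozygote excess loads on F_IS, not on F_ST.
3. **Outlier null.** A structured-coalescent simulation of a finite
   hierarchical island model, calibrated by bisection so its among-group and
   within-group differentiation match the observed values, yields the joint
   neutral distribution of (H_BP, F_ST). Each SNP gets a
   heterozygosity-conditioned upper-tail p-value and a signed z-score.
4. **HMM segmentation.** A three-state Gaussian hidden Markov model on the
   genome-ordered z-scores (exceptionally low / background / exceptionally
   high differentiation) is fitted by Baum–Welch; islands are maximal runs
   of SNPs decoded "high", retained under a region-level false discovery
   rate of 0.001.
5. **Classification.** A SNP shows parallel differentiation when the same
   allele is at strictly higher frequency in the same habitat in both
   lake–stream contrasts and its pairwise F_ST is permutation-significant in
   both. Islands with at least one such SNP are islands of parallel
   differentiation (IPD); the rest are non-parallel (IND).
6. **Context.** Ripley's K on the genetic map tests whether outlier SNPs
   cluster beyond what recombination-rate variation explains; smoothing
   splines of the genetic map give local recombination rates;
   RAD-locus-aware windows give per-population nucleotide diversity
   contrasts; and a genome permutation test asks whether IPDs co-localize
   with QTL confidence intervals per trait.

## F-statistics with inbreeding

For each SNP, gene copies are decomposed in a nested analysis of variance:
among groups, among populations within groups, among individuals within
populations, and within individuals. Because every individual contributes
exactly two gene copies, the among-individual coefficient is exactly 2; the
unbalanced population and group coefficients follow the standard nested-ANOVA
formulas on gene-copy counts. F_ST (total) is the among-population share
(among-group plus among-population components) of the total variance; F_IS is
the correlation of gene copies within individuals within populations. PCR
duplicates mimic inbreeding, and with the individual level in the model they
inflate F_IS while leaving F_ST unbiased — the property the estimator is
chosen for.

Multi-locus summaries are ratios of summed variance components (not means of
per-locus ratios); negative per-locus components are retained in the sums.
Loci with fewer than two non-missing genotypes in a population are skipped.
Degenerate hierarchies are handled explicitly: a single group, or one
population per group, collapses to the corresponding lower-level analysis.

H_BP, the conditioning axis of the outlier test, is the expected
heterozygosity `2*p*(1-p)` of the unweighted mean of per-population allele
frequencies. Any fixed convention works here as long as observed data and
null simulation use the same one — both call the same code path.

## The hierarchical island model null

The null simulator is a structured coalescent on a finite hierarchical island
model: `n_groups = 10` groups of `demes_per_group = 100` demes (deliberately
exceeding the real but unknown numbers), migration at scaled rate
`4Nm_within` between demes of one group and `4Nm_among` between groups, one
infinite-sites mutation placed uniformly on the simulated genealogy, and
diploid genotypes formed with each individual's second gene copy identical by
descent with probability F_IS (per sampled deme). Sampled demes mirror the
observed design; each replicate yields one SNP whose (H_BP, F_ST) is computed
with the *same* AMOVA estimator as the data.

Two implementation points deserve note:

* **Exchangeability lumping.** A naive event-by-event simulation spends
  almost all its time on migrations that move a lineage, alone in its deme
  (or group), to an empty deme (or group). Such moves leave the co-occupancy
  pattern unchanged: they are self-loops of the lumped Markov chain on
  occupancy patterns, and removing self-loops changes neither the embedded
  jump chain nor the holding times. The production engine therefore skips
  them exactly, making 10 x 100 demes tractable; a naive engine is retained
  and the test suite verifies distributional agreement between the two
  (two-sample Kolmogorov–Smirnov on F_ST and H_BP).
* **Migration calibration.** `calibrate_migration()` matches the simulated
  mean among-group (F_CT) and within-group (F_SC) differentiation to the
  observed values by alternating log-scale bisections with bracket
  shrinking, followed by a low-noise polish; the final check compares the
  achieved values to the targets within a relative tolerance of 10% (with an
  absolute floor of 0.004 and the Monte-Carlo block standard error of the
  final evaluation added, since targets near zero cannot be matched more
  precisely than the evaluation noise). Rates above 150 (4Nm) are treated as
  the high-migration boundary where differentiation is indistinguishable
  from zero.

### Conditional p-values at a discrete null

The null table is binned into 20 equal-count heterozygosity bins (merged to
at least 500 replicates each), and each SNP's p-value is the upper-tail rank
of its F_ST among the null F_ST values of its bin. Two subtleties matter for
calibration, and both were measured on matched-model self-simulations:

* **SNP class.** The scan operates on SNPs with minor allele frequency above
  1%, and the null table is restricted to the same class. Below that
  frequency the conditional F_ST distribution given heterozygosity is nearly
  degenerate, so such SNPs are uninformative for outlier detection (they are
  also the class removed before HMM segmentation, where they would disrupt
  the detection of high-differentiation states).
* **Ties.** A finite-sample coalescent null is discrete: low-frequency
  configurations concentrate large F_ST atoms, and a plain exceedance rank
  (count ties as exceedances) is strongly conservative — in the lowest
  heterozygosity bins the nominal 5% level rejects at well under 1%. The
  p-value therefore breaks observed–null ties uniformly at random,
  p = (#\{null > obs\} + U(1 + #\{null = obs\}))/(n_bin + 1), which is
  exactly uniform for test SNPs exchangeable with the null whatever the atom
  structure. A deterministic mid-rank option (`ties = "midrank"`) is
  available when reproducibility without an RNG state is preferred over
  exact calibration.

The z-score is `qnorm(1 - p)`: strongly differentiated SNPs map to large
positive z, unusually undifferentiated SNPs to large negative z, and the
two-sided information is carried by the sign rather than by two separate
tests.

## HMM segmentation and island calling

The three states emit z under state-specific normal distributions. Parameters
are estimated by Baum–Welch on the concatenated SNP dataset, with
chromosomes as independent chains sharing one parameter set — estimation
borrows strength genome-wide while no state run can cross a chromosome
boundary. Numerical choices: emission means initialized at the 0.1/0.5/0.9 z
quantiles, standard deviations at the sample standard deviation, sticky
transitions (0.99 self-transition), 10 restarts with jittered means keeping
the best likelihood, convergence when the log-likelihood changes by less
than 1e-6 (at most 500 iterations), state identifiability enforced by
sorting states on their emission means after every M-step, and emission
standard deviations floored at 0.05 (with a warning) to prevent collapse
onto single points.

Two further identification rules keep the state labels meaningful on weak
data. First, the initial distribution is tied to the stationary distribution
of the transition matrix at every M-step: with chromosomes as separate
chains there are only ~20 first positions, far too few to estimate a free
initial law, and a free estimate can drift to placing its mass on an extreme
state — turning every chromosome's first SNP into a confidently decoded
singleton. Second, the "background" label must belong to the dominant state
of the chain: mean ordering alone cannot identify the labels, and on
signal-poor data the maximum-likelihood fit occasionally models the bulk of
the z distribution with the top-mean state (which would decode the whole
genome as "high"). Restarts whose stationary distribution is dominated by
the middle state are therefore preferred, and if no restart satisfies this,
the best fit is relabelled so the dominant state sits in the background
position.

Decoding is posterior (forward–backward): the reported state is the per-SNP
maximum-posterior state, the SNP-wise notion of "most likely state". Viterbi
decoding is available as an option for path-wise questions.

Candidate islands are maximal runs of consecutive "high" SNPs. Each
candidate's local false discovery rate is the mean posterior probability of
*not* being high over its member SNPs; candidates are ranked by local FDR
and accepted while the running mean over accepted candidates stays at or
below 0.001. The same procedure applied to the "low" state reports regions
of exceptionally low differentiation separately. On pure-noise input the EM
may still split the single Gaussian across states — an ordinary
mixture-likelihood gain — but no SNP then reaches the posterior confidence
an island call requires; the neutral-specificity property is enforced at the
island level, not at the level of posterior state shares.

Island extents are reported from the first to the last member SNP; no
flanking half-distances are added, so sizes are conservative where SNP
sampling is sparse.

## Parallel differentiation

The per-SNP condition is deliberately strict: (a) the same allele at
strictly higher frequency in the same habitat in both contrasts — an exact
frequency tie fails — and (b) pairwise F_ST permutation-significant in both
contrasts at alpha 0.05 (configurable; the per-SNP permutation draws the
focal population's genotype counts from the pooled counts, the counts-level
equivalent of shuffling individuals). One parallel SNP suffices to label an
island IPD, because a single habitat-associated allele frequency shift
replicated across independent contrasts is already unlikely under drift —
and per-island counts of significant SNPs in each contrast are reported so
stricter definitions can be applied downstream.

## Genomic context

**Ripley's K.** K(t) = (L/n^2) x #\{ordered pairs within genetic distance
t\}, evaluated on 50 distances from 0 to half the chromosome's genetic
length, with no edge correction — observed and null curves are computed
identically, so the comparison is internally consistent. The null resamples
n positions *from the chromosome's own SNP positions* (without replacement),
which controls both for recombination-rate variation (distances are genetic)
and for the non-random placement of RAD loci. Because the decision
"observed K above the envelope at any t" aggregates ~50 strongly correlated
comparisons, pointwise envelopes would over-reject badly; the clustering
decision is instead a global worst-rank Monte-Carlo test (with uniform
randomized tie-breaking, since K takes few distinct values at small outlier
counts), and the reported 95%/99% envelopes are simultaneous order-statistic
envelopes at the matching family-wise level. Chromosomes with two or fewer
outliers are skipped; a chromosome whose outlier set is the whole SNP set is
vacuous and reported unclustered.

**Recombination rates.** cM positions are linearly interpolated between map
markers (positions beyond the terminal marker are clamped, with a warning).
Local rates are the first derivative of a smoothing spline
(`stats::smooth.spline`, `spar = 0.7` — note `spar` is R's smoothness
parameter on [0, 1], the convention this package commits to), clamped at
zero and reported in cM/Mb. The spline trades bias for variance: around a
sharp change in slope the fitted rate overshoots for 1-3 Mb unless the map
is marker-dense; the synthetic two-slope check uses a 10 kb marker table,
where recovery is within 10% beyond 1 Mb of the break. Chromosomes with
fewer than four markers fall back to piecewise-linear slopes.

**Diversity windows.** Windows accumulate whole RAD loci until they hold at
least 2,500 sequenced sites, so windows have near-constant information
content and loci are never split. Per-site diversity in a population is
`n/(n-1) * 2p(1-p)` from the random-allele dataset (one copy per
individual), which sidesteps the genotype-level homozygote-excess bias;
window pi averages over all sequenced sites, monomorphic sites contributing
zero. Windows are labelled background/IND/IPD by island overlap (IPD takes
precedence) and compared per population by Welch t-tests with Bonferroni
adjustment over the three comparisons.

**QTL overlap.** Islands of parallel differentiation are extended by ±10 kb
(compensating sparse RAD sampling of island edges) and intersected with
per-trait QTL confidence intervals. The permutation test re-places all
islands uniformly at random (lengths preserved, chromosome ends respected,
placed islands free to overlap each other) 100,000 times and reports
per-trait empirical p-values, Bonferroni-corrected over traits. Both the
physical and the genetic coordinate system should be run: recombination-rate
variation inflates confidence intervals on the physical map, and agreement
between the two coordinate systems is itself informative. Island placement
is independent per island; a spacing-preserving variant was considered and
rejected as the default because independent placement is the least
structured null consistent with "random positions".

## The synthetic-data generator

`simulate_dataset()` emulates the sampling design the analysis targets: six
demes (10–21 diploids each; 91 in total) in three hierarchical groups — two
stream-resident demes forming their own groups and four lake-like demes
(two lake shores plus two downstream sites dominated by migratory lake fish)
in one group. Defaults: ~10^4 SNPs on 20 autosomes of 20 Mb (the sex
chromosome XIX is excluded throughout), background differentiation 0.03
split evenly between the two Balding–Nichols levels (ancestral to group,
group to deme, so that the total per-deme coefficient is
1-(1-f)^2 = 0.03), homozygote excess F_IS = 0.25 in three demes and 0.05 in
the rest (mimicking the uneven PCR-duplicate load of different library
preparations), and a piecewise-constant recombination profile integrated
into a marker table every 200 kb.

Planted islands receive habitat-associated frequency shifts of configurable
magnitude (default demos use 0.7–0.8): for parallel islands the shift
direction is shared by all stream-habitat demes; for non-parallel islands
one randomly chosen stream group is shifted alone, so differentiation
appears in a single lake–stream contrast only. Inbreeding is modelled as
identical-by-descent copying of one gene copy with probability F_IS — the
same construction as in the null simulator; note this reduces the expected
number of independent gene copies to 2n(1-f/2), and halves heterozygosity,
but it is *not* literally equivalent to an outbred sample of n(1-f)
diploids: genotype configurations remain those of partially inbred
individuals, and only the moments of downstream summaries match an
effective-copy-number reduction.

What the generator does **not** emulate: linkage disequilibrium decay within
the background (background SNPs are exchangeable given their deme
frequencies), sequencing depth heterogeneity and genotype-quality structure
(filters are exercised on constructed fixtures instead), allele-frequency
ascertainment of real RAD data, and selection acting during sampling.
Passing tests on synthetic data therefore demonstrate the statistical
machinery under the stated model, not robustness to every artifact of real
RAD datasets.

## Problem sizes and reproducibility

The test suite and the acceptance script run at sizes chosen to exercise
each claim meaningfully on one CPU: the outlier-calibration check uses a
50,000-replicate null table and 20,000 matched test SNPs at the full
10 x 100 metapopulation; HMM recovery uses 10 planted 15-SNP islands at
z-shift +5 among 10^4 background SNPs, and neutral specificity 100 noise
replicates of the same size; the end-to-end demo runs ~5,000 SNPs with ten
planted islands. A single global seed fans out to per-stage seeds through a
fixed derivation, so reruns are bit-identical and any stage can be
reproduced in isolation.

## Known limitations

* The null model assumes equal deme sizes and symmetric migration within
  levels; calibration matches two moments (F_CT, F_SC) and does not attempt
  to match the full site-frequency spectrum.
* Region-level FDR control interprets the posterior state probabilities
  literally; model misspecification of the emission distributions (e.g.
  heavy-tailed z) propagates into the local FDR.
* Island extents are SNP-delimited and depend on marker density; sparse
  regions yield conservative sizes.
* The parallel/non-parallel classification is binary per island and driven
  by the configured contrasts; gradients of parallelism across more than two
  contrasts are out of scope.
* p-values and the Ripley clustering decision use randomized tie-breaking;
  under a fixed seed results are reproducible, but two analyses with
  different RNG states can disagree on knife-edge cases (deterministic
  mid-rank alternatives are provided).
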