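---
title: "Methods: admixture analysis and scenario testing for a two-species hybrid zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture analysis and scenario testing for a two-species hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`canidmix` analyses hybrid zones between two divergent canid
populations — the motivating system is the reintroduced red wolf
population and the surrounding coyote population of eastern North
Carolina — from noninvasively collected material (scat), genotyped at a
panel of polymorphic microsatellite loci (17 in the motivating survey).
Noninvasive samples are low quality, so every stage of the pipeline has
to manage genotyping error explicitly; and the survey has no a priori
individual identities, so scats must be deduplicated into individuals
before any population-level inference.

The pipeline runs, end to end:

1. **Consensus genotyping** from replicate PCRs (`call_consensus()`).
2. **Individual identification**: matching against reference animals and
   transitive regrouping of scats (`match_genotypes()`,
   `regroup_individuals()`), with the panel's discriminatory power
   quantified by probability-of-identity statistics (`compute_pid()`).
3. **Population-genetic summaries** per zone and region:
   Hardy–Weinberg exact tests, heterozygosities, Weir–Cockerham
   F-statistics, allelic richness, and the Wahlund-effect regression of
   per-locus F~IS~ on F~ST~ (`popgen_summary()` and friends).
4. **Admixture estimation** with a two-cluster Bayesian model
   (`fit_admixture()`), replicate-run alignment (`align_runs()`),
   Evanno ΔK model choice (`evanno_deltaK()`) and anchoring of the
   anonymous clusters to species via known individuals
   (`anchor_clusters()`).
5. **Scenario testing**: solving how many wolves, coyotes and hybrids a
   hypothesised hybridization regime implies for the observed mean
   ancestry (`solve_composition()`), simulating those genotypes
   (`build_scenario_dataset()`), and comparing the scenario's ancestry
   distribution with the observed one by Kolmogorov–Smirnov distance
   and logistic steepness (`run_scenario_comparison()`).

A synthetic-data module (`generate_landscape()` and collaborators)
generates every input the pipeline needs, with the statistical
structure the study design assumes, so the whole chain is testable
without any field data.

# The admixture model

`fit_admixture()` implements the standard admixture mixture model for
unlinked codominant markers. Each of the two allele copies individual
*i* carries at locus *l* originates from cluster *k* with probability
*q~ik~*; conditional on its origin the copy is a draw from that
cluster's allele frequencies *P~kl·~*. The sampler is a Gibbs scheme
over

* **Z** — the latent cluster origin of every allele copy
  (categorical, proportional to *q~ik~ P~kla~*);
* **q** — individual admixture proportions, Dirichlet-conjugate given
  Z with a symmetric Dirichlet(α) prior;
* **P** — cluster allele frequencies, Dirichlet-conjugate given Z;
* **α** — updated by a Metropolis step on log α (step 0.1) under a
  uniform prior on (0, 10), so the degree of admixture in the sample is
  learned rather than assumed;
* under the **correlated-frequencies prior** (the default, appropriate
  for recently diverged populations) *P~kl·~* drifts around a shared
  ancestral vector *P~Al·~* with per-cluster drift *F~k~*:
  *P~kl·~* ~ Dirichlet(*P~Al·~*(1−*F~k~*)/*F~k~*). *P~A~* is updated by
  a pairwise mass-transfer Metropolis step (normal, step 0.05) and
  *F~k~* by a reflected random walk (step 0.05) with a uniform prior on
  (10^−4^, 0.999). The uncorrelated alternative uses independent
  Dirichlet(λ = 1) priors and is convenient for fast exploratory runs.

Missing loci contribute nothing to the likelihood. Point estimates are
posterior means of thinned post-burn-in samples (default: keep every
10th sweep), with equal-tailed 90% credibility intervals. The model
log-probability reported for ΔK bookkeeping is
mean(log L) − var(log L)/2 over the retained samples, matching the
estimator conventionally used for this model so that ΔK tables are
comparable with the field's practice. The sampler is written in C++
(via Rcpp) because chain lengths of 10^5^–10^6^ sweeps over tens of
thousands of allele copies are the norm for this model class.

Replicate runs differ only by seed. `align_runs()` resolves
label switching by exhaustively permuting cluster labels (K! options)
to maximise inner-product similarity with the running mean of aligned
runs, then composites by averaging — the behaviour of the standard
cluster-matching tools at small K. `anchor_clusters()` orients the
composite so that cluster 1 is the cluster with the highest mean *q*
among known individuals of the focal species; two species claiming the
same cluster is an error listing the offending individuals.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 2 | number of clusters |
| `model` | `"correlated"` | frequency prior (see above) |
| `burnin`, `reps` | 5 000, 50 000 | sweeps discarded / retained-from |
| `thin` | 10 | keep every thin-th sweep |
| `lambda` | 1 | Dirichlet parameter of the frequency prior |
| `alpha`, `alpha_max` | 1, 10 | initial admixture hyperparameter and its prior bound |
| `ci` | 0.90 | credibility-interval mass |

The defaults are desk-scale: on ~300 individuals × 17 loci a run takes
well under a minute. The field-standard settings for a publication-grade
analysis (burn-in 10^5^, 10^6^ reps, K from 1 to 10, five to ten runs
per K) are reached by changing `burnin`/`reps` only; on the synthetic
fixtures the desk-scale composite agrees with longer chains to well
within the credibility intervals, which is why the tests use the
smaller sizes.

# Consensus, matching and identification power

A heterozygous genotype is accepted only when each of exactly two
alleles is seen in at least two independent PCRs; a homozygote only
when a single allele is seen alone in at least three. Samples with
fewer than 6 accepted loci are excluded. These are the replication
rules used for noninvasive canid genotyping; they make single-PCR
dropout or false alleles unable to fix a wrong genotype. A locus where
more than two alleles gain replicate support is set missing and
flagged — the field protocols do not define this case, and discarding
is the conservative choice.

Matching uses exact identity on shared loci by default
(`max_mismatch = 0`, `min_overlap = 6`): the replication rules already
suppress genotyping error, and the identity power of the panel is
verified separately via PID. Per locus,
PID = Σp~i~^4^ + ΣΣ~i<j~(2p~i~p~j~)^2^ and
PID~sibs~ = 0.25 + 0.5Σp~i~^2^ + 0.5(Σp~i~^2^)^2^ − 0.25Σp~i~^4^;
multilocus values multiply across loci. Regrouping closes the pairwise
match relation transitively; inconsistent groups (A~B, B~C, A≁C) are
still merged but flagged, mirroring conservative practice. An
individual's coordinate is the mean of its samples' coordinates and its
zone is looked up from that centroid, so animals detected in several
zones are counted once.

# Population-genetic summaries

The Hardy–Weinberg test is the conditional exact test: Monte Carlo
tables are generated by re-pairing the observed allele pool (1000
replicates by default) and the p-value is the share of tables — the
observed one included — whose Levene conditional probability does not
exceed the observed table's. F-statistics are the Weir–Cockerham (1984)
variance-components estimators, summed over alleles and loci for
multilocus values. Heterozygosity uses Nei's unbiased correction
2n/(2n−1). Allelic richness follows the bootstrap-to-smallest-group
convention (resampling with replacement, 1000 resamples) rather than
rarefaction, because that is what the motivating survey's text
describes; rarefaction could be added but is deliberately not the
default. The F~IS~ interval is a bias-corrected percentile bootstrap
over loci; a global Hardy–Weinberg p-value combines per-locus tests by
Fisher's method (the combination rule is a package choice — the
motivating survey reports a single global P without naming one).

The Wahlund regression is the diagnostic for pooled structure: when two
differentiated populations are analysed as one sample, per-locus F~IS~
and F~ST~ become positively correlated, and the package reports the
Pearson correlation with its t-test alongside the OLS slope and
intercept.

# Hybrid-class simulation and scenario testing

`simulate_class()` is gamete-based with unlinked loci and no mutation:
a parental gamete draws one allele per locus from that pool's
frequencies; an F1 gamete picks its origin pool per locus with
probability ½; F2 = two F1 gametes; backcrosses = one F1 gamete plus
one parental gamete. Gametes come from pool frequencies, not resampled
individuals — the documented behaviour of the standard hybrid-genotype
simulator this module mirrors. The six classes carry expected focal
ancestries {1, 0, 0.5, 0.5, 0.75, 0.25}.

`solve_composition()` inverts the ancestry balance
q̄·T = h·H + R (h = 0.5 for hybrids) for the core region, with the
scenario supplying the hybrid proportion H/T. Peripheral regions are
assumed to hold no focal-species individuals while hybridization is
occurring, so their small observed ancestry is attributed to hybrids
(H = q̄·T/h); in the no-interbreeding scenario it is attributed to
focal-species individuals instead. All rounding is half-up, and the
hybrid total is split as evenly as possible over the four classes with
any remainder going to F1, BC×wolf, BC×coyote, then F2 — this
deterministic convention reproduces the published table exactly,
including its one uneven split. One published row's coyote total
disagrees with its own balance equation by one individual; the solver
follows the equation.

Distribution comparison is a two-sample Kolmogorov–Smirnov statistic
evaluated at every pooled data point (so ties are exact), with the
asymptotic p-value. The steepness summary fits
y = a/(1 + e^(−c(x−b))) to the ancestry values sorted ascending
against their 1-based rank, by Levenberg–Marquardt least squares with
quartile-based starting values; rank (not the ancestry value) is the
abscissa because the published midpoints (~226–233 of 311) identify it.
A steep c means a bimodal, parentals-only distribution; abundant
hybrids flatten the transition.

# The synthetic-data generator

`generate_parental_frequencies()` draws an ancestral frequency vector
per locus from a flat Dirichlet and perturbs it per pool with a
Dirichlet of concentration (1−d)/d (a Balding–Nichols construction),
so one interpretable knob d maps monotonically onto expected F~ST~;
d = 0 gives identical pools and d = 1 alternately fixed alleles. The
default panel is 17 loci × 5 alleles. The default landscape
(`default_zone_counts()`) emulates the motivating survey: 75 wolves,
224 coyotes and 12 hybrids (three per class) over six zones listed east
to west, parental classes forming an east–west gradient, with zones as
consecutive unit intervals on one axis — the analyses only use zone
order, not real geography. The replicate-PCR observation model applies,
per PCR, whole-locus failure, independent allelic dropout of each
heterozygote allele, and a uniform false allele from the locus
registry; its default rates (failure 0.1, dropout 0.1, false allele
0.02, 4 replicates) are in the range reported for canid scat work —
the motivating survey does not print its rates, so these are
configurable, not calibrated.

What the generator does **not** emulate: spatially explicit dispersal
or territoriality, linkage, null alleles, allele-size homoplasy,
mitochondrial markers, or uneven per-zone detection effort. Tests that
pass on this generator therefore certify the estimators and the
pipeline plumbing under the study's idealised statistical assumptions,
not robustness to those real-data complications.

# Numerical choices and degenerate inputs

* Cluster frequencies are floored at 10^−9^ after each draw so that
  log-densities in the Metropolis steps stay finite.
* Monomorphic loci: HWE returns p = 1 with a warning; F-statistic
  components are zero; a locus with no typed copies is dropped from
  frequency estimation with a warning.
* A zone with fewer than two individuals is excluded from the ANOVA
  (warning); if fewer than two zones remain, means are reported without
  a test. Constant ancestry across zones yields an undefined F and a
  single letter group.
* LSD letters come from a greedy sweep of maximal pairwise
  non-significant runs over the descending means.
* The hybrid-count χ² is reported with both the asymptotic df = k−1
  p-value and a Monte Carlo p-value (10 000 multinomial draws by
  default), because published χ² values for small hybrid counts are
  not always consistent with the asymptotic reference.
* The logistic fit reports a convergence flag and best-so-far
  parameters instead of failing; fewer than four values is an error.
* All simulation functions take integer seeds and are exactly
  reproducible; the admixture sampler consumes R's RNG stream, so
  `set.seed()` governs it too.

# Known limitations

* With 17 microsatellite loci at moderate divergence the posterior mean
  ancestry of a *pure* individual sits near 0.95, not 1 — an exact
  single-individual posterior computed with known cluster frequencies
  shows the same ~0.05 shortfall, so this is the information content of
  the panel, not a sampler artefact. Likewise F2 and backcross
  individuals' realised genome ancestry genuinely scatters around the
  class expectation (sd ≈ 0.06–0.09 at 17 unlinked loci). Composite
  ancestry estimates on class-structured fixtures therefore show a mean
  absolute error around 0.07–0.08 against idealised class ancestries;
  materially tighter recovery requires more loci, more alleles per
  locus, or stronger divergence.
* ΔK cannot evaluate K = 1 (it needs an interior point); the standard
  caveat that ΔK favours K = 2 in hierarchical data applies.
* The exhaustive alignment is factorial in K and capped at K ≤ 8;
  large-K composites would need a greedy matcher.
* The scenario solver treats the hybrid mean ancestry as exactly 0.5;
  backcross-heavy hybrid pools would need the class mix made explicit.
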