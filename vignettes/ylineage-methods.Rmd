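---
title: "Methods: Y-STR lineage analysis with ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-STR lineage analysis with ylineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

`ylineage` analyses 17-locus Yfiler Y-chromosome STR haplotype sets of the
kind produced in forensic and population-genetic surveys: per-sample repeat
counts at 15 single-copy loci plus the duplicated DYS385 system, annotated
with population, department and haplogroup labels. This vignette explains
each method, its assumptions, the tunable parameters, and the design choices
made where the methodology is genuinely open. The package's reference
scenario is a survey of 83 male chromosomes from two adjacent Colombian
departments (Tolima and Huila) carrying 16 haplogroups, including a rare
Native American lineage cluster fixed for DYS391 allele 6; a synthetic
generator reproduces that scenario so every stage can be exercised without
access to restricted databases.

## Data model and normalization

A `sample_set` couples a `locus_panel` (locus names, mutation rates, network
weights, multi-copy flags) with an allele matrix. Two conventions matter:

* **DYS385 is an unordered pair.** Standard typing cannot assign the two
  amplified copies to their sites, so the state is stored as a sorted pair;
  `11-14` and `14-11` are the same genotype. For descriptive allele counts
  the two sorted copies count as two loci (the usual "17 loci" convention),
  while haplotype identity compares the pair as a unit.
* **DYS389II is stored as the full repeat count.** The nested structure is
  only resolved by `normalize_for_network()`, which replaces DYS389II with
  `DYS389II - DYS389I` (renamed `DYS389II-I`) and drops DYS385, leaving the
  15 independent single-copy loci required by network construction and
  dating. A full count smaller than DYS389I is physically impossible and
  rejected. The operation is idempotent.

Missing calls are recorded as missing (never zero) and excluded pairwise
from distances without rescaling; samples missing more than two loci are
rejected by default (`max_missing`), since the targeted data sets are
complete profiles. Intermediate (fractional) alleles such as 17.2 are legal
states; the mutational step count between states is `|a - b|` rounded
half-up, with any non-zero non-integral offset counting as one step. The
one-step reading of intermediate offsets is a deliberately conservative
convention — partial-repeat variants arise from single indel events — and is
confined to `step_count()`.

## Diversity statistics

Haplotype diversity uses the Nei unbiased estimator
$HD = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, algebraically identical to
the probability that two chromosomes drawn without replacement differ (the
test suite proves this identity against a brute-force pairwise count).
`diversity_table()` reports, per group, the distinct-haplotype count, the
number of polymorphic loci, the mean number of alleles per locus with its
sample (n − 1) standard deviation, and `HD` — the latter only for groups of
at least five chromosomes, the usual reporting convention for small clades.
Percentages in `lineage_frequencies()` are exact; any rounding (the source
tables for the reference scenario truncate to two decimals) is left to the
caller.

## AMOVA

`amova_fst()` implements the one-level analysis of molecular variance used
to decide whether two sampling strata can be pooled. Pairwise distances
(locus mismatches by default, stepwise repeat differences by flag) are
treated as squared distances; total and within-group sums of squares scaled
by group sizes yield mean squares, variance components via the average
group-size coefficient $n_0$, and
$\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. The mismatch default
matches the haplotype-level $F_{ST}$-style statistic conventionally
reported; the stepwise metric gives the $R_{ST}$-like molecular analogue.
Significance comes from group-label permutation with the $(B+1)/(N+1)$
estimator (10 000 permutations by default) and a binomial standard error on
p. Slightly negative indices are reported as computed — they are the
expected behaviour of an unbiased estimator under panmixia. The estimator
is exactly valid but discrete: on small, weakly differentiated samples tied
permutation statistics make it mildly conservative, which is why the null
calibration test uses a well-differentiated haplotype pool where ties are
negligible.

## Median-joining networks

`build_mj_network()` constructs the weighted median-joining network under
the weighted stepwise distance $d(a,b) = \sum_l w_l\,|a_l - b_l|$.
Locus weights come from `assign_weights()`: inverse mutation rates mapped
affinely onto the conventional integer range [3, 10] (slowest locus 10,
fastest 3, half-up rounding, degenerate rate spans mapping to 10). The
published description of the reference analysis states the 3–10 weighting
scheme without printing per-locus values, so the affine inverse-rate map is
a documented package choice; the bundled per-locus rates are approximate
father–son estimates and serve only as weighting defaults.

Construction proceeds in three phases:

1. **Minimum spanning network.** All links whose cost equals the minimal
   connection cost between their endpoints (the minimax path weight over a
   spanning tree) are retained, keeping every tie.
2. **Median vectors.** Componentwise medians of node triplets are candidate
   latent haplotypes. Candidates are examined exhaustively over all
   triplets and accepted one at a time — the candidate giving the largest
   strict reduction of the minimum-spanning cost first, lexicographic order
   breaking ties — until no candidate improves the cost. Examining all
   triplets rather than only topologically adjacent ones is a superset of
   the classical search; with integer costs and strict improvement the loop
   terminates, the result is independent of input order (nodes are kept in
   canonical lexicographic order), and on small instances the output is a
   fixpoint of exhaustive Steiner-point search over the allele grid, which
   the tests verify directly.
3. **Pruning.** Median vectors with degree ≤ 1, or lying on no shortest
   path between observed nodes, are removed iteratively.

The tolerance `epsilon` (default 0, the customary default of network
software for this analysis) relaxes link retention: a link is kept when its
cost is within `epsilon` of the minimal connection cost. Tying `epsilon` to
link retention rather than to the median search keeps the node set
identical across tolerances, so an `epsilon = 0` network is always a
subgraph of the `epsilon = 1` network on the same input — a property the
tests check. An optional maximum-parsimony post-pruning (`mp_prune`)
restricts links to those occurring in at least one minimum spanning tree;
it is off by default because the reference analysis does not mention it.
Multi-step differences are drawn as one link labelled with the mutated loci
and step counts, not as chains of latent nodes.

## Rho-statistic dating

`tmrca_dating()` infers the founder haplotype as the per-locus mode
(smallest allele on ties), computes
$\rho = \frac{1}{n}\sum_i d(h_i, \text{ancestor})$ with unweighted stepwise
distances, the star-genealogy standard error
$\sigma_\rho = \sqrt{\sum_i d_i}/n$, and converts to calendar time as
$T = \rho \cdot g / (L\mu)$ with the effective rate
$\mu = 6.9\times10^{-4}$ mutations/locus/25 years and $g = 25$ years. The
generation time is embedded in the quoted rate and configurable. Distances
are taken directly to the ancestor (star assumption) rather than along
network branches: for near-star clusters the two coincide, and the direct
form needs no tree reconstruction. The clock is linear in $\rho$, strictly
increasing in $\rho$ and decreasing in $L$ and $\mu$. Note that a
standard-error printed in the reference publication for this quantity
("± 0,5345 years") is dimensionally inconsistent with its own $\rho$
scaling and is treated as a typographical artifact, not a target.

## Haplogroup prediction

`fit_frequency_model()` / `predict_haplogroup()` reproduce the structure of
the Bayesian Y-STR haplogroup predictors used for pre-SNP screening:
per-haplogroup, per-locus allele frequencies with additive smoothing
(`pseudocount` 0.5 by default — the published predictors' training corpora
and smoothing are unpublished, so only the Bayesian structure is
reproduced), uniform priors by default, and a naive product likelihood
evaluated in log space. Duplicated loci are excluded by default, mirroring
network practice; as pair-valued categorical features by flag. Alleles
never seen in training receive their smoothing mass, so posteriors stay
proper.

## Frequency PCA

`pca_populations()` ordinates population-by-haplogroup frequency matrices:
column-centered covariance PCA by default (the convention of the desktop
packages used for such figures), correlation mode by flag. Axes are ordered
by decreasing eigenvalue, variance fractions sum to one when total variance
is positive, and the sign convention (dominant loading positive per axis)
makes outputs backend-independent. A published two-axis figure for the
reference scenario reports 66.46% variance explained; reproducing that
number requires the original 32-population frequency table and identical
preprocessing, so it is treated as a soft reference, not a test target.

## Synthetic data: what it emulates and what it does not

The generators are first-class, tested code; their defaults are the
reference study's conditions.

* `simulate_star(n, age_years)` draws each lineage's mutation count from
  Poisson($L\mu T/g$), places mutations on rate-weighted loci and applies
  ±1 steps with a reflecting boundary at allele 1 (a −1 step at allele 1 is
  redrawn as +1; the boundary choice avoids impossible states and is
  otherwise inconsequential for realistic repeat counts). The default panel
  applies the single effective dating rate to every locus, the regime in
  which the rho clock's assumptions hold exactly; heterogeneous-rate panels
  are accepted for weight testing.
* `simulate_coalescent(n, Ne)` draws a Kingman genealogy (tree via
  `ape::rcoal`, rescaled so the two-sample TMRCA expectation is `Ne`
  generations) and drops mutations on branches as Poisson processes. Rho
  dating on coalescent data is scattered and unbiased only for star-like
  trees — the package's own calibration note, illustrated in the tests.
* `simulate_study_like()` reproduces the reference composition: 83
  chromosomes in 16 haplogroups (42/41 across two departments), founder
  haplotypes at least 5 steps apart, within-haplogroup stepwise variants
  limited to 2 steps, and the published number of distinct haplotypes per
  haplogroup with multiplicities assigned by the most-even partition. The
  most-even partition is not arbitrary: it reproduces every published
  per-clade diversity value (0.904(8), 0.997, 1.000) exactly, and fixes the
  overall sharing structure at 77 distinct haplotypes with six doubletons.
  One consequence worth recording: with that published sharing structure,
  the overall 17-locus Nei diversity is necessarily ≈ 0.998 — the value
  0.9680 printed alongside "77 of 83 unique" in the source is unattainable
  under the estimator's own definition (the minimum consistent with 77
  unique is ≈ 0.996), and the corresponding acceptance check documents this
  by failing. The Q1a2-M346*(xM3) cluster is fixed for DYS391 allele 6
  (the defining allele is held immutable within the cluster); department
  labels are assigned at random, giving the null AMOVA scenario.

The generators emulate haplotype structure, not demography: no migration,
admixture, population growth or locus-specific directional mutation. Tests
passing on synthetic data therefore validate the estimators' arithmetic and
calibration under their stated models, not robustness to real-data
violations of those models.

## Numerical choices and problem sizes

Deterministic tie-breaks are documented at each site: smallest allele for
modal ties, lexicographic node order in networks, sorted storage of
unordered pairs. All stochastic functions take a `seed` and restore the
ambient RNG state, so pipelines are byte-reproducible; the pipeline
manifest records seeds, parameters and an input digest. Monte-Carlo checks
in the test suite use 150–300 replicates of 16–25-chromosome samples and
200-replicate permutation calibrations with 199 permutations — sizes chosen
so each check's Monte-Carlo error is several times smaller than its
tolerance. Default analysis settings are larger (10 000 permutations for
AMOVA).

## Known limitations

* Hierarchical (multi-level) AMOVA and significance correction for
  many-population pairwise matrices are out of scope.
* Rho dating ignores mutation-rate heterogeneity and multi-hit cancellation
  (a few percent downward at ages of several thousand years under the
  stepwise model — visible in, and bounded by, the recovery tests).
* The haplogroup predictor reproduces the published method's structure, not
  its proprietary training data; its accuracy claims are therefore
  self-consistency claims.
* Median-joining networks are reconstructed under the package's documented
  tie-breaking; other implementations may emit cosmetically different but
  cost-equivalent median vectors.
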