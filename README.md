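# ylineage

Analysis of Y-chromosome short-tandem-repeat (Y-STR) haplotype surveys of
the kind used to characterize paternal lineages in admixed populations:
17-locus Yfiler profiles annotated with population, department and
haplogroup labels. The package is aimed at population and forensic
geneticists who need the full downstream chain behind such a survey —
haplotype table handling, diversity statistics, population differentiation,
haplotype networks, founder dating, haplogroup screening and ordination —
as reproducible, scriptable R functions.

## What it computes

* **Haplotype I/O and normalization** — YHRD-style tab-delimited tables
  with the duplicated DYS385 system stored as an unordered pair and the
  nested DYS389I/II counts resolved for phylogenetic work
  (`read_haplotype_table()`, `normalize_for_network()`).
* **Diversity** — Nei unbiased haplotype diversity
  `HD = n/(n−1) · (1 − Σ pᵢ²)`, per-haplogroup descriptive tables and
  lineage frequency tables (`nei_diversity()`, `diversity_table()`,
  `lineage_frequencies()`).
* **AMOVA** — one-level analysis of molecular variance with
  `Φ_ST = σ²_among / (σ²_among + σ²_within)` and a permutation test using
  the (B+1)/(N+1) estimator (`amova_fst()`).
* **Median-joining networks** — weighted stepwise distance
  `d(a,b) = Σ_l w_l |a_l − b_l|`, integer locus weights in [3, 10] from
  inverse mutation rates, minimum-spanning-network links, median (latent)
  vectors and pruning; GraphML/DOT/TSV export (`build_mj_network()`,
  `assign_weights()`, `export_network()`).
* **Founder dating** — modal ancestral haplotype, rho statistic
  `ρ = mean mutational steps to the ancestor` and the clock
  `T = ρ·25/(L·μ)` with `μ = 6.9×10⁻⁴`/locus/25 years
  (`tmrca_dating()`).
* **Haplogroup prediction** — naive-Bayes allele-frequency model with
  additive smoothing (`fit_frequency_model()`, `predict_haplogroup()`).
* **Ordination** — covariance/correlation PCA of population × haplogroup
  frequency matrices (`pca_populations()`).
* **Simulation** — star and Kingman-coalescent genealogies under the
  stepwise mutation model, and a study-like generator reproducing an
  83-sample, 16-haplogroup survey with a DYS391*6 Native lineage cluster
  (`simulate_star()`, `simulate_coalescent()`, `simulate_study_like()`).
* **Pipeline** — `run_pipeline()` chains the stages and writes
  TSV/JSON/GraphML artifacts plus a seed-recording manifest;
  `inst/cli/ylineage.R` is a thin command-line front end.

## Worked example

```r
library(ylineage)

s <- simulate_study_like(seed = 42)   # 83-chromosome study-like survey
s
#> <sample_set> 83 samples, 16 loci (1 multi-copy)
#>   haplogroups: 16 distinct
#>   departments: Huila=42, Tolima=41

lf <- lineage_frequencies(s)
sum(lf$pct_total[grepl("^R1b", lf$haplogroup)])
#> [1] 57.83133            # R1b sublineages: 48 of 83 chromosomes

amova_fst(s, n_perm = 10000, seed = 42)
#> AMOVA (mismatch distances): Phi_ST = 0.01141, p = 0.11489 +/- 0.0032 (10000 permutations)
#>   variance among = 0.04920, within = 4.26441; groups: Huila (n=42), Tolima (n=41)

q <- subset_samples(normalize_for_network(s), "^Q1a2-M346",
                    haplogroup_pattern = TRUE)
build_mj_network(q)
#> <mj_network> 4 nodes (4 observed, 0 median vectors), 3 edges, epsilon = 0
#>   7 chromosomes collapsed into the observed nodes

tmrca_dating(q)
#> TMRCA: rho = 0.5714 +/- 0.2857 over 15 loci (mu = 0.00069 /locus/25 yr)
#>   age = 1380 +/- 690 years
```

Reading the output: the simulated survey shows no department structure
(Φ_ST ≈ 0.01, p ≈ 0.11, so Huila and Tolima pool into one population), the
seven DYS391*6 carrier chromosomes collapse into a small star-like network,
and the rho clock dates that cluster's founder to roughly 1.4 kyr for this
realization (the generating age is 1809 years; single-cluster estimates
scatter around it, as the test suite quantifies over replicates).

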