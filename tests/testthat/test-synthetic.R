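test_that("a zero-age star is the founder repeated", {
  s <- simulate_star(10, age_years = 0, seed = 1)
  f <- default_founder_haplotype(uniform_rate_panel())
  expect_true(all(apply(s$alleles, 1, function(r) all(r == f))))
  expect_equal(attr(s, "n_mutations"), rep(0L, 10))
})

test_that("per-lineage mutation counts match Poisson moments", {
  lambda <- 15 * 6.9e-4 * 1809 / 25  # 0.7489
  s <- simulate_star(1000, age_years = 1809, seed = 2)
  k <- attr(s, "n_mutations")
  expect_equal(mean(k), lambda, tolerance = 0.1)          # MC error ~ 3.5%
  expect_equal(stats::var(k), lambda, tolerance = 0.15)
})

test_that("mean distance to the founder approximates the mutation expectation", {
  lambda <- 15 * 6.9e-4 * 1809 / 25
  s <- simulate_star(3000, age_years = 1809, seed = 3)
  f <- default_founder_haplotype(uniform_rate_panel())
  rho <- rho_statistic(s, ancestor = f)$rho
  # slightly below lambda because multiple hits at one locus can cancel
  expect_lt(abs(rho - lambda) / lambda, 0.05)
})

test_that("pairwise distances on a star are about twice the per-lineage rate", {
  lambda <- 15 * 6.9e-4 * 1809 / 25
  s <- simulate_star(200, age_years = 1809, seed = 4)
  D <- pairwise_distance_matrix(s, metric = "stepwise")
  mean_pair <- mean(D[upper.tri(D)])
  expect_lt(abs(mean_pair - 2 * lambda) / (2 * lambda), 0.10)
})

test_that("generators are deterministic given a seed and spare the ambient RNG", {
  s1 <- simulate_star(20, 1809, seed = 7)
  s2 <- simulate_star(20, 1809, seed = 7)
  expect_identical(s1$alleles, s2$alleles)
  c1 <- simulate_coalescent(8, seed = 7)
  c2 <- simulate_coalescent(8, seed = 7)
  expect_identical(c1$alleles, c2$alleles)
  set.seed(99); x <- runif(1); set.seed(99)
  invisible(simulate_study_like(seed = 5))
  expect_equal(runif(1), x)
})

test_that("coalescent pair TMRCA has the configured expectation", {
  Ne <- 300
  depths <- vapply(1:500, function(i)
    attr(simulate_coalescent(2, Ne = Ne, seed = i), "tmrca_years"), numeric(1))
  expect_lt(abs(mean(depths) / (Ne * 25) - 1), 0.15)
  expect_error(simulate_coalescent(1), "n >= 2")
})

test_that("allele states never fall below one (reflecting boundary)", {
  p <- locus_panel(c("A", "B", "C"), rate = rep(6.9e-4, 3), rate_units = "per_25y")
  s <- simulate_star(200, age_years = 2e5, panel = p, founder = c(A = 1, B = 1, C = 2),
                     seed = 9)
  expect_true(all(s$alleles >= 1))
})

test_that("the study-like generator reproduces the published sharing structure", {
  comp <- study_haplogroup_composition()
  expect_equal(sum(comp$total), 83)
  expect_equal(sum(comp$distinct), 77)
  s <- simulate_study_like(seed = 10)
  expect_equal(nsamples(s), 83)
  expect_equal(as.integer(table(s$samples$department)[c("Huila", "Tolima")]),
               c(42L, 41L))
  tab <- table(s$samples$haplogroup)
  expect_equal(as.integer(tab[comp$haplogroup]), comp$total)
  expect_equal(length(haplotype_multiplicities(s)), 77L)

  dt <- diversity_table(s)
  dt <- dt[dt$group != "Total", ]
  expect_equal(nrow(dt), 16)
  expect_equal(sum(!is.na(dt$hd)), 6)  # clades with n >= 5
  # most-even multiplicity partitions reproduce every published clade diversity
  expect_equal(dt$hd[dt$group == "Q1a2-M346*(xM3)"], 0.9047619, tolerance = 1e-6)
  expect_equal(dt$hd[dt$group == "Q1a2-M3*(xM19,M194,M199)"], 1)
  expect_equal(dt$hd[dt$group == "R1b-S116*(xU152,M529,M65,M153,M167)"],
               0.9969231, tolerance = 1e-6)
  expect_equal(dt$hd[dt$group == "R1b-U152"], 1)
  expect_equal(dt$hd[dt$group == "R1b-M529"], 1)
  expect_equal(dt$hd[dt$group == "T-M70"], 1)
})

test_that("the designated lineage is fixed for DYS391 allele six", {
  s <- simulate_study_like(seed = 11)
  q <- grepl("^Q1a2-M346", s$samples$haplogroup)
  expect_true(all(s$alleles[q, "DYS391"] == 6))
  expect_true(all(s$alleles[!q, "DYS391"] != 6))
})

test_that("haplogroup founders are mutually separated", {
  s <- simulate_study_like(seed = 12)
  f <- attr(s, "founders")
  D <- pairwise_distance_matrix(f, metric = "stepwise")
  expect_true(all(D[upper.tri(D)] >= 5))
})

test_that("random department labels carry no structure", {
  fst <- vapply(1:5, function(seed)
    amova_fst(simulate_study_like(seed = seed), n_perm = 100, seed = seed)$fst,
    numeric(1))
  expect_lt(mean(abs(fst)), 0.05)
})

test_that("the DYS391*6 cluster is a connected near-star in the network", {
  s <- normalize_for_network(simulate_study_like(seed = 13))
  q <- subset_samples(s, "^Q1a2-M346", haplogroup_pattern = TRUE)
  net <- build_mj_network(q)
  g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                     vertices = net$nodes$id)
  expect_equal(igraph::components(g)$no, 1)
  expect_equal(sum(net$nodes$multiplicity), 7)
  # star-like: every observed node within a couple of links of the modal node
  expect_lte(igraph::diameter(g), 4)
})

test_that("sim_config dispatches to the generators", {
  cfg <- sim_config("star", n_samples = 5, true_age_years = 0, seed = 1)
  s <- simulate_sampleset(cfg)
  expect_equal(nsamples(s), 5)
  expect_error(sim_config("star", true_age_years = -1), ">= 0")
  st <- simulate_sampleset(sim_config("study", seed = 2))
  expect_equal(nsamples(st), 83)
})
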