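test_that("Nei diversity hits its closed-form anchors", {
  expect_equal(nei_diversity(rep(1, 7)), 1, tolerance = 1e-9)
  expect_equal(nei_diversity(12), 0)
  expect_equal(nei_diversity(c(2, 2, 1, 1, 1)), 0.904761904761905, tolerance = 1e-12)
  expect_equal(nei_diversity(c(3, 1, 2)), nei_diversity(c(1, 2, 3)))
  expect_error(nei_diversity(1), "n < 2")
  expect_error(nei_diversity(c(2, 0)), "positive")
})

test_that("Nei formula is algebraically the pairwise-mismatch probability", {
  set.seed(42)
  for (rep in 1:25) {
    counts <- sample(1:6, sample(2:8, 1), replace = TRUE)
    labels <- rep(seq_along(counts), counts)
    n <- length(labels)
    unequal <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      unequal <- unequal + (labels[i] != labels[j])
    expect_equal(nei_diversity(counts), unequal / choose(n, 2),
                 tolerance = 1e-12)
  }
})

test_that("haplotype multiplicities count identity over the full panel", {
  A <- rbind(c(14, 10), c(14, 10), c(14, 10))
  expect_equal(unname(haplotype_multiplicities(toy_set(A))), 3L)
  B <- rbind(c(14, 10), c(15, 10), c(14, 11))
  expect_equal(unname(haplotype_multiplicities(toy_set(B))), rep(1L, 3))
  # DYS385 is compared as an unordered pair: sorted storage makes 11-14 == 14-11
  s <- random_yfiler_set(4, seed = 5)
  s$alleles[2, ] <- s$alleles[1, ]
  expect_equal(sum(haplotype_multiplicities(s) == 2), 1)
})

test_that("a three-sample clade with seven diallelic loci summarizes as published", {
  # 17 storage loci, two haplotypes differing at 7 single-copy loci
  panel <- yfiler_panel()
  base <- default_founder_haplotype(panel)
  other <- base
  other[c("DYS19", "DYS390", "DYS391", "DYS439", "DYS456", "DYS458", "DYS635")] <-
    other[c("DYS19", "DYS390", "DYS391", "DYS439", "DYS456", "DYS458", "DYS635")] + 1
  s <- sample_set(panel,
                  data.frame(sample_id = c("x1", "x2", "x3"),
                             haplogroup = "E1b1b-M78"),
                  rbind(base, base, other))
  row <- diversity_table(s)[1, ]
  expect_equal(row$n, 3)
  expect_equal(row$n_distinct, 2)
  expect_equal(row$n_polymorphic, 7)
  expect_equal(row$mean_alleles, 24 / 17, tolerance = 1e-12)
  expect_equal(round(row$mean_alleles, 3), 1.412)
  expect_equal(round(row$sd_alleles, 3), 0.507)
  expect_true(is.na(row$hd))  # n < 5
})

test_that("diversity table totals equal whole-set statistics", {
  s <- simulate_study_like(seed = 3)
  dt <- diversity_table(s)
  tot <- dt[dt$group == "Total", ]
  expect_equal(tot$n, nsamples(s))
  expect_equal(tot$n_distinct, length(haplotype_multiplicities(s)))
  expect_equal(tot$hd, nei_diversity(haplotype_multiplicities(s)))
  expect_equal(sum(dt$n[dt$group != "Total"]), nsamples(s))
  # diversity reported only for clades of five or more
  small <- dt$group != "Total" & dt$n < 5
  expect_true(all(is.na(dt$hd[small])))
  expect_true(all(!is.na(dt$hd[dt$n >= 5])))
})

test_that("a monomorphic group has no polymorphic loci", {
  A <- matrix(rep(c(14, 10, 21), each = 4), 4)
  dt <- diversity_table(toy_set(A))
  expect_equal(dt$n_polymorphic[1], 0)
  expect_equal(dt$mean_alleles[1], 1)
  expect_equal(dt$sd_alleles[1], 0)
})

test_that("lineage frequencies sum to their margins", {
  s <- simulate_study_like(seed = 4)
  lf <- lineage_frequencies(s)
  hg_rows <- lf$haplogroup != "Total"
  for (col in grep("^count_", names(lf), value = TRUE))
    expect_equal(sum(lf[[col]][hg_rows]), lf[[col]][!hg_rows])
  for (col in grep("^pct_", names(lf), value = TRUE))
    expect_equal(sum(lf[[col]][hg_rows]), 100, tolerance = 1e-9)
  # single group, single haplogroup -> 100%
  one <- toy_set(matrix(1, 2, 2))
  expect_equal(lineage_frequencies(one, "population")$pct_total, c(100, 100))
})

test_that("allele fractions are exact percentages", {
  expect_equal(allele_fraction(0, 10), 0)
  expect_equal(allele_fraction(48, 83), 100 * 48 / 83)
  expect_error(allele_fraction(1, 0), "positive")
  expect_error(allele_fraction(5, 3), "exceeds")
})
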