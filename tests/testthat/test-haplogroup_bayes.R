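# handcrafted model with known per-locus frequencies (bypasses fitting)
toy_model <- function(f1 = 0.8, f2 = 0.2) {
  structure(list(
    haplogroups = c("hg1", "hg2"),
    priors = c(hg1 = 0.5, hg2 = 0.5),
    pseudocount = 0.5,
    loci = "L1",
    freq = list(L1 = list(
      f = matrix(c(f1, f2, 1 - f1, 1 - f2), 2,
                 dimnames = list(c("hg1", "hg2"), c("13", "14"))),
      A = 2, n = c(hg1 = 10, hg2 = 10)))),
    class = "hg_freq_model")
}

test_that("fitted frequencies match a hand tally", {
  A <- matrix(c(13, 13, 14, 15,
                10, 10, 10, 11), 4, 2,
              dimnames = list(NULL, c("L1", "L2")))
  s <- toy_set(A, haplogroup = c("A", "A", "A", "B"))
  m <- fit_frequency_model(s, pseudocount = 0.5)
  # L1: states {13,14,15}, A_l = 3; class A: 2x13, 1x14 of n=3
  expect_equal(m$freq$L1$f["A", "13"], (2 + 0.5) / (3 + 0.5 * 3))
  expect_equal(m$freq$L1$f["A", "15"], 0.5 / (3 + 0.5 * 3))
  expect_equal(m$freq$L1$f["B", "15"], (1 + 0.5) / (1 + 0.5 * 3))
  expect_equal(unname(rowSums(m$freq$L1$f)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(m$freq$L2$f)), c(1, 1), tolerance = 1e-12)
})

test_that("smoothing limits behave as point mass and uniform", {
  A <- matrix(c(13, 15, 10, 12), 2, 2, dimnames = list(NULL, c("L1", "L2")))
  s <- toy_set(A, haplogroup = c("A", "B"))
  sharp <- fit_frequency_model(s, pseudocount = 1e-9)
  expect_equal(sharp$freq$L1$f["A", "13"], 1, tolerance = 1e-6)
  flat <- fit_frequency_model(s, pseudocount = 1e9)
  expect_equal(unname(flat$freq$L1$f["A", ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("Bayes rule on a one-locus toy gives the hand-computed posterior", {
  m <- toy_model(0.8, 0.2)
  post <- predict_haplogroup(m, c(L1 = 13))
  expect_equal(post$posterior[post$haplogroup == "hg1"], 0.8, tolerance = 1e-12)
  expect_equal(post$posterior[post$haplogroup == "hg2"], 0.2, tolerance = 1e-12)
  expect_equal(attr(post, "haplogroup"), "hg1")
  # identical frequency tables across classes -> posterior equals the prior
  flat <- toy_model(0.7, 0.7)
  flat$priors <- c(hg1 = 0.3, hg2 = 0.7)
  pf <- predict_haplogroup(flat, c(L1 = 13))
  expect_equal(pf$posterior[match(c("hg1", "hg2"), pf$haplogroup)], c(0.3, 0.7),
               tolerance = 1e-12)
})

test_that("a class-private allele dominates the posterior at small pseudocount", {
  A <- matrix(c(rep(13, 5), rep(15, 5), rep(c(10, 12), each = 5)), 10, 2,
              dimnames = list(NULL, c("L1", "L2")))
  s <- toy_set(A, haplogroup = rep(c("Q", "R"), each = 5))
  m <- fit_frequency_model(s, pseudocount = 0.01)
  post <- predict_haplogroup(m, c(L1 = 13, L2 = 10))
  expect_equal(attr(post, "haplogroup"), "Q")
  expect_gt(post$posterior[1], 0.99)
})

test_that("log-space computation matches the direct product and normalizes", {
  set.seed(13)
  for (rep in 1:10) {
    A <- matrix(sample(10:14, 12 * 4, replace = TRUE), 12,
                dimnames = list(NULL, paste0("L", 1:4)))
    s <- toy_set(A, haplogroup = sample(c("A", "B", "C"), 12, replace = TRUE))
    m <- tryCatch(fit_frequency_model(s), error = function(e) NULL)
    if (is.null(m)) next
    h <- setNames(sample(10:14, 4), paste0("L", 1:4))
    post <- predict_haplogroup(m, h)
    expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
    direct <- vapply(m$haplogroups, function(hg) {
      p <- m$priors[hg]
      for (loc in m$loci) {
        key <- as.character(h[loc])
        e <- m$freq[[loc]]
        p <- p * (if (key %in% colnames(e$f)) e$f[hg, key]
                  else m$pseudocount / (e$n[hg] + m$pseudocount * e$A))
      }
      p
    }, numeric(1))
    direct <- direct / sum(direct)
    expect_equal(post$posterior[match(m$haplogroups, post$haplogroup)],
                 unname(direct), tolerance = 1e-10)
    # locus order does not matter
    post2 <- predict_haplogroup(m, h[c(3, 1, 4, 2)])
    expect_equal(post$posterior, post2$posterior, tolerance = 1e-12)
  }
})

test_that("self-consistency: predictions on model-structured data beat chance", {
  s <- simulate_study_like(seed = 17)
  m <- fit_frequency_model(s)
  hits <- vapply(seq_len(nsamples(s)), function(i)
    attr(predict_haplogroup(m, get_haplotype(s, i)), "haplogroup") ==
      s$samples$haplogroup[i], logical(1))
  expect_gt(mean(hits), 1 / 16)  # well above the 16-class chance rate
  expect_gt(mean(hits), 0.5)     # founder separation makes classes learnable
})

test_that("a JSON round trip preserves predictions exactly", {
  s <- simulate_study_like(seed = 18)
  m <- fit_frequency_model(s)
  f <- withr::local_tempfile(fileext = ".json")
  write_frequency_model(m, f)
  m2 <- read_frequency_model(f)
  h <- get_haplotype(s, 5)
  expect_equal(predict_haplogroup(m, h)$posterior,
               predict_haplogroup(m2, h)$posterior, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  s1 <- toy_set(matrix(1:4, 2, 2), haplogroup = "onlyone")
  expect_error(fit_frequency_model(s1), "two haplogroup classes")
  s <- simulate_study_like(seed = 1)
  m <- fit_frequency_model(s)
  expect_error(predict_haplogroup(m, c(NOPE = 1)), "no typed loci")
})
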