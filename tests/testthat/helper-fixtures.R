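# shared fixtures: small panels and randomized sample sets built in code

toy_panel <- function(k = 3, rates = NULL) {
  locus_panel(paste0("L", seq_len(k)), rate = rates)
}

toy_set <- function(A, panel = NULL, haplogroup = "HG1", department = "D1",
                    population = "P1") {
  A <- as.matrix(A)
  panel <- panel %||% toy_panel(ncol(A))
  n <- nrow(A)
  sample_set(panel,
             data.frame(sample_id = paste0("s", seq_len(n)),
                        population = rep_len(population, n),
                        department = rep_len(department, n),
                        haplogroup = rep_len(haplogroup, n)),
             A, max_missing = ncol(A))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# randomized full-Yfiler sample set (decimal alleles, unordered pairs,
# occasional missing call) for round-trip properties
random_yfiler_set <- function(n, seed) {
  set.seed(seed)
  panel <- yfiler_panel()
  cols <- allele_cols_of(panel)
  A <- matrix(sample(8:30, n * length(cols), replace = TRUE), n,
              dimnames = list(NULL, cols))
  # sprinkle intermediate alleles and one missing locus
  dec <- which(matrix(runif(length(A)) < 0.05, nrow(A)))
  A[dec] <- A[dec] + 0.2
  if (n > 2) A[1, "DYS392"] <- NA
  # keep DYS389 nesting plausible
  A[, "DYS389II"] <- A[, "DYS389I"] + sample(10:20, n, replace = TRUE)
  sample_set(panel,
             data.frame(sample_id = sprintf("r%02d", seq_len(n)),
                        population = sample(c("PopA", "PopB"), n, TRUE),
                        department = sample(c("Huila", "Tolima"), n, TRUE),
                        haplogroup = sample(c("R1b", "Q1a2"), n, TRUE)),
             A)
}

# expanded storage columns of a panel (test-side copy of the convention)
allele_cols_of <- function(panel) {
  unlist(lapply(seq_len(nrow(panel)), function(i)
    if (panel$duplicated[i]) paste0(panel$locus[i], c(".a", ".b"))
    else panel$locus[i]))
}

expect_sets_equal <- function(a, b) {
  expect_identical(a$panel$locus, b$panel$locus)
  expect_identical(a$samples, b$samples)
  expect_equal(a$alleles, b$alleles)
}

# truncation to the precision used by the published tables
trunc_digits <- function(x, d) trunc(x * 10^d) / 10^d
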