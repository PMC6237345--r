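#' Pairwise haplotype distance matrix
#'
#' Two metrics over a shared panel: `"mismatch"` counts the loci at which two
#' haplotypes differ (duplicated loci compare their unordered pairs as one
#' locus); `"stepwise"` sums per-locus repeat-step differences under the
#' stepwise mutation model (see [step_count()]; for a duplicated locus the
#' sorted copies are compared componentwise). Loci missing in either
#' haplotype are excluded pairwise.
#'
#' @param x a [sample_set()], or a numeric allele matrix over single-copy loci.
#' @param metric `"mismatch"` or `"stepwise"`.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(x, metric = c("mismatch", "stepwise")) {
  metric <- match.arg(metric)
  if (inherits(x, "sample_set")) {
    panel <- x$panel
    A <- x$alleles
    loci <- panel$locus
    cols <- lapply(loci, function(l) locus_columns(panel, l))
  } else {
    A <- as.matrix(x)
    if (nrow(A) < 2) stopf("need at least two haplotypes")
    loci <- colnames(A) %||% paste0("L", seq_len(ncol(A)))
    cols <- lapply(seq_len(ncol(A)), identity)
  }
  n <- nrow(A)
  if (n < 2) stopf("need at least two haplotypes")
  D <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
  for (k in seq_along(loci)) {
    sub <- A[, cols[[k]], drop = FALSE]
    contrib <- matrix(0, n, n)
    for (c_idx in seq_len(ncol(sub))) {
      v <- sub[, c_idx]
      contrib <- contrib + outer(v, v, step_count)
    }
    # pairwise exclusion: a locus missing in either haplotype contributes 0
    contrib[is.na(contrib)] <- 0
    if (metric == "mismatch") contrib <- (contrib > 0) + 0
    D <- D + contrib
  }
  D
}

#' One-level AMOVA with a permutation test
#'
#' Analysis of molecular variance partitioning squared haplotype distances
#' into among-group and within-group components. With groups `g = 1..G` of
#' sizes `n_g` and distance matrix `d`, the sums of squares are
#' `SSD_total = (1/n) * sum_{i<j} d_ij` and
#' `SSD_within = sum_g (1/n_g) * sum_{i<j in g} d_ij`; mean squares follow
#' with `G - 1` and `n - G` degrees of freedom, the among-group variance
#' component uses the average group-size coefficient
#' `n0 = (n - sum n_g^2 / n) / (G - 1)`, and
#' `Phi_ST = var_among / (var_among + var_within)`. Significance is assessed
#' by permuting group labels; the tail probability uses the `(B + 1) /
#' (n_perm + 1)` estimator with `B` permutations reaching `Phi_ST` at least
#' as large as observed, and its binomial standard error
#' `sqrt(p (1 - p) / n_perm)` is reported alongside. Negative fixation
#' indices are reported as computed, not truncated at zero.
#'
#' @param s a [sample_set()].
#' @param group_by grouping label column (default `"department"`).
#' @param metric distance metric, see [pairwise_distance_matrix()]. The
#'   default mismatch metric gives the haplotype-level F_ST-like statistic;
#'   `"stepwise"` gives the R_ST-like molecular analogue.
#' @param n_perm number of label permutations (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed optional RNG seed making the permutation stream reproducible;
#'   the caller's RNG state is untouched.
#' @return an object of class `amova_result`: `fst`, `var_among`,
#'   `var_within`, `p_value`, `p_se`, `n_perm`, `seed`, `metric`,
#'   `group_sizes`.
#' @examples
#' s <- simulate_study_like(seed = 7)
#' amova_fst(s, n_perm = 200, seed = 1)
#' @export
amova_fst <- function(s, group_by = "department",
                      metric = c("mismatch", "stepwise"),
                      n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(s, "sample_set"))
  metric <- match.arg(metric)
  labels <- s$samples[[group_by]]
  if (anyNA(labels)) stopf("missing %s labels", group_by)
  f <- factor(labels)
  sizes <- table(f)
  if (nlevels(f) < 2) stopf("AMOVA needs at least two groups")
  if (any(sizes < 2)) stopf("every group needs at least two samples")
  if (n_perm < 100) warnf("n_perm = %d is very small; the p-value will be coarse", n_perm)

  D <- pairwise_distance_matrix(s, metric = metric)
  n <- nrow(D)
  G <- nlevels(f)
  ssd_total <- sum(D) / (2 * n)
  n0 <- (n - sum(sizes^2) / n) / (G - 1)

  phi_of <- function(f) {
    ssd_within <- 0
    for (lev in levels(f)) {
      idx <- which(f == lev)
      ssd_within <- ssd_within + sum(D[idx, idx]) / (2 * length(idx))
    }
    ms_among <- (ssd_total - ssd_within) / (G - 1)
    ms_within <- ssd_within / (n - G)
    var_among <- (ms_among - ms_within) / n0
    var_within <- ms_within
    denom <- var_among + var_within
    fst <- if (denom == 0) 0 else var_among / denom
    list(fst = fst, var_among = var_among, var_within = var_within)
  }

  obs <- phi_of(f)
  perm_fst <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) phi_of(sample(f))$fst, numeric(1))
  })
  hits <- sum(perm_fst >= obs$fst)
  p <- (hits + 1) / (n_perm + 1)
  structure(list(fst = obs$fst, var_among = obs$var_among,
                 var_within = obs$var_within,
                 p_value = p, p_se = sqrt(p * (1 - p) / n_perm),
                 n_perm = as.integer(n_perm), seed = seed, metric = metric,
                 group_sizes = as.integer(sizes),
                 groups = levels(f)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s distances): Phi_ST = %.5f, p = %.5f +/- %.4f (%d permutations)\n",
              x$metric, x$fst, x$p_value, x$p_se, x$n_perm))
  cat(sprintf("  variance among = %.5f, within = %.5f; groups: %s\n",
              x$var_among, x$var_within,
              paste(sprintf("%s (n=%d)", x$groups, x$group_sizes), collapse = ", ")))
  invisible(x)
}
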