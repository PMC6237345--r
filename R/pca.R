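#' Population-by-haplogroup frequency matrix
#'
#' Validated container for relative haplogroup frequencies per population.
#' Row sums may be below 1: ordinations are routinely run on a subset of
#' informative haplogroups.
#'
#' @param x numeric matrix with population rownames and haplogroup colnames;
#'   entries in `[0, 1]`.
#' @param tol row-sum tolerance above 1.
#' @return a `frequency_matrix`.
#' @export
frequency_matrix <- function(x, tol = 1e-6) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("frequency matrices must be complete")
  if (any(x < 0) || any(x > 1)) stopf("entries must be relative frequencies in [0, 1]")
  if (any(rowSums(x) > 1 + tol)) stopf("row sums exceed 1")
  if (is.null(rownames(x))) rownames(x) <- paste0("pop", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("hg", seq_len(ncol(x)))
  class(x) <- c("frequency_matrix", class(x))
  x
}

#' Haplogroup frequency matrix of a sample set
#' @param s a [sample_set()] with haplogroup labels.
#' @param by metadata column defining the populations (rows).
#' @return a [frequency_matrix()].
#' @export
haplogroup_frequency_matrix <- function(s, by = "population") {
  stopifnot(inherits(s, "sample_set"))
  lf <- lineage_frequencies(s, group_by = by)
  hg_rows <- lf$haplogroup != "Total"
  pct <- lf[hg_rows, grep("^pct_", names(lf)), drop = FALSE]
  pct$pct_total <- NULL
  m <- t(as.matrix(pct)) / 100
  rownames(m) <- sub("^pct_", "", rownames(m))
  colnames(m) <- lf$haplogroup[hg_rows]
  frequency_matrix(m)
}

#' Principal component analysis of haplogroup frequencies
#'
#' Column-centered PCA of a population-by-haplogroup frequency matrix, the
#' standard ordination for comparing lineage composition across populations.
#' The default `"covariance"` mode decomposes raw (centered) frequencies, so
#' common haplogroups dominate; `"correlation"` standardizes each haplogroup
#' to unit variance first. Axes are ordered by decreasing eigenvalue and the
#' sign convention makes the largest-magnitude loading on each axis
#' positive, so results are reproducible across linear-algebra backends.
#'
#' @param m a [frequency_matrix()] (validated) or plain numeric matrix with
#'   at least 3 rows and 2 columns and no missing entries.
#' @param mode `"covariance"` or `"correlation"`.
#' @return an object of class `freq_pca`: `scores` (zero column means),
#'   `loadings`, `sdev`, `var_fraction` (non-increasing, summing to 1 when
#'   total variance is positive), `total_variance`, `mode`. A constant
#'   matrix yields zero fractions with a warning.
#' @examples
#' m <- matrix(runif(40), 10, 4)
#' p <- pca_populations(m)
#' sum(p$var_fraction)  # 1
#' @export
pca_populations <- function(m, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  X <- unclass(as.matrix(m))
  if (nrow(X) < 3) stopf("PCA needs at least 3 populations (rows)")
  if (ncol(X) < 2) stopf("PCA needs at least 2 haplogroups (columns)")
  if (anyNA(X)) stopf("PCA input must have no missing entries")
  Xc <- sweep(X, 2, colMeans(X))
  if (mode == "correlation") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warnf("constant haplogroup columns left unscaled in correlation mode")
      sds[sds == 0] <- 1
    }
    Xc <- sweep(Xc, 2, sds, "/")
  }
  total_var <- sum(apply(Xc, 2, stats::var))
  if (total_var == 0) {
    warnf("input matrix is constant across populations; all eigenvalues are zero")
    k <- min(nrow(X) - 1, ncol(X))
    return(structure(list(
      scores = matrix(0, nrow(X), k, dimnames = list(rownames(X), paste0("PC", 1:k))),
      loadings = matrix(0, ncol(X), k, dimnames = list(colnames(X), paste0("PC", 1:k))),
      sdev = rep(0, k), var_fraction = rep(0, k),
      total_variance = 0, mode = mode), class = "freq_pca"))
  }
  fit <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  scores <- fit$x
  loadings <- fit$rotation
  for (k in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- fit$sdev^2
  structure(list(scores = scores, loadings = loadings, sdev = fit$sdev,
                 var_fraction = ev / sum(ev), total_variance = total_var,
                 mode = mode),
            class = "freq_pca")
}

#' @export
print.freq_pca <- function(x, ...) {
  cat(sprintf("<freq_pca> %s mode, %d axes\n", x$mode, length(x$sdev)))
  vf <- round(100 * x$var_fraction, 2)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  if (length(vf) >= 2)
    cat(sprintf("  first two axes: %.2f%%\n", sum(vf[1:2])))
  invisible(x)
}
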