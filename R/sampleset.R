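#' A set of typed Y-STR haplotypes with sample metadata
#'
#' The central container: a [locus_panel()] plus one record per sampled
#' chromosome (sample id, population, department and haplogroup labels) and an
#' allele matrix. Duplicated loci are stored as two columns (`<locus>.a`,
#' `<locus>.b`) kept sorted ascending, so that the unordered-pair states
#' `11-14` and `14-11` are identical. Missing calls are `NA`, never zero.
#'
#' @param panel a [locus_panel()].
#' @param samples data frame with columns `sample_id`, `population`,
#'   `department`, `haplogroup` (missing label columns are filled with `NA`).
#' @param alleles numeric matrix, one row per sample, columns matching the
#'   panel's expanded storage columns (see Details). Unsorted DYS385 pairs are
#'   sorted on construction.
#' @param max_missing maximum number of loci a sample may miss before it is
#'   rejected (default 2; the Yfiler data sets the package targets are
#'   complete profiles).
#' @return an object of class `sample_set`.
#' @examples
#' p <- locus_panel(c("DYS19", "DYS391"))
#' s <- sample_set(p, data.frame(sample_id = c("a", "b")),
#'                 matrix(c(14, 15, 10, 11), 2, 2,
#'                        dimnames = list(NULL, c("DYS19", "DYS391"))))
#' s
#' @export
sample_set <- function(panel, samples, alleles, max_missing = 2L) {
  stopifnot(inherits(panel, "locus_panel"))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) == 0) stopf("a sample_set must contain at least one record")
  if (!"sample_id" %in% names(samples)) stopf("`samples` needs a sample_id column")
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample ids: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  for (col in c("population", "department", "haplogroup"))
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  samples <- samples[c("sample_id", "population", "department", "haplogroup")]

  cols <- allele_columns(panel)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "double"
  if (nrow(alleles) != nrow(samples))
    stopf("allele matrix has %d rows for %d samples", nrow(alleles), nrow(samples))
  if (is.null(colnames(alleles))) {
    if (ncol(alleles) != length(cols))
      stopf("allele matrix has %d columns; panel expects %d", ncol(alleles), length(cols))
    colnames(alleles) <- cols
  }
  missing_cols <- setdiff(cols, colnames(alleles))
  if (length(missing_cols))
    stopf("allele matrix lacks panel loci: %s", paste(missing_cols, collapse = ", "))
  alleles <- alleles[, cols, drop = FALSE]
  if (any(alleles < 0, na.rm = TRUE)) stopf("allele states must be >= 0")
  # enforce sorted unordered pairs
  for (loc in panel$locus[panel$duplicated]) {
    pc <- locus_columns(panel, loc)
    pair <- alleles[, pc, drop = FALSE]
    alleles[, pc] <- t(apply(pair, 1, sort, na.last = TRUE))
  }
  rownames(alleles) <- samples$sample_id

  n_miss <- vapply(seq_len(nrow(alleles)), function(i) {
    sum(vapply(panel$locus, function(loc)
      anyNA(alleles[i, locus_columns(panel, loc)]), logical(1)))
  }, integer(1))
  bad <- n_miss > max_missing
  if (any(bad))
    stopf("samples missing more than %d loci: %s", max_missing,
          paste(samples$sample_id[bad], collapse = ", "))

  structure(list(panel = panel, samples = samples, alleles = alleles),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, %d loci (%d multi-copy)\n",
              nrow(x$samples), nrow(x$panel), sum(x$panel$duplicated)))
  hg <- x$samples$haplogroup
  if (!all(is.na(hg)))
    cat("  haplogroups:", length(unique(hg[!is.na(hg)])), "distinct\n")
  dep <- x$samples$department
  if (!all(is.na(dep))) {
    tb <- table(dep)
    cat("  departments:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples
#' @param s a `sample_set`.
#' @export
nsamples <- function(s) nrow(s$samples)

#' Subset a sample set by row index or metadata predicate
#'
#' @param s a `sample_set`.
#' @param i integer/logical row index, or a character haplogroup pattern when
#'   `haplogroup_pattern = TRUE`.
#' @param haplogroup_pattern interpret `i` as a regular expression matched
#'   against the haplogroup labels.
#' @return the restricted `sample_set`.
#' @examples
#' s <- simulate_study_like(seed = 1)
#' subset_samples(s, "^Q1a2-M346", haplogroup_pattern = TRUE)
#' @export
subset_samples <- function(s, i, haplogroup_pattern = FALSE) {
  stopifnot(inherits(s, "sample_set"))
  if (haplogroup_pattern) {
    stopifnot(is.character(i), length(i) == 1)
    i <- grepl(i, s$samples$haplogroup)
  }
  sample_set(s$panel, s$samples[i, , drop = FALSE],
             s$alleles[i, , drop = FALSE], max_missing = nrow(s$panel))
}

#' Construct a single haplotype
#'
#' A haplotype maps locus names to allele states; states of duplicated loci
#' are unordered pairs stored sorted ascending.
#'
#' @param alleles named list (or named numeric vector) of allele states;
#'   length-2 entries are treated as unordered pairs.
#' @return an object of class `haplotype` (named list).
#' @examples
#' haplotype(list(DYS19 = 14, DYS385 = c(14, 11)))$DYS385  # 11 14
#' @export
haplotype <- function(alleles) {
  if (is.numeric(alleles) && !is.null(names(alleles))) alleles <- as.list(alleles)
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  out <- lapply(alleles, function(a) {
    a <- as.numeric(a)
    if (any(a < 0, na.rm = TRUE)) stopf("allele states must be >= 0")
    if (length(a) == 2) sort(a, na.last = TRUE) else a
  })
  class(out) <- "haplotype"
  out
}

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype>",
      paste(names(x), vapply(x, function(a) paste(a, collapse = "-"), ""),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract one record as a haplotype object
#' @param s a `sample_set`.
#' @param i row index or sample id.
#' @export
get_haplotype <- function(s, i) {
  stopifnot(inherits(s, "sample_set"))
  if (is.character(i)) i <- match(i, s$samples$sample_id)
  row <- s$alleles[i, ]
  out <- lapply(seq_len(nrow(s$panel)), function(k)
    unname(row[locus_columns(s$panel, s$panel$locus[k])]))
  names(out) <- s$panel$locus
  haplotype(out)
}

# Expand a haplotype object to the panel's storage columns (NA for absent loci).
haplotype_row <- function(h, panel) {
  cols <- allele_columns(panel)
  out <- setNames(rep(NA_real_, length(cols)), cols)
  for (loc in intersect(names(h), panel$locus)) {
    pc <- locus_columns(panel, loc)
    v <- h[[loc]]
    if (length(v) != length(pc))
      stopf("locus %s: state has %d values, panel expects %d", loc, length(v), length(pc))
    out[pc] <- if (length(v) == 2) sort(v, na.last = TRUE) else v
  }
  out
}
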