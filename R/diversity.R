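#' Nei unbiased haplotype diversity
#'
#' For a sample of `n = sum(counts)` chromosomes partitioned into haplotype
#' classes with multiplicities `counts`, the unbiased (Nei) diversity is
#' \deqn{HD = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big)}
#' with `p_i = counts_i / n`. It equals the probability that two chromosomes
#' drawn without replacement carry different haplotypes, so it is 0 for a
#' single shared haplotype and 1 when all haplotypes are distinct.
#'
#' @param counts positive integer multiplicities (order irrelevant).
#' @return diversity in `[0, 1]`.
#' @examples
#' nei_diversity(rep(1, 7))          # 1: all distinct
#' nei_diversity(c(2, 2, 1, 1, 1))   # 0.9047619
#' @export
nei_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || anyNA(counts) || any(counts < 1) ||
      any(counts != floor(counts)))
    stopf("`counts` must be a non-empty set of positive integers")
  n <- sum(counts)
  if (n < 2) stopf("diversity is undefined for n < 2")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Haplotype multiplicities of a sample set
#'
#' Groups records by haplotype identity and returns the class sizes. Identity
#' uses all panel loci by default (with duplicated loci compared as unordered
#' pairs); a locus subset can be supplied, e.g. to count identity on a
#' normalized sub-panel. Missing calls compare equal only to missing calls.
#'
#' @param s a [sample_set()].
#' @param loci optional character vector of panel locus names.
#' @return named integer vector of multiplicities (names are the haplotype
#'   keys); `sum()` equals [nsamples()].
#' @examples
#' s <- simulate_study_like(seed = 1)
#' length(haplotype_multiplicities(s))  # number of distinct haplotypes
#' @export
haplotype_multiplicities <- function(s, loci = NULL) {
  stopifnot(inherits(s, "sample_set"))
  loci <- loci %||% s$panel$locus
  missing_loci <- setdiff(loci, s$panel$locus)
  if (length(missing_loci))
    stopf("unknown loci: %s", paste(missing_loci, collapse = ", "))
  cols <- unlist(lapply(loci, function(l) locus_columns(s$panel, l)))
  keys <- apply(s$alleles[, cols, drop = FALSE], 1, paste, collapse = "/")
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# distinct allele states per locus; a duplicated locus contributes its two
# sorted copies as separate loci, matching the Yfiler "17 loci" convention
alleles_per_locus <- function(s) {
  apply(s$alleles, 2, function(v) length(unique(v[!is.na(v)])))
}

#' Per-group diversity statistics table
#'
#' One row per group (plus a `Total` row) with: sample count, distinct
#' haplotype count, number of polymorphic loci (loci with more than one
#' allele state), mean number of distinct alleles per locus with its sample
#' (`n - 1`) standard deviation, and Nei haplotype diversity. Diversity is
#' reported only for groups of five or more chromosomes (the usual reporting
#' convention for small clades) and is `NA` otherwise.
#'
#' @param s a [sample_set()].
#' @param group_by grouping label: `"haplogroup"`, `"department"` or
#'   `"population"`.
#' @param min_n_hd minimum group size for reporting diversity (default 5).
#' @return data frame with columns `group`, `n`, `n_distinct`,
#'   `n_polymorphic`, `mean_alleles`, `sd_alleles`, `hd`.
#' @export
diversity_table <- function(s, group_by = c("haplogroup", "department", "population"),
                            min_n_hd = 5L) {
  stopifnot(inherits(s, "sample_set"))
  group_by <- match.arg(group_by)
  labels <- s$samples[[group_by]]
  if (all(is.na(labels))) stopf("no %s labels present", group_by)
  groups <- sort(unique(labels))
  one_row <- function(label, sub) {
    mult <- haplotype_multiplicities(sub)
    n_all <- alleles_per_locus(sub)
    data.frame(group = label,
               n = nsamples(sub),
               n_distinct = length(mult),
               n_polymorphic = sum(n_all > 1),
               mean_alleles = mean(n_all),
               sd_alleles = stats::sd(n_all),
               hd = if (nsamples(sub) >= min_n_hd) nei_diversity(mult) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(groups, function(g) one_row(g, subset_samples(s, labels == g)))
  rows <- c(rows, list(one_row("Total", s)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lineage (haplogroup) frequency table
#'
#' Absolute and relative haplogroup frequencies per group plus the pooled
#' totals, in the layout of a haplogroup-frequency table: one row per
#' haplogroup, `count_*` and `pct_*` column pairs, and a final `Total` row.
#' Percentages are exact (`100 * count / n`); any rounding is left to the
#' caller.
#'
#' @param s a [sample_set()] with haplogroup labels.
#' @param group_by column splitting the sample (default `"department"`).
#' @return data frame of counts and percentages.
#' @export
lineage_frequencies <- function(s, group_by = "department") {
  stopifnot(inherits(s, "sample_set"))
  hg <- s$samples$haplogroup
  if (all(is.na(hg))) stopf("no haplogroup labels present")
  labels <- s$samples[[group_by]]
  groups <- sort(unique(labels[!is.na(labels)]))
  hgs <- sort(unique(hg))
  out <- data.frame(haplogroup = c(hgs, "Total"), stringsAsFactors = FALSE)
  add_group <- function(name, idx) {
    counts <- as.integer(table(factor(hg[idx], levels = hgs)))
    n <- sum(counts)
    out[[paste0("count_", name)]] <<- c(counts, n)
    out[[paste0("pct_", name)]] <<- c(100 * counts / n, 100)
  }
  for (g in groups) add_group(g, labels == g)
  add_group("total", rep(TRUE, length(hg)))
  out
}

#' Percentage of a count within a total
#'
#' Plain frequency arithmetic (`100 * count / total`), used for reporting
#' database and sample allele frequencies.
#'
#' @param count integer count, `0 <= count <= total`.
#' @param total positive integer total.
#' @return percentage.
#' @examples
#' allele_fraction(334, 197102)  # 0.1694556
#' @export
allele_fraction <- function(count, total) {
  if (!is_count(count) || !is_count(total)) stopf("count and total must be non-negative integers")
  if (total == 0) stopf("total must be positive")
  if (count > total) stopf("count exceeds total")
  100 * count / total
}
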