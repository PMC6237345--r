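#' Normalize a Yfiler sample set for network and dating analyses
#'
#' Phylogenetic analyses of Y-STRs work on independent single-copy,
#' non-nested loci. This step (i) removes duplicated loci (DYS385, whose two
#' copies cannot be assigned to a specific site by standard typing) and
#' (ii) replaces the nested DYS389II count by the non-overlapping repeat
#' number `DYS389II - DYS389I`, renaming the locus `DYS389II-I`. A 17-locus
#' Yfiler set becomes the 15-locus single-copy panel. Already-normalized sets
#' are returned unchanged, so the operation is idempotent.
#'
#' @param s a [sample_set()].
#' @return a `sample_set` on the normalized panel.
#' @examples
#' s <- simulate_study_like(seed = 1)
#' ns <- normalize_for_network(s)
#' nloci(ns)  # 15
#' @export
normalize_for_network <- function(s) {
  stopifnot(inherits(s, "sample_set"))
  panel <- s$panel
  already <- !any(panel$duplicated) && "DYS389II-I" %in% panel$locus &&
    !"DYS389II" %in% panel$locus
  if (already) return(s)
  if (!all(c("DYS389I", "DYS389II") %in% panel$locus))
    stopf("normalization needs both DYS389I and DYS389II in the panel")

  a1 <- s$alleles[, "DYS389I"]
  a2 <- s$alleles[, "DYS389II"]
  bad <- !is.na(a1) & !is.na(a2) & a2 < a1
  if (any(bad))
    stopf("DYS389II < DYS389I (impossible nested count) for: %s",
          paste(s$samples$sample_id[bad], collapse = ", "))

  keep <- !panel$duplicated
  new_panel <- panel[keep, , drop = FALSE]
  new_panel$locus[new_panel$locus == "DYS389II"] <- "DYS389II-I"
  new_panel$duplicated <- FALSE
  new_panel <- locus_panel(new_panel$locus, rate = new_panel$rate,
                           weight = new_panel$weight,
                           duplicated = new_panel$duplicated,
                           rate_units = attr(panel, "rate_units"))

  keep_cols <- unlist(lapply(panel$locus[keep], function(l) locus_columns(panel, l)))
  alleles <- s$alleles[, keep_cols, drop = FALSE]
  colnames(alleles)[colnames(alleles) == "DYS389II"] <- "DYS389II-I"
  alleles[, "DYS389II-I"] <- a2 - a1
  sample_set(new_panel, s$samples, alleles, max_missing = nrow(new_panel))
}
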