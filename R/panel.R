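#' Locus panel: loci, mutation rates, network weights
#'
#' A `locus_panel` describes the Y-STR loci a data set is typed at: locus
#' names, per-locus mutation rates, integer network weights and a flag for
#' multi-copy loci (DYS385a/b is amplified as a single system whose two copies
#' cannot be assigned to a chromosome arm, so its state is an unordered pair).
#'
#' @param loci character vector of unique locus names, in panel order.
#' @param rate positive per-locus mutation rates. Units are declared with
#'   `rate_units`: `"per_25y"` (mutations/locus/25 years, the effective-rate
#'   convention used for founder dating) or `"per_generation"`.
#' @param weight integer weights in `[1, 10]` used by the median-joining
#'   network; defaults to [assign_weights()] applied to `rate`.
#' @param duplicated logical flag per locus marking multi-copy systems.
#' @param rate_units unit declaration for `rate`.
#' @return an object of class `locus_panel` (a data frame with one row per
#'   locus plus a `rate_units` attribute).
#' @seealso [yfiler_panel()], [assign_weights()]
#' @examples
#' locus_panel(c("DYS19", "DYS391"), rate = c(2.3e-3, 2.6e-3))
#' @export
locus_panel <- function(loci, rate = NULL, weight = NULL, duplicated = NULL,
                        rate_units = c("per_25y", "per_generation")) {
  rate_units <- match.arg(rate_units)
  loci <- as.character(loci)
  if (length(loci) == 0) stopf("a locus panel needs at least one locus")
  if (anyDuplicated(loci)) stopf("duplicate locus names: %s",
                                 paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (is.null(rate)) rate <- rep(6.9e-4, length(loci))
  if (length(rate) != length(loci)) stopf("`rate` must have one entry per locus")
  if (any(!is.finite(rate)) || any(rate <= 0)) stopf("mutation rates must be strictly positive")
  if (is.null(weight)) weight <- assign_weights(rate)
  if (length(weight) != length(loci)) stopf("`weight` must have one entry per locus")
  if (any(weight != floor(weight)) || any(weight < 1)) stopf("weights must be integers >= 1")
  if (is.null(duplicated)) duplicated <- rep(FALSE, length(loci))
  duplicated <- as.logical(duplicated)
  if (length(duplicated) != length(loci) || anyNA(duplicated))
    stopf("`duplicated` must be a logical flag per locus")
  out <- data.frame(locus = loci, rate = as.numeric(rate),
                    weight = as.integer(weight), duplicated = duplicated,
                    stringsAsFactors = FALSE)
  attr(out, "rate_units") <- rate_units
  class(out) <- c("locus_panel", "data.frame")
  out
}

# Approximate published father-son mutation rates (per locus per generation)
# for the Yfiler loci; used only as weighting defaults, not for dating.
default_ystr_rates <- function() {
  c(DYS19 = 2.3e-3, DYS389I = 2.5e-3, DYS389II = 3.6e-3, DYS390 = 2.1e-3,
    DYS391 = 2.6e-3, DYS392 = 0.4e-3, DYS393 = 1.1e-3, DYS385 = 2.3e-3,
    DYS438 = 0.4e-3, DYS439 = 5.0e-3, DYS437 = 1.2e-3, DYS448 = 1.8e-3,
    DYS456 = 4.2e-3, DYS458 = 6.4e-3, DYS635 = 3.8e-3, YGATAH4 = 2.8e-3,
    `DYS389II-I` = 3.6e-3)
}

#' The 17-locus Yfiler panel
#'
#' Standard AmpFlSTR Yfiler panel: 15 single-copy loci plus the duplicated
#' DYS385 system, with approximate published per-generation mutation rates as
#' weighting defaults. With `normalized = TRUE` the network-ready panel is
#' returned instead: DYS385 dropped and DYS389II replaced by the non-nested
#' count DYS389II-I (see [normalize_for_network()]).
#'
#' @param normalized logical; return the 15-locus network panel?
#' @return a [locus_panel()].
#' @examples
#' yfiler_panel()
#' nloci(yfiler_panel(normalized = TRUE))  # 15
#' @export
yfiler_panel <- function(normalized = FALSE) {
  loci <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
            "DYS393", "DYS385", "DYS438", "DYS439", "DYS437", "DYS448",
            "DYS456", "DYS458", "DYS635", "YGATAH4")
  if (normalized) {
    loci <- setdiff(loci, "DYS385")
    loci[loci == "DYS389II"] <- "DYS389II-I"
    dup <- rep(FALSE, length(loci))
  } else {
    dup <- loci == "DYS385"
  }
  rates <- unname(default_ystr_rates()[loci])
  locus_panel(loci, rate = rates, duplicated = dup,
              rate_units = "per_generation")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("<locus_panel> %d loci (%d multi-copy), rates %s\n",
              nrow(x), sum(x$duplicated), attr(x, "rate_units")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Number of loci in a panel or sample set
#' @param x a `locus_panel` or `sample_set`.
#' @return integer locus count (a duplicated locus counts once).
#' @export
nloci <- function(x) {
  if (inherits(x, "sample_set")) x <- x$panel
  nrow(x)
}

# Expanded storage column names: duplicated loci occupy two sorted columns.
allele_columns <- function(panel) {
  unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$duplicated[i]) paste0(panel$locus[i], c(".a", ".b"))
    else panel$locus[i]
  }), use.names = FALSE)
}

# Columns of the expanded matrix belonging to one locus.
locus_columns <- function(panel, locus) {
  i <- match(locus, panel$locus)
  if (is.na(i)) stopf("locus '%s' is not in the panel", locus)
  if (panel$duplicated[i]) paste0(locus, c(".a", ".b")) else locus
}
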