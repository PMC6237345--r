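#' Read a tab-delimited Y-STR haplotype table
#'
#' Parses YHRD-style tables: the columns `SampleID`, `Population`,
#' `Department`, `Haplogroup` followed by one column per locus. States of
#' duplicated loci (DYS385) are written as `a-b` pairs; the pair is unordered,
#' so `11-14` and `14-11` parse identically. Empty cells, `NA` and `.` are
#' recorded as missing calls (never as zero).
#'
#' @param path path to the table.
#' @param panel optional [locus_panel()]; by default one is derived from the
#'   header (loci known to the Yfiler panel keep their default rates, DYS385
#'   is flagged duplicated).
#' @param pair_sep separator inside unordered-pair tokens (default `"-"`).
#' @param sep field separator (default tab).
#' @param max_missing passed to [sample_set()].
#' @return a validated [sample_set()].
#' @seealso [write_haplotype_table()]
#' @export
read_haplotype_table <- function(path, panel = NULL, pair_sep = "-",
                                 sep = "\t", max_missing = 2L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  meta_cols <- c("SampleID", "Population", "Department", "Haplogroup")
  if (!"SampleID" %in% names(raw)) stopf("%s: header lacks a SampleID column", path)
  loci <- setdiff(names(raw), meta_cols)
  if (length(loci) == 0) stopf("%s: no locus columns found", path)

  if (is.null(panel)) {
    dup <- vapply(loci, function(l)
      identical(l, "DYS385") || any(grepl(pair_sep, raw[[l]], fixed = TRUE)),
      logical(1))
    rates <- default_ystr_rates()[loci]
    rates[is.na(rates)] <- 2e-3
    panel <- locus_panel(loci, rate = unname(rates), duplicated = dup,
                         rate_units = "per_generation")
  } else if (!setequal(panel$locus, loci)) {
    stopf("%s: header loci do not match the supplied panel", path)
  }
  panel <- panel[match(loci, panel$locus), , drop = FALSE]
  class(panel) <- c("locus_panel", "data.frame")

  parse_one <- function(tok, row, col) {
    if (is.na(tok)) return(NA_real_)
    tok <- trimws(tok)
    if (tok %in% c("", "NA", ".")) return(NA_real_)
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stopf("row %d, column %s: malformed allele token '%s'", row, col, tok)
    v
  }
  n <- nrow(raw)
  cols <- allele_columns(panel)
  alleles <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(nrow(panel))) {
    loc <- panel$locus[k]
    toks <- raw[[loc]]
    if (panel$duplicated[k]) {
      for (i in seq_len(n)) {
        if (is.na(toks[i])) next
        tok <- trimws(toks[i])
        if (tok %in% c("", "NA", ".")) next
        parts <- strsplit(tok, pair_sep, fixed = TRUE)[[1]]
        if (length(parts) != 2)
          stopf("row %d, column %s: expected an '%s'-separated pair, got '%s'",
                i, loc, pair_sep, tok)
        pair <- sort(c(parse_one(parts[1], i, loc), parse_one(parts[2], i, loc)))
        alleles[i, locus_columns(panel, loc)] <- pair
      }
    } else {
      alleles[, loc] <- vapply(seq_len(n), function(i) parse_one(toks[i], i, loc),
                               numeric(1))
    }
  }
  samples <- data.frame(
    sample_id = raw$SampleID,
    population = if ("Population" %in% names(raw)) raw$Population else NA_character_,
    department = if ("Department" %in% names(raw)) raw$Department else NA_character_,
    haplogroup = if ("Haplogroup" %in% names(raw)) raw$Haplogroup else NA_character_,
    stringsAsFactors = FALSE)
  sample_set(panel, samples, alleles, max_missing = max_missing)
}

# lossless numeric -> text (17.2 stays "17.2", integers have no decimals)
format_allele <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) as.character(v), ""))
}

#' Write a sample set as a tab-delimited haplotype table
#'
#' Inverse of [read_haplotype_table()]: the written file re-reads to a
#' bit-identical `sample_set` (allele text forms are lossless, unordered
#' pairs serialize sorted).
#'
#' @param s a [sample_set()].
#' @param path output path.
#' @param pair_sep separator for unordered-pair states.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(s, path, pair_sep = "-") {
  stopifnot(inherits(s, "sample_set"))
  if (nrow(s$samples) == 0) stopf("refusing to write an empty sample_set")
  panel <- s$panel
  out <- data.frame(SampleID = s$samples$sample_id,
                    Population = s$samples$population,
                    Department = s$samples$department,
                    Haplogroup = s$samples$haplogroup,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_len(nrow(panel))) {
    loc <- panel$locus[k]
    if (panel$duplicated[k]) {
      pc <- locus_columns(panel, loc)
      a <- s$alleles[, pc[1]]; b <- s$alleles[, pc[2]]
      out[[loc]] <- ifelse(is.na(a) & is.na(b), "",
                           paste0(format_allele(a), pair_sep, format_allele(b)))
    } else {
      out[[loc]] <- format_allele(s$alleles[, loc])
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
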