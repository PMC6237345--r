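# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mutational step count between two allele states
#'
#' Distance between repeat counts under the stepwise mutation model:
#' `|a - b|` rounded half-up to the nearest integer, with any non-zero
#' non-integral offset (intermediate alleles such as 13 vs 13.2) counting as
#' at least one step. `NA` propagates.
#'
#' @param a,b numeric allele states (repeat counts, possibly fractional).
#' @return integer-valued numeric vector of step counts.
#' @examples
#' step_count(13, 16)    # 3
#' step_count(13, 13.2)  # 1: intermediate alleles are one step away
#' @export
step_count <- function(a, b) {
  d <- abs(a - b)
  s <- floor(d + 0.5)
  out <- ifelse(d == 0, 0, pmax(s, 1))
  out[is.na(d)] <- NA_real_
  out
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small stable string digest (djb2 over UTF-8 bytes), used for provenance
# records so that reruns on identical input are recognisable.
str_digest <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
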