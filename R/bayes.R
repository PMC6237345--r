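#' Fit a haplogroup allele-frequency model
#'
#' Naive-Bayes frequency model for haplogroup prediction from Y-STR alleles,
#' the screening step used to choose SNP panels before wet-lab confirmation.
#' For each haplogroup `hg` and locus `l` the smoothed allele frequency is
#' \deqn{f(a \mid hg, l) = \frac{count + c}{n_{hg,l} + c\,A_l}}
#' where `c` is the additive pseudocount, `A_l` the number of allele states
#' observed at locus `l` anywhere in the training set, and `n_{hg,l}` the
#' number of training chromosomes of that haplogroup typed at the locus.
#' Duplicated loci are excluded by default (mirroring network practice);
#' with `include_duplicated = TRUE` their unordered pair is treated as a
#' single categorical state with pair-frequency smoothing.
#'
#' @param s a [sample_set()] with haplogroup labels (at least two classes).
#' @param pseudocount additive smoothing mass (> 0, default 0.5).
#' @param include_duplicated use duplicated loci as pair-valued features?
#' @param priors optional named haplogroup prior weights (default uniform).
#' @return an object of class `hg_freq_model`.
#' @seealso [predict_haplogroup()]
#' @export
fit_frequency_model <- function(s, pseudocount = 0.5,
                                include_duplicated = FALSE, priors = NULL) {
  stopifnot(inherits(s, "sample_set"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) stopf("pseudocount must be > 0")
  hg <- s$samples$haplogroup
  if (anyNA(hg)) stopf("all training samples need haplogroup labels")
  classes <- sort(unique(hg))
  if (length(classes) < 2) stopf("need at least two haplogroup classes")

  panel <- s$panel
  loci <- panel$locus[include_duplicated | !panel$duplicated]
  state_of <- function(locus, row) {
    v <- s$alleles[row, locus_columns(panel, locus)]
    if (anyNA(v)) return(NA_character_)
    paste(v, collapse = "|")
  }
  freq <- list()
  for (loc in loci) {
    states <- vapply(seq_len(nsamples(s)), function(i) state_of(loc, i), "")
    seen <- sort(unique(states[!is.na(states)]))
    if (length(seen) == 0) next
    counts <- matrix(0, length(classes), length(seen),
                     dimnames = list(classes, seen))
    ok <- !is.na(states)
    tb <- table(factor(hg[ok], levels = classes), factor(states[ok], levels = seen))
    counts[] <- as.numeric(tb)
    n_cl <- rowSums(counts)
    f <- (counts + pseudocount) / (n_cl + pseudocount * length(seen))
    freq[[loc]] <- list(f = f, A = length(seen), n = n_cl)
  }
  if (is.null(priors)) priors <- setNames(rep(1, length(classes)), classes)
  if (!all(classes %in% names(priors))) stopf("priors must cover every haplogroup class")
  priors <- priors[classes] / sum(priors[classes])
  structure(list(haplogroups = classes, priors = priors,
                 pseudocount = pseudocount, loci = names(freq), freq = freq),
            class = "hg_freq_model")
}

#' Posterior haplogroup probabilities for a Y-STR haplotype
#'
#' Applies Bayes' rule with the naive per-locus independence assumption:
#' `P(hg | h) proportional to prior(hg) * prod_l f(a_l | hg, l)`, computed in
#' log space. Loci missing from the haplotype (or from the model) are
#' skipped; an allele state never seen in training receives its smoothing
#' mass `c / (n_hg,l + c * A_l)`.
#'
#' @param model an [fit_frequency_model()] fit.
#' @param h a [haplotype()], a named numeric vector, or a named list of
#'   states (pairs allowed for duplicated loci).
#' @return data frame of `haplogroup` and `posterior`, sorted decreasing,
#'   with the predicted class in `attr(, "haplogroup")`.
#' @export
predict_haplogroup <- function(model, h) {
  stopifnot(inherits(model, "hg_freq_model"))
  if (!inherits(h, "haplotype")) h <- haplotype(h)
  logp <- log(model$priors)
  used <- 0L
  for (loc in intersect(names(h), model$loci)) {
    v <- h[[loc]]
    if (anyNA(v)) next
    key <- paste(if (length(v) == 2) sort(v) else v, collapse = "|")
    entry <- model$freq[[loc]]
    f <- if (key %in% colnames(entry$f)) entry$f[, key]
         else model$pseudocount / (entry$n + model$pseudocount * entry$A)
    logp <- logp + log(f)
    used <- used + 1L
  }
  if (used == 0L) stopf("haplotype shares no typed loci with the model")
  post <- exp(logp - logsumexp(logp))
  out <- data.frame(haplogroup = model$haplogroups, posterior = unname(post),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$posterior, out$haplogroup), ]
  rownames(out) <- NULL
  attr(out, "haplogroup") <- out$haplogroup[1]
  attr(out, "loci_used") <- used
  out
}

#' Serialize / restore a frequency model as JSON
#' @param model an `hg_freq_model`.
#' @param path file path.
#' @return `path` invisibly; `read_frequency_model()` returns the model.
#' @rdname frequency_model_io
#' @export
write_frequency_model <- function(model, path) {
  stopifnot(inherits(model, "hg_freq_model"))
  payload <- list(
    haplogroups = model$haplogroups,
    priors = as.list(model$priors),
    pseudocount = model$pseudocount,
    loci = model$loci,
    freq = lapply(model$freq, function(e)
      list(states = colnames(e$f), f = unclass(e$f), A = e$A, n = as.list(e$n))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname frequency_model_io
#' @export
read_frequency_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- lapply(p$freq, function(e) {
    f <- as.matrix(e$f)
    colnames(f) <- e$states
    list(f = f, A = e$A, n = unlist(e$n))
  })
  structure(list(haplogroups = p$haplogroups,
                 priors = unlist(p$priors),
                 pseudocount = p$pseudocount,
                 loci = p$loci, freq = freq),
            class = "hg_freq_model")
}
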