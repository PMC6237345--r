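#' Haplogroup composition of the Tolima-Huila study design
#'
#' The published per-department haplogroup counts (16 sublineages, n = 83;
#' 42 Huila + 41 Tolima chromosomes) together with the published number of
#' distinct haplotypes per haplogroup (77 in total). This table is the
#' default composition emulated by [simulate_study_like()] and the input for
#' the pooled-region haplogroup diversity computation.
#'
#' @return data frame with columns `haplogroup`, `huila`, `tolima`, `total`,
#'   `distinct`.
#' @examples
#' comp <- study_haplogroup_composition()
#' sum(comp$total)     # 83
#' sum(comp$distinct)  # 77
#' nei_diversity(comp$total)
#' @export
study_haplogroup_composition <- function() {
  data.frame(
    haplogroup = c("E1b1b-M78", "E1b1b-M81", "E1b1b-M123", "G-M201",
                   "J1-M267", "J2a-M410*(xM67,M92)", "J2a-M67*(xM92)",
                   "Q1a2-M346*(xM3)", "Q1a2-M3*(xM19,M194,M199)",
                   "R1b-U106", "R1b-S116*(xU152,M529,M65,M153,M167)",
                   "R1b-U152", "R1b-M529", "R1b-M153", "R1b-M167", "T-M70"),
    huila   = c(2, 1, 1, 3, 1, 0, 1, 3, 4, 1, 12, 2, 6, 1, 1, 3),
    tolima  = c(1, 3, 0, 0, 1, 2, 0, 4, 3, 3, 14, 3, 3, 0, 2, 2),
    total   = c(3, 4, 1, 3, 2, 2, 1, 7, 7, 4, 26, 5, 9, 1, 3, 5),
    distinct = c(2, 3, 1, 3, 2, 2, 1, 5, 7, 3, 25, 5, 9, 1, 3, 5),
    stringsAsFactors = FALSE)
}

#' Default founder haplotype for simulations
#'
#' A typical Yfiler profile used as the simulation root; values are
#' plausible modal repeat counts, synthetic by construction.
#'
#' @param panel a [locus_panel()]; supported are the full and normalized
#'   Yfiler panels from [yfiler_panel()].
#' @return named numeric vector over the panel's storage columns.
#' @export
default_founder_haplotype <- function(panel = yfiler_panel()) {
  full <- c(DYS19 = 14, DYS389I = 13, DYS389II = 29, DYS390 = 24, DYS391 = 11,
            DYS392 = 13, DYS393 = 13, DYS385.a = 11, DYS385.b = 14,
            DYS438 = 12, DYS439 = 12, DYS437 = 15, DYS448 = 19, DYS456 = 15,
            DYS458 = 17, DYS635 = 23, YGATAH4 = 12, `DYS389II-I` = 16)
  cols <- allele_columns(panel)
  if (!all(cols %in% names(full)))
    stopf("no default founder for loci: %s",
          paste(setdiff(cols, names(full)), collapse = ", "))
  full[cols]
}

#' Uniform effective-rate simulation panel
#'
#' The normalized Yfiler loci with the single effective dating rate
#' `6.9e-4` mutations/locus/25 years at every locus: the default generating
#' panel for the simulators, under which the rho clock assumptions hold
#' exactly. Pass a heterogeneous-rate panel to study rate variation.
#'
#' @param mu effective rate applied to every locus.
#' @return a [locus_panel()].
#' @export
uniform_rate_panel <- function(mu = 6.9e-4) {
  p <- yfiler_panel(normalized = TRUE)
  locus_panel(p$locus, rate = rep(mu, nrow(p)), rate_units = "per_25y")
}

# per-column mutation probabilities proportional to locus rates (a duplicated
# locus splits its rate across its two copies)
column_probs <- function(panel) {
  p <- unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$duplicated[i]) rep(panel$rate[i] / 2, 2) else panel$rate[i]
  }))
  p / sum(p)
}

# apply k single-step mutations to one expanded allele row; reflecting lower
# boundary at allele 1 (a -1 step from allele 1 is redrawn as +1)
apply_mutations <- function(row, k, probs, forbid = integer(0)) {
  if (k == 0) return(row)
  p <- probs
  if (length(forbid)) p[forbid] <- 0
  cols <- sample.int(length(row), k, replace = TRUE, prob = p)
  steps <- sample(c(-1, 1), k, replace = TRUE)
  for (m in seq_len(k)) {
    j <- cols[m]
    nv <- row[j] + steps[m]
    if (!is.na(nv) && nv < 1) nv <- row[j] + 1
    row[j] <- nv
  }
  row
}

# restore sorted unordered pairs after mutation
resort_pairs <- function(A, panel) {
  for (loc in panel$locus[panel$duplicated]) {
    pc <- locus_columns(panel, loc)
    A[, pc] <- t(apply(A[, pc, drop = FALSE], 1, sort, na.last = TRUE))
  }
  A
}

#' Simulate a star genealogy under the stepwise mutation model
#'
#' Each of `n` lineages descends independently from the founder over
#' `age_years` years; its mutation count is Poisson with mean
#' `L * mu * age_years / generation_years`, mutations hit loci with
#' probability proportional to the panel rates and move the repeat count by
#' one step up or down with equal probability (reflecting at allele 1).
#' This is the generating model under which the rho statistic is an unbiased
#' clock, so it is the reference scenario for validating founder dating.
#'
#' @param n number of chromosomes.
#' @param age_years true age of the star radiation.
#' @param panel a [locus_panel()] (default: normalized Yfiler).
#' @param founder founder haplotype (named vector over storage columns).
#' @param mu effective mutation rate per locus per `generation_years` years.
#' @param generation_years calendar span of `mu` (default 25).
#' @param haplogroup,population,department labels for the records.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return a [sample_set()]; the per-lineage mutation counts are in
#'   `attr(, "n_mutations")`.
#' @examples
#' s <- simulate_star(n = 25, age_years = 1809, seed = 1)
#' tmrca_dating(s)
#' @export
simulate_star <- function(n, age_years = 1809,
                          panel = uniform_rate_panel(),
                          founder = default_founder_haplotype(panel),
                          mu = 6.9e-4, generation_years = 25,
                          haplogroup = "Q-M242*(xM3)", population = "Sim",
                          department = NA_character_, seed = NULL) {
  stopifnot(is_count(n), n >= 1, age_years >= 0)
  L <- nrow(panel)
  probs <- column_probs(panel)
  lambda <- L * mu * age_years / generation_years
  with_seed(seed, {
    k <- stats::rpois(n, lambda)
    A <- t(vapply(seq_len(n), function(i)
      apply_mutations(founder, k[i], probs), founder))
    A <- resort_pairs(A, panel)
    s <- sample_set(panel,
                    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                               population = population, department = department,
                               haplogroup = haplogroup),
                    A, max_missing = L)
    attr(s, "n_mutations") <- k
    s
  })
}

#' Simulate a Kingman coalescent sample under the stepwise mutation model
#'
#' Draws an n-coalescent genealogy (exponential waiting times; tree from
#' `ape::rcoal`, whose depths are in units of the pairwise coalescent
#' expectation and are rescaled so that `E[TMRCA]` for `n = 2` equals `Ne`
#' generations), then places mutations on branches as Poisson processes with
#' the per-locus rates and applies them as single repeat steps.
#' Coalescent genealogies are non-star, so rho dating on them illustrates
#' the scatter and bias the star assumption hides.
#'
#' @param n number of chromosomes (>= 2).
#' @param Ne effective (male) population size in generations: the coalescent
#'   time scale.
#' @inheritParams simulate_star
#' @return a [sample_set()] with the genealogy in `attr(, "tree")`.
#' @export
simulate_coalescent <- function(n, Ne = 500,
                                panel = uniform_rate_panel(),
                                founder = default_founder_haplotype(panel),
                                mu = 6.9e-4, generation_years = 25,
                                haplogroup = "Sim", population = "Sim",
                                department = NA_character_, seed = NULL) {
  if (!is_count(n) || n < 2) stopf("coalescent simulation needs n >= 2")
  L <- nrow(panel)
  probs <- column_probs(panel)
  with_seed(seed, {
    tree <- ape::rcoal(n)
    # branch lengths -> years: coalescent units * Ne generations * years/gen
    len_years <- tree$edge.length * Ne * generation_years
    ord <- rev(ape::postorder(tree))  # root-to-tip edge order
    n_nodes <- max(tree$edge)
    states <- vector("list", n_nodes)
    root <- n + 1L
    states[[root]] <- founder
    for (e in ord) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      k <- stats::rpois(1, L * mu * len_years[e] / generation_years)
      states[[child]] <- apply_mutations(states[[parent]], k, probs)
    }
    A <- do.call(rbind, states[seq_len(n)])
    A <- resort_pairs(A, panel)
    s <- sample_set(panel,
                    data.frame(sample_id = sprintf("C%03d", seq_len(n)),
                               population = population, department = department,
                               haplogroup = haplogroup),
                    A, max_missing = L)
    attr(s, "tree") <- tree
    attr(s, "tmrca_years") <- max(ape::branching.times(tree)) * Ne * generation_years
    s
  })
}

#' Simulate a study-like Y-STR data set
#'
#' Emulates the structure of the Tolima-Huila sample: 83 chromosomes in 16
#' haplogroups with the published composition, per-haplogroup founder
#' haplotypes separated by at least `founder_min_steps` mutational steps,
#' within-haplogroup stepwise-mutation diversification reproducing the
#' published number of distinct haplotypes per haplogroup (multiplicities
#' follow the most-even partition, which reproduces every published
#' per-haplogroup diversity value), a Q1a2-M346*(xM3) lineage cluster fixed
#' for the globally rare DYS391 allele 6, and department labels assigned at
#' random (no population structure, the null AMOVA scenario).
#'
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @param composition a composition table as returned by
#'   [study_haplogroup_composition()].
#' @param panel a [locus_panel()] (default full Yfiler).
#' @param founder_min_steps minimum stepwise separation between haplogroup
#'   founders (default 5).
#' @param max_variant_steps maximum mutational steps of a within-haplogroup
#'   variant from its founder (default 2, keeping haplogroups separated).
#' @param dys391_allele allele fixed at DYS391 in the Q1a2-M346*(xM3)
#'   cluster (default 6).
#' @return a [sample_set()]; founder haplotypes in `attr(, "founders")`.
#' @examples
#' s <- simulate_study_like(seed = 1)
#' nsamples(s)                                 # 83
#' length(haplotype_multiplicities(s))         # 77
#' @export
simulate_study_like <- function(seed = NULL,
                                composition = study_haplogroup_composition(),
                                panel = yfiler_panel(),
                                founder_min_steps = 5L,
                                max_variant_steps = 2L,
                                dys391_allele = 6) {
  stopifnot(is.data.frame(composition),
            all(c("haplogroup", "huila", "tolima", "total", "distinct") %in%
                  names(composition)))
  if (!all(composition$huila + composition$tolima == composition$total))
    stopf("composition department counts do not sum to the totals")
  if (any(composition$distinct > composition$total) || any(composition$distinct < 1))
    stopf("distinct counts must be in [1, total]")
  cols <- allele_columns(panel)
  base <- default_founder_haplotype(panel)
  probs <- column_probs(panel)
  single_cols <- which(cols %in% panel$locus[!panel$duplicated])
  dys391_col <- match("DYS391", cols)
  q_group <- grepl("^Q1a2-M346", composition$haplogroup)

  with_seed(seed, {
    # founders: random sparse offsets, enforced minimum mutual separation
    founders <- matrix(NA_real_, nrow(composition), length(cols),
                       dimnames = list(composition$haplogroup, cols))
    for (g in seq_len(nrow(composition))) {
      repeat {
        f <- base
        off_cols <- sample(setdiff(single_cols, dys391_col), 6)
        f[off_cols] <- f[off_cols] + sample(c(-2, -1, 1, 2), 6, replace = TRUE)
        if (q_group[g]) f[dys391_col] <- dys391_allele
        ok <- TRUE
        if (g > 1) {
          d <- rowSums(abs_steps_row(founders[seq_len(g - 1), , drop = FALSE], f))
          ok <- all(d >= founder_min_steps)
        }
        if (ok && all(f >= 1)) { founders[g, ] <- f; break }
      }
    }

    rows <- list(); meta <- list()
    for (g in seq_len(nrow(composition))) {
      n_g <- composition$total[g]; k_g <- composition$distinct[g]
      # most-even multiplicity partition of n_g into k_g classes
      part <- rep(floor(n_g / k_g), k_g)
      if (n_g %% k_g) part[seq_len(n_g %% k_g)] <- part[seq_len(n_g %% k_g)] + 1
      forbid <- if (q_group[g]) dys391_col else integer(0)
      variants <- matrix(founders[g, ], 1, length(cols), byrow = TRUE)
      colnames(variants) <- cols
      keys <- paste(variants[1, ], collapse = "/")
      while (nrow(variants) < k_g) {
        k_mut <- sample.int(max_variant_steps, 1,
                            prob = 0.7^seq_len(max_variant_steps))
        v <- apply_mutations(founders[g, ], k_mut, probs, forbid = forbid)
        v <- resort_pairs(matrix(v, 1, dimnames = list(NULL, cols)), panel)[1, ]
        key <- paste(v, collapse = "/")
        if (!key %in% keys) {
          variants <- rbind(variants, v)
          keys <- c(keys, key)
        }
      }
      for (v in seq_len(k_g)) {
        rows[[length(rows) + 1]] <-
          variants[rep(v, part[v]), , drop = FALSE]
        meta[[length(meta) + 1]] <-
          data.frame(haplogroup = composition$haplogroup[g],
                     n = part[v], stringsAsFactors = FALSE)
      }
    }
    A <- do.call(rbind, rows)
    hg <- unlist(lapply(meta, function(m) rep(m$haplogroup, m$n)))
    n <- nrow(A)
    departments <- sample(c(rep("Huila", sum(composition$huila)),
                            rep("Tolima", sum(composition$tolima))))
    s <- sample_set(panel,
                    data.frame(sample_id = sprintf("TH%03d", seq_len(n)),
                               population = "Tolima-Huila",
                               department = departments,
                               haplogroup = hg),
                    A, max_missing = nrow(panel))
    attr(s, "founders") <- founders
    s
  })
}

#' Bundle simulation settings
#'
#' Light-weight validated configuration for the generators, convenient for
#' scripted runs: `simulate(config)` dispatches on the genealogy.
#'
#' @param genealogy `"star"`, `"coalescent"` or `"study"`.
#' @param n_samples number of chromosomes (ignored for `"study"`, which
#'   takes its size from the composition).
#' @param true_age_years star radiation age.
#' @param Ne coalescent time scale (generations).
#' @param seed RNG seed.
#' @param ... further arguments passed to the generator.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genealogy = c("star", "coalescent", "study"),
                       n_samples = 25, true_age_years = 1809, Ne = 500,
                       seed = NULL, ...) {
  genealogy <- match.arg(genealogy)
  if (true_age_years < 0) stopf("true_age_years must be >= 0")
  structure(list(genealogy = genealogy, n_samples = n_samples,
                 true_age_years = true_age_years, Ne = Ne, seed = seed,
                 extra = list(...)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @export
simulate_sampleset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  args <- config$extra
  switch(config$genealogy,
         star = do.call(simulate_star,
                        c(list(n = config$n_samples,
                               age_years = config$true_age_years,
                               seed = config$seed), args)),
         coalescent = do.call(simulate_coalescent,
                              c(list(n = config$n_samples, Ne = config$Ne,
                                     seed = config$seed), args)),
         study = do.call(simulate_study_like,
                         c(list(seed = config$seed), args)))
}
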