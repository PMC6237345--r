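#' Run the full lineage-analysis pipeline
#'
#' Executes the study analysis order on one haplotype table: read/convert,
#' haplogroup frequency and diversity tables, AMOVA between groups,
#' normalization, median-joining network and rho/TMRCA dating of a
#' designated lineage subset, and (when at least three populations are
#' available) PCA of haplogroup frequencies. All artifacts are written under
#' `output_dir` (TSV for human tables, JSON for numbers, GraphML for the
#' network) together with a run manifest recording the package version,
#' seeds, parameters and an input digest, so that a rerun with the same seed
#' is byte-identical.
#'
#' @param input path to a haplotype table (see [read_haplotype_table()]) or a
#'   [sample_set()].
#' @param output_dir output directory (created if needed).
#' @param group_by grouping label for AMOVA (default `"department"`).
#' @param network_subset regular expression selecting the haplogroup subset
#'   whose network and TMRCA are computed (default the DYS391*6 carrier
#'   lineage `"^Q1a2-M346"`); `NULL` uses all samples.
#' @param metric AMOVA distance metric.
#' @param n_perm AMOVA permutations.
#' @param epsilon network link tolerance.
#' @param mu,generation_years dating clock, see [tmrca_years()].
#' @param pca_matrix optional [frequency_matrix()] for the PCA stage; by
#'   default one is built from the input's population labels and the stage
#'   is skipped (recorded in the manifest) when fewer than three populations
#'   are present.
#' @param seed seed for the stochastic stages.
#' @return invisibly, a list with every stage result and the manifest.
#' @examples
#' \donttest{
#' s <- simulate_study_like(seed = 1)
#' out <- run_pipeline(s, tempfile("run"), n_perm = 200, seed = 1)
#' names(out)
#' }
#' @export
run_pipeline <- function(input, output_dir, group_by = "department",
                         network_subset = "^Q1a2-M346",
                         metric = c("mismatch", "stepwise"),
                         n_perm = 10000L, epsilon = 0, mu = 6.9e-4,
                         generation_years = 25, pca_matrix = NULL, seed = 1L) {
  metric <- match.arg(metric)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list()

  res$data <- stage("convert", {
    s <- if (inherits(input, "sample_set")) input else read_haplotype_table(input)
    write_haplotype_table(s, out_path("haplotypes.tsv"))
    s
  })
  s <- res$data

  res$frequencies <- stage("diversity", {
    lf <- lineage_frequencies(s, group_by = group_by)
    utils::write.table(lf, out_path("haplogroup_frequencies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dt <- diversity_table(s, group_by = "haplogroup")
    utils::write.table(dt, out_path("diversity_by_haplogroup.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n = nsamples(s),
           n_distinct = length(haplotype_multiplicities(s)),
           hd_overall = nei_diversity(haplotype_multiplicities(s)),
           hd_haplogroups = nei_diversity(
             as.integer(table(s$samples$haplogroup)))),
      out_path("diversity.json"), digits = NA, auto_unbox = TRUE)
    list(frequencies = lf, diversity = dt)
  })

  res$amova <- stage("amova", {
    a <- amova_fst(s, group_by = group_by, metric = metric, n_perm = n_perm,
                   seed = seed)
    jsonlite::write_json(unclass(a)[c("fst", "var_among", "var_within",
                                      "p_value", "p_se", "n_perm", "metric",
                                      "groups", "group_sizes")],
                         out_path("amova.json"), digits = NA, auto_unbox = TRUE)
    a
  })

  res$normalized <- stage("normalize", normalize_for_network(s))
  sub <- if (is.null(network_subset)) res$normalized
         else subset_samples(res$normalized, network_subset, haplogroup_pattern = TRUE)

  res$network <- stage("network", {
    net <- build_mj_network(sub, epsilon = epsilon)
    export_network(net, out_path("network.graphml"), format = "graphml")
    export_network(net, out_path("network_edges.tsv"), format = "edgelist")
    net
  })

  res$tmrca <- stage("tmrca", {
    tm <- tmrca_dating(sub, mu = mu, generation_years = generation_years)
    jsonlite::write_json(
      list(n = nsamples(sub), subset = network_subset %||% "all",
           rho = tm$rho, sigma_rho = tm$sigma_rho, L = tm$L, mu = tm$mu,
           years = tm$years, years_se = tm$years_se,
           ancestor = as.list(tm$ancestor)),
      out_path("tmrca.json"), digits = NA, auto_unbox = TRUE)
    tm
  })

  res$pca <- stage("pca", {
    m <- pca_matrix %||% tryCatch(haplogroup_frequency_matrix(s, by = "population"),
                                  error = function(e) NULL)
    if (is.null(m) || nrow(m) < 3) {
      "skipped: fewer than 3 populations"
    } else {
      p <- pca_populations(m)
      utils::write.table(cbind(population = rownames(p$scores),
                               as.data.frame(p$scores)),
                         out_path("pca_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(var_fraction = p$var_fraction,
                                pc12_percent = 100 * sum(p$var_fraction[1:2])),
                           out_path("pca.json"), digits = NA, auto_unbox = TRUE)
      p
    }
  })

  manifest <- list(
    package = "ylineage",
    version = as.character(utils::packageVersion("ylineage")),
    seed = seed, n_perm = n_perm, metric = metric, epsilon = epsilon,
    mu = mu, generation_years = generation_years,
    group_by = group_by, network_subset = network_subset %||% "all",
    n_samples = nsamples(s),
    input_digest = str_digest(apply(s$alleles, 1, paste, collapse = "/")),
    pca = if (is.character(res$pca)) res$pca else "computed",
    files = sort(list.files(output_dir)))
  jsonlite::write_json(manifest, out_path("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
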