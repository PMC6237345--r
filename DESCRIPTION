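Package: ylineage
Title: Y-Chromosome STR Lineage Analysis: Diversity, AMOVA, Median-Joining
    Networks and Rho-Statistic Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of Y-chromosome
    short tandem repeat (Y-STR) haplotypes from the 17-locus Yfiler panel.
    Reads and writes YHRD-style tab-delimited haplotype tables (including the
    duplicated DYS385 locus and the DYS389I/II nesting), computes Nei unbiased
    haplotype diversity and per-haplogroup descriptive statistics, runs
    one-level analyses of molecular variance (AMOVA) with permutation tests,
    builds weighted median-joining haplotype networks with mutation-rate
    derived locus weights, dates founder lineages with the rho statistic under
    a stepwise mutation model, predicts haplogroups from Y-STR alleles with a
    naive-Bayes frequency model, ordinates population-by-haplogroup frequency
    matrices by principal component analysis, and simulates study-like data
    sets (star and coalescent genealogies under the stepwise mutation model)
    so that every stage can be exercised without access to restricted
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
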