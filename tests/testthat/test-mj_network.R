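# independent oracles for the network tests -----------------------------------

# weighted L1 distance matrix, plain double loop
oracle_dist <- function(A, w = rep(1, ncol(A))) {
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    D[i, j] <- sum(w * ylineage::step_count(A[i, ], A[j, ]))
  D
}

# MSN membership by its defining property: (i,j) is an MSN link iff i and j
# are not connected using only strictly shorter links
oracle_msn <- function(D) {
  n <- nrow(D)
  out <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    adj <- D < d; diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    out[i, j] <- !(igraph::components(g)$membership[i] ==
                     igraph::components(g)$membership[j])
  }
  out
}

oracle_mst_cost <- function(A, w = rep(1, ncol(A))) {
  D <- oracle_dist(A, w)
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE, mode = "undirected")
  sum(igraph::E(igraph::mst(g))$weight)
}

net_allele_matrix <- function(net) net$alleles

# -----------------------------------------------------------------------------

test_that("locus weights map inverse rates onto [3, 10]", {
  expect_equal(assign_weights(rep(2e-3, 5)), rep(10L, 5))
  expect_equal(assign_weights(c(1e-3, 2e-3)), c(10L, 3L))
  set.seed(1)
  r <- runif(12, 5e-4, 8e-3)
  w <- assign_weights(r)
  expect_true(all(w >= 3 & w <= 10))
  expect_equal(w[which.max(r)], 3L)
  expect_equal(w[which.min(r)], 10L)
  # monotone: faster locus never outweighs a slower one
  ord <- order(r)
  expect_true(all(diff(w[ord]) <= 0))
  expect_error(assign_weights(c(1e-3, 0)), "positive")
})

test_that("identical haplotypes collapse into multiplicity-weighted nodes", {
  A <- matrix(rep(c(14, 10), each = 6), 6)
  cc <- collapse_identical(A)
  expect_equal(nrow(cc$alleles), 1)
  expect_equal(cc$multiplicity, 6L)
  B <- matrix(c(14, 10, 15, 11, 16, 12), 3, byrow = TRUE)
  expect_equal(collapse_identical(B)$multiplicity, rep(1L, 3))
  s <- simulate_study_like(seed = 2)
  cc2 <- collapse_identical(normalize_for_network(s))
  expect_equal(sum(cc2$multiplicity), 83)
  expect_match(cc2$composition[1], "Tolima-Huila:")
})

test_that("two haplotypes one step apart give a bare two-node network", {
  net <- build_mj_network(rbind(c(14, 10), c(14, 11)))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_equal(net$edges$cost, 1)
})

test_that("a triplet whose median is observed stays a star", {
  net <- build_mj_network(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_equal(nrow(net$edges), 2)  # the 2-step diagonal is not a minimal link
})

test_that("the classic three-haplotype instance gains its unique median vector", {
  A <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  net <- build_mj_network(A)
  med <- net$alleles[net$nodes$type == "median", , drop = FALSE]
  expect_equal(nrow(med), 1)
  expect_equal(unname(med[1, ]), c(1, 0, 0))
  expect_equal(sum(net$edges$cost), 3)  # down from the 4-cost MST
  # exhaustive grid search confirms (1,0,0) is the only improving Steiner point
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  base <- oracle_mst_cost(A)
  improving <- grid[apply(grid, 1, function(v)
    oracle_mst_cost(rbind(A, v)) < base - 1e-9), , drop = FALSE]
  expect_equal(unname(improving), matrix(c(1, 0, 0), 1))
})

test_that("small random networks match the exhaustive-search oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:5, 1); L <- sample(2:4, 1)
    A <- unique(matrix(sample(0:3, n * L, replace = TRUE), n))
    if (nrow(A) < 3) next
    w <- sample(1:3, L, replace = TRUE)
    net <- build_mj_network(A, weights = w)
    Af <- net_allele_matrix(net)

    # (1) the emitted edge set is exactly the MSN of the final node set
    D <- oracle_dist(Af, w)
    want <- oracle_msn(D)
    got <- matrix(FALSE, nrow(Af), nrow(Af))
    idx <- cbind(match(net$edges$from, rownames(Af)),
                 match(net$edges$to, rownames(Af)))
    got[idx] <- TRUE; got <- got | t(got); got[lower.tri(got)] <- FALSE
    expect_equal(got, want)

    # (2) all observed haplotypes are present and connected
    obs_keys <- apply(A, 1, paste, collapse = "/")
    fin_keys <- apply(Af, 1, paste, collapse = "/")
    expect_true(all(obs_keys %in% fin_keys))
    g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                       vertices = net$nodes$id)
    expect_equal(igraph::components(g)$no, 1)

    # (3) median vectors never increase the minimum spanning cost
    expect_lte(oracle_mst_cost(Af, w), oracle_mst_cost(A, w))

    # (4) fixpoint under exhaustive grid Steiner search within allele ranges
    rng <- apply(A, 2, range)
    grid <- as.matrix(expand.grid(lapply(seq_len(L), function(k)
      rng[1, k]:rng[2, k])))
    base <- oracle_mst_cost(Af, w)
    for (r in seq_len(nrow(grid))) {
      if (paste(grid[r, ], collapse = "/") %in% fin_keys) next
      expect_gte(oracle_mst_cost(rbind(Af, grid[r, ]), w), base - 1e-9)
    }
  }
})

test_that("epsilon-0 networks are subgraphs of epsilon-1 networks", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- unique(matrix(sample(0:4, 5 * 3, replace = TRUE), 5))
    n0 <- build_mj_network(A, epsilon = 0)
    n1 <- build_mj_network(A, epsilon = 1)
    expect_identical(n0$nodes$label, n1$nodes$label)
    e0 <- paste(n0$edges$from, n0$edges$to)
    e1 <- paste(n1$edges$from, n1$edges$to)
    expect_true(all(e0 %in% e1))
  }
})

test_that("the network is invariant to input row order", {
  set.seed(12)
  A <- unique(matrix(sample(0:3, 5 * 3, replace = TRUE), 5))
  n1 <- build_mj_network(A)
  n2 <- build_mj_network(A[rev(seq_len(nrow(A))), ])
  expect_identical(n1$nodes$label, n2$nodes$label)
  expect_identical(n1$edges[c("from", "to", "cost")],
                   n2$edges[c("from", "to", "cost")])
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  s <- normalize_for_network(simulate_study_like(seed = 8))
  q <- subset_samples(s, "^Q1a2-M346", haplogroup_pattern = TRUE)
  net <- build_mj_network(q)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(sort(igraph::V(g)$multiplicity), sort(net$nodes$multiplicity))
  expect_true(igraph::isomorphic(g, as_igraph(net)))
  # median vectors export with multiplicity 0
  A3 <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(build_mj_network(A3), f2)
  g2 <- read_network(f2)
  expect_equal(igraph::V(g2)$multiplicity[igraph::V(g2)$type == "median"], 0)
  # other formats write without error
  f3 <- withr::local_tempfile(fileext = ".dot")
  expect_silent(export_network(net, f3, format = "dot"))
  f4 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f4, format = "edgelist")
  expect_true(file.exists(sub("\\.tsv$", "_nodes.tsv", f4)))
})

test_that("duplicated loci are refused until normalized", {
  s <- simulate_study_like(seed = 1)
  expect_error(build_mj_network(s), "normalize_for_network")
  expect_error(collapse_identical(s), "normalize_for_network")
})
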