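#' Map mutation rates to integer network locus weights
#'
#' Slowly mutating loci carry more phylogenetic signal, so median-joining
#' networks down-weight fast loci. Inverse rates are mapped affinely onto the
#' conventional integer range `[3, 10]` (slowest locus 10, fastest 3) with
#' half-up rounding; a degenerate panel where all rates are equal maps to the
#' top of the range.
#'
#' @param rates strictly positive per-locus mutation rates.
#' @return integer weights in `[3, 10]`, monotone non-increasing in rate.
#' @examples
#' assign_weights(c(1e-3, 2e-3))   # 10, 3
#' assign_weights(rep(2e-3, 4))    # all 10
#' @export
assign_weights <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) == 0 || anyNA(rates) || any(rates <= 0))
    stopf("mutation rates must be strictly positive")
  inv <- 1 / rates
  span <- max(inv) - min(inv)
  if (span == 0) return(rep(10L, length(rates)))
  as.integer(floor(3 + 7 * (inv - min(inv)) / span + 0.5))
}

#' Collapse identical haplotypes into weighted nodes
#'
#' Groups identical rows of a normalized (single-copy) haplotype set into
#' network nodes with multiplicities and, for sample sets, a population
#' composition annotation per node.
#'
#' @param x a [sample_set()] on a single-copy panel, or a numeric matrix.
#' @param by metadata column used for the composition annotation.
#' @return list with `alleles` (unique rows, lexicographic order),
#'   `multiplicity`, `composition` (e.g. `"Huila:2;Tolima:1"`, `NA` for bare
#'   matrices) and `sample_ids`.
#' @export
collapse_identical <- function(x, by = "population") {
  if (inherits(x, "sample_set")) {
    if (any(x$panel$duplicated))
      stopf("collapse_identical expects a normalized single-copy panel; run normalize_for_network() first")
    A <- x$alleles
    labels <- x$samples[[by]]
    ids <- x$samples$sample_id
  } else {
    A <- as.matrix(x)
    labels <- rep(NA_character_, nrow(A))
    ids <- rownames(A) %||% paste0("h", seq_len(nrow(A)))
  }
  if (nrow(A) == 0) stopf("empty input")
  keys <- apply(A, 1, paste, collapse = "/")
  ord <- do.call(order, as.data.frame(A))
  first <- ord[!duplicated(keys[ord])]
  uk <- keys[first]
  mult <- as.integer(table(keys)[uk])
  comp <- vapply(uk, function(k) {
    lab <- labels[keys == k]
    if (all(is.na(lab))) return(NA_character_)
    tb <- table(lab)
    paste(sprintf("%s:%d", names(tb), tb), collapse = ";")
  }, "", USE.NAMES = FALSE)
  list(alleles = A[first, , drop = FALSE], multiplicity = mult,
       composition = comp,
       sample_ids = lapply(uk, function(k) ids[keys == k]))
}

# ---- internal graph primitives (hand-rolled so that igraph can serve as an
# ---- independent oracle in the tests) ----

# weighted stepwise distance matrix between rows of A
wdist <- function(A, weights) {
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (k in seq_len(ncol(A))) {
    v <- A[, k]
    D <- D + weights[k] * outer(v, v, step_count)
  }
  D
}

# Prim MST: list(edges = matrix(i, j, w), cost)
prim_mst <- function(D) {
  n <- nrow(D)
  if (n == 1) return(list(edges = matrix(numeric(0), 0, 3), cost = 0))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]; parent <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (it in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[it, ] <- c(parent[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]; parent[upd] <- v
  }
  list(edges = edges, cost = sum(edges[, 3]))
}

# minimax path weights over the MST (max edge along the unique tree path)
minimax_matrix <- function(n, mst_edges) {
  lam <- matrix(0, n, n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mst_edges))) {
    i <- mst_edges[r, 1]; j <- mst_edges[r, 2]; w <- mst_edges[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  for (src in seq_len(n)) {
    visited <- rep(FALSE, n); visited[src] <- TRUE
    stack <- list(c(src, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1]; mx <- top[2]
      lam[src, v] <- mx
      nb <- adj[[v]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!visited[u]) {
          visited[u] <- TRUE
          stack[[length(stack) + 1]] <- c(u, max(mx, nb[r, 2]))
        }
      }
    }
  }
  lam
}

# minimum spanning network with tolerance eps:
# keep (i, j) iff d_ij <= minimax_ij + eps  (eps = 0 gives the classical MSN)
msn_edges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n == 1) return(matrix(numeric(0), 0, 3))
  lam <- minimax_matrix(n, prim_mst(D)$edges)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= lam[i, j] + eps) out <- rbind(out, c(i, j, D[i, j]))
  out
}

# Kruskal forest cost over an explicit edge list on n vertices
kruskal_cost <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  cost <- 0; used <- 0
  for (r in order(edges[, 3])) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) { parent[a] <- b; cost <- cost + edges[r, 3]; used <- used + 1 }
    if (used == n - 1) break
  }
  cost
}

# componentwise medians of all triplets of rows of A, deduplicated, excluding
# vectors already present
triplet_medians <- function(A) {
  n <- nrow(A)
  if (n < 3) return(A[0, , drop = FALSE])
  idx <- utils::combn(n, 3)
  A1 <- A[idx[1, ], , drop = FALSE]
  A2 <- A[idx[2, ], , drop = FALSE]
  A3 <- A[idx[3, ], , drop = FALSE]
  M <- A1 + A2 + A3 - pmax(A1, A2, A3) - pmin(A1, A2, A3)
  keys <- apply(M, 1, paste, collapse = "/")
  have <- apply(A, 1, paste, collapse = "/")
  keep <- !duplicated(keys) & !(keys %in% have)
  M[keep, , drop = FALSE]
}

#' Build a weighted median-joining haplotype network
#'
#' Implements the median-joining procedure over a set of observed haplotype
#' nodes under the weighted stepwise distance
#' `d(a, b) = sum_l w_l * steps(a_l, b_l)`:
#' minimum-spanning-network links (all ties at the minimal connecting cost
#' retained), iterative addition of median (quasi-median) vectors —
#' componentwise medians of node triplets, accepted while they strictly
#' reduce the minimum-spanning cost of the node set, best reduction first
#' with lexicographic tie-breaking — and removal of obsolete median vectors
#' (degree at most one, or lying on no shortest path between observed
#' nodes). The tolerance `epsilon` relaxes link retention: an edge is kept
#' when its cost is within `epsilon` of the minimal connection cost between
#' its endpoints, so `epsilon = 0` networks are subgraphs of `epsilon = 1`
#' networks on the same input. Nodes are processed in canonical lexicographic
#' order, making the result independent of input order.
#'
#' @param x a normalized [sample_set()], the node list from
#'   [collapse_identical()], or a numeric haplotype matrix.
#' @param weights integer per-locus weights; defaults to
#'   [assign_weights()] on the panel rates for sample sets, unit weights for
#'   bare matrices.
#' @param epsilon non-negative link-retention tolerance (default 0, the
#'   usual default of median-joining software).
#' @param mp_prune optional maximum-parsimony post-pruning: keep only links
#'   that occur in at least one minimum spanning tree (default off).
#' @param max_nodes safety cap on total node count.
#' @return an object of class `mj_network` with elements `nodes` (data frame:
#'   `id`, `type`, `multiplicity`, `composition`, `label`), `alleles`,
#'   `edges` (data frame: `from`, `to`, `cost`, `steps`, `loci`), `weights`,
#'   `epsilon`, `provenance`.
#' @examples
#' A <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
#' net <- build_mj_network(A)
#' net$nodes  # one median vector (1,0,0) added
#' @export
build_mj_network <- function(x, weights = NULL, epsilon = 0, mp_prune = FALSE,
                             max_nodes = 500L) {
  if (epsilon < 0) stopf("epsilon must be non-negative")
  if (inherits(x, "sample_set")) {
    if (any(x$panel$duplicated))
      stopf("network construction needs a single-copy panel; run normalize_for_network() first")
    weights <- weights %||% x$panel$weight
    nodes <- collapse_identical(x)
    loci <- x$panel$locus
  } else if (is.list(x) && !is.null(x$alleles) && !is.null(x$multiplicity)) {
    nodes <- x
    loci <- colnames(nodes$alleles) %||% paste0("L", seq_len(ncol(nodes$alleles)))
  } else {
    nodes <- collapse_identical(as.matrix(x))
    loci <- colnames(nodes$alleles) %||% paste0("L", seq_len(ncol(nodes$alleles)))
  }
  A_obs <- nodes$alleles
  if (is.null(weights)) weights <- rep(1L, ncol(A_obs))
  if (length(weights) != ncol(A_obs)) stopf("need one weight per locus")
  n_obs <- nrow(A_obs)

  A <- A_obs
  # --- median-vector search: best strict cost reduction first ---
  repeat {
    if (nrow(A) >= max_nodes) break
    D <- wdist(A, weights)
    base <- prim_mst(D)
    cand <- triplet_medians(A)
    if (nrow(cand) == 0) break
    n <- nrow(A)
    deltas <- vapply(seq_len(nrow(cand)), function(r) {
      dv <- colSums(weights * t(abs_steps_row(A, cand[r, ])))
      edges <- rbind(base$edges, cbind(seq_len(n), n + 1, dv))
      kruskal_cost(n + 1, edges) - base$cost
    }, numeric(1))
    if (min(deltas) >= 0) break
    best <- which(deltas == min(deltas))
    if (length(best) > 1) {
      ord <- do.call(order, as.data.frame(cand[best, , drop = FALSE]))
      best <- best[ord[1]]
    }
    A <- rbind(A, cand[best, , drop = FALSE])
  }

  is_median <- c(rep(FALSE, n_obs), rep(TRUE, nrow(A) - n_obs))

  # --- prune obsolete median vectors ---
  repeat {
    D <- wdist(A, weights)
    E <- msn_edges(D, epsilon)
    deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(A))
    drop <- is_median & deg <= 1
    if (!any(drop)) {
      # shortest-path usefulness: a median must sit on some shortest
      # observed-observed path in the network
      if (any(is_median) && !is.null(E)) {
        g <- igraph::graph_from_data_frame(
          data.frame(from = E[, 1], to = E[, 2]), directed = FALSE,
          vertices = data.frame(name = seq_len(nrow(A))))
        sp <- igraph::distances(g, weights = E[, 3])
        obs_idx <- which(!is_median)
        for (m in which(is_median)) {
          on_path <- FALSE
          for (a in obs_idx) {
            if (any(sp[a, m] + sp[m, obs_idx] <= sp[a, obs_idx] + 1e-9)) {
              on_path <- TRUE; break
            }
          }
          if (!on_path) drop[m] <- TRUE
        }
      }
    }
    if (!any(drop)) break
    A <- A[!drop, , drop = FALSE]
    is_median <- is_median[!drop]
  }

  # --- canonical node order: observed (lexicographic) then medians ---
  lex_rank <- order(do.call(order, as.data.frame(A)))
  ord <- order(is_median, lex_rank)
  A <- A[ord, , drop = FALSE]
  is_median <- is_median[ord]
  n_obs2 <- sum(!is_median)
  # map observed rows back to collapse metadata
  obs_keys <- apply(A_obs, 1, paste, collapse = "/")
  row_keys <- apply(A, 1, paste, collapse = "/")
  obs_match <- match(row_keys, obs_keys)

  D <- wdist(A, weights)
  E <- msn_edges(D, epsilon)
  if (mp_prune && !is.null(E) && nrow(E) > 1) {
    keep <- vapply(seq_len(nrow(E)), function(r) {
      w <- E[r, 3]
      sub <- E[E[, 3] < w, , drop = FALSE]
      if (nrow(sub) == 0) return(TRUE)
      parent <- seq_len(nrow(A))
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (q in seq_len(nrow(sub))) parent[find(sub[q, 1])] <- find(sub[q, 2])
      find(E[r, 1]) != find(E[r, 2])
    }, logical(1))
    E <- E[keep, , drop = FALSE]
  }

  ids <- character(nrow(A))
  ids[!is_median] <- paste0("H", seq_len(n_obs2))
  ids[is_median] <- paste0("mv", seq_len(sum(is_median)))
  lab <- apply(A, 1, function(r) paste(r, collapse = "-"))
  node_df <- data.frame(
    id = ids, type = ifelse(is_median, "median", "observed"),
    multiplicity = ifelse(is_median, 0L, nodes$multiplicity[obs_match]),
    composition = ifelse(is_median, NA_character_, nodes$composition[obs_match]),
    label = lab, stringsAsFactors = FALSE)

  edge_df <- if (is.null(E) || nrow(E) == 0) {
    data.frame(from = character(0), to = character(0), cost = numeric(0),
               steps = numeric(0), loci = character(0))
  } else {
    do.call(rbind, lapply(seq_len(nrow(E)), function(r) {
      i <- E[r, 1]; j <- E[r, 2]
      st <- step_count(A[i, ], A[j, ])
      st[is.na(st)] <- 0
      diff <- which(st > 0)
      data.frame(from = ids[i], to = ids[j], cost = E[r, 3],
                 steps = sum(st),
                 loci = paste(sprintf("%s(%d)", loci[diff], st[diff]), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(A) <- ids
  colnames(A) <- loci
  structure(list(nodes = node_df, alleles = A, edges = edge_df,
                 weights = as.integer(weights), epsilon = epsilon,
                 provenance = list(
                   input_digest = str_digest(apply(A_obs, 1, paste, collapse = "/")),
                   n_observed_nodes = n_obs2,
                   n_chromosomes = sum(node_df$multiplicity),
                   epsilon = epsilon, weights = as.integer(weights),
                   mp_prune = mp_prune)),
            class = "mj_network")
}

# per-row |step| matrix between each row of A and vector v
abs_steps_row <- function(A, v) {
  out <- abs(sweep(A, 2, v))
  s <- floor(out + 0.5)
  res <- ifelse(out == 0, 0, pmax(s, 1))
  res[is.na(out)] <- 0
  res
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("<mj_network> %d nodes (%d observed, %d median vectors), %d edges, epsilon = %g\n",
              nrow(x$nodes), sum(x$nodes$type == "observed"),
              sum(x$nodes$type == "median"), nrow(x$edges), x$epsilon))
  cat(sprintf("  %d chromosomes collapsed into the observed nodes\n",
              x$provenance$n_chromosomes))
  invisible(x)
}

#' Convert a median-joining network to an igraph graph
#' @param net an `mj_network`.
#' @return an undirected `igraph` graph with node attributes `type`,
#'   `multiplicity`, `composition`, `haplotype` and edge attributes `weight`
#'   (cost), `steps`, `loci`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mj_network"))
  v <- data.frame(name = net$nodes$id, type = net$nodes$type,
                  multiplicity = net$nodes$multiplicity,
                  composition = ifelse(is.na(net$nodes$composition), "",
                                       net$nodes$composition),
                  haplotype = net$nodes$label, stringsAsFactors = FALSE)
  e <- net$edges
  if (nrow(e) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(v$name)
    for (at in setdiff(names(v), "name"))
      g <- igraph::set_vertex_attr(g, at, value = v[[at]])
    return(g)
  }
  igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = e$cost, steps = e$steps,
               loci = e$loci, stringsAsFactors = FALSE),
    directed = FALSE, vertices = v)
}

#' Export a median-joining network
#'
#' Writes the network with all node and edge attributes (multiplicity,
#' population composition, mutated loci and step counts per link; median
#' vectors carry multiplicity 0).
#'
#' @param net an `mj_network`.
#' @param path output file.
#' @param format `"graphml"` (lossless, re-importable), `"dot"`, or
#'   `"edgelist"` (TSV edge table; node attributes go to a companion
#'   `*_nodes.tsv` file).
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "mj_network"))
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nodes_path <- sub("(\\.tsv)?$", "_nodes.tsv", path)
    utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = format)
  }
  invisible(path)
}

#' Re-import a GraphML network export
#' @param path a GraphML file written by [export_network()].
#' @return an `igraph` graph.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  igraph::read_graph(path, format = "graphml")
}
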