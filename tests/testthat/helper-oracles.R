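# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (igraph, matrix solves) so that agreement is
# evidence, not tautology.

# --- shortest-path module oracle -------------------------------------------
# BFS distances over an adjacency list built from a plain edge data frame.
oracle_bfs_dist <- function(edges, from, nodes, reverse = FALSE) {
  adj <- split(if (reverse) edges$source else edges$target,
               if (reverse) edges$target else edges$source)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  dist
}

# Union over all ordered DEG pairs of every edge lying on some
# minimum-length directed path: edge (u, v) is on a shortest a->b path
# iff dist_a[u] + 1 + dist_b_rev[v] == dist_a[b].
oracle_module_pairs <- function(edges, nodes, degs) {
  keep <- rep(FALSE, nrow(edges))
  for (a in degs) {
    da <- oracle_bfs_dist(edges, a, nodes)
    for (b in degs) {
      if (a == b || is.infinite(da[b])) next
      db <- oracle_bfs_dist(edges, b, nodes, reverse = TRUE)
      keep <- keep | (da[edges$source] + 1 + db[edges$target] == da[b])
    }
  }
  unique(paste(edges$source[keep], edges$target[keep]))
}

random_pathway <- function(n_nodes, n_edges, seed,
                           types = c("activation", "inhibition",
                                     "binding", "indirect")) {
  withr::with_seed(seed, {
    genes <- paste0("n", seq_len(n_nodes))
    s <- sample(genes, n_edges, replace = TRUE)
    t <- sample(genes, n_edges, replace = TRUE)
    keep <- s != t
    e <- unique(data.frame(source = s[keep], target = t[keep],
                           type = sample(types, sum(keep),
                                         replace = TRUE),
                           stringsAsFactors = FALSE))
    pathway_graph(paste0("rand", seed), genes, e)
  })
}

# Random DAG over n nodes: edges only from lower to higher topological
# index, so the propagation system is always solvable.
random_dag <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    genes <- paste0("n", seq_len(n_nodes))
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pick <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
    e <- data.frame(source = genes[pick[, 1]], target = genes[pick[, 2]],
                    type = sample(c("activation", "inhibition"),
                                  nrow(pick), replace = TRUE),
                    stringsAsFactors = FALSE)
    pathway_graph(paste0("dag", seed), genes, e)
  })
}

# relaxed fixed-point iteration PF <- (1-a) PF + a (dE + B PF)
oracle_fixed_point <- function(B, de, damping = 0.9, iters = 10000L) {
  pf <- de
  for (i in seq_len(iters))
    pf <- (1 - damping) * pf + damping * (de + B %*% pf)
  drop(pf)
}

# exact hypergeometric upper tail by enumeration of all draws
oracle_pnde_enum <- function(obs, pathway, de_total, universe) {
  draws <- utils::combn(universe, de_total)
  in_path <- colSums(draws <= pathway)  # first `pathway` items = pathway
  mean(in_path >= obs)
}

# implied covariance of a linear structural model child = sum(b parent)+e
oracle_implied_cov <- function(genes, pairs, b, err_var) {
  k <- length(genes)
  A <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(nrow(pairs))) A[pairs$target[i], pairs$source[i]] <- b[i]
  S <- solve(diag(k) - A)
  S %*% diag(err_var, k) %*% t(S)
}

# population standardised coefficients implied by raw coefficients
oracle_standardized_coef <- function(module, b, err_var = 1) {
  pairs <- unique(module$edges[, c("source", "target")])
  S <- oracle_implied_cov(module$genes, pairs, b,
                          rep(err_var, length(module$genes)))
  sds <- sqrt(diag(S))
  unname(b * sds[pairs$source] / sds[pairs$target])
}
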