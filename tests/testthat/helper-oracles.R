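# Independent brute-force oracles used to cross-check the pipeline's
# statistics and graph measures. Deliberately naive implementations that do
# not share code with the package.

# hypergeometric upper tail P(X >= k) as an explicit combinatorial sum
oracle_hyper_sum <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  drivers <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% drivers))
  mean(hits >= k)
}

# all-pairs BFS distances on an adjacency matrix
oracle_bfs <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (d[s, v] > dist) {
            d[s, v] <- dist
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# exact betweenness by enumerating every simple path between every pair and
# crediting interior nodes of the shortest ones fractionally
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    recurse <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (v in which(adj[u, ] == 1)) {
        if (!(v %in% path)) recurse(c(path, v))
      }
    }
    recurse(s)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / length(shortest)
      }
    }
  }
  btw
}

# principal eigenvector of the dense adjacency, max-normalized
oracle_eigen <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)
  ev / max(ev)
}

# two-sample KS statistic by a double loop over pooled thresholds
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (t in pts) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# random connected simple graph with n nodes (adjacency matrix)
random_connected_adj <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    if (n == 1) return(adj)
    d <- oracle_bfs(adj)
    if (all(is.finite(d))) return(adj)
  }
}

adj_to_graph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}

# evidence-item fixture builder
make_evidence <- function(compound_id, target_id, class = "NP",
                          ref = FALSE, value = NA_real_, relation = "exact",
                          source_db = "S1", assay = "IC50") {
  data.frame(compound_id = compound_id, target_id = target_id, class = class,
             source_db = source_db,
             literature_ref_id = ifelse(ref, "REF1", NA_character_),
             has_literature_ref = ref,
             assay_type = ifelse(is.na(value), NA_character_, assay),
             relation = ifelse(is.na(value), NA_character_, relation),
             value_nM = value,
             unit = ifelse(is.na(value), NA_character_, "nM"),
             stringsAsFactors = FALSE)
}

small_scenario_config <- function(seed = 1, ...) {
  scenario_config(seed = seed, n_np_compounds = 60, n_ct_compounds = 25,
                  n_targets = 200, n_pathways = 30, n_families = 6,
                  n_tumor_types = 10, ...)
}
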