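# Protein-protein interaction topology: project NP/CT target classifications
# onto a PPI network and compare degree, betweenness, eigenvector centrality
# and mean shortest distance to cancer drivers across node groups, with
# size-matched random-control baselines for the distance comparison.

#' Load an undirected simple PPI network from an edge list
#'
#' Accepts a two-column TSV (`from`, `to`, optional further annotation
#' columns, header optional) or a three-column SIF file
#' (`node relation node`). Self-loops and duplicate edges are dropped and
#' their counts reported as graph attributes `n_self_loops_dropped` and
#' `n_duplicate_edges_dropped`.
#'
#' @param path edge-list path.
#' @param format "tsv" or "sif"; guessed from the file extension by default.
#' @return undirected simple igraph graph with gene-symbol vertex names.
#' @export
load_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty edge-list file: returning empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- vapply(parts, length, 1L)
  min_cols <- if (format == "sif") 3L else 2L
  bad <- which(lens < min_cols)
  # tolerate a header row in TSV input
  if (format == "tsv" && length(lines) > 1 &&
      identical(tolower(parts[[1]][1:2]), c("from", "to"))) {
    parts <- parts[-1]
    lens <- lens[-1]
    bad <- which(lens < min_cols)
  }
  if (length(bad) > 0) {
    stop(sprintf("malformed edge row(s) at line(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", if (format == "sif") 3L else 2L)
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  g2 <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  n_dup <- igraph::ecount(g2) - igraph::ecount(igraph::simplify(g2))
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "n_self_loops_dropped", n_loops)
  g <- igraph::set_graph_attr(g, "n_duplicate_edges_dropped", as.integer(n_dup))
  g
}

#' Compute topology profiles for every node
#'
#' Degree = distinct-neighbor count; betweenness = exact shortest-path
#' betweenness, unnormalized, each unordered source-target pair counted once
#' with fractional credit across equal-length shortest paths; eigenvector
#' centrality = principal-eigenvector scores normalized so the maximum is 1
#' (on disconnected graphs scores outside the dominant component may be ~0).
#' Nodes are grouped NP_ONLY / CT_ONLY / BOTH / UNTARGETED by the supplied
#' hit sets.
#'
#' @param graph undirected igraph graph with named vertices.
#' @param np_targets,ct_targets character vectors of targets hit at the
#'   working affinity threshold.
#' @param driver_genes character vector of driver gene symbols.
#' @return data.frame `node_id`, `degree`, `betweenness`, `eigenvector`,
#'   `mean_dist_to_drivers`, `group`, `is_driver`.
#' @export
compute_centralities <- function(graph, np_targets = character(0),
                                 ct_targets = character(0),
                                 driver_genes = character(0)) {
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph, loops = FALSE)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  eig <- eigenvector_centrality(graph)
  np_hit <- nodes %in% np_targets
  ct_hit <- nodes %in% ct_targets
  group <- ifelse(np_hit & ct_hit, "BOTH",
                  ifelse(np_hit, "NP_ONLY",
                         ifelse(ct_hit, "CT_ONLY", "UNTARGETED")))
  mdd <- mean_distance_to_drivers(graph, driver_genes)
  data.frame(node_id = nodes, degree = as.numeric(deg),
             betweenness = as.numeric(btw), eigenvector = as.numeric(eig),
             mean_dist_to_drivers = as.numeric(mdd[nodes]),
             group = group, is_driver = nodes %in% driver_genes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Eigenvector centrality by deterministic power iteration
#'
#' Principal-eigenvector scores of the adjacency matrix, max-normalized.
#' Iterates on the shifted matrix A + I (same eigenvectors as A, and the
#' shift guarantees convergence on bipartite-like structures) from the
#' all-ones start vector to an infinity-norm tolerance of 1e-10, at most
#' 1000 iterations. On disconnected graphs scores outside the dominant
#' component decay toward 0.
#'
#' @param graph undirected igraph graph.
#' @param tol convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return named numeric vector of scores in `[0,1]` with max 1.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 1000) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (igraph::ecount(graph) == 0) {
    return(stats::setNames(rep(0, n), nodes))
  }
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  v <- rep(1, n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v   # (A + I) v
    w <- w / max(w)
    if (max(abs(w - v)) < tol) {
      return(stats::setNames(w, nodes))
    }
    v <- w
  }
  comp <- igraph::components(graph)
  stop(sprintf("eigenvector iteration did not converge (largest component: %d nodes)",
               max(comp$csize)), call. = FALSE)
}

#' Mean shortest-path distance to driver nodes
#'
#' For each node, the mean unweighted shortest-path length to every
#' reachable driver, excluding the node itself when it is a driver; NA when
#' no driver is reachable (such nodes are excluded from group means).
#'
#' @param graph undirected igraph graph with named vertices.
#' @param driver_genes character vector of driver gene symbols.
#' @param nodes nodes to evaluate (default all).
#' @return named numeric vector (NA where undefined).
#' @export
mean_distance_to_drivers <- function(graph, driver_genes,
                                     nodes = igraph::V(graph)$name) {
  drivers <- intersect(driver_genes, igraph::V(graph)$name)
  if (length(drivers) == 0 || length(nodes) == 0) {
    return(stats::setNames(rep(NA_real_, length(nodes)), nodes))
  }
  d <- igraph::distances(graph, v = nodes, to = drivers)
  res <- apply(d, 1, function(row) {
    row <- row[is.finite(row) & row > 0]
    if (length(row) == 0) NA_real_ else mean(row)
  })
  stats::setNames(as.numeric(res), nodes)
}

#' Compare a topology measure across node groups
#'
#' Pairwise two-sided Mann-Whitney U tests between groups (chosen for the
#' heavy-tailed distributions of centrality measures). For
#' `mean_dist_to_drivers` an additional empirical comparison against
#' `n_controls` uniformly random node sets of matched size is run per group:
#' p = (1 + #controls with mean <= observed) / (n_controls + 1).
#'
#' @param profiles data.frame from [compute_centralities()].
#' @param measure one of "degree", "betweenness", "eigenvector",
#'   "mean_dist_to_drivers".
#' @param groups group labels to compare (default all groups present);
#'   groups with fewer than 3 members are skipped with a warning.
#' @param n_controls random control sets for the distance comparison.
#' @param seed RNG seed for the controls (recorded in the output).
#' @return list with `pairwise` (data.frame `group_a`, `group_b`, `n_a`,
#'   `n_b`, `median_a`, `median_b`, `U`, `p_value`), `controls` (data.frame
#'   `group`, `n`, `observed_mean`, `empirical_p`, or NULL), `measure`,
#'   `test` ("mann-whitney"), `seed`.
#' @export
compare_groups <- function(profiles, measure,
                           groups = sort(unique(profiles$group)),
                           n_controls = 1000, seed = 1) {
  stopifnot_msg(measure %in% names(profiles), "unknown measure: %s", measure)
  vals <- split(profiles[[measure]], profiles$group)
  vals <- lapply(vals, function(v) v[!is.na(v)])
  ok <- vapply(vals[groups], length, 1L) >= 3
  if (any(!ok)) {
    warning(sprintf("group(s) with <3 members skipped: %s",
                    paste(groups[!ok], collapse = ", ")))
  }
  groups <- groups[ok]
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else NULL
  pairwise <- NULL
  if (!is.null(pairs)) {
    rows <- apply(pairs, 2, function(pr) {
      a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      data.frame(group_a = pr[1], group_b = pr[2], n_a = length(a),
                 n_b = length(b), median_a = stats::median(a),
                 median_b = stats::median(b), U = unname(wt$statistic),
                 p_value = wt$p.value, stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
  }
  controls <- NULL
  if (measure == "mean_dist_to_drivers" && length(groups) > 0) {
    set.seed(seed)
    pool <- profiles$mean_dist_to_drivers
    names(pool) <- profiles$node_id
    pool <- pool[!is.na(pool)]
    rows <- lapply(groups, function(g) {
      obs <- mean(vals[[g]])
      size <- length(vals[[g]])
      ctrl <- replicate(n_controls, mean(sample(pool, size)))
      data.frame(group = g, n = size, observed_mean = obs,
                 empirical_p = (1 + sum(ctrl <= obs)) / (n_controls + 1),
                 stringsAsFactors = FALSE)
    })
    controls <- do.call(rbind, rows)
  }
  list(pairwise = pairwise, controls = controls, measure = measure,
       test = "mann-whitney", seed = seed)
}

#' Top-ranked nodes per group and measure
#'
#' @param profiles data.frame from [compute_centralities()].
#' @param k nodes per (group, measure) (default 6).
#' @param measures measures to rank.
#' @return data.frame `measure`, `group`, `rank`, `node_id`, `value`,
#'   `is_driver`; ties broken by lexicographic node id.
#' @export
top_nodes_report <- function(profiles, k = 6,
                             measures = c("betweenness", "degree",
                                          "eigenvector")) {
  rows <- list()
  for (m in measures) {
    for (g in sort(unique(profiles$group))) {
      sub <- profiles[profiles$group == g, , drop = FALSE]
      ord <- order(-sub[[m]], sub$node_id)
      sub <- sub[utils::head(ord, k), , drop = FALSE]
      if (nrow(sub) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, group = g, rank = seq_len(nrow(sub)),
        node_id = sub$node_id, value = sub[[m]],
        is_driver = sub$is_driver, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
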