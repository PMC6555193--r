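# Pathway crosstalk network over entity-level pathways: nodes are pathways,
# an edge exists iff two pathways share at least one gene, weighted by the
# shared-gene count. Distances are hop counts on the unweighted graph;
# weights are stored for reporting only.

#' Build the shared-gene pathway-pathway network
#'
#' @param pathways named list of entity-level pathway gene sets (>= 2,
#'   unique ids).
#' @return list with `graph` (igraph, vertex names = pathway ids, edge
#'   attribute `weight` = shared-gene count; isolated pathways retained as
#'   isolated nodes) and `edges` (data.frame `p1`, `p2`,
#'   `shared_gene_count`).
#' @export
build_pathway_graph <- function(pathways) {
  stopifnot_msg(length(pathways) >= 2, "need at least 2 pathways")
  ids <- names(pathways)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("pathway ids must be present and unique", call. = FALSE)
  }
  genes <- sort(unique(unlist(pathways, use.names = FALSE)))
  # incidence matrix genes x pathways; crossprod gives shared-gene counts
  inc <- vapply(pathways, function(g) as.integer(genes %in% g),
                integer(length(genes)))
  if (length(genes) == 1) {
    inc <- matrix(inc, nrow = 1, dimnames = list(NULL, ids))
  }
  shared <- crossprod(inc)
  shared[lower.tri(shared, diag = TRUE)] <- 0
  hit <- which(shared >= 1, arr.ind = TRUE)
  edges <- data.frame(p1 = ids[hit[, 1]], p2 = ids[hit[, 2]],
                      shared_gene_count = shared[hit],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p1, edges$p2), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$p1, to = edges$p2, weight = edges$shared_gene_count),
    directed = FALSE, vertices = ids)
  list(graph = g, edges = edges)
}

#' Mean shortest-path distance between two pathway sets
#'
#' Mean unweighted hop distance over all unordered pairs {a, b}, a != b,
#' a in A, b in B, restricted to pairs within one connected component;
#' cross-component pairs are excluded (not infinite) and their count
#' reported.
#'
#' @param graph pathway graph (igraph).
#' @param set_a,set_b character vectors of pathway ids (non-empty).
#' @return list `mean_distance` (NA when no connected pair), `n_pairs`,
#'   `n_excluded`, `defined`.
#' @export
set_distance <- function(graph, set_a, set_b) {
  stopifnot_msg(length(set_a) > 0 && length(set_b) > 0,
                "both pathway sets must be non-empty")
  nodes <- igraph::V(graph)$name
  set_a <- intersect(set_a, nodes)
  set_b <- intersect(set_b, nodes)
  stopifnot_msg(length(set_a) > 0 && length(set_b) > 0,
                "pathway sets not found in graph")
  d <- igraph::distances(graph, v = set_a, to = set_b, weights = NA)
  # unordered deduplication: pair {a,b} counted once even if in both sets
  seen <- character(0)
  vals <- numeric(0)
  for (a in set_a) {
    for (b in set_b) {
      if (a == b) next
      key <- paste(sort(c(a, b)), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      vals <- c(vals, d[a, b])
    }
  }
  finite <- vals[is.finite(vals)]
  list(mean_distance = if (length(finite)) mean(finite) else NA_real_,
       n_pairs = length(finite), n_excluded = sum(!is.finite(vals)),
       defined = length(finite) > 0)
}

#' Random-control distribution for pathway set distances
#'
#' Draws `n_reps` pairs of uniformly random pathway sets of the given sizes
#' and computes their set distance, yielding the null distribution against
#' which an observed distance is compared:
#' p = (1 + #controls <= observed) / (n_reps + 1).
#'
#' @param graph pathway graph.
#' @param size_a,size_b sizes of the random sets.
#' @param n_reps replicates (default 1000).
#' @param seed RNG seed.
#' @return list `distances` (numeric vector, NA where undefined), `seed`.
#' @export
control_distance <- function(graph, size_a, size_b, n_reps = 1000, seed = 1) {
  nodes <- igraph::V(graph)$name
  stopifnot_msg(size_a >= 1 && size_b >= 1 &&
                  size_a <= length(nodes) && size_b <= length(nodes),
                "infeasible control set sizes")
  set.seed(seed)
  dists <- vapply(seq_len(n_reps), function(i) {
    a <- sample(nodes, size_a)
    b <- sample(nodes, size_b)
    set_distance(graph, a, b)$mean_distance
  }, 1.0)
  list(distances = dists, seed = seed)
}

#' Empirical p-value of an observed distance against controls
#'
#' @param observed observed mean distance.
#' @param controls numeric vector of control distances (NAs dropped).
#' @return p = (1 + #controls <= observed) / (n + 1).
#' @export
empirical_p <- function(observed, controls) {
  controls <- controls[!is.na(controls)]
  (1 + sum(controls <= observed)) / (length(controls) + 1)
}

#' Neighboring-pathway synergy candidates
#'
#' All pathway-graph edges (P, Q) where P is targeted by NPs only and Q is a
#' driver-enriched pathway targeted by CT drugs (alone or together with
#' NPs), annotated with the shared genes and the NP/CT targets involved.
#'
#' @param pathway_graph list from [build_pathway_graph()].
#' @param labels data.frame from [classify_entities()] at pathway level
#'   (classified at the working affinity threshold).
#' @param enriched_ids character vector of driver-enriched pathway ids.
#' @param pathways named list of pathway gene sets.
#' @param np_targets,ct_targets targets hit at the threshold.
#' @return data.frame `np_pathway`, `enriched_pathway`,
#'   `enriched_pathway_label`, `shared_genes`, `np_targets_in_np_pathway`,
#'   `ct_targets_in_enriched_pathway` (pipe-delimited).
#' @export
neighbor_synergy_candidates <- function(pathway_graph, labels, enriched_ids,
                                        pathways, np_targets, ct_targets) {
  lab <- stats::setNames(labels$label, labels$entity_id)
  edges <- pathway_graph$edges
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    for (ord in list(c(edges$p1[i], edges$p2[i]),
                     c(edges$p2[i], edges$p1[i]))) {
      p <- ord[1]; q <- ord[2]
      if (is.na(lab[p]) || is.na(lab[q])) next
      if (lab[p] == "NP_ONLY" && q %in% enriched_ids &&
          lab[q] %in% c("CT_ONLY", "BOTH")) {
        rows[[length(rows) + 1]] <- data.frame(
          np_pathway = p, enriched_pathway = q,
          enriched_pathway_label = unname(lab[q]),
          shared_genes = join_pipe(intersect(pathways[[p]], pathways[[q]])),
          np_targets_in_np_pathway = join_pipe(
            intersect(pathways[[p]], np_targets)),
          ct_targets_in_enriched_pathway = join_pipe(
            intersect(pathways[[q]], ct_targets)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(np_pathway = character(0),
                      enriched_pathway = character(0),
                      enriched_pathway_label = character(0),
                      shared_genes = character(0),
                      np_targets_in_np_pathway = character(0),
                      ct_targets_in_enriched_pathway = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
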