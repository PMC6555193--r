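# Compound-compound network at strong binding affinity: nodes are compounds
# (NP or CT), an edge exists iff two compounds share at least one sub-
# threshold target, weighted by the shared-target count. Communities are
# detected by multilevel (Louvain) modularity optimization on the weighted
# graph, which handles disconnected networks, then characterized by
# compound-class enrichment and target protein families.

#' Build the shared-target compound-compound network
#'
#' @param interactions aggregated interactions with a `class` column,
#'   already filtered to exact binding below the working threshold (e.g.
#'   [filter_by_affinity()] at 100 nM).
#' @return list with `graph` (igraph; vertex attributes `name` and `class`;
#'   edge attribute `weight` = shared-target count; compounds with >= 1
#'   qualifying target included, possibly isolated), `edges` (data.frame
#'   `c1`, `c2`, `weight`), and `targets_of` (named list compound ->
#'   qualifying targets).
#' @export
build_compound_graph <- function(interactions) {
  targets_of <- lapply(split(interactions$target_id, interactions$compound_id),
                       unique)
  cpds <- sort(names(targets_of))
  targets_of <- targets_of[cpds]
  cls <- stats::setNames(interactions$class[!duplicated(interactions$compound_id)],
                         interactions$compound_id[!duplicated(interactions$compound_id)])
  if (length(cpds) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(list(graph = g,
                edges = data.frame(c1 = character(0), c2 = character(0),
                                   weight = integer(0)),
                targets_of = targets_of))
  }
  genes <- sort(unique(unlist(targets_of, use.names = FALSE)))
  inc <- vapply(targets_of, function(g) as.integer(genes %in% g),
                integer(length(genes)))
  if (length(genes) == 1) inc <- matrix(inc, nrow = 1, dimnames = list(NULL, cpds))
  shared <- crossprod(inc)
  shared[lower.tri(shared, diag = TRUE)] <- 0
  hit <- which(shared >= 1, arr.ind = TRUE)
  edges <- data.frame(c1 = cpds[hit[, 1]], c2 = cpds[hit[, 2]],
                      weight = as.integer(shared[hit]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$c1, edges$c2), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$c1, to = edges$c2, weight = edges$weight),
    directed = FALSE, vertices = cpds)
  g <- igraph::set_vertex_attr(g, "class",
                               value = as.character(cls[igraph::V(g)$name]))
  list(graph = g, edges = edges, targets_of = targets_of)
}

#' Detect compound communities by multilevel modularity optimization
#'
#' Louvain-style greedy modularity maximization using edge weights at
#' resolution 1.0. The algorithm is visit-order sensitive, so the RNG seed
#' is fixed and recorded; identical graph + seed give identical partitions.
#'
#' @param graph weighted compound graph (igraph).
#' @param seed RNG seed.
#' @return list `membership` (data.frame `compound_id`, `community_id`),
#'   `modularity` (weighted modularity of the partition), `n_communities`,
#'   `seed`.
#' @export
detect_communities <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 0) {
    return(list(membership = data.frame(compound_id = character(0),
                                        community_id = integer(0)),
                modularity = NA_real_, n_communities = 0L, seed = seed))
  }
  set.seed(seed)
  weights <- if (igraph::ecount(graph) > 0) igraph::E(graph)$weight else NULL
  comm <- igraph::cluster_louvain(graph, weights = weights, resolution = 1.0)
  memb <- igraph::membership(comm)
  list(membership = data.frame(compound_id = names(memb),
                               community_id = as.integer(memb),
                               stringsAsFactors = FALSE, row.names = NULL),
       modularity = igraph::modularity(graph, memb, weights = weights),
       n_communities = length(unique(memb)), seed = seed)
}

#' Characterize communities by compound class and target family
#'
#' Per community: NP/CT member counts, a two-sided Fisher exact test of
#' class enrichment (community membership x class against the rest of the
#' graph), and counts of distinct community targets per protein family.
#' Targets without a family annotation are counted under "unclassified".
#'
#' @param membership data.frame `compound_id`, `community_id` from
#'   [detect_communities()].
#' @param classes named character vector compound -> class ("NP"/"CT").
#' @param targets_of named list compound -> qualifying targets.
#' @param families data.frame `target_id`, `family` (target -> protein
#'   family).
#' @return list `communities` (data.frame `community_id`, `n_np`, `n_ct`,
#'   `odds_ratio`, `p_value`) and `families` (data.frame `community_id`,
#'   `family`, `n_targets`).
#' @export
community_composition <- function(membership, classes, targets_of, families) {
  fam <- stats::setNames(families$family, families$target_id)
  total_np <- sum(classes[membership$compound_id] == "NP")
  total_ct <- sum(classes[membership$compound_id] == "CT")
  comm_rows <- list()
  fam_rows <- list()
  for (cid in sort(unique(membership$community_id))) {
    members <- membership$compound_id[membership$community_id == cid]
    n_np <- sum(classes[members] == "NP")
    n_ct <- sum(classes[members] == "CT")
    tab <- matrix(c(n_np, n_ct, total_np - n_np, total_ct - n_ct), nrow = 2)
    ft <- stats::fisher.test(tab)
    comm_rows[[length(comm_rows) + 1]] <- data.frame(
      community_id = cid, n_np = n_np, n_ct = n_ct,
      odds_ratio = unname(ft$estimate), p_value = ft$p.value,
      stringsAsFactors = FALSE)
    tgts <- unique(unlist(targets_of[members], use.names = FALSE))
    if (length(tgts) > 0) {
      f <- fam[tgts]
      f[is.na(f)] <- "unclassified"
      tf <- table(f)
      fam_rows[[length(fam_rows) + 1]] <- data.frame(
        community_id = cid, family = names(tf),
        n_targets = as.integer(tf), stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  communities <- do.call(rbind, comm_rows)
  fams <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(community_id = integer(0), family = character(0),
               n_targets = integer(0))
  rownames(communities) <- NULL
  fams <- fams[order(fams$community_id, -fams$n_targets, fams$family), ,
               drop = FALSE]
  rownames(fams) <- NULL
  list(communities = communities, families = fams)
}
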