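# End-to-end orchestration: catalog integration -> evidence aggregation ->
# coverage -> driver enrichment -> PPI topology -> pathway crosstalk ->
# compound communities, with a JSON run manifest recording seeds and per-
# stage row counts so no stage drops records silently.

#' Run the full analysis pipeline over a scenario directory
#'
#' @param config list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{scenario_dir}{directory holding the input files (see
#'       [generate_scenario()]).}
#'     \item{out_dir}{output directory for report tables and manifest.}
#'     \item{thresholds_nM}{affinity thresholds, default `c(100, 1000)`; the
#'       first is the working threshold for networks.}
#'     \item{alpha}{enrichment FDR threshold, default 0.05.}
#'     \item{n_controls}{random-control replicates, default 200.}
#'     \item{seed}{RNG seed for controls and community detection, default 1.}
#'   }
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list of the in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(thresholds_nM = c(100, 1000), alpha = 0.05,
                   n_controls = 200, seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot_msg(!is.null(config$scenario_dir) && !is.null(config$out_dir),
                "config needs scenario_dir and out_dir")
  stopifnot_msg(all(config$thresholds_nM > 0), "thresholds must be positive")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  thr <- sort(config$thresholds_nM)[1]
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(seed = config$seed, thresholds_nM = config$thresholds_nM,
                   alpha = config$alpha, stages = list())

  say("stage: load inputs")
  sc <- stage("load", load_scenario(config$scenario_dir))

  say("stage: compound catalog")
  merged <- stage("compound_catalog", merge_compounds(sc$compounds))
  scrub <- stage("compound_catalog",
                 scrub_drugs(merged$catalog, sc$exclusion))
  catalog <- scrub$catalog
  write_tsv(catalog, file.path(out, "catalog.tsv"))
  write_tsv(merged$conflicts, file.path(out, "catalog_conflicts.tsv"))
  write_tsv(scrub$removed, file.path(out, "catalog_removed.tsv"))
  manifest$stages$compound_catalog <- list(
    n_records_in = nrow(sc$compounds), n_compounds = nrow(merged$catalog),
    n_removed = nrow(scrub$removed),
    n_kept = nrow(catalog))

  say("stage: evidence model")
  # drop evidence of scrubbed compounds; membership maps source records to
  # merged catalog ids, so trace removed catalog ids back to source ids
  removed_members <- sc$compounds$compound_id[
    merged$membership %in% scrub$removed$compound_id]
  ev <- sc$evidence[!sc$evidence$compound_id %in% removed_members, ,
                    drop = FALSE]
  interactions <- stage("evidence_model", aggregate_interactions(ev))
  esum <- stage("evidence_model", summarize_evidence(interactions))
  write_tsv(interactions, file.path(out, "interactions_aggregated.tsv"))
  write_tsv(esum$interactions, file.path(out, "evidence_summary_interactions.tsv"))
  write_tsv(esum$targets, file.path(out, "evidence_summary_targets.tsv"))
  manifest$stages$evidence_model <- list(
    n_evidence_in = nrow(sc$evidence),
    n_evidence_dropped_scrubbed = nrow(sc$evidence) - nrow(ev),
    n_interactions = nrow(interactions))

  say("stage: coverage")
  cov <- stage("coverage",
               coverage_table(interactions, sc$pathways,
                              default_strata(thr)))
  write_tsv(cov, file.path(out, "coverage_all_pathways.tsv"))
  drv_cov <- stage("coverage",
                   driver_tumor_coverage(sc$drivers, interactions, thr))
  write_tsv(drv_cov, file.path(out, "driver_tumor_coverage.tsv"))
  dist <- stage("coverage",
                suppressWarnings(per_compound_distributions(
                  interactions, sc$pathways, sc$drivers,
                  thresholds = config$thresholds_nM)))
  write_tsv(dist$distributions, file.path(out, "per_compound_distributions.tsv"))
  if (!is.null(dist$tests)) {
    write_tsv(dist$tests, file.path(out, "per_compound_ks_tests.tsv"))
  }
  manifest$stages$coverage <- list(n_strata = nrow(cov))

  say("stage: driver enrichment")
  driver_genes <- unique(sc$drivers$gene)
  enr <- stage("driver_enrichment",
               aberrational_pathways(sc$pathways, driver_genes,
                                     alpha = config$alpha))
  write_tsv(enr$results, file.path(out, "enrichment.tsv"))
  strong <- filter_by_affinity(interactions, thr)
  opp <- stage("driver_enrichment",
               np_only_opportunity_pathways(enr$enriched_ids, sc$pathways,
                                            strong, driver_genes))
  write_tsv(opp, file.path(out, "opportunity_pathways.tsv"))
  cov5 <- stage("driver_enrichment",
                coverage_table(interactions, sc$pathways[enr$enriched_ids],
                               default_strata(thr)))
  write_tsv(cov5, file.path(out, "coverage_cancer_pathways.tsv"))
  manifest$stages$driver_enrichment <- list(
    n_pathways = length(sc$pathways), n_enriched = length(enr$enriched_ids),
    n_opportunity = nrow(opp))

  say("stage: PPI topology")
  np_strong <- unique(strong$target_id[strong$class == "NP"])
  ct_strong <- unique(strong$target_id[strong$class == "CT"])
  g <- stage("ppi_topology", load_network(sc$ppi_path))
  profiles <- stage("ppi_topology",
                    compute_centralities(g, np_strong, ct_strong, driver_genes))
  write_tsv(profiles, file.path(out, "topology_profiles.tsv"))
  comp_rows <- list()
  for (m in c("degree", "betweenness", "eigenvector",
              "mean_dist_to_drivers")) {
    cmp <- stage("ppi_topology",
                 suppressWarnings(compare_groups(
                   profiles, m, n_controls = config$n_controls,
                   seed = config$seed)))
    if (!is.null(cmp$pairwise)) {
      comp_rows[[m]] <- cbind(data.frame(measure = m), cmp$pairwise)
    }
    if (!is.null(cmp$controls)) {
      write_tsv(cmp$controls, file.path(out, "topology_distance_controls.tsv"))
    }
  }
  write_tsv(do.call(rbind, comp_rows), file.path(out, "topology_comparisons.tsv"))
  write_tsv(top_nodes_report(profiles), file.path(out, "topology_top_nodes.tsv"))
  manifest$stages$ppi_topology <- list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_self_loops_dropped = igraph::graph_attr(g, "n_self_loops_dropped"),
    n_duplicate_edges_dropped = igraph::graph_attr(g, "n_duplicate_edges_dropped"))

  say("stage: pathway crosstalk")
  entity_ids <- sc$hierarchy$pathway_id[sc$hierarchy$entity_level]
  entity_sets <- sc$pathways[entity_ids]
  pg <- stage("pathway_crosstalk", build_pathway_graph(entity_sets))
  labels <- classify_entities(np_strong, ct_strong, entity_sets)
  enriched_entity <- intersect(enr$enriched_ids, entity_ids)
  nodes_tbl <- labels
  nodes_tbl$enriched <- nodes_tbl$entity_id %in% enriched_entity
  write_tsv(pg$edges, file.path(out, "crosstalk_edges.tsv"))
  write_tsv(nodes_tbl, file.path(out, "crosstalk_nodes.tsv"))
  np_pw <- labels$entity_id[labels$label %in% c("NP_ONLY", "BOTH")]
  ct_pw <- labels$entity_id[labels$label %in% c("CT_ONLY", "BOTH")]
  xdist <- if (length(np_pw) > 0 && length(ct_pw) > 0) {
    stage("pathway_crosstalk", set_distance(pg$graph, np_pw, ct_pw))
  } else {
    list(mean_distance = NA_real_, n_pairs = 0L, n_excluded = 0L,
         defined = FALSE)
  }
  if (xdist$defined) {
    ctrl <- stage("pathway_crosstalk",
                  control_distance(pg$graph, length(np_pw), length(ct_pw),
                                   n_reps = config$n_controls,
                                   seed = config$seed))
    xdist$empirical_p <- empirical_p(xdist$mean_distance, ctrl$distances)
  }
  cand <- stage("pathway_crosstalk",
                neighbor_synergy_candidates(pg, labels, enriched_entity,
                                            entity_sets, np_strong, ct_strong))
  write_tsv(cand, file.path(out, "crosstalk_candidates.tsv"))
  manifest$stages$pathway_crosstalk <- list(
    n_entity_pathways = length(entity_sets), n_edges = nrow(pg$edges),
    np_ct_mean_distance = xdist$mean_distance,
    np_ct_distance_empirical_p = if (xdist$defined) xdist$empirical_p else NA,
    n_candidates = nrow(cand))

  say("stage: compound communities")
  cg <- stage("compound_communities", build_compound_graph(strong))
  part <- stage("compound_communities",
                detect_communities(cg$graph, seed = config$seed))
  classes <- stats::setNames(igraph::V(cg$graph)$class,
                             igraph::V(cg$graph)$name)
  comp <- if (nrow(part$membership) > 0) {
    stage("compound_communities",
          community_composition(part$membership, classes, cg$targets_of,
                                sc$families))
  } else {
    NULL
  }
  write_tsv(cg$edges, file.path(out, "compound_graph.tsv"))
  write_tsv(part$membership, file.path(out, "compound_partition.tsv"))
  if (!is.null(comp)) {
    write_tsv(comp$communities, file.path(out, "community_report.tsv"))
    write_tsv(comp$families, file.path(out, "community_families.tsv"))
  }
  manifest$stages$compound_communities <- list(
    n_compounds = igraph::vcount(cg$graph), n_edges = nrow(cg$edges),
    n_communities = part$n_communities, modularity = part$modularity)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: %s", out)
  invisible(list(catalog = catalog, interactions = interactions,
                 evidence_summary = esum, coverage = cov,
                 coverage_cancer = cov5, driver_tumor = drv_cov,
                 distributions = dist, enrichment = enr, opportunity = opp,
                 profiles = profiles, pathway_graph = pg,
                 crosstalk_candidates = cand, compound_graph = cg,
                 partition = part, communities = comp, manifest = manifest))
}
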