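#!/usr/bin/env Rscript
# Build the shared-gene pathway crosstalk network over entity-level
# pathways, measure NP-to-CT pathway-set distances against random controls,
# and enumerate neighboring-pathway synergy candidates.

suppressPackageStartupMessages(library(npnet))
stopifnot(dir.exists("results/scenario"))

sc <- load_scenario("results/scenario")
entity_ids <- sc$hierarchy$pathway_id[sc$hierarchy$entity_level]
sets <- sc$pathways[entity_ids]
pg <- build_pathway_graph(sets)
message(sprintf("crosstalk network: %d entity-level pathways, %d edges",
                length(sets), nrow(pg$edges)))

strong <- filter_by_affinity(aggregate_interactions(sc$evidence), 100)
np_t <- unique(strong$target_id[strong$class == "NP"])
ct_t <- unique(strong$target_id[strong$class == "CT"])
labels <- classify_entities(np_t, ct_t, sets)

dir.create("results/crosstalk", showWarnings = FALSE)
write.table(pg$edges, "results/crosstalk/edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(labels, "results/crosstalk/node_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

np_pw <- labels$entity_id[labels$label %in% c("NP_ONLY", "BOTH")]
ct_pw <- labels$entity_id[labels$label %in% c("CT_ONLY", "BOTH")]
if (length(np_pw) > 0 && length(ct_pw) > 0) {
  obs <- set_distance(pg$graph, np_pw, ct_pw)
  ctrl <- control_distance(pg$graph, length(np_pw), length(ct_pw),
                           n_reps = 1000, seed = 20260101)
  p <- empirical_p(obs$mean_distance, ctrl$distances)
  message(sprintf("NP-to-CT pathway distance %.3f over %d pairs (empirical p vs random sets = %.4f)",
                  obs$mean_distance, obs$n_pairs, p))
}

enr <- aberrational_pathways(sc$pathways, unique(sc$drivers$gene))
cand <- neighbor_synergy_candidates(pg, labels,
                                    intersect(enr$enriched_ids, entity_ids),
                                    sets, np_t, ct_t)
write.table(cand, "results/crosstalk/synergy_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d neighboring-pathway synergy candidates (NP-only pathway adjacent to enriched CT/BOTH pathway)",
                nrow(cand)))
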