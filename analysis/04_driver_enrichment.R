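#!/usr/bin/env Rscript
# Identify driver-enriched (pan-cancer aberrational) pathways by
# hypergeometric over-representation with Benjamini-Yekutieli FDR control,
# then enumerate NP-only therapeutic-opportunity pathways: enriched
# pathways with no CT drug target but at least one NP target at <100 nM.

suppressPackageStartupMessages(library(npnet))
stopifnot(dir.exists("results/scenario"))

sc <- load_scenario("results/scenario")
drivers <- unique(sc$drivers$gene)
enr <- aberrational_pathways(sc$pathways, drivers, alpha = 0.05)
dir.create("results/enrichment", showWarnings = FALSE)
write.table(enr$results, "results/enrichment/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d pathways driver-enriched at BY q < 0.05",
                length(enr$enriched_ids), length(sc$pathways)))

truth <- sc$truth
recovered <- intersect(truth$planted_enriched_pathway_ids, enr$enriched_ids)
message(sprintf("planted enriched pathways recovered: %d of %d",
                length(recovered),
                length(truth$planted_enriched_pathway_ids)))

strong <- filter_by_affinity(aggregate_interactions(sc$evidence), 100)
opp <- np_only_opportunity_pathways(enr$enriched_ids, sc$pathways, strong,
                                    drivers)
write.table(opp, "results/enrichment/opportunity_pathways.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d NP-only opportunity pathways (%d with the NP target itself a driver)",
                nrow(opp), sum(opp$np_target_is_driver)))
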