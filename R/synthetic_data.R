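# Seeded synthetic scenario generator.
#
# Emulates the statistical structure of the public data sources behind the
# NP/CT target-network analysis: multi-source interaction evidence with an
# NP-heavy Level-I / CT-heavy Level-III mixture, log-spread binding
# affinities, family-structured compound-target sharing, driver-dense
# planted pathways, a pathway hierarchy with entity-level leaves, a PPI
# network with high-degree driver nodes, and an exclusion-list planting.
# Every generated target appears in the PPI network and in at least one
# pathway (closed world for downstream joins). Identical config + seed
# yields byte-identical output files; the planted ground truth is returned
# and written as JSON for recovery tests.

#' Build and validate a synthetic scenario configuration
#'
#' Defaults define the standard study conditions used throughout the
#' analysis scripts and tests: 150 NP and 50 CT compounds over 500 targets
#' in 12 protein families, 60 pathways of 8-30 genes (half entity-level),
#' 10% drivers over 20 tumor types, 7 evidence sources, a log10-normal
#' binding distribution centered at ~160 nM with 1.3 decades of spread,
#' class-specific literature-reference and binding-value probabilities
#' (NP sparse, CT rich), 6 planted driver-enriched pathways of which 3 are
#' NP-only opportunity pathways, and driver nodes with 15 extra PPI edges.
#'
#' @param seed integer RNG seed.
#' @param n_np_compounds,n_ct_compounds compound counts per class.
#' @param n_targets,n_families,n_pathways,n_tumor_types,n_sources counts.
#' @param entity_level_fraction fraction of pathways flagged entity-level.
#' @param pathway_size_range integer (min, max) genes per pathway, min >= 2.
#' @param driver_fraction fraction of targets planted as drivers
#'   (|drivers| = floor(fraction * n_targets)).
#' @param p_literature_ref,p_binding_value per-evidence-item probabilities
#'   for NP-class compounds.
#' @param ct_p_literature_ref,ct_p_binding_value per-item probabilities for
#'   CT-class compounds (a CT binding value always carries a reference).
#' @param p_relation_qualifier fraction of binding values reported as lt/gt
#'   bounds instead of exact values.
#' @param affinity_log10_nM_mean,affinity_log10_nM_sd log10-normal binding
#'   distribution parameters (nM).
#' @param mean_targets_per_compound positive real.
#' @param family_affinity_bias odds multiplier for sampling targets within
#'   the compound's own family.
#' @param n_planted_enriched_pathways,n_planted_opportunity_pathways counts
#'   of planted driver-enriched pathways and of the subset additionally
#'   planted as NP-only opportunity pathways.
#' @param ppi_within_pathway_edge_p,ppi_background_edge_p PPI edge
#'   probabilities.
#' @param driver_extra_degree extra random PPI edges attached per driver.
#' @return validated config list of class "scenario_config".
#' @export
scenario_config <- function(seed = 1,
                            n_np_compounds = 150,
                            n_ct_compounds = 50,
                            n_targets = 500,
                            n_families = 12,
                            n_pathways = 60,
                            entity_level_fraction = 0.5,
                            pathway_size_range = c(8, 30),
                            driver_fraction = 0.1,
                            n_tumor_types = 20,
                            n_sources = 7,
                            p_literature_ref = 0.2,
                            p_binding_value = 0.35,
                            ct_p_literature_ref = 0.95,
                            ct_p_binding_value = 0.9,
                            p_relation_qualifier = 0.1,
                            affinity_log10_nM_mean = 2.2,
                            affinity_log10_nM_sd = 1.3,
                            mean_targets_per_compound = 5,
                            family_affinity_bias = 8,
                            n_planted_enriched_pathways = 6,
                            n_planted_opportunity_pathways = 3,
                            ppi_within_pathway_edge_p = 0.15,
                            ppi_background_edge_p = 0.004,
                            driver_extra_degree = 15) {
  cfg <- as.list(environment())
  probs <- c("entity_level_fraction", "driver_fraction", "p_literature_ref",
             "p_binding_value", "ct_p_literature_ref", "ct_p_binding_value",
             "p_relation_qualifier", "ppi_within_pathway_edge_p",
             "ppi_background_edge_p")
  for (p in probs) {
    stopifnot_msg(cfg[[p]] >= 0 && cfg[[p]] <= 1, "%s must be in [0,1]", p)
  }
  counts <- c("n_np_compounds", "n_ct_compounds", "n_targets", "n_families",
              "n_pathways", "n_tumor_types", "n_sources")
  for (cn in counts) {
    stopifnot_msg(cfg[[cn]] >= 1, "%s must be a positive count", cn)
  }
  stopifnot_msg(length(pathway_size_range) == 2 &&
                  pathway_size_range[1] >= 2 &&
                  pathway_size_range[1] <= pathway_size_range[2],
                "pathway_size_range must be (min >= 2, max >= min)")
  stopifnot_msg(mean_targets_per_compound > 0,
                "mean_targets_per_compound must be positive")
  stopifnot_msg(family_affinity_bias > 0,
                "family_affinity_bias must be positive")
  stopifnot_msg(driver_extra_degree >= 0, "driver_extra_degree must be >= 0")
  stopifnot_msg(n_planted_enriched_pathways >= 0 &&
                  n_planted_enriched_pathways <= n_pathways,
                "more planted enriched pathways than pathways")
  stopifnot_msg(n_planted_opportunity_pathways >= 0 &&
                  n_planted_opportunity_pathways <= n_planted_enriched_pathways,
                "planted opportunity pathways must be a subset of planted enriched pathways")
  n_drivers <- floor(driver_fraction * n_targets)
  if (n_planted_enriched_pathways > 0) {
    stopifnot_msg(n_drivers >= 2,
                  "planting enriched pathways requires >= 2 driver genes (driver_fraction too small)")
  }
  structure(cfg, class = "scenario_config")
}

#' Generate evidence items for a set of compound-target pairs
#'
#' Each pair receives 1..n_sources evidence items from distinct sources.
#' Per item, a literature reference is present with the class's reference
#' probability and a binding value with the class's value probability
#' (for CT items a binding value forces a reference); binding values are
#' drawn log10-normally in nM and a configurable fraction is reported as a
#' relation-qualified bound (lt/gt) instead of an exact value.
#'
#' @param pairs data.frame `compound_id`, `target_id`, `class`.
#' @param config scenario configuration.
#' @return data.frame of evidence items: `compound_id`, `target_id`,
#'   `class`, `source_db`, `literature_ref_id`, `assay_type`, `relation`,
#'   `value_nM`, `unit`.
#' @export
generate_evidence_mixture <- function(pairs, config) {
  stopifnot_msg(nrow(pairs) >= 1, "no interactions supplied")
  n_items <- 1L + stats::rbinom(nrow(pairs), config$n_sources - 1L, 0.15)
  idx <- rep(seq_len(nrow(pairs)), n_items)
  ev <- pairs[idx, c("compound_id", "target_id", "class"), drop = FALSE]
  rownames(ev) <- NULL
  # distinct source per item within one pair
  ev$source_db <- unlist(lapply(n_items, function(k) {
    paste0("S", sort(sample.int(config$n_sources, k)))
  }), use.names = FALSE)
  m <- nrow(ev)
  is_ct <- ev$class == "CT"
  p_ref <- ifelse(is_ct, config$ct_p_literature_ref, config$p_literature_ref)
  p_val <- ifelse(is_ct, config$ct_p_binding_value, config$p_binding_value)
  has_ref <- stats::runif(m) < p_ref
  has_val <- stats::runif(m) < p_val
  # a CT-class binding value always carries an accessible reference
  has_ref <- has_ref | (has_val & is_ct)
  ev$literature_ref_id <- ifelse(has_ref,
                                 sprintf("REF%06d", sample.int(10^6 - 1, m,
                                                               replace = TRUE)),
                                 NA_character_)
  value <- round(10^stats::rnorm(m, config$affinity_log10_nM_mean,
                                 config$affinity_log10_nM_sd), 4)
  qualified <- stats::runif(m) < config$p_relation_qualifier
  ev$assay_type <- ifelse(has_val, sample(ASSAY_TYPES, m, replace = TRUE),
                          NA_character_)
  ev$relation <- ifelse(has_val,
                        ifelse(qualified,
                               sample(c("lt", "gt"), m, replace = TRUE),
                               "exact"),
                        NA_character_)
  ev$value_nM <- ifelse(has_val, value, NA_real_)
  ev$unit <- ifelse(has_val, "nM", NA_character_)
  ev
}

#' Generate a complete synthetic input scenario on disk
#'
#' Writes compounds.tsv (NP and CT source records), interactions.tsv (one
#' row per evidence item), pathways.gmt, pathway_hierarchy.tsv, ppi.tsv,
#' drivers.tsv, families.tsv, exclusion_list.tsv, truth.json and
#' run_manifest.json under `dir`, and returns the planted ground truth.
#'
#' Planted driver-enriched pathways draw 75% of their members from the
#' driver set (well above the scenario-wide driver fraction); planted
#' opportunity pathways additionally receive at least one NP interaction
#' with an exact binding value < 100 nM while every CT exact value on their
#' member genes is pushed to >= 100 nM.
#'
#' @param config scenario configuration from [scenario_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the ScenarioTruth list: `planted_enriched_pathway_ids`,
#'   `planted_opportunity_pathway_ids`, `planted_family_of_compound`,
#'   `planted_driver_set`, plus `files` (named paths).
#' @export
generate_scenario <- function(config, dir) {
  stopifnot_msg(inherits(config, "scenario_config"),
                "config must come from scenario_config()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  targets <- sprintf("G%04d", seq_len(config$n_targets))
  family_ids <- sprintf("FAM%02d", seq_len(config$n_families))
  target_family <- sample(family_ids, config$n_targets, replace = TRUE)
  names(target_family) <- targets

  n_drivers <- floor(config$driver_fraction * config$n_targets)
  drivers <- sort(sample(targets, n_drivers))
  tumor_ids <- sprintf("TT%02d", seq_len(config$n_tumor_types))
  driver_tumors <- lapply(drivers, function(d) {
    sort(sample(tumor_ids, sample(1:3, 1)))
  })

  # pathways: planted enriched pathways are driver-dense (75% members
  # drivers), others sample uniformly from all targets
  pathway_ids <- sprintf("PW%03d", seq_len(config$n_pathways))
  planted_enriched <- if (config$n_planted_enriched_pathways > 0) {
    pathway_ids[seq_len(config$n_planted_enriched_pathways)]
  } else {
    character(0)
  }
  planted_opportunity <- if (config$n_planted_opportunity_pathways > 0) {
    planted_enriched[seq_len(config$n_planted_opportunity_pathways)]
  } else {
    character(0)
  }
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  pathways <- stats::setNames(vector("list", config$n_pathways), pathway_ids)
  for (i in seq_len(config$n_pathways)) {
    if (pathway_ids[i] %in% planted_enriched) {
      k_driver <- min(max(ceiling(0.75 * sizes[i]), 2), length(drivers))
      k_other <- sizes[i] - k_driver
      genes <- c(sample(drivers, k_driver),
                 if (k_other > 0) sample(setdiff(targets, drivers), k_other))
    } else {
      genes <- sample(targets, sizes[i])
    }
    pathways[[i]] <- sort(genes)
  }
  # closed world: every target belongs to >= 1 pathway
  orphans <- setdiff(targets, unique(unlist(pathways, use.names = FALSE)))
  non_planted <- setdiff(pathway_ids, planted_enriched)
  if (length(orphans) > 0 && length(non_planted) > 0) {
    host <- sample(non_planted, length(orphans), replace = TRUE)
    for (j in seq_along(orphans)) {
      pathways[[host[j]]] <- sort(c(pathways[[host[j]]], orphans[j]))
    }
  }

  # hierarchy: a random forest; entity-level pathways are leaves
  n_entity <- floor(config$entity_level_fraction * config$n_pathways)
  entity_ids <- sort(sample(pathway_ids, n_entity))
  internal <- setdiff(pathway_ids, entity_ids)
  parent <- stats::setNames(rep(NA_character_, config$n_pathways), pathway_ids)
  if (length(internal) > 1) {
    for (i in seq_along(internal)[-1]) {
      if (stats::runif(1) < 0.7) {
        parent[internal[i]] <- sample(internal[seq_len(i - 1)], 1)
      }
    }
  }
  if (length(internal) > 0) {
    for (e in entity_ids) {
      if (stats::runif(1) < 0.8) parent[e] <- sample(internal, 1)
    }
  }

  # compounds: one family each; multi-key identities; 1-2 source records
  n_np <- config$n_np_compounds
  n_ct <- config$n_ct_compounds
  cpd_ids <- c(sprintf("NP%04d", seq_len(n_np)), sprintf("CT%04d", seq_len(n_ct)))
  cpd_class <- c(rep("NP", n_np), rep("CT", n_ct))
  cpd_family <- sample(family_ids, n_np + n_ct, replace = TRUE)
  names(cpd_family) <- cpd_ids

  keys <- data.frame(
    compound_id = cpd_ids, class = cpd_class,
    name = paste0(ifelse(cpd_class == "NP", "natural compound ", "drug "),
                  seq_along(cpd_ids)),
    smiles = sprintf("SMI_%s", cpd_ids),
    inchikey = sprintf("IK%04d-%s-N", seq_along(cpd_ids), substr(cpd_ids, 1, 2)),
    pubchem_cid = as.character(100000 + seq_along(cpd_ids)),
    cas = sprintf("50-%04d-%d", seq_along(cpd_ids), seq_along(cpd_ids) %% 10),
    stringsAsFactors = FALSE)
  np_sources <- c("S1", "S2")
  rec_rows <- lapply(seq_along(cpd_ids), function(i) {
    src1 <- if (cpd_class[i] == "NP") sample(np_sources, 1) else "S3"
    r1 <- data.frame(class = cpd_class[i], name = keys$name[i],
                     smiles = NA_character_, inchikey = keys$inchikey[i],
                     pubchem_cid = NA_character_, cas = keys$cas[i],
                     source_db = src1, compound_id = cpd_ids[i],
                     stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5) {
      src2 <- paste0("S", sample(3:config$n_sources, 1))
      r2 <- data.frame(class = cpd_class[i], name = NA_character_,
                       smiles = keys$smiles[i], inchikey = keys$inchikey[i],
                       pubchem_cid = keys$pubchem_cid[i], cas = NA_character_,
                       source_db = src2, compound_id = cpd_ids[i],
                       stringsAsFactors = FALSE)
      rbind(r1, r2)
    } else {
      r1
    }
  })
  compound_records <- do.call(rbind, rec_rows)
  rownames(compound_records) <- NULL

  # compound-target pairs: targets sampled with within-family odds bias
  pair_rows <- lapply(seq_along(cpd_ids), function(i) {
    k <- min(1L + stats::rpois(1, config$mean_targets_per_compound - 1),
             config$n_targets)
    w <- ifelse(target_family == cpd_family[cpd_ids[i]],
                config$family_affinity_bias, 1)
    tg <- sample(targets, k, prob = w)
    data.frame(compound_id = cpd_ids[i], target_id = tg,
               class = cpd_class[i], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL

  evidence <- generate_evidence_mixture(pairs, config)

  # opportunity planting: scrub CT strong binding off opportunity-pathway
  # genes, then guarantee one NP exact < 100 nM hit per opportunity pathway
  if (length(planted_opportunity) > 0) {
    opp_genes <- unique(unlist(pathways[planted_opportunity],
                               use.names = FALSE))
    bump <- evidence$class == "CT" & evidence$target_id %in% opp_genes &
      !is.na(evidence$value_nM) & evidence$value_nM < 100
    evidence$value_nM[bump] <- round(evidence$value_nM[bump] + 150, 4)
    np_ids <- cpd_ids[cpd_class == "NP"]
    for (p in planted_opportunity) {
      gene <- sample(pathways[[p]], 1)
      cpd <- sample(np_ids, 1)
      evidence <- rbind(evidence, data.frame(
        compound_id = cpd, target_id = gene, class = "NP",
        source_db = "S1",
        literature_ref_id = sprintf("REF%06d", sample.int(10^6 - 1, 1)),
        assay_type = sample(ASSAY_TYPES, 1), relation = "exact",
        value_nM = round(stats::runif(1, 1, 90), 4), unit = "nM",
        stringsAsFactors = FALSE))
    }
  }
  rownames(evidence) <- NULL

  # PPI: within-pathway edges, background edges, extra driver edges; every
  # interacting target guaranteed non-isolated
  edge_keys <- character(0)
  add_edges <- function(a, b, keys) {
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    k <- paste(lo, hi, sep = "\r")
    new <- !duplicated(k) & !(k %in% keys)
    list(a = lo[new], b = hi[new], keys = c(keys, k[new]))
  }
  ppi_a <- character(0); ppi_b <- character(0)
  for (p in pathway_ids) {
    g <- pathways[[p]]
    if (length(g) < 2) next
    prs <- utils::combn(g, 2)
    pick <- stats::runif(ncol(prs)) < config$ppi_within_pathway_edge_p
    if (any(pick)) {
      res <- add_edges(prs[1, pick], prs[2, pick], edge_keys)
      ppi_a <- c(ppi_a, res$a); ppi_b <- c(ppi_b, res$b)
      edge_keys <- res$keys
    }
  }
  n_bg <- stats::rbinom(1, choose(config$n_targets, 2),
                        config$ppi_background_edge_p)
  if (n_bg > 0) {
    res <- add_edges(sample(targets, n_bg, replace = TRUE),
                     sample(targets, n_bg, replace = TRUE), edge_keys)
    ppi_a <- c(ppi_a, res$a); ppi_b <- c(ppi_b, res$b)
    edge_keys <- res$keys
  }
  if (config$driver_extra_degree > 0) {
    for (d in drivers) {
      res <- add_edges(rep(d, config$driver_extra_degree),
                       sample(setdiff(targets, d), config$driver_extra_degree),
                       edge_keys)
      ppi_a <- c(ppi_a, res$a); ppi_b <- c(ppi_b, res$b)
      edge_keys <- res$keys
    }
  }
  deg_nodes <- unique(c(ppi_a, ppi_b))
  isolated <- setdiff(unique(evidence$target_id), deg_nodes)
  for (t in isolated) {
    res <- add_edges(t, sample(setdiff(targets, t), 1), edge_keys)
    ppi_a <- c(ppi_a, res$a); ppi_b <- c(ppi_b, res$b)
    edge_keys <- res$keys
  }
  ppi <- data.frame(from = ppi_a, to = ppi_b, stringsAsFactors = FALSE)
  ppi <- ppi[order(ppi$from, ppi$to), , drop = FALSE]
  rownames(ppi) <- NULL

  # exclusion planting: 3 NP compounds whose (uppercased) names appear on
  # the drug exclusion list
  excluded <- sort(sample(cpd_ids[cpd_class == "NP"], min(3, n_np)))
  exclusion <- data.frame(
    name = toupper(keys$name[match(excluded, keys$compound_id)]),
    smiles = NA_character_, inchikey = NA_character_,
    pubchem_cid = NA_character_, cas = NA_character_,
    stringsAsFactors = FALSE)

  files <- c(
    compounds = file.path(dir, "compounds.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    pathway_hierarchy = file.path(dir, "pathway_hierarchy.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    drivers = file.path(dir, "drivers.tsv"),
    families = file.path(dir, "families.tsv"),
    exclusion_list = file.path(dir, "exclusion_list.tsv"),
    truth = file.path(dir, "truth.json"),
    run_manifest = file.path(dir, "run_manifest.json"))

  write_tsv(compound_records, files[["compounds"]])
  write_tsv(evidence[, c("compound_id", "target_id", "source_db",
                         "literature_ref_id", "assay_type", "relation",
                         "value_nM", "unit")], files[["interactions"]])
  write_gmt(pathways, files[["pathways"]])
  write_tsv(data.frame(pathway_id = pathway_ids,
                       parent_id = unname(parent[pathway_ids]),
                       entity_level = pathway_ids %in% entity_ids,
                       stringsAsFactors = FALSE),
            files[["pathway_hierarchy"]])
  write_tsv(ppi, files[["ppi"]])
  write_tsv(data.frame(gene = rep(drivers, lengths(driver_tumors)),
                       tumor_type = unlist(driver_tumors, use.names = FALSE),
                       stringsAsFactors = FALSE),
            files[["drivers"]])
  write_tsv(data.frame(target_id = targets,
                       family = unname(target_family),
                       stringsAsFactors = FALSE),
            files[["families"]])
  write_tsv(exclusion, files[["exclusion_list"]])

  truth <- list(
    planted_enriched_pathway_ids = planted_enriched,
    planted_opportunity_pathway_ids = planted_opportunity,
    planted_family_of_compound = as.list(cpd_family),
    planted_driver_set = drivers,
    planted_excluded_np = excluded)
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE)
  jsonlite::write_json(list(seed = config$seed, config = unclass(config),
                            n_targets = config$n_targets,
                            n_evidence_items = nrow(evidence),
                            n_ppi_edges = nrow(ppi)),
                       files[["run_manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  truth$files <- files
  invisible(truth)
}

#' Load the files of a generated scenario
#'
#' @param dir scenario directory from [generate_scenario()].
#' @return list: `compounds` (source records), `evidence` (items with
#'   derived levels), `pathways` (gene-set list), `hierarchy`, `ppi_path`,
#'   `drivers`, `families`, `exclusion`, `truth`.
#' @export
load_scenario <- function(dir) {
  ev <- read_interactions(file.path(dir, "interactions.tsv"))
  compounds <- read_tsv(file.path(dir, "compounds.tsv"))
  cls <- stats::setNames(compounds$class, compounds$compound_id)
  ev$class <- unname(cls[ev$compound_id])
  list(
    compounds = compounds,
    evidence = ev,
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    hierarchy = read_tsv(file.path(dir, "pathway_hierarchy.tsv")),
    ppi_path = file.path(dir, "ppi.tsv"),
    drivers = read_tsv(file.path(dir, "drivers.tsv")),
    families = read_tsv(file.path(dir, "families.tsv")),
    exclusion = read_tsv(file.path(dir, "exclusion_list.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE))
}
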