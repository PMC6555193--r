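# Coverage comparison between natural products (NP) and cancer drugs (CT):
# four-way classification of targets / pathways / drivers / tumor types by
# which compound class hits them, stratified by evidence level and binding
# affinity, plus per-compound promiscuity distribution comparisons.

COVERAGE_LABELS <- c("NP_ONLY", "CT_ONLY", "BOTH", "NEITHER")

#' Classify entities by compound-class coverage
#'
#' An entity (target, pathway, or network node) is covered by a class when
#' its gene set intersects that class's hit targets. A pathway counts as
#' targeted as soon as one member target is hit; BOTH does not require any
#' single shared target.
#'
#' @param np_targets character vector of targets hit by NP compounds.
#' @param ct_targets character vector of targets hit by CT drugs.
#' @param membership named list mapping entity id to its gene set; for
#'   target-level classification pass the identity mapping (or a character
#'   vector of target ids).
#' @return data.frame `entity_id`, `label` in
#'   NP_ONLY/CT_ONLY/BOTH/NEITHER; labels partition the entity universe.
#' @export
classify_entities <- function(np_targets, ct_targets, membership) {
  if (is.character(membership)) {
    membership <- stats::setNames(as.list(membership), membership)
  }
  stopifnot_msg(!is.null(names(membership)), "membership must be named")
  empty <- vapply(membership, function(g) length(g) == 0, TRUE)
  if (any(empty)) {
    warning(sprintf("%d entit(ies) with empty membership classified NEITHER",
                    sum(empty)))
  }
  np_hit <- vapply(membership, function(g) any(g %in% np_targets), TRUE)
  ct_hit <- vapply(membership, function(g) any(g %in% ct_targets), TRUE)
  label <- ifelse(np_hit & ct_hit, "BOTH",
                  ifelse(np_hit, "NP_ONLY",
                         ifelse(ct_hit, "CT_ONLY", "NEITHER")))
  data.frame(entity_id = names(membership), label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Targets hit by a class within a stratum (levels subset + optional affinity
# threshold).
stratum_targets <- function(interactions, levels, threshold_nM = NULL,
                            class = NULL) {
  keep <- interactions$max_level %in% levels
  if (!is.null(threshold_nM) && !is.na(threshold_nM)) {
    keep <- keep & !is.na(interactions$best_exact_value_nM) &
      interactions$best_exact_value_nM < threshold_nM
  }
  if (!is.null(class)) keep <- keep & interactions$class == class
  unique(interactions$target_id[keep])
}

#' Default evidence/affinity strata
#'
#' The four standard table rows: all evidence levels; levels II-III; level
#' III; level III restricted to exact binding < 100 nM.
#'
#' @param threshold_nM affinity threshold for the strongest stratum.
#' @return list of strata (name, levels, threshold_nM).
#' @export
default_strata <- function(threshold_nM = 100) {
  list(
    list(name = "Evidence levels I, II, III", levels = c("I", "II", "III"),
         threshold_nM = NA_real_),
    list(name = "Evidence levels II, III", levels = c("II", "III"),
         threshold_nM = NA_real_),
    list(name = "Evidence levels III", levels = "III",
         threshold_nM = NA_real_),
    list(name = sprintf("Evidence level III, binding LT%d", threshold_nM),
         levels = "III", threshold_nM = as.numeric(threshold_nM))
  )
}

#' Coverage table across evidence/affinity strata
#'
#' One row per stratum: unique-target counts (target-level classification)
#' and pathway counts with percents of the supplied pathway universe
#' (pathway-level classification). Pass the driver-enriched pathway subset
#' to obtain the cancer-pathway variant.
#'
#' @param interactions aggregated interactions with a `class` column.
#' @param pathways named list of pathway gene sets (the pathway universe).
#' @param strata list as produced by [default_strata()].
#' @return data.frame of CoverageRow records; percents are rounded to 2
#'   decimals.
#' @export
coverage_table <- function(interactions, pathways, strata = default_strata()) {
  stopifnot_msg(length(pathways) > 0, "empty pathway universe")
  n_univ <- length(pathways)
  rows <- lapply(strata, function(s) {
    np <- stratum_targets(interactions, s$levels, s$threshold_nM, "NP")
    ct <- stratum_targets(interactions, s$levels, s$threshold_nM, "CT")
    # restrict target counts to targets appearing in the pathway universe
    univ_genes <- unique(unlist(pathways, use.names = FALSE))
    npu <- intersect(np, univ_genes)
    ctu <- intersect(ct, univ_genes)
    pcls <- classify_entities(np, ct, pathways)
    pn <- table(factor(pcls$label, levels = COVERAGE_LABELS))
    data.frame(
      stratum = s$name,
      n_targets_np_only = length(setdiff(npu, ctu)),
      n_targets_ct_only = length(setdiff(ctu, npu)),
      n_targets_both = length(intersect(npu, ctu)),
      n_pathways_np_only = as.integer(pn[["NP_ONLY"]]),
      n_pathways_ct_only = as.integer(pn[["CT_ONLY"]]),
      n_pathways_both = as.integer(pn[["BOTH"]]),
      pct_np_only = round(100 * pn[["NP_ONLY"]] / n_univ, 2),
      pct_ct_only = round(100 * pn[["CT_ONLY"]] / n_univ, 2),
      pct_both = round(100 * pn[["BOTH"]] / n_univ, 2),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative coverage increase attributable to NP-only entities
#'
#' `100 * np_only / (ct_only + both)`: the headline percentage by which
#' adding natural products grows the covered set relative to drug-covered
#' entities. The reporting layer rounds to the nearest integer percent.
#'
#' @param np_only,ct_only,both non-negative counts.
#' @return unrounded percent.
#' @export
relative_increase <- function(np_only, ct_only, both) {
  stopifnot_msg(all(c(np_only, ct_only, both) >= 0), "counts must be >= 0")
  if (ct_only + both == 0) {
    stop("relative increase undefined: no CT-covered entities (division by zero)",
         call. = FALSE)
  }
  100 * np_only / (ct_only + both)
}

#' Share of NP-only target coverage within pathways covered by both classes
#'
#' Over all (pathway, target) pairs where the pathway is classified BOTH and
#' the member target is covered by any interaction in the stratum, the
#' fraction of pairs whose target is NP_ONLY.
#'
#' @param pathway_labels data.frame from [classify_entities()] at pathway
#'   level.
#' @param target_labels data.frame from [classify_entities()] at target
#'   level (identity membership over the covered-target universe).
#' @param pathways named list of pathway gene sets.
#' @return fraction in `[0,1]`.
#' @export
within_pathway_interaction_share <- function(pathway_labels, target_labels,
                                             pathways) {
  both_ids <- pathway_labels$entity_id[pathway_labels$label == "BOTH"]
  stopifnot_msg(length(both_ids) > 0, "no pathway classified BOTH")
  tl <- stats::setNames(target_labels$label, target_labels$entity_id)
  covered <- names(tl)[tl %in% c("NP_ONLY", "CT_ONLY", "BOTH")]
  n_pairs <- 0L
  n_np <- 0L
  for (p in both_ids) {
    members <- intersect(pathways[[p]], covered)
    n_pairs <- n_pairs + length(members)
    n_np <- n_np + sum(tl[members] == "NP_ONLY")
  }
  if (n_pairs == 0) return(NA_real_)
  n_np / n_pairs
}

#' Driver coverage per tumor type
#'
#' For each tumor type, counts of its driver genes in each coverage class at
#' the affinity threshold, plus the total driver count. A tumor type is
#' "NP-improved" iff at least one of its drivers is covered by NPs only.
#'
#' @param drivers data.frame with columns `gene` and `tumor_type` (one row
#'   per association).
#' @param interactions aggregated interactions with a `class` column.
#' @param threshold_nM affinity threshold (default 100).
#' @return data.frame `tumor_type`, `ct_only`, `np_only`, `both`,
#'   `total_drivers`, `np_improved`.
#' @export
driver_tumor_coverage <- function(drivers, interactions, threshold_nM = 100) {
  stopifnot_msg(all(c("gene", "tumor_type") %in% names(drivers)),
                "drivers needs columns gene, tumor_type")
  np <- stratum_targets(interactions, EVIDENCE_LEVELS, threshold_nM, "NP")
  ct <- stratum_targets(interactions, EVIDENCE_LEVELS, threshold_nM, "CT")
  genes <- unique(drivers$gene)
  cls <- classify_entities(np, ct, genes)
  lab <- stats::setNames(cls$label, cls$entity_id)
  rows <- lapply(split(drivers$gene, drivers$tumor_type), function(g) {
    g <- unique(g)
    tab <- table(factor(lab[g], levels = COVERAGE_LABELS))
    data.frame(ct_only = as.integer(tab[["CT_ONLY"]]),
               np_only = as.integer(tab[["NP_ONLY"]]),
               both = as.integer(tab[["BOTH"]]),
               total_drivers = length(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(tumor_type = names(rows), stringsAsFactors = FALSE),
               out)
  out$np_improved <- out$np_only >= 1
  rownames(out) <- NULL
  out[order(out$tumor_type), , drop = FALSE]
}

#' Per-compound interaction distributions and KS comparisons
#'
#' For each entity type (targets, pathways, tumor types, drivers) and
#' affinity threshold, the per-compound counts for NP and CT compounds and a
#' two-sided two-sample Kolmogorov-Smirnov comparison (asymptotic p).
#' Compounds with zero qualifying interactions are excluded by default.
#' Significance is flagged at the Bonferroni-adjusted threshold 0.004.
#'
#' @param interactions aggregated interactions with a `class` column.
#' @param pathways named list of pathway gene sets; per-compound pathway
#'   count = number of pathways containing any of the compound's qualifying
#'   targets.
#' @param drivers data.frame `gene`, `tumor_type`.
#' @param thresholds numeric affinity thresholds (default 100 and 1000 nM).
#' @param cancer_pathway_ids optional pathway id subset for cancer-pathway
#'   variants (adds target/pathway rows restricted to that subset).
#' @param include_zero include compounds with zero qualifying interactions
#'   at count 0 (default FALSE).
#' @param p_threshold significance threshold (default 0.004).
#' @return list with `distributions` (data.frame `type`, `threshold_nM`,
#'   `class`, `compound_id`, `count`) and `tests` (data.frame `type`,
#'   `threshold_nM`, `n_np`, `n_ct`, `D`, `p_value`, `significant`).
#' @export
per_compound_distributions <- function(interactions, pathways, drivers,
                                       thresholds = c(100, 1000),
                                       cancer_pathway_ids = NULL,
                                       include_zero = FALSE,
                                       p_threshold = 0.004) {
  driver_genes <- unique(drivers$gene)
  tumor_of <- split(drivers$tumor_type, drivers$gene)
  dist_rows <- list()
  test_rows <- list()

  count_per_compound <- function(sub, value_fun) {
    by_cpd <- split(sub$target_id, sub$compound_id)
    vapply(by_cpd, value_fun, 1L)
  }

  types <- list(
    targets = function(tg) length(unique(tg)),
    pathways = function(tg) sum(vapply(pathways,
                                       function(g) any(tg %in% g), TRUE)),
    tumor_types = function(tg) {
      length(unique(unlist(tumor_of[intersect(unique(tg), driver_genes)],
                           use.names = FALSE)))
    },
    drivers = function(tg) length(intersect(unique(tg), driver_genes))
  )
  if (!is.null(cancer_pathway_ids)) {
    cp <- pathways[cancer_pathway_ids]
    cp_genes <- unique(unlist(cp, use.names = FALSE))
    types$cancer_pathway_targets <- function(tg) {
      length(intersect(unique(tg), cp_genes))
    }
    types$cancer_pathways <- function(tg) {
      sum(vapply(cp, function(g) any(tg %in% g), TRUE))
    }
  }

  for (thr in thresholds) {
    sub <- filter_by_affinity(interactions, thr)
    for (type in names(types)) {
      counts <- count_per_compound(sub, types[[type]])
      cls <- stats::setNames(sub$class[!duplicated(sub$compound_id)],
                             sub$compound_id[!duplicated(sub$compound_id)])
      if (include_zero) {
        all_cls <- stats::setNames(
          interactions$class[!duplicated(interactions$compound_id)],
          interactions$compound_id[!duplicated(interactions$compound_id)])
        zero <- setdiff(names(all_cls), names(counts))
        counts <- c(counts, stats::setNames(rep(0L, length(zero)), zero))
        cls <- all_cls[names(counts)]
      }
      np <- counts[cls[names(counts)] == "NP"]
      ct <- counts[cls[names(counts)] == "CT"]
      dist_rows[[length(dist_rows) + 1]] <- data.frame(
        type = type, threshold_nM = thr,
        class = as.character(cls[names(counts)]),
        compound_id = names(counts), count = as.integer(counts),
        stringsAsFactors = FALSE, row.names = NULL)
      if (length(np) < 2 || length(ct) < 2) {
        warning(sprintf("%s at <%g nM: <2 qualifying compounds in a class; KS skipped",
                        type, thr))
        next
      }
      ks <- suppressWarnings(stats::ks.test(np, ct, exact = FALSE))
      test_rows[[length(test_rows) + 1]] <- data.frame(
        type = type, threshold_nM = thr, n_np = length(np),
        n_ct = length(ct), D = unname(ks$statistic),
        p_value = ks$p.value, significant = ks$p.value < p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  list(distributions = do.call(rbind, dist_rows),
       tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL)
}
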