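# Three-tier evidence framework for compound-target interactions.
#
# Each database entry supporting a compound-target pair is one evidence item.
# Level I:   database entry only (no accessible literature reference and no
#            binding value with a reference).
# Level II:  literature reference, no binding affinity value.
# Level III: both an experimental binding value and a literature reference.
# A pair's level is the maximum over its items; a target's level is the
# maximum over the pairs that touch it. Affinity filtering considers only
# exact-relation assay values (IC50, EC50, Ki, KD) in nM.

ASSAY_TYPES <- c("IC50", "EC50", "Ki", "KD")

#' Assign the evidence level of a single evidence item
#'
#' Level III iff the item has both a binding value and a literature
#' reference; Level II iff it has a reference but no value; Level I
#' otherwise (including a value without an accessible reference).
#'
#' @param has_literature_ref logical vector.
#' @param value_nM numeric vector, NA when no binding value.
#' @return character vector of levels in `c("I","II","III")`.
#' @export
assign_evidence_level <- function(has_literature_ref, value_nM) {
  stopifnot_msg(length(has_literature_ref) == length(value_nM),
                "has_literature_ref and value_nM lengths differ")
  has_val <- !is.na(value_nM)
  ref <- !is.na(has_literature_ref) & has_literature_ref
  ifelse(has_val & ref, "III", ifelse(ref, "II", "I"))
}

#' Read an interaction-evidence table from TSV
#'
#' Expected columns: `compound_id`, `target_id`, `source_db`,
#' `literature_ref_id` (empty allowed), `assay_type`, `relation`
#' (exact/lt/gt), `value_nM`, `unit`. Rows carrying a binding value with a
#' unit other than "nM" are rejected: no unit conversion layer is provided,
#' inputs must already be in nM.
#'
#' @param path TSV path.
#' @return data.frame of evidence items with derived columns
#'   `has_literature_ref` (logical) and `level`.
#' @export
read_interactions <- function(path) {
  df <- read_tsv(path, colClasses = list(literature_ref_id = "character"))
  needed <- c("compound_id", "target_id", "source_db", "literature_ref_id",
              "assay_type", "relation", "value_nM", "unit")
  missing_cols <- setdiff(needed, names(df))
  stopifnot_msg(length(missing_cols) == 0,
                "interactions file missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  df$value_nM <- as.numeric(df$value_nM)
  bad_unit <- which(!is.na(df$value_nM) & (is.na(df$unit) | df$unit != "nM"))
  if (length(bad_unit) > 0) {
    stop(sprintf("binding values with unit != 'nM' at row(s): %s",
                 paste(utils::head(bad_unit, 10), collapse = ", ")),
         call. = FALSE)
  }
  bad_assay <- which(!is.na(df$value_nM) &
                       (is.na(df$assay_type) | !df$assay_type %in% ASSAY_TYPES |
                          is.na(df$relation) |
                          !df$relation %in% c("exact", "lt", "gt")))
  if (length(bad_assay) > 0) {
    stop(sprintf("binding values without valid assay_type/relation at row(s): %s",
                 paste(utils::head(bad_assay, 10), collapse = ", ")),
         call. = FALSE)
  }
  df$has_literature_ref <- !is.na(df$literature_ref_id) &
    nzchar(df$literature_ref_id)
  df$level <- assign_evidence_level(df$has_literature_ref, df$value_nM)
  df
}

#' Aggregate evidence items for one compound-target pair
#'
#' @param items data.frame of evidence items for a single pair (columns
#'   `compound_id`, `target_id`, `has_literature_ref`, `value_nM`,
#'   `relation`; `level` derived if absent).
#' @return one-row data.frame: `compound_id`, `target_id`, `max_level`,
#'   `best_exact_value_nM` (minimum over exact-relation values, NA if none),
#'   `n_evidence`.
#' @export
aggregate_interaction <- function(items) {
  stopifnot_msg(nrow(items) >= 1, "at least one evidence item required")
  if (length(unique(items$compound_id)) != 1 ||
      length(unique(items$target_id)) != 1) {
    stop("evidence items span more than one (compound_id, target_id) pair",
         call. = FALSE)
  }
  aggregate_interactions(items)
}

#' Aggregate an evidence table to unique compound-target interactions
#'
#' Per pair: `max_level` is the maximum item level; `best_exact_value_nM` the
#' minimum over exact-relation binding values (most potent assay), NA when no
#' exact value exists. Relation-qualified values (lt/gt bounds) never
#' contribute a best value.
#'
#' @param evidence data.frame of evidence items; extra columns `class` and
#'   `source_db` are carried through (`class` must be constant per compound).
#' @return data.frame with one row per (compound_id, target_id).
#' @export
aggregate_interactions <- function(evidence) {
  if (!"level" %in% names(evidence)) {
    evidence$level <- assign_evidence_level(evidence$has_literature_ref,
                                            evidence$value_nM)
  }
  key <- paste(evidence$compound_id, evidence$target_id, sep = "\r")
  idx <- split(seq_len(nrow(evidence)), key)
  idx <- idx[order(names(idx))]
  rows <- lapply(idx, function(i) {
    ev <- evidence[i, , drop = FALSE]
    exact <- !is.na(ev$value_nM) & !is.na(ev$relation) & ev$relation == "exact"
    best <- if (any(exact)) min(ev$value_nM[exact]) else NA_real_
    out <- data.frame(
      compound_id = ev$compound_id[1],
      target_id = ev$target_id[1],
      max_level = rank_level(max(level_rank(ev$level))),
      best_exact_value_nM = best,
      n_evidence = nrow(ev),
      stringsAsFactors = FALSE)
    if ("class" %in% names(ev)) out$class <- ev$class[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum evidence level per target
#'
#' The target-focused view: a target's level is the maximum `max_level` over
#' all interactions touching it, optionally computed separately per compound
#' class.
#'
#' @param interactions aggregated interactions from
#'   [aggregate_interactions()].
#' @param by_class if TRUE, one row per (target_id, class).
#' @return data.frame `target_id` (, `class`), `max_level`.
#' @export
target_max_level <- function(interactions, by_class = FALSE) {
  stopifnot_msg(nrow(interactions) >= 1, "no interactions supplied")
  if (by_class) {
    stopifnot_msg("class" %in% names(interactions),
                  "by_class requires a class column")
    agg <- stats::aggregate(level_rank(interactions$max_level),
                            by = list(target_id = interactions$target_id,
                                      class = interactions$class), FUN = max)
  } else {
    agg <- stats::aggregate(level_rank(interactions$max_level),
                            by = list(target_id = interactions$target_id),
                            FUN = max)
  }
  agg$max_level <- rank_level(agg$x)
  agg$x <- NULL
  agg <- agg[order(agg$target_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Filter interactions by exact binding affinity
#'
#' Keeps interactions whose best exact-relation binding value is strictly
#' below the threshold. Interactions supported only by relation-qualified
#' bounds (lt/gt) never qualify.
#'
#' @param interactions aggregated interactions.
#' @param threshold_nM positive threshold in nM (100 = strong binding).
#' @return the qualifying subset.
#' @export
filter_by_affinity <- function(interactions, threshold_nM) {
  stopifnot_msg(is.numeric(threshold_nM) && threshold_nM > 0,
                "threshold_nM must be positive")
  keep <- !is.na(interactions$best_exact_value_nM) &
    interactions$best_exact_value_nM < threshold_nM
  interactions[keep, , drop = FALSE]
}

#' Summarize interaction and target counts by class and evidence level
#'
#' Produces the level-mixture tables: interaction counts by (class, level)
#' and target counts by (class, max level over the class's interactions),
#' overall and restricted to interactions carrying an exact binding value.
#'
#' @param interactions aggregated interactions with a `class` column.
#' @return list of data.frames `interactions`, `targets`,
#'   `interactions_exact`, `targets_exact`, each with columns `class`,
#'   `level`, `n`, `pct` (percent within class, 2 decimals).
#' @export
summarize_evidence <- function(interactions) {
  stopifnot_msg("class" %in% names(interactions),
                "summarize_evidence requires a class column")
  tab_int <- function(df) {
    if (nrow(df) == 0) {
      return(data.frame(class = character(0), level = character(0),
                        n = integer(0), pct = numeric(0)))
    }
    counts <- as.data.frame(table(class = df$class,
                                  level = factor(df$max_level,
                                                 levels = EVIDENCE_LEVELS)),
                            stringsAsFactors = FALSE)
    names(counts)[3] <- "n"
    totals <- tapply(counts$n, counts$class, sum)
    counts$pct <- round(100 * counts$n / as.numeric(totals[counts$class]), 2)
    counts$pct[is.nan(counts$pct)] <- 0
    counts[order(counts$class, counts$level), , drop = FALSE]
  }
  tab_tgt <- function(df) {
    if (nrow(df) == 0) return(tab_int(df))
    tl <- target_max_level(df, by_class = TRUE)
    names(tl)[names(tl) == "max_level"] <- "max_level"
    tab_int(data.frame(class = tl$class, max_level = tl$max_level,
                       stringsAsFactors = FALSE))
  }
  exact <- interactions[!is.na(interactions$best_exact_value_nM), , drop = FALSE]
  list(interactions = tab_int(interactions),
       targets = tab_tgt(interactions),
       interactions_exact = tab_int(exact),
       targets_exact = tab_tgt(exact))
}
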