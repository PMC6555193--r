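# Driver-gene over-representation: hypergeometric upper-tail test per
# pathway with Benjamini-Yekutieli FDR control (valid under dependency,
# which overlapping pathways induce), and enumeration of NP-only
# therapeutic-opportunity pathways.

#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` driver genes when drawing `n` genes from a universe of `N`
#' containing `K` drivers. Upper tail is inclusive of `k`.
#'
#' @param k observed drivers in the pathway.
#' @param n pathway size.
#' @param K drivers in the universe.
#' @param N universe size.
#' @return p-value in `[0,1]`.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  stopifnot_msg(all(k >= 0 & k <= n & n <= N & k <= K & K <= N),
                "require 0 <= k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjusted p-values with the harmonic-sum correction
#' `c(m) = sum_{i=1..m} 1/i`, valid under arbitrary dependence among tests:
#' sorted ascending, `q_(i) = min(1, p_(i) * m * c(m) / i)` made monotone
#' non-increasing from the largest rank down; returned in input order.
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return adjusted q-values, same order as input.
#' @export
by_adjust <- function(p) {
  stopifnot_msg(all(!is.na(p) & p >= 0 & p <= 1), "p-values must be in [0,1]")
  stats::p.adjust(p, method = "BY")
}

#' Identify driver-enriched (pan-cancer aberrational) pathways
#'
#' One hypergeometric upper-tail test per pathway against the driver set,
#' with BY adjustment across pathways; enriched iff q < alpha. The gene
#' universe defaults to the union of genes over all supplied pathways;
#' drivers absent from the universe are dropped from K (count reported via
#' message).
#'
#' @param pathways named list of pathway gene sets.
#' @param driver_genes character vector of driver gene symbols (non-empty).
#' @param alpha FDR threshold (default 0.05).
#' @param universe optional explicit gene universe.
#' @return list with `enriched_ids` (character) and `results` data.frame
#'   (`pathway_id`, `k`, `n`, `K`, `N`, `p_value`, `q_value`, `enriched`).
#' @export
aberrational_pathways <- function(pathways, driver_genes, alpha = 0.05,
                                  universe = NULL) {
  stopifnot_msg(length(driver_genes) > 0, "empty driver set")
  stopifnot_msg(length(pathways) > 0, "no pathways supplied")
  if (is.null(universe)) {
    universe <- unique(unlist(pathways, use.names = FALSE))
  }
  driver_genes <- unique(driver_genes)
  dropped <- setdiff(driver_genes, universe)
  if (length(dropped) > 0) {
    message(sprintf("%d driver gene(s) absent from the universe dropped from K",
                    length(dropped)))
  }
  drivers <- intersect(driver_genes, universe)
  stopifnot_msg(length(drivers) > 0, "no driver gene present in the universe")
  N <- length(universe)
  K <- length(drivers)
  res <- data.frame(
    pathway_id = names(pathways),
    k = vapply(pathways, function(g) length(intersect(unique(g), drivers)), 1L),
    n = vapply(pathways, function(g) length(intersect(unique(g), universe)), 1L),
    K = K, N = N, stringsAsFactors = FALSE, row.names = NULL)
  res$p_value <- hypergeom_pvalue(res$k, res$n, res$K, res$N)
  res$q_value <- by_adjust(res$p_value)
  res$enriched <- res$q_value < alpha
  list(enriched_ids = res$pathway_id[res$enriched], results = res)
}

#' NP-only therapeutic-opportunity pathways
#'
#' Driver-enriched pathways with no CT drug target at the affinity threshold
#' and at least one NP target at that threshold. Each entry lists the NP
#' targets and compounds involved and flags whether any NP-hit target is
#' itself a driver (distinguishing direct driver engagement from engagement
#' of a non-driver pathway member).
#'
#' @param enriched_ids character vector of enriched pathway ids.
#' @param pathways named list of pathway gene sets.
#' @param interactions aggregated interactions with a `class` column,
#'   already filtered to the affinity threshold (e.g. via
#'   [filter_by_affinity()] at 100 nM).
#' @param driver_genes character vector of driver gene symbols.
#' @return data.frame `pathway_id`, `np_targets`, `np_compounds`
#'   (pipe-delimited), `n_np_targets`, `np_target_is_driver`.
#' @export
np_only_opportunity_pathways <- function(enriched_ids, pathways, interactions,
                                         driver_genes) {
  np_t <- unique(interactions$target_id[interactions$class == "NP"])
  ct_t <- unique(interactions$target_id[interactions$class == "CT"])
  rows <- lapply(enriched_ids, function(p) {
    genes <- unique(pathways[[p]])
    if (any(genes %in% ct_t)) return(NULL)
    hits <- intersect(genes, np_t)
    if (length(hits) == 0) return(NULL)
    cpds <- unique(interactions$compound_id[
      interactions$class == "NP" & interactions$target_id %in% hits])
    data.frame(pathway_id = p,
               np_targets = join_pipe(hits),
               np_compounds = join_pipe(cpds),
               n_np_targets = length(hits),
               np_target_is_driver = any(hits %in% driver_genes),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(pathway_id = character(0), np_targets = character(0),
                      np_compounds = character(0), n_np_targets = integer(0),
                      np_target_is_driver = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
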