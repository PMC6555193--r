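# Compound catalog: multi-key identity merging and exclusion-list scrubbing.
#
# A compound can be keyed by up to five identifiers (chemical name, SMILES,
# InChIKey, PubChem CID, CAS number). Records from different source databases
# are unified whenever they share at least one exactly matching key, taken to
# the transitive closure, mirroring how redundancies are removed when natural
# product source databases are combined.

KEY_FIELDS <- c("name", "smiles", "inchikey", "pubchem_cid", "cas")

# Normalized key value for matching: names are case/whitespace-insensitive,
# every other key is compared verbatim.
normalize_key <- function(field, value) {
  if (field == "name") normalize_name(value) else as.character(value)
}

#' Merge compound records into unique compounds by multi-key identity
#'
#' Two input records belong to the same output compound iff they are connected
#' under the transitive closure of "share at least one exactly matching key"
#' (names matched case-insensitively after whitespace normalization, other
#' keys exactly). Output key fields are the field-wise union; a key field
#' that ends up multi-valued within one merged compound is retained
#' pipe-delimited and flagged in the conflict report.
#'
#' @param records data.frame with columns `class` (NP or CT), the five key
#'   columns `name`, `smiles`, `inchikey`, `pubchem_cid`, `cas` (NA allowed,
#'   at least one non-NA per record), and `source_db`.
#' @return list with:
#'   \describe{
#'     \item{catalog}{data.frame: `compound_id`, `class`, five key columns
#'       (pipe-delimited when multi-valued), `source_dbs` (pipe-delimited),
#'       `n_records`.}
#'     \item{membership}{integer vector mapping input record index to output
#'       compound row.}
#'     \item{conflicts}{data.frame (`compound_id`, `field`, `values`): key
#'       fields carrying more than one distinct value after the merge, plus
#'       any cross-class merges (field `class`).}
#'   }
#' @export
merge_compounds <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("class", KEY_FIELDS, "source_db"), names(records))
  stopifnot_msg(length(missing_cols) == 0,
                "records missing column(s): %s", paste(missing_cols, collapse = ", "))
  n <- nrow(records)
  if (n == 0) {
    return(list(catalog = empty_catalog(), membership = integer(0),
                conflicts = empty_conflicts()))
  }
  all_null <- rowSums(!is.na(records[KEY_FIELDS]) &
                        records[KEY_FIELDS] != "") == 0
  if (any(all_null)) {
    stop(sprintf("record(s) with all-null keys rejected: index %s",
                 paste(which(all_null), collapse = ", ")), call. = FALSE)
  }

  # union-find over records; records sharing a normalized (field, value) pair
  # are unioned, which yields the transitive closure of pairwise key matches
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (field in KEY_FIELDS) {
    vals <- normalize_key(field, records[[field]])
    vals[!is.na(vals) & !nzchar(vals)] <- NA_character_
    groups <- split(seq_len(n)[!is.na(vals)], vals[!is.na(vals)])
    for (g in groups) {
      if (length(g) > 1) for (i in g[-1]) union_(g[1], i)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comp <- match(roots, sort(unique(roots)))

  ids <- sprintf("C%05d", seq_len(max(comp)))
  conflicts <- list()
  rows <- lapply(seq_len(max(comp)), function(ci) {
    idx <- which(comp == ci)
    classes <- sort(unique(records$class[idx]))
    # a record set mixing NP and CT resolves to CT (drug identity dominates)
    cls <- if (length(classes) == 1) classes else "CT"
    if (length(classes) > 1) {
      conflicts[[length(conflicts) + 1]] <<- data.frame(
        compound_id = ids[ci], field = "class",
        values = paste(classes, collapse = "|"), stringsAsFactors = FALSE)
    }
    keys <- lapply(KEY_FIELDS, function(field) {
      vals <- records[[field]][idx]
      vals <- unique(vals[!is.na(vals) & nzchar(vals)])
      if (field == "name") {
        vals <- vals[!duplicated(normalize_name(vals))]
        n_distinct <- length(unique(normalize_name(vals)))
      } else {
        n_distinct <- length(vals)
      }
      if (n_distinct > 1) {
        conflicts[[length(conflicts) + 1]] <<- data.frame(
          compound_id = ids[ci], field = field,
          values = paste(sort(vals), collapse = "|"), stringsAsFactors = FALSE)
      }
      join_pipe(vals)
    })
    names(keys) <- KEY_FIELDS
    cbind(data.frame(compound_id = ids[ci], class = cls,
                     stringsAsFactors = FALSE),
          as.data.frame(keys, stringsAsFactors = FALSE),
          data.frame(source_dbs = join_pipe(records$source_db[idx]),
                     n_records = length(idx), stringsAsFactors = FALSE))
  })
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  conflicts <- if (length(conflicts) > 0) {
    do.call(rbind, conflicts)
  } else {
    empty_conflicts()
  }
  list(catalog = catalog, membership = ids[comp], conflicts = conflicts)
}

empty_catalog <- function() {
  df <- data.frame(compound_id = character(0), class = character(0),
                   stringsAsFactors = FALSE)
  for (f in KEY_FIELDS) df[[f]] <- character(0)
  df$source_dbs <- character(0)
  df$n_records <- integer(0)
  df
}

empty_conflicts <- function() {
  data.frame(compound_id = character(0), field = character(0),
             values = character(0), stringsAsFactors = FALSE)
}

#' Remove natural products matching drug exclusion lists
#'
#' An NP compound is removed when any of its key values matches any exclusion
#' keyset on the same field, under the same matching rules as
#' [merge_compounds()] (names case/whitespace-insensitive, other keys exact).
#' CT compounds are never removed.
#'
#' @param catalog catalog data.frame from [merge_compounds()] (key fields may
#'   be pipe-delimited multi-valued).
#' @param exclusion data.frame with any subset of the five key columns; each
#'   row is one exclusion keyset.
#' @return list with `catalog` (scrubbed) and `removed` (data.frame
#'   `compound_id`, `matched_field`, `matched_value`).
#' @export
scrub_drugs <- function(catalog, exclusion) {
  exclusion <- as.data.frame(exclusion, stringsAsFactors = FALSE)
  removed <- data.frame(compound_id = character(0), matched_field = character(0),
                        matched_value = character(0), stringsAsFactors = FALSE)
  if (nrow(exclusion) == 0 || nrow(catalog) == 0) {
    return(list(catalog = catalog, removed = removed))
  }
  excl_values <- lapply(KEY_FIELDS, function(field) {
    if (!field %in% names(exclusion)) return(character(0))
    v <- normalize_key(field, exclusion[[field]])
    unique(v[!is.na(v) & nzchar(v)])
  })
  names(excl_values) <- KEY_FIELDS

  drop <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    if (catalog$class[i] != "NP") next
    for (field in KEY_FIELDS) {
      vals <- split_pipe(catalog[[field]][i])
      if (length(vals) == 0) next
      hit <- normalize_key(field, vals) %in% excl_values[[field]]
      if (any(hit)) {
        drop[i] <- TRUE
        removed <- rbind(removed, data.frame(
          compound_id = catalog$compound_id[i], matched_field = field,
          matched_value = vals[hit][1], stringsAsFactors = FALSE))
        break
      }
    }
  }
  list(catalog = catalog[!drop, , drop = FALSE], removed = removed)
}

#' Write a compound catalog (and conflict report) to TSV
#'
#' @param merged list from [merge_compounds()].
#' @param path output TSV path for the catalog.
#' @param conflict_path optional path for the conflict report TSV.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(merged, path, conflict_path = NULL) {
  write_tsv(merged$catalog, path)
  if (!is.null(conflict_path)) write_tsv(merged$conflicts, conflict_path)
  invisible(path)
}
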