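#' Read gene sets from a GMT file
#'
#' GMT format: one pathway per line, tab-separated as
#' `pathway_id  description  gene1  gene2 ...`.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (genes), names are pathway ids;
#'   descriptions attached as the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in GMT file", call. = FALSE)
  }
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(desc, ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to the pathway id.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
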