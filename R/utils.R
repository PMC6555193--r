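# Internal helpers shared across modules.

EVIDENCE_LEVELS <- c("I", "II", "III")

#' Normalize a chemical name for matching
#'
#' Lowercases, trims, and collapses internal whitespace. No stemming and no
#' synonym expansion: synonym lists are inputs, not inference.
#'
#' @param x character vector of names (NA allowed).
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  out[is.na(x)] <- NA_character_
  out
}

# level label -> integer rank (I=1, II=2, III=3)
level_rank <- function(level) {
  match(as.character(level), EVIDENCE_LEVELS)
}

rank_level <- function(rank) {
  EVIDENCE_LEVELS[rank]
}

# Deterministic TSV writer: UTF-8, LF line endings, empty string for NA so
# byte-identical reruns are achievable.
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", ...)
}

# split pipe-delimited multi-valued field
split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

join_pipe <- function(x) {
  x <- sort(unique(x[!is.na(x) & nzchar(x)]))
  if (length(x) == 0) NA_character_ else paste(x, collapse = "|")
}

# stop unless all conditions hold; msg sprintf-style
stopifnot_msg <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
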