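#' Build an entity span table
#'
#' Entity spans are the unit of annotation: a typed, contiguous run of
#' characters inside a text. Offsets are 0-based and half-open, i.e. a span
#' `(start, end)` covers characters `start, ..., end - 1`, matching the
#' JSON-lines interchange convention.
#'
#' @param start,end Integer vectors of 0-based half-open character offsets.
#' @param type Character vector of entity type labels (e.g. `"Symptom"`).
#' @param surface Optional character vector of covered text; computed from
#'   `text` when omitted.
#' @param text Optional sentence/record text used to fill in `surface`.
#' @return A tibble with columns `start`, `end`, `type`, `surface`, sorted by
#'   `start`.
#' @examples
#' entity_spans(0, 3, "Exam", text = "心电图检查")
#' @export
entity_spans <- function(start = integer(), end = integer(), type = character(),
                         surface = NULL, text = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.null(surface)) {
    surface <- if (is.null(text)) NA_character_ else str_slice(text, start, end)
  }
  type <- rep_len(as.character(type), length(start))
  surface <- rep_len(as.character(surface), length(start))
  o <- order(start)
  tibble::new_tibble(list(start = start[o], end = end[o], type = type[o],
                          surface = surface[o]), nrow = length(start))
}

# shared span validation; `what` identifies the offending record/sentence in
# error messages
validate_spans <- function(text, spans, what = "record") {
  if (is.null(spans) || nrow(spans) == 0L) {
    return(entity_spans())
  }
  stopifnot(all(c("start", "end", "type", "surface") %in% names(spans)))
  n <- str_length(text)
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
  if (any(bad)) {
    abort(sprintf("%s: span (%d,%d) out of range for text of length %d",
                  what, spans$start[which(bad)[1]], spans$end[which(bad)[1]], n))
  }
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    abort(sprintf("%s: overlapping entity spans", what))
  }
  sliced <- str_slice(text, spans$start, spans$end)
  if (anyNA(spans$surface)) {
    spans$surface[is.na(spans$surface)] <- sliced[is.na(spans$surface)]
  }
  mism <- spans$surface != sliced
  if (any(mism)) {
    abort(sprintf("%s: surface %s does not match text slice %s", what,
                  spans$surface[which(mism)[1]], sliced[which(mism)[1]]))
  }
  spans[, c("start", "end", "type", "surface")]
}

# validate every row of a record/sentence tibble in place
validate_corpus <- function(x, id_col) {
  x[[id_col]] <- as.character(x[[id_col]])
  x$entities <- map2(x$text, seq_len(nrow(x)), function(txt, i) {
    validate_spans(txt, x$entities[[i]],
                   what = sprintf("%s %s", id_col, x[[id_col]][i]))
  })
  x
}

# pick the identifier column of a record- or sentence-level tibble
corpus_id_col <- function(x) {
  for (col in c("sent_id", "record_id", "doc_id")) {
    if (col %in% names(x)) return(col)
  }
  abort("expected a `sent_id` or `record_id` column")
}

# flat entity table (one row per span) with the parent id attached
unnest_entities <- function(x, id_col = corpus_id_col(x)) {
  ents <- imap(x$entities, function(e, i) {
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    e$.id <- x[[id_col]][i]
    e
  })
  out <- list_rbind(ents)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(start = integer(), end = integer(), type = character(),
                  surface = character(), .id = character())
  }
  names(out)[names(out) == ".id"] <- id_col
  as_tibble(out)
}
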