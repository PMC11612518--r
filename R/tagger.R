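#' Build a gazetteer from a training corpus
#'
#' Collects every distinct entity surface seen in training and assigns it
#' one type by majority vote over its annotated occurrences; ties go to the
#' lexicographically smallest type (a message notes each tie). The gazetteer
#' makes the augment-tag-evaluate loop runnable without a learned model: any
#' benefit of augmentation shows up mechanically as new dictionary entries.
#'
#' @param train Record or sentence tibble with gold annotations.
#' @return A tibble of class `gazetteer`: `surface`, `type`, `n` (occurrence
#'   count of the winning type). Empty corpus gives an empty gazetteer with
#'   a warning.
#' @export
build_gazetteer <- function(train) {
  ents <- unnest_entities(train)
  if (nrow(ents) == 0L) {
    warn("empty training corpus: gazetteer has no entries")
    out <- tibble(surface = character(), type = character(), n = integer())
    class(out) <- c("gazetteer", class(out))
    return(out)
  }
  counts <- ents %>%
    count(.data$surface, .data$type, name = "n") %>%
    arrange(.data$surface, desc(.data$n), .data$type)
  ties <- counts %>%
    group_by(.data$surface) %>%
    filter(n() > 1L, .data$n == max(.data$n)) %>%
    summarise(k = n(), .groups = "drop") %>%
    filter(.data$k > 1L)
  if (nrow(ties)) {
    rlang::inform(sprintf(
      "gazetteer: %d surface(s) with tied types resolved lexicographically (e.g. '%s')",
      nrow(ties), ties$surface[1]))
  }
  out <- counts %>%
    group_by(.data$surface) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    arrange(.data$surface)
  class(out) <- c("gazetteer", class(out))
  out
}

#' Tag sentences by longest-match gazetteer lookup
#'
#' Deterministic left-to-right maximum matching: at each position the
#' longest gazetteer surface starting there is tagged with its type and the
#' scan resumes after it; uncovered characters stay outside any entity.
#'
#' @param sentences Sentence tibble to tag (gold entities, if present, are
#'   ignored).
#' @param gazetteer A [build_gazetteer()] result.
#' @return A sentence tibble with the same ids and texts and predicted
#'   `entities`.
#' @export
tag_corpus <- function(sentences, gazetteer) {
  type_of <- stats::setNames(gazetteer$type, gazetteer$surface)
  max_len <- if (nrow(gazetteer)) max(str_length(gazetteer$surface)) else 0L
  id_col <- corpus_id_col(sentences)
  out <- tibble(sent_id = as.character(sentences[[id_col]]),
                text = sentences$text,
                entities = map(sentences$text, function(txt) {
                  tag_one(txt, type_of, max_len)
                }),
                provenance = "predicted")
  validate_corpus(out, "sent_id")
}

tag_one <- function(txt, type_of, max_len) {
  n <- str_length(txt)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (len < 1L) break
      ty <- type_of[str_sub(txt, i, i + len - 1L)]
      if (!is.na(ty)) {
        hit_len <- len
        hit_type <- unname(ty)
        break
      }
    }
    if (hit_len > 0L) {
      starts <- c(starts, i - 1L)
      ends <- c(ends, i - 1L + hit_len)
      types <- c(types, hit_type)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  entity_spans(starts, ends, types, text = txt)
}

#' Wrap a tagging model into the tagger contract
#'
#' External models (neural sequence labelers, remote services, ...) attach
#' to the pipeline through this contract: a tagger maps a sentence tibble to
#' a long BIO tag table. The wrapper validates the output — one tag per
#' character of every input sentence, and a well-formed BIO sequence — and
#' errors on any violation.
#'
#' @param fn Function `sentence tibble -> long BIO tibble` (as produced by
#'   [spans_to_bio()]).
#' @return A validated tagger function with the same signature.
#' @seealso [gazetteer_tagger()] for the built-in reference tagger.
#' @export
as_tagger <- function(fn) {
  stopifnot(is.function(fn))
  function(sentences) {
    id_col <- corpus_id_col(sentences)
    bio <- fn(sentences)
    bid <- intersect(c("sent_id", "record_id", "doc_id", "id"), names(bio))[1]
    if (is.na(bid)) abort("tagger contract violation: output has no id column")
    for (i in seq_len(nrow(sentences))) {
      sid <- as.character(sentences[[id_col]][i])
      got <- sum(bio[[bid]] == sid)
      want <- str_length(sentences$text[i])
      if (got != want) {
        abort(sprintf(
          "tagger contract violation: sentence %s has %d characters but %d tags",
          sid, want, got))
      }
    }
    # full BIO validity (orphan I-tags, malformed labels) checked strictly
    bio_to_spans(bio, strict = TRUE)
    bio
  }
}

#' The built-in gazetteer tagger, as a contract-conforming function
#'
#' @param gazetteer A [build_gazetteer()] result.
#' @return A tagger function `sentence tibble -> long BIO tibble` satisfying
#'   the [as_tagger()] contract.
#' @export
gazetteer_tagger <- function(gazetteer) {
  as_tagger(function(sentences) spans_to_bio(tag_corpus(sentences, gazetteer)))
}
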