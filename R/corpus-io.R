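#' Read span-annotated records from a JSON-lines file
#'
#' One clinical record per line, in the dialect
#' `{"id": str, "text": str, "entities": [{"start": int, "end": int,
#' "type": str}, ...]}`. Key names vary across corpus releases, so every key
#' is remappable through `keys`. Offsets in the file may be half-open
#' (`end` exclusive, the package convention) or inclusive-end; the latter is
#' converted at this boundary.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @param keys Named list remapping the JSON key names; any subset of
#'   `id`, `text`, `entities`, `start`, `end`, `type` may be overridden.
#' @param span_convention `"exclusive"` (default, 0-based half-open) or
#'   `"inclusive"` (0-based inclusive `end`, converted by adding 1).
#' @return A tibble with one row per record: `record_id`, `text`, and an
#'   `entities` list-column of [entity_spans()] tables. All span invariants
#'   (in range, non-overlapping, surface equal to the text slice) are
#'   enforced; violations raise an error naming the record.
#' @seealso [write_records()], [split_sentences()]
#' @export
read_records <- function(path, keys = list(),
                         span_convention = c("exclusive", "inclusive")) {
  span_convention <- match.arg(span_convention)
  k <- utils::modifyList(
    list(id = "id", text = "text", entities = "entities",
         start = "start", end = "end", type = "type"),
    keys)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(record_id = character(), text = character(),
                  entities = list()))
  }
  rows <- map(seq_along(lines), function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) abort(sprintf("line %d: malformed JSON (%s)",
                                        i, conditionMessage(e))))
    if (is.null(obj[[k$text]])) {
      abort(sprintf("line %d: missing text key '%s'", i, k$text))
    }
    ents <- obj[[k$entities]] %||% list()
    starts <- map_int(ents, function(e) as.integer(e[[k$start]]))
    ends <- map_int(ents, function(e) as.integer(e[[k$end]]))
    if (span_convention == "inclusive") ends <- ends + 1L
    list(record_id = as.character(obj[[k$id]] %||% sprintf("rec%05d", i)),
         text = as.character(obj[[k$text]]),
         entities = entity_spans(starts, ends,
                                 map_chr(ents, function(e) as.character(e[[k$type]])),
                                 text = as.character(obj[[k$text]])))
  })
  out <- tibble(record_id = map_chr(rows, "record_id"),
                text = map_chr(rows, "text"),
                entities = map(rows, "entities"))
  validate_corpus(out, "record_id")
}

#' Write records (or sentences) to a JSON-lines file
#'
#' Inverse of [read_records()]. Output is deterministic: identical input
#' produces byte-identical files.
#'
#' @param x A record- or sentence-level tibble with `text` and `entities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  id_col <- corpus_id_col(x)
  lines <- map_chr(seq_len(nrow(x)), function(i) {
    e <- x$entities[[i]]
    ents <- map(seq_len(nrow(e)), function(j) {
      list(start = e$start[j], end = e$end[j], type = e$type[j])
    })
    jsonlite::toJSON(list(id = x[[id_col]][i], text = x$text[i], entities = ents),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Split records into period-delimited sentences
#'
#' Clinical records run to hundreds of characters, so they are cut at the
#' Chinese period into sentence-level units before tagging or augmentation.
#' Each separator character stays attached to the sentence it ends, so the
#' concatenated sentence texts reproduce the record text exactly. Entity
#' offsets are re-based to the sentence. An empty trailing segment after a
#' final period is dropped.
#'
#' @param records Record tibble from [read_records()] (or any tibble with
#'   `record_id`/`text`/`entities`).
#' @param separators Character vector of single-character sentence
#'   separators. Default `"。"` (the Chinese period).
#' @param split_policy What to do with an entity that straddles a sentence
#'   boundary: `"error"` (default; well-formed data has none) or
#'   `"keep-record"` (leave that record unsplit).
#' @return A sentence tibble: `doc_id`, `sent_index` (1-based), `sent_id`,
#'   `text`, `entities` (re-based), `provenance` (`"original"`), `parent_id`,
#'   and a `substitutions` list-column (empty for originals).
#' @export
split_sentences <- function(records, separators = "。",
                            split_policy = c("error", "keep-record")) {
  split_policy <- match.arg(split_policy)
  id_col <- corpus_id_col(records)
  out <- map(seq_len(nrow(records)), function(i) {
    rid <- records[[id_col]][i]
    txt <- records$text[i]
    ents <- records$entities[[i]]
    chars <- str_split(txt, "")[[1]]
    cuts <- which(chars %in% separators)            # 1-based separator pos
    bounds <- unique(c(0L, cuts, length(chars)))    # 0-based segment edges
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    seg_of <- function(s0) findInterval(s0, starts)
    if (nrow(ents) > 0L) {
      seg <- seg_of(ents$start)
      crossing <- ents$end > ends[seg]
      if (any(crossing)) {
        if (split_policy == "error") {
          abort(sprintf("record %s: entity (%d,%d) crosses a sentence boundary",
                        rid, ents$start[which(crossing)[1]],
                        ents$end[which(crossing)[1]]))
        }
        starts <- 0L; ends <- length(chars)  # keep-record: do not split
        seg <- rep(1L, nrow(ents))
      }
    } else {
      seg <- integer()
    }
    tibble(
      doc_id = rid,
      sent_index = seq_along(starts),
      sent_id = sprintf("%s#%d", rid, seq_along(starts)),
      text = str_slice(txt, starts, ends),
      entities = map(seq_along(starts), function(s) {
        sel <- ents[seg == s, , drop = FALSE]
        if (nrow(sel) == 0L) return(entity_spans())
        entity_spans(sel$start - starts[s], sel$end - starts[s], sel$type,
                     surface = sel$surface)
      }),
      provenance = "original",
      parent_id = rid,
      substitutions = list(empty_substitutions())
    )
  })
  res <- list_rbind(out)
  validate_corpus(as_tibble(res), "sent_id")
}

empty_substitutions <- function() {
  tibble(entity = integer(), segment = character(), replacement = character())
}

#' Convert entity spans to character-level BIO tags
#'
#' Each character gets one tag: `B-<type>` opens a mention, `I-<type>`
#' continues it, `O` is outside any mention.
#'
#' @param sentences A sentence (or record) tibble with `text` and `entities`.
#' @return A long tibble with one row per character: id column (as in
#'   `sentences`), `pos` (0-based), `char`, `tag`.
#' @seealso [bio_to_spans()] for the inverse.
#' @export
spans_to_bio <- function(sentences) {
  id_col <- corpus_id_col(sentences)
  chars_by_sent <- str_split(sentences$text, "")
  tags_by_sent <- map(seq_len(nrow(sentences)), function(i) {
    ents <- validate_spans(sentences$text[i], sentences$entities[[i]],
                           what = sentences[[id_col]][i])
    tags <- rep("O", length(chars_by_sent[[i]]))
    for (j in seq_len(nrow(ents))) {
      s <- ents$start[j]; e <- ents$end[j]
      tags[s + 1L] <- paste0("B-", ents$type[j])
      if (e - s > 1L) tags[(s + 2L):e] <- paste0("I-", ents$type[j])
    }
    tags
  })
  lens <- lengths(chars_by_sent)
  out <- tibble::new_tibble(
    list(id = rep(sentences[[id_col]], lens),
         pos = sequence(lens) - 1L,
         char = unlist(chars_by_sent, use.names = FALSE) %||% character(0),
         tag = unlist(tags_by_sent, use.names = FALSE) %||% character(0)),
    nrow = sum(lens))
  names(out)[1L] <- id_col
  out
}

#' Recover entity spans from character-level BIO tags
#'
#' Inverse of [spans_to_bio()]: `bio_to_spans(spans_to_bio(s))` reproduces
#' `s`'s text and spans exactly.
#'
#' @param bio Long tag tibble (`sent_id`/`pos`/`char`/`tag`) as produced by
#'   [spans_to_bio()] or [read_bio()].
#' @param strict If `TRUE` (default) an orphan `I-` tag (one not preceded by
#'   `B-`/`I-` of the same type) is an error; if `FALSE` it is repaired to a
#'   `B-` tag.
#' @return A sentence tibble with `sent_id`, `text`, `entities`.
#' @export
bio_to_spans <- function(bio, strict = TRUE) {
  id_col <- intersect(c("sent_id", "record_id", "doc_id", "id"), names(bio))[1]
  if (is.na(id_col)) abort("expected an id column in the BIO table")
  bad <- !grepl("^(O|[BI]-\\w+)$", bio$tag)
  if (any(bad)) {
    abort(sprintf("%s: malformed tag '%s'",
                  bio[[id_col]][which(bad)[1]], bio$tag[which(bad)[1]]))
  }
  ids <- unique(bio[[id_col]])
  chunks <- split(seq_len(nrow(bio)), factor(bio[[id_col]], levels = ids))
  all_kind <- substr(bio$tag, 1L, 1L)
  all_type <- ifelse(all_kind == "O", NA_character_, substring(bio$tag, 3L))
  rows <- map(ids, function(sid) {
    idx <- chunks[[sid]]
    idx <- idx[order(bio$pos[idx])]
    kind <- all_kind[idx]
    ttype <- all_type[idx]
    prev_type <- c(NA_character_, ttype[-length(ttype)])
    prev_kind <- c("O", kind[-length(kind)])
    orphan <- kind == "I" &
      (prev_kind == "O" | is.na(prev_type) | prev_type != ttype)
    if (any(orphan)) {
      if (strict) {
        abort(sprintf("%s: orphan I-tag at position %d (use strict = FALSE to repair)",
                      sid, bio$pos[idx][which(orphan)[1]]))
      }
      kind[orphan] <- "B"
    }
    starts <- which(kind == "B")
    ends <- map_int(starts, function(s) {
      e <- s
      while (e < length(kind) && kind[e + 1L] == "I" && ttype[e + 1L] == ttype[s]) {
        e <- e + 1L
      }
      e
    })
    txt <- paste(bio$char[idx], collapse = "")
    list(text = txt,
         entities = entity_spans(starts - 1L, ends, ttype[starts], text = txt))
  })
  out <- tibble::new_tibble(
    list(sent_id = as.character(ids),
         text = map_chr(rows, "text"),
         entities = map(rows, "entities")),
    nrow = length(ids))
  validate_corpus(out, "sent_id")
}

#' Read and write two-column BIO files
#'
#' The on-disk format is CoNLL-style: UTF-8, one `<char>\t<tag>` pair per
#' line, a blank line between sentences. `write_bio()` then [read_bio()] is
#' the identity (and the reverse is byte-identical).
#'
#' @param path File path.
#' @return `read_bio()`: a long tag tibble (`sent_id` `"s1"`, `"s2"`, ... in
#'   file order, `pos`, `char`, `tag`). `write_bio()`: `path`, invisibly.
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # drop trailing blank lines so the final sentence is not followed by empties
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(tibble(sent_id = character(), pos = integer(),
                  char = character(), tag = character()))
  }
  blank <- !nzchar(lines)
  keep <- !blank
  grp <- cumsum(blank)[keep]            # blank lines delimit sentences
  sid <- match(grp, unique(grp))
  parts <- str_split(lines[keep], "\t")
  nc <- lengths(parts)
  if (any(nc != 2L)) {
    abort(sprintf("line %d: expected 2 tab-separated columns, found %d",
                  which(keep)[which(nc != 2L)[1]], nc[nc != 2L][1]))
  }
  tags <- map_chr(parts, 2L)
  bad <- !grepl("^(O|[BI]-\\w+)$", tags)
  if (any(bad)) {
    abort(sprintf("line %d: malformed tag '%s'",
                  which(keep)[which(bad)[1]], tags[bad][1]))
  }
  out <- tibble(sent_id = sprintf("s%d", sid),
                char = map_chr(parts, 1L), tag = tags)
  out %>%
    group_by(.data$sent_id) %>%
    mutate(pos = row_number() - 1L) %>%
    ungroup() %>%
    select("sent_id", "pos", "char", "tag")
}

#' @param bio Long tag tibble as produced by [spans_to_bio()].
#' @rdname read_bio
#' @export
write_bio <- function(bio, path) {
  id_col <- intersect(c("sent_id", "record_id", "doc_id", "id"), names(bio))[1]
  ids <- unique(bio[[id_col]])
  chunks <- split(seq_len(nrow(bio)), factor(bio[[id_col]], levels = ids))
  blocks <- map_chr(ids, function(sid) {
    sub <- bio[chunks[[sid]], , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    paste(paste0(sub$char, "\t", sub$tag), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
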