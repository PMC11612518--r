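#' Construct a synonym lexicon
#'
#' The lexicon abstracts a word2vec-style synonym database as a hermetic,
#' file-backed object: named synonym groups (headword -> candidate synonyms)
#' plus optional embedding vectors used to rank candidates by cosine
#' similarity. A headword with an empty group is a known word with no
#' recorded synonyms (useful as a segmentation dictionary entry).
#'
#' @param groups Named list: headword -> character vector of synonyms. A word
#'   must not be listed as its own synonym.
#' @param vectors Optional named list (or matrix rows) of numeric embedding
#'   vectors, all of one dimension.
#' @return An object of class `synonym_lexicon`.
#' @seealso [read_lexicon()], [find_synonyms()]
#' @export
synonym_lexicon <- function(groups = list(), vectors = NULL) {
  stopifnot(is.list(groups))
  if (length(groups) && is.null(names(groups))) {
    abort("`groups` must be a named list (headword -> synonyms)")
  }
  groups <- map(groups, function(g) unique(as.character(g[nzchar(g)])))
  self <- map_lgl(names(groups), function(h) h %in% groups[[h]])
  if (any(self)) {
    abort(sprintf("word '%s' is listed as its own synonym", names(groups)[self][1]))
  }
  if (!is.null(vectors)) {
    if (is.matrix(vectors)) {
      vectors <- stats::setNames(
        lapply(seq_len(nrow(vectors)), function(i) vectors[i, ]),
        rownames(vectors))
    }
    d <- unique(lengths(vectors))
    if (length(d) > 1L) abort("all embedding vectors must share one dimension")
  }
  structure(list(groups = groups, vectors = vectors), class = "synonym_lexicon")
}

#' @export
print.synonym_lexicon <- function(x, ...) {
  cat(sprintf("<synonym_lexicon: %d headwords, %d synonyms%s>\n",
              length(x$groups), sum(lengths(x$groups)),
              if (is.null(x$vectors)) "" else
                sprintf(", %d-d vectors for %d words",
                        length(x$vectors[[1]]), length(x$vectors))))
  invisible(x)
}

#' Read a synonym lexicon from TSV files
#'
#' The group file has one line per headword: `headword<TAB>syn1,syn2,...`
#' (the synonym list may be empty). The optional vectors file has
#' `word<TAB>v1 v2 ... vd` with whitespace-separated floats.
#'
#' @param path Path to the group TSV.
#' @param vectors_path Optional path to the vectors file.
#' @return A [synonym_lexicon()].
#' @export
read_lexicon <- function(path, vectors_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  groups <- list()
  for (i in seq_along(lines)) {
    parts <- str_split(lines[i], "\t")[[1]]
    if (length(parts) < 1L || !nzchar(parts[1])) {
      abort(sprintf("lexicon line %d: missing headword", i))
    }
    syns <- if (length(parts) >= 2L && nzchar(parts[2])) {
      str_split(parts[2], ",")[[1]]
    } else character(0)
    groups[[parts[1]]] <- syns
  }
  vectors <- NULL
  if (!is.null(vectors_path)) {
    vlines <- readLines(vectors_path, encoding = "UTF-8", warn = FALSE)
    vlines <- vlines[nzchar(trimws(vlines))]
    vectors <- list()
    for (ln in vlines) {
      parts <- str_split(ln, "\t")[[1]]
      vectors[[parts[1]]] <- as.numeric(str_split(trimws(parts[2]), "\\s+")[[1]])
    }
  }
  synonym_lexicon(groups, vectors)
}

#' Write a synonym lexicon to TSV
#'
#' @param lexicon A [synonym_lexicon()].
#' @param path Output path for the group TSV.
#' @param vectors_path Optional output path for the vectors file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path, vectors_path = NULL) {
  lines <- map_chr(names(lexicon$groups), function(h) {
    paste0(h, "\t", paste(lexicon$groups[[h]], collapse = ","))
  })
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(vectors_path) && !is.null(lexicon$vectors)) {
    vlines <- map_chr(names(lexicon$vectors), function(w) {
      paste0(w, "\t", paste(format(lexicon$vectors[[w]], trim = TRUE), collapse = " "))
    })
    writeLines(vlines, vectors_path, useBytes = TRUE)
  }
  invisible(path)
}

#' All words known to a lexicon
#'
#' Headwords plus every group member; doubles as the default segmentation
#' dictionary during synthesis.
#'
#' @param lexicon A [synonym_lexicon()].
#' @return Character vector of distinct words.
#' @export
lexicon_words <- function(lexicon) {
  unique(c(names(lexicon$groups) %||% character(0),
           unlist(lexicon$groups, use.names = FALSE) %||% character(0)))
}

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between Unicode strings,
#' computed per code point. Vectorized over pairs (`a` and `b` are recycled
#' to a common length).
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("头昏", "头晕")  # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  ua <- unique(a)
  # one C-level call per distinct query keeps bulk comparisons fast
  for (u in ua) {
    idx <- a == u
    out[idx] <- lev_to_many(u, b[idx])
  }
  out
}

# distances from one query to many candidates in one call
lev_to_many <- function(query, words) {
  if (length(words) == 0L) return(integer(0))
  as.integer(utils::adist(query, words)[1, ])
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal dimension and non-zero norm.
#' @return `dot(u, v) / (|u| |v|)`, a value in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must share one dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Find ranked near-synonym candidates for a word
#'
#' Candidate search mirrors how a synonym database is queried. If `query` is
#' a lexicon headword, its own synonym group is the candidate pool. If it is
#' absent, edit distance locates the nearest lexicon entries: every headword
#' within `max_dist` of the query (and that headword's group) enters the
#' pool. A near-headword is only admitted when the distance is also below
#' the query's length, so short queries cannot match entries with which they
#' share no content. Candidates are ranked by edit distance to the query
#' (ascending), then embedding cosine similarity (descending, when vectors
#' are available for both words), then lexicographically; the query itself is
#' never returned.
#'
#' @param query A single word.
#' @param lexicon A [synonym_lexicon()].
#' @param top_k Maximum number of candidates (default 5).
#' @param max_dist Edit-distance radius for locating lexicon entries when the
#'   query is not a headword (default 2).
#' @param near_headwords `"fallback"` (default: only search near headwords
#'   when the query is not itself one), `"always"`, or `"never"`.
#' @return A tibble `word`, `edit_distance` (to the query), `similarity`
#'   (cosine, `NA` when unavailable), at most `top_k` rows. Empty when
#'   nothing qualifies; an unknown query is not an error.
#' @export
find_synonyms <- function(query, lexicon, top_k = 5L, max_dist = 2L,
                          near_headwords = c("fallback", "always", "never")) {
  near_headwords <- match.arg(near_headwords)
  stopifnot(top_k >= 1L, max_dist >= 0L)
  heads <- names(lexicon$groups)
  pool <- character(0)
  is_head <- query %in% heads
  if (is_head) pool <- lexicon$groups[[query]]
  if ((near_headwords == "always") ||
      (near_headwords == "fallback" && !is_head)) {
    eff <- min(max_dist, str_length(query) - 1L)
    if (eff >= 0L && length(heads)) {
      d <- lev_to_many(query, heads)
      near <- heads[d <= eff]
      pool <- c(pool, near, unlist(lexicon$groups[near], use.names = FALSE))
    }
  }
  pool <- setdiff(unique(pool), query)
  if (length(pool) == 0L) {
    return(tibble(word = character(), edit_distance = integer(),
                  similarity = double()))
  }
  sim <- rep(NA_real_, length(pool))
  if (!is.null(lexicon$vectors) && query %in% names(lexicon$vectors)) {
    qv <- lexicon$vectors[[query]]
    have <- pool %in% names(lexicon$vectors)
    sim[have] <- map_dbl(pool[have], function(w) {
      cosine_similarity(qv, lexicon$vectors[[w]])
    })
  }
  tibble(word = pool, edit_distance = lev_to_many(query, pool),
         similarity = sim) %>%
    arrange(.data$edit_distance, desc(.data$similarity), .data$word) %>%
    utils::head(top_k)
}
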