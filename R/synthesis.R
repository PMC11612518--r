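#' Augmentation configuration
#'
#' Tunables of the Segmentation Synonym Sentence Synthesis step.
#'
#' @param min_segments Minimum number of simple words an entity must segment
#'   into to be eligible for substitution. Default 1: every entity is
#'   eligible, which is what reproduces single-word substitutions such as
#'   头昏 -> 头晕; raise it to restrict augmentation to compound mentions.
#' @param top_k,max_dist Synonym search knobs, see [find_synonyms()].
#' @param policy `"single"` (default): one variant per
#'   (entity, segment, candidate) triple, so variant counts stay linear in
#'   the synonym counts; `"cross"`: additionally every combination of
#'   per-segment choices within an entity.
#' @param max_variants Cap on variants kept per sentence (uniform seeded
#'   sampling when exceeded). Default `Inf`.
#' @param dedupe Drop variants whose text duplicates the original sentence
#'   or an earlier variant. Default `TRUE`.
#' @param seed Integer seed driving all sampling, for reproducible corpora.
#' @param substitute_context Also substitute segments outside entity spans.
#'   Off by default: only entity-internal vocabulary is replaced.
#' @return A list of class `ssss_config`.
#' @export
augment_config <- function(min_segments = 1L, top_k = 5L, max_dist = 2L,
                           policy = c("single", "cross"),
                           max_variants = Inf, dedupe = TRUE, seed = 42L,
                           substitute_context = FALSE) {
  policy <- match.arg(policy)
  stopifnot(min_segments >= 1L, max_variants >= 0L, top_k >= 1L, max_dist >= 0L)
  structure(list(min_segments = as.integer(min_segments),
                 top_k = as.integer(top_k), max_dist = as.integer(max_dist),
                 policy = policy, max_variants = max_variants,
                 dedupe = isTRUE(dedupe), seed = as.integer(seed),
                 substitute_context = isTRUE(substitute_context)),
            class = "ssss_config")
}

#' Replace a region of a sentence and re-project its entity spans
#'
#' The elementary resynthesis move: a region of the text is replaced by a
#' (possibly different-length) string and every entity span is shifted or
#' resized so all spans still address the right characters. With
#' `substitute_context = FALSE` the region must lie entirely inside exactly
#' one entity span; that span absorbs the length change and its surface is
#' re-sliced, spans before the region are untouched, spans after it shift by
#' the length difference.
#'
#' @param sentence A one-row sentence tibble (see [split_sentences()]).
#' @param start,end 0-based half-open region within the sentence text.
#' @param replacement Non-empty replacement string.
#' @param substitute_context Allow the region to lie outside every entity
#'   span (it must still not cross a span boundary).
#' @return The modified one-row sentence tibble, spans re-validated.
#' @export
project_span <- function(sentence, start, end, replacement,
                         substitute_context = FALSE) {
  stopifnot(nrow(sentence) == 1L)
  if (!nzchar(replacement)) abort("`replacement` must be non-empty")
  txt <- sentence$text[1]
  n <- str_length(txt)
  if (start < 0L || end > n || start >= end) {
    abort(sprintf("region (%d,%d) out of range for text of length %d",
                  start, end, n))
  }
  ents <- sentence$entities[[1]]
  inside <- which(ents$start <= start & end <= ents$end)
  crossing <- which(ents$start < end & start < ents$end &
                      !(ents$start <= start & end <= ents$end))
  if (length(crossing)) {
    abort(sprintf("region (%d,%d) crosses entity span (%d,%d)", start, end,
                  ents$start[crossing[1]], ents$end[crossing[1]]))
  }
  if (!substitute_context && length(inside) != 1L) {
    abort(sprintf("region (%d,%d) lies outside every entity span", start, end))
  }
  delta <- str_length(replacement) - (end - start)
  new_text <- paste0(str_slice(txt, 0L, start), replacement,
                     str_slice(txt, end, n))
  new_ents <- ents
  if (nrow(ents)) {
    after <- ents$start >= end
    new_ents$start[after] <- ents$start[after] + delta
    new_ents$end[after] <- ents$end[after] + delta
    if (length(inside) == 1L) {
      new_ents$end[inside] <- ents$end[inside] + delta
    }
    new_ents$surface <- str_slice(new_text, new_ents$start, new_ents$end)
  }
  out <- sentence
  out$text[1] <- new_text
  out$entities[[1]] <- validate_spans(new_text, new_ents,
                                      what = sentence$sent_id[1] %||% "sentence")
  out
}

# enumerate substitution plans for one sentence; a plan is a tibble of
# (entity, seg_start, seg_len, replacement) rows applied together
substitution_plans <- function(ents, seg_fun, lexicon, config) {
  plans <- list()
  for (i in seq_len(nrow(ents))) {
    segs <- seg_fun(ents$surface[i])
    if (nrow(segs) < config$min_segments) next
    cand <- map(segs$text, function(w) {
      find_synonyms(w, lexicon, top_k = config$top_k,
                    max_dist = config$max_dist)$word
    })
    if (config$policy == "single") {
      for (j in seq_len(nrow(segs))) {
        for (w in cand[[j]]) {
          plans[[length(plans) + 1L]] <- tibble(
            entity = i, seg_start = segs$start[j],
            seg_len = str_length(segs$text[j]),
            segment = segs$text[j], replacement = w)
        }
      }
    } else {
      # cross-product over segments: each segment keeps its word or takes a
      # candidate; the all-keep combination is skipped
      choice_sets <- map(seq_len(nrow(segs)), function(j) c(NA_character_, cand[[j]]))
      grid <- expand.grid(choice_sets, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        picks <- as.character(unlist(grid[r, , drop = FALSE], use.names = FALSE))
        sel <- which(!is.na(picks))
        if (length(sel) == 0L) next
        plans[[length(plans) + 1L]] <- tibble(
          entity = i, seg_start = segs$start[sel],
          seg_len = str_length(segs$text[sel]),
          segment = segs$text[sel], replacement = picks[sel])
      }
    }
  }
  plans
}

#' Synthesize synonym-substituted variants of one sentence
#'
#' The SSSS core: each entity mention is segmented into simple words
#' ([segment_text()]), each segment is looked up in the synonym lexicon
#' ([find_synonyms()]), and for every accepted substitution the sentence is
#' resynthesized with spans re-projected ([project_span()]). Entity labels
#' are inherited unchanged, so every variant carries exactly the same number
#' and types of entities as its parent.
#'
#' @param sentence A one-row sentence tibble.
#' @param lexicon A [synonym_lexicon()].
#' @param config An [augment_config()].
#' @param segmenter Optional segmenter function (see [as_segmenter()]);
#'   defaults to forward maximum matching over the lexicon's word list.
#' @param .stream Integer stream index decorrelating the per-sentence
#'   sampling seed; [augment_corpus()] passes the sentence ordinal so a
#'   `max_variants` cap never breaks corpus-level determinism.
#' @return A sentence tibble of 0 or more variants, `provenance`
#'   `"synthesized"`, `parent_id` set to the parent's `sent_id`, and the
#'   applied substitutions logged in the `substitutions` list-column.
#' @export
synthesize_sentence <- function(sentence, lexicon, config = augment_config(),
                                segmenter = NULL, .stream = 1L) {
  stopifnot(nrow(sentence) == 1L)
  seg_fun <- segmenter %||% fmm_segmenter(lexicon)
  ents <- sentence$entities[[1]]
  plans <- substitution_plans(ents, seg_fun, lexicon, config)
  if (length(plans) == 0L) return(sentence[0, ])
  variants <- map(plans, function(plan) {
    v <- sentence
    # apply right-to-left so earlier regions keep their offsets
    ord <- order(plan$entity, plan$seg_start, decreasing = TRUE)
    for (r in ord) {
      e <- v$entities[[1]]
      region_start <- e$start[plan$entity[r]] + plan$seg_start[r]
      v <- project_span(v, region_start, region_start + plan$seg_len[r],
                        plan$replacement[r],
                        substitute_context = config$substitute_context)
    }
    v$provenance[1] <- "synthesized"
    v$parent_id[1] <- sentence$sent_id[1]
    v$substitutions[[1]] <- tibble(entity = plan$entity,
                                   segment = plan$segment,
                                   replacement = plan$replacement)
    v
  })
  out <- list_rbind(variants)
  if (config$dedupe) {
    keep <- !duplicated(out$text) & out$text != sentence$text[1]
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) > config$max_variants) {
    stream_seed <- (config$seed + 7919 * as.integer(.stream)) %% .Machine$integer.max
    idx <- withr::with_seed(stream_seed,
                            sort(sample.int(nrow(out), config$max_variants)))
    out <- out[idx, , drop = FALSE]
  }
  if (nrow(out)) {
    out$sent_id <- sprintf("%s+v%d", sentence$sent_id[1], seq_len(nrow(out)))
  }
  out
}

#' Augment a corpus by Segmentation Synonym Sentence Synthesis
#'
#' Runs [synthesize_sentence()] over every sentence and returns the original
#' sentences plus all variants (each original followed by its variants),
#' together with an expansion report. Identical inputs, configuration and
#' seed give a byte-identical corpus.
#'
#' @param x A record tibble ([read_records()]) — split into sentences first —
#'   or an already-split sentence tibble.
#' @param lexicon A [synonym_lexicon()].
#' @param config An [augment_config()].
#' @param segmenter Optional segmenter (see [synthesize_sentence()]).
#' @return An object of class `ssss_augmentation`: a list with `corpus` (the
#'   augmented sentence tibble), `by_type` (pre/post entity counts and the
#'   expansion factor per entity type), `by_sentence` (variants emitted per
#'   original sentence), and `config`. [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods are provided.
#' @examples
#' lex <- synonym_lexicon(list("头昏" = "头晕"))
#' sen <- split_sentences(tibble::tibble(
#'   record_id = "r1", text = "主因头部外伤出血伴头昏3.5小时入院",
#'   entities = list(entity_spans(9, 11, "Symptom",
#'                                text = "主因头部外伤出血伴头昏3.5小时入院"))))
#' aug <- augment_corpus(sen, lex)
#' aug$corpus$text
#' @export
augment_corpus <- function(x, lexicon, config = augment_config(),
                           segmenter = NULL) {
  sentences <- if ("sent_id" %in% names(x)) x else split_sentences(x)
  pieces <- map(seq_len(nrow(sentences)), function(i) {
    orig <- sentences[i, , drop = FALSE]
    vars <- synthesize_sentence(orig, lexicon, config, segmenter, .stream = i)
    list(rows = bind_rows(orig, vars), n_variants = nrow(vars))
  })
  corpus <- list_rbind(map(pieces, "rows"))
  by_sentence <- tibble(sent_id = sentences$sent_id,
                        n_variants = map_int(pieces, "n_variants"))
  pre <- unnest_entities(sentences, "sent_id") %>% count(.data$type, name = "pre")
  post <- unnest_entities(corpus, "sent_id") %>% count(.data$type, name = "post")
  by_type <- dplyr::full_join(pre, post, by = "type") %>%
    mutate(pre = dplyr::coalesce(.data$pre, 0L),
           post = dplyr::coalesce(.data$post, 0L),
           factor = ifelse(.data$pre > 0, .data$post / .data$pre, NA_real_)) %>%
    arrange(.data$type)
  structure(list(corpus = corpus, by_type = by_type,
                 by_sentence = by_sentence, config = config),
            class = "ssss_augmentation")
}

#' @export
print.ssss_augmentation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ssss_augmentation: %d sentences -> %d (+%d variants); %d entities -> %d (x%.2f)>\n",
    g$n_sentences_pre, g$n_sentences_post,
    g$n_sentences_post - g$n_sentences_pre,
    g$n_entities_pre, g$n_entities_post, g$expansion_factor))
  print(x$by_type)
  invisible(x)
}

#' @rdname augment_corpus
#' @param x An `ssss_augmentation` object.
#' @param ... Unused.
#' @export
tidy.ssss_augmentation <- function(x, ...) x$by_type

#' @rdname augment_corpus
#' @export
glance.ssss_augmentation <- function(x, ...) {
  tibble(n_sentences_pre = nrow(x$by_sentence),
         n_sentences_post = nrow(x$corpus),
         n_entities_pre = sum(x$by_type$pre),
         n_entities_post = sum(x$by_type$post),
         expansion_factor = sum(x$by_type$post) / max(1L, sum(x$by_type$pre)))
}

#' @rdname augment_corpus
#' @param object An `ssss_augmentation` object.
#' @export
autoplot.ssss_augmentation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_type, c("pre", "post"),
                              names_to = "stage", values_to = "entities")
  long$stage <- factor(long$stage, levels = c("pre", "post"),
                       labels = c("pre-expansion", "post-expansion"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$entities,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "entity type", y = "entity count", fill = NULL,
                  title = "SSSS corpus expansion by entity type") +
    ggplot2::theme_minimal()
}

#' Write an augmentation report as JSON
#'
#' @param aug An `ssss_augmentation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_augmentation_report <- function(aug, path) {
  jsonlite::write_json(
    list(by_type = aug$by_type, by_sentence = aug$by_sentence,
         config = unclass(aug$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
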