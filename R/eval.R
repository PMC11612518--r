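#' Strictly match predicted against gold entity spans
#'
#' A prediction is a true positive only if an as-yet-unmatched gold span has
#' the identical `(start, end, type)` triple — boundaries and type must all
#' agree. Matching is one-to-one; leftover predictions are false positives
#' and leftover gold spans false negatives.
#'
#' @param gold,pred Entity span tibbles for the same sentence.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_entities <- function(gold, pred) {
  gkey <- span_key(gold)
  pkey <- span_key(pred)
  tp <- 0L
  unmatched <- gkey
  for (k in pkey) {
    hit <- match(k, unmatched)
    if (!is.na(hit)) {
      tp <- tp + 1L
      unmatched <- unmatched[-hit]
    }
  }
  c(tp = tp, fp = length(pkey) - tp, fn = length(gkey) - tp)
}

span_key <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0L) return(character(0))
  paste(spans$start, spans$end, spans$type, sep = "\r")
}

# percent-scale precision/recall/F1 from counts; precision (recall) is NA
# when there are no predictions (no gold) to judge it on, and F1 is 0
# whenever P + R has no positive value
prf <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  r <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  denom <- ifelse(is.na(p), 0, p) + ifelse(is.na(r), 0, r)
  f1 <- ifelse(!is.na(p) & !is.na(r) & denom > 0, 2 * p * r / denom, 0)
  list(precision = p, recall = r, f1 = f1)
}

# align two sentence-level corpora row by row, erroring on text mismatch
align_corpora <- function(gold, pred) {
  if (nrow(gold) != nrow(pred)) {
    abort(sprintf("gold has %d sentences but pred has %d", nrow(gold), nrow(pred)))
  }
  mism <- which(gold$text != pred$text)
  if (length(mism)) {
    abort(sprintf("sentence %d: gold and pred texts differ", mism[1]))
  }
  invisible(TRUE)
}

#' Score a predicted corpus against gold, entity level, strict match
#'
#' Micro-averaged precision, recall and F1 (percent scale), overall and per
#' entity type. The per-type score restricts both gold and predictions to
#' that type, so per-type TP/FP/FN counts sum to the overall counts.
#'
#' @param gold,pred Sentence tibbles over the same texts, aligned row by row
#'   (a text mismatch is an error).
#' @return An object of class `ner_score` with `by_type` and `overall`
#'   count/metric tibbles; `tidy()` returns the per-type table, `glance()`
#'   the overall one-row summary, and `autoplot()` a metric bar chart.
#' @examples
#' s <- split_sentences(tibble::tibble(
#'   record_id = "r1", text = "头昏3小时",
#'   entities = list(entity_spans(0, 2, "Symptom", text = "头昏3小时"))))
#' glance(score_ner(s, s))  # perfect prediction
#' @export
score_ner <- function(gold, pred) {
  align_corpora(gold, pred)
  counts <- map(seq_len(nrow(gold)), function(i) {
    g <- gold$entities[[i]]
    p <- pred$entities[[i]]
    types <- union(g$type, p$type)
    if (length(types) == 0L) return(NULL)
    tibble(type = types,
           counts = map(types, function(tt) {
             match_entities(g[g$type == tt, , drop = FALSE],
                            p[p$type == tt, , drop = FALSE])
           }))
  })
  flat <- list_rbind(counts)
  if (is.null(flat) || nrow(flat) == 0L) {
    by_type <- tibble(type = character(), tp = integer(), fp = integer(),
                      fn = integer(), precision = double(), recall = double(),
                      f1 = double())
  } else {
    by_type <- flat %>%
      mutate(tp = map_int(.data$counts, "tp"),
             fp = map_int(.data$counts, "fp"),
             fn = map_int(.data$counts, "fn")) %>%
      group_by(.data$type) %>%
      summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                .groups = "drop") %>%
      arrange(.data$type)
    by_type <- dplyr::bind_cols(by_type, as_tibble(prf(by_type$tp, by_type$fp,
                                                       by_type$fn)))
  }
  overall <- tibble(tp = sum(by_type$tp), fp = sum(by_type$fp),
                    fn = sum(by_type$fn))
  overall <- dplyr::bind_cols(overall, as_tibble(prf(overall$tp, overall$fp,
                                                     overall$fn)))
  structure(list(by_type = by_type, overall = overall), class = "ner_score")
}

#' @export
print.ner_score <- function(x, ...) {
  cat(sprintf("<ner_score: P %.2f%%  R %.2f%%  F1 %.2f%%  (TP %d, FP %d, FN %d)>\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$tp, x$overall$fp, x$overall$fn))
  print(x$by_type)
  invisible(x)
}

#' @rdname score_ner
#' @param x An `ner_score` object.
#' @param ... Unused.
#' @export
tidy.ner_score <- function(x, ...) x$by_type

#' @rdname score_ner
#' @export
glance.ner_score <- function(x, ...) x$overall

#' @rdname score_ner
#' @param object An `ner_score` object.
#' @export
autoplot.ner_score <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_type, c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "entity type", y = "percent", fill = NULL,
                  title = "Entity-level strict-match scores") +
    ggplot2::theme_minimal()
}

#' Assign test entities to training-frequency strata
#'
#' Each gold test entity is keyed (by default on its exact
#' `(surface, type)` pair) and looked up in the training annotations:
#' frequency 0 makes it an *unknown* entity, frequency below `threshold` a
#' *low-frequency* one, and frequency at or above `threshold` (default 5) a
#' *high-frequency* one.
#'
#' @param train Training record or sentence tibble (the frequency source).
#' @param test Test record or sentence tibble (gold annotations).
#' @param threshold Low/high boundary, default 5 (a frequency of exactly 5 is
#'   high).
#' @param key `"surface_type"` (default) or `"surface"` (ignore the type when
#'   counting).
#' @return A tibble with one row per gold test entity: the id column of
#'   `test`, `start`, `end`, `type`, `surface`, `train_freq`, `stratum`
#'   (factor unknown/low/high).
#' @export
stratify_entities <- function(train, test, threshold = 5L,
                              key = c("surface_type", "surface")) {
  key <- match.arg(key)
  freq <- entity_frequencies(train, key)
  ents <- unnest_entities(test)
  ents$train_freq <- freq[entity_key(ents, key)]
  ents$train_freq[is.na(ents$train_freq)] <- 0L
  ents$stratum <- frequency_stratum(ents$train_freq, threshold)
  ents
}

entity_key <- function(spans, key) {
  if (key == "surface") spans$surface else paste(spans$surface, spans$type, sep = "\r")
}

entity_frequencies <- function(corpus, key) {
  ents <- unnest_entities(corpus)
  if (nrow(ents) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(entity_key(ents, key))
  stats::setNames(as.integer(tab), names(tab))
}

frequency_stratum <- function(freq, threshold) {
  factor(ifelse(freq == 0L, "unknown",
                ifelse(freq < threshold, "low", "high")),
         levels = c("unknown", "low", "high"))
}

#' Score a prediction per training-frequency stratum
#'
#' Strict entity-level scores computed separately for unknown, low- and
#' high-frequency test entities (see [stratify_entities()]). A matched
#' prediction is credited to the stratum of the gold entity it matches;
#' an unmatched gold entity counts as a false negative in its own stratum;
#' an unmatched prediction is assigned a stratum by its *own*
#' `(surface, type)` training frequency.
#'
#' @inheritParams stratify_entities
#' @param gold,pred Aligned sentence tibbles over the same texts.
#' @return An object of class `ner_strata` with a `by_stratum` tibble
#'   (counts plus percent-scale precision/recall/F1) and the `threshold`;
#'   `tidy()` returns the table, `autoplot()` a bar chart.
#' @export
score_by_stratum <- function(gold, pred, train, threshold = 5L,
                             key = c("surface_type", "surface")) {
  key <- match.arg(key)
  align_corpora(gold, pred)
  freq <- entity_frequencies(train, key)
  lookup_stratum <- function(spans) {
    f <- freq[entity_key(spans, key)]
    f[is.na(f)] <- 0L
    frequency_stratum(f, threshold)
  }
  rows <- map(seq_len(nrow(gold)), function(i) {
    g <- gold$entities[[i]]
    p <- pred$entities[[i]]
    gkey <- span_key(g); pkey <- span_key(p)
    matched_g <- rep(FALSE, length(gkey))
    matched_p <- rep(FALSE, length(pkey))
    for (j in seq_along(pkey)) {
      hit <- which(!matched_g & gkey == pkey[j])
      if (length(hit)) {
        matched_g[hit[1]] <- TRUE
        matched_p[j] <- TRUE
      }
    }
    gs <- lookup_stratum(g)
    ps <- lookup_stratum(p)
    bind_rows(
      if (length(gkey)) tibble(stratum = gs,
                               what = ifelse(matched_g, "tp", "fn")),
      if (any(!matched_p)) tibble(stratum = ps[!matched_p], what = "fp"))
  })
  flat <- list_rbind(rows)
  by_stratum <- tibble(stratum = factor(c("unknown", "low", "high"),
                                        levels = c("unknown", "low", "high")))
  tally <- function(w) {
    if (is.null(flat) || nrow(flat) == 0L) return(rep(0L, 3L))
    as.integer(table(flat$stratum[flat$what == w])[as.character(by_stratum$stratum)])
  }
  by_stratum$tp <- dplyr::coalesce(tally("tp"), 0L)
  by_stratum$fp <- dplyr::coalesce(tally("fp"), 0L)
  by_stratum$fn <- dplyr::coalesce(tally("fn"), 0L)
  by_stratum <- dplyr::bind_cols(
    by_stratum, as_tibble(prf(by_stratum$tp, by_stratum$fp, by_stratum$fn)))
  structure(list(by_stratum = by_stratum, threshold = as.integer(threshold),
                 key = key),
            class = "ner_strata")
}

#' @export
print.ner_strata <- function(x, ...) {
  cat(sprintf("<ner_strata: threshold %d, key %s>\n", x$threshold, x$key))
  print(x$by_stratum)
  invisible(x)
}

#' @rdname score_by_stratum
#' @param x An `ner_strata` object.
#' @param ... Unused.
#' @export
tidy.ner_strata <- function(x, ...) x$by_stratum

#' @rdname score_by_stratum
#' @export
glance.ner_strata <- function(x, ...) {
  tibble(threshold = x$threshold, key = x$key,
         tp = sum(x$by_stratum$tp), fp = sum(x$by_stratum$fp),
         fn = sum(x$by_stratum$fn))
}

#' @rdname score_by_stratum
#' @param object An `ner_strata` object.
#' @export
autoplot.ner_strata <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_stratum,
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "training-frequency stratum", y = "percent", fill = NULL,
                  title = "Strict-match scores by entity frequency stratum") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as JSON
#'
#' @param score An `ner_score` or `ner_strata` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(score, path) {
  payload <- if (inherits(score, "ner_score")) {
    list(overall = score$overall, by_type = score$by_type)
  } else {
    list(by_stratum = score$by_stratum, threshold = score$threshold)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
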