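#' Segment text into simple words
#'
#' Splits a mention (or any text) into "simple words" by forward maximum
#' matching: scanning left to right, the longest lexicon word starting at the
#' current position wins; characters not covered by any lexicon word fall
#' back to single-character segments. Runs of ASCII letters or digits
#' (`"MRI"`, `"3.5"`) are atomic: they are emitted whole and a lexicon match
#' is never allowed to end in the middle of one. The result is a pure
#' function of `(text, lexicon)`.
#'
#' @param text A non-empty string.
#' @param lexicon Character vector of known words (may be empty). Also
#'   accepts a [synonym_lexicon()], whose full word list is used.
#' @return A tibble of segments: `text`, `start` (0-based offset). Segments
#'   are contiguous, non-overlapping, and concatenate to `text`.
#' @examples
#' segment_text("盆腔MRI", c("盆腔", "MRI"))
#' @export
segment_text <- function(text, lexicon = character()) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty string")
  }
  if (inherits(lexicon, "synonym_lexicon")) lexicon <- lexicon_words(lexicon)
  lexicon <- unique(lexicon[nzchar(lexicon)])
  n <- str_length(text)
  # atomic ASCII alphanumeric runs (decimals kept whole)
  run_end <- integer(n)  # for each 1-based pos inside a run, the run's end
  run_start <- integer(n)
  m <- str_locate_all(text, "[A-Za-z]+|[0-9]+(?:\\.[0-9]+)*")[[1]]
  if (nrow(m) > 0L) {
    for (r in seq_len(nrow(m))) {
      run_start[m[r, 1]:m[r, 2]] <- m[r, 1]
      run_end[m[r, 1]:m[r, 2]] <- m[r, 2]
    }
  }
  by_len <- split(lexicon, str_length(lexicon))
  max_len <- if (length(lexicon)) max(str_length(lexicon)) else 0L
  segs_text <- character(0)
  segs_start <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- ""
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (len < 1L) break
      words <- by_len[[as.character(len)]]
      if (is.null(words)) next
      cand <- str_sub(text, i, i + len - 1L)
      endpos <- i + len - 1L
      # reject matches that would split an ASCII run on either side
      splits_run <- (run_end[endpos] > 0L && run_end[endpos] > endpos) ||
        (run_start[i] > 0L && run_start[i] < i)
      if (!splits_run && cand %in% words) {
        hit <- cand
        break
      }
    }
    if (nzchar(hit)) {
      segs_text <- c(segs_text, hit)
      segs_start <- c(segs_start, i - 1L)
      i <- i + str_length(hit)
    } else if (run_start[i] == i) {
      segs_text <- c(segs_text, str_sub(text, i, run_end[i]))
      segs_start <- c(segs_start, i - 1L)
      i <- run_end[i] + 1L
    } else {
      segs_text <- c(segs_text, str_sub(text, i, i))
      segs_start <- c(segs_start, i - 1L)
      i <- i + 1L
    }
  }
  tibble(text = segs_text, start = segs_start)
}

#' Wrap an external word segmenter
#'
#' Production systems typically segment with a statistical segmenter (e.g. a
#' jieba port); this adapter plugs one in. The wrapped function must return
#' the words of its input in order; the adapter computes offsets and enforces
#' the concatenation contract (the words must reconstruct the input exactly).
#'
#' @param fn A function `text -> character vector of words`.
#' @return A segmenter: a function `text -> segment tibble` as returned by
#'   [segment_text()].
#' @examples
#' whole <- as_segmenter(function(x) x)  # identity: one segment
#' whole("心电图")
#' @export
as_segmenter <- function(fn) {
  stopifnot(is.function(fn))
  function(text) {
    words <- as.character(fn(text))
    if (paste(words, collapse = "") != text) {
      abort(sprintf(
        "segmenter contract violation: words %s do not concatenate to input '%s'",
        paste0("[", paste(words, collapse = ", "), "]"), text))
    }
    lens <- str_length(words)
    tibble(text = words, start = as.integer(cumsum(c(0L, lens[-length(lens)]))))
  }
}

# default segmenter used by the synthesis step: forward maximum matching
# over the synonym lexicon's word list
fmm_segmenter <- function(lexicon) {
  words <- if (inherits(lexicon, "synonym_lexicon")) lexicon_words(lexicon) else lexicon
  function(text) segment_text(text, words)
}
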