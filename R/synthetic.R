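#' Specification for a synthetic clinical-style benchmark corpus
#'
#' Describes a template-based corpus with typed entity mentions at exactly
#' controlled training frequencies, plus a matching synonym lexicon with
#' known groups, so the whole augment-tag-evaluate loop is testable without
#' any licensed clinical data. Surfaces are short Chinese-style strings;
#' structural realism (offsets, types, synonym groups, frequencies) is the
#' goal, not clinical narrative.
#'
#' The default specification mirrors the imbalance typical of clinical NER
#' training sets — disease and treatment mentions scarce, exam and anatomy
#' mentions frequent — and reserves, for every synonym group, a variant
#' surface that occurs only in the test set. Those reserved surfaces are
#' *unknown* entities (training frequency 0) that SSSS augmentation can
#' synthesize from the training mentions, which is exactly the mechanism the
#' end-to-end benchmark exercises.
#'
#' @param inventory Tibble `surface`, `type`, `train_freq`, `test_freq`.
#'   Rows with `train_freq = 0` and `test_freq > 0` are the reserved
#'   unknown-stratum surfaces.
#' @param groups Named list of synonym groups (see [synonym_lexicon()]);
#'   headwords double as the segmentation dictionary.
#' @param templates Tibble `type`, `before`, `after`: sentence frames whose
#'   single slot takes the entity surface. Every type in `inventory` needs
#'   at least one template.
#' @param sentences_per_record How many sentences are joined into one record
#'   (exercising sentence splitting downstream). Default 3.
#' @return A list of class `ssss_spec`.
#' @seealso [generate_corpus()]
#' @export
synthetic_spec <- function(inventory = default_inventory(),
                           groups = default_groups(),
                           templates = default_templates(),
                           sentences_per_record = 3L) {
  inventory <- as_tibble(inventory)
  templates <- as_tibble(templates)
  stopifnot(all(c("surface", "type", "train_freq", "test_freq") %in%
                  names(inventory)),
            all(c("type", "before", "after") %in% names(templates)),
            sentences_per_record >= 1L)
  missing_tpl <- setdiff(unique(inventory$type), unique(templates$type))
  if (length(missing_tpl)) {
    abort(sprintf("no sentence template for entity type '%s'", missing_tpl[1]))
  }
  spec <- structure(list(inventory = inventory, groups = groups,
                         templates = templates,
                         sentences_per_record = as.integer(sentences_per_record)),
                    class = "ssss_spec")
  validate_unknown_reachability(spec)
  spec
}

# every reserved unknown surface must be synthesizable from some training
# surface of the same type by a single SSSS substitution
validate_unknown_reachability <- function(spec) {
  lex <- synonym_lexicon(spec$groups)
  inv <- spec$inventory
  unknown <- inv[inv$train_freq == 0L & inv$test_freq > 0L, , drop = FALSE]
  if (nrow(unknown) == 0L) return(invisible(TRUE))
  seg_fun <- fmm_segmenter(lex)
  reachable <- map(seq_len(nrow(inv)), function(i) {
    if (inv$train_freq[i] == 0L) return(NULL)
    segs <- seg_fun(inv$surface[i])
    vars <- unlist(map(seq_len(nrow(segs)), function(j) {
      cand <- find_synonyms(segs$text[j], lex)$word
      map_chr(cand, function(w) {
        paste0(
          str_slice(inv$surface[i], 0L, segs$start[j]), w,
          str_slice(inv$surface[i], segs$start[j] + str_length(segs$text[j]),
                    str_length(inv$surface[i])))
      })
    }))
    if (length(vars)) tibble(surface = vars, type = inv$type[i]) else NULL
  })
  reach <- list_rbind(reachable)
  ok <- map_lgl(seq_len(nrow(unknown)), function(i) {
    any(reach$surface == unknown$surface[i] & reach$type == unknown$type[i])
  })
  if (!all(ok)) {
    abort(sprintf(
      "reserved unknown surface '%s' is not reachable from any training surface",
      unknown$surface[which(!ok)[1]]))
  }
  invisible(TRUE)
}

#' @rdname synthetic_spec
#' @export
default_inventory <- function() {
  tibble(
    surface = c("头部", "盆腔", "右手中指",
                "右中指",
                "头昏", "头晕", "疼痛不适",
                "心电图", "颈动脉彩超",
                "双侧颈动脉彩超",
                "盆腔MRI",
                "盆腔核磁共振检查",
                "脑梗死", "多发脑梗死",
                "头孢哌酮",
                "头孢哌酮舒巴坦钠"),
    type = c("Body", "Body", "Body", "Body",
             "Symptom", "Symptom", "Symptom",
             "Exam", "Exam", "Exam", "Exam", "Exam",
             "Disease", "Disease",
             "Treatment", "Treatment"),
    train_freq = c(8L, 3L, 6L, 0L,
                   7L, 0L, 2L,
                   9L, 4L, 0L, 6L, 0L,
                   2L, 0L,
                   3L, 0L),
    test_freq = c(2L, 2L, 1L, 2L,
                  2L, 2L, 1L,
                  2L, 1L, 2L, 1L, 2L,
                  1L, 2L,
                  1L, 2L)
  )
}

#' @rdname synthetic_spec
#' @export
default_groups <- function() {
  list(
    "头昏" = "头晕",                                  # dizziness pair
    "右手中指" = "右中指",                # right (hand) middle finger
    "颈动脉彩超" =
      "双侧颈动脉彩超",                   # (bilateral) carotid doppler
    "脑梗死" = "多发脑梗死",          # (multiple) cerebral infarction
    "头孢哌酮" =
      "头孢哌酮舒巴坦钠",             # cefoperazone (sulbactam)
    "MRI" = "核磁共振检查",                   # MRI -> NMR examination
    # known words with no recorded synonyms (segmentation entries)
    "盆腔" = character(0),
    "头部" = character(0),
    "疼痛不适" = character(0),
    "心电图" = character(0)
  )
}

#' @rdname synthetic_spec
#' @export
default_templates <- function() {
  tibble(
    type = c("Body", "Body", "Symptom", "Symptom", "Exam", "Exam",
             "Disease", "Disease", "Treatment", "Treatment"),
    before = c("患者", "查体见",
               "患者自述", "入院后出现",
               "行", "完善",
               "诊断为", "既往",
               "给予", "继续"),
    after = c("处不适。", "无异常。",
              "数日。", "。",
              "检查。", "未见异常。",
              "。", "病史。",
              "治疗。", "抗感染。")
  )
}

#' Generate a synthetic benchmark corpus
#'
#' Realizes a [synthetic_spec()] into training and test record tibbles, the
#' matching [synonym_lexicon()], and a truth manifest listing each surface's
#' planned training-frequency stratum. Per-type entity counts match the
#' specification exactly (not in expectation); the only randomness is the
#' order of mentions and the choice among templates, both driven by `seed`,
#' so a rerun with the same seed is byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed. Default 7.
#' @param threshold Low/high frequency boundary recorded in the manifest.
#' @return A list of class `ssss_corpus`: `train`, `test` (record tibbles),
#'   `lexicon`, `manifest`, `spec`, `seed`.
#' @export
generate_corpus <- function(spec = synthetic_spec(), seed = 7L, threshold = 5L) {
  stopifnot(inherits(spec, "ssss_spec"))
  lexicon <- synonym_lexicon(spec$groups)
  out <- withr::with_seed(as.integer(seed), {
    list(train = realize_split(spec, "train_freq", "tr"),
         test = realize_split(spec, "test_freq", "te"))
  })
  manifest <- spec$inventory %>%
    mutate(planned_stratum = frequency_stratum(.data$train_freq, threshold)) %>%
    arrange(.data$type, .data$surface)
  structure(list(train = out$train, test = out$test, lexicon = lexicon,
                 manifest = manifest, spec = spec, seed = as.integer(seed)),
            class = "ssss_corpus")
}

# build one split: expand the per-surface frequency plan into a shuffled
# mention list, drop each mention into a random template for its type, then
# pack sentences into multi-sentence records
realize_split <- function(spec, freq_col, prefix) {
  inv <- spec$inventory
  mentions <- tibble(
    surface = rep(inv$surface, inv[[freq_col]]),
    type = rep(inv$type, inv[[freq_col]]))
  if (nrow(mentions) == 0L) {
    return(tibble(record_id = character(), text = character(),
                  entities = list()))
  }
  mentions <- mentions[sample.int(nrow(mentions)), , drop = FALSE]
  sents <- map(seq_len(nrow(mentions)), function(i) {
    tpl <- spec$templates[spec$templates$type == mentions$type[i], , drop = FALSE]
    tpl <- tpl[sample.int(nrow(tpl), 1L), , drop = FALSE]
    s0 <- str_length(tpl$before)
    txt <- paste0(tpl$before, mentions$surface[i], tpl$after)
    list(text = txt,
         entities = entity_spans(s0, s0 + str_length(mentions$surface[i]),
                                 mentions$type[i], text = txt))
  })
  rec_of <- ceiling(seq_along(sents) / spec$sentences_per_record)
  recs <- map(unique(rec_of), function(r) {
    parts <- sents[rec_of == r]
    texts <- map_chr(parts, "text")
    offsets <- cumsum(c(0L, str_length(texts)[-length(texts)]))
    ents <- list_rbind(map2(parts, offsets, function(p, off) {
      e <- p$entities
      entity_spans(e$start + off, e$end + off, e$type, surface = e$surface)
    }))
    txt <- paste(texts, collapse = "")
    list(record_id = sprintf("%s%04d", prefix, r), text = txt,
         entities = validate_spans(txt, ents, what = sprintf("%s%04d", prefix, r)))
  })
  tibble(record_id = map_chr(recs, "record_id"),
         text = map_chr(recs, "text"),
         entities = map(recs, "entities"))
}

#' @export
print.ssss_corpus <- function(x, ...) {
  cat(sprintf(
    "<ssss_corpus: %d train / %d test records, %d train / %d test entities, seed %d>\n",
    nrow(x$train), nrow(x$test),
    nrow(unnest_entities(x$train)), nrow(unnest_entities(x$test)), x$seed))
  invisible(x)
}

#' Write a generated corpus to fixture files
#'
#' Writes `train.jsonl`, `test.jsonl`, `lexicon.tsv` and `manifest.tsv`
#' under `outdir`. Output is byte-deterministic given the generated object.
#'
#' @param corpus An [generate_corpus()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixtures <- function(corpus, outdir) {
  stopifnot(inherits(corpus, "ssss_corpus"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_records(corpus$train, file.path(outdir, "train.jsonl"))
  write_records(corpus$test, file.path(outdir, "test.jsonl"))
  write_lexicon(corpus$lexicon, file.path(outdir, "lexicon.tsv"))
  man <- corpus$manifest
  man$planned_stratum <- as.character(man$planned_stratum)
  lines <- c(paste(names(man), collapse = "\t"),
             map_chr(seq_len(nrow(man)), function(i) {
               paste(unlist(man[i, ], use.names = FALSE), collapse = "\t")
             }))
  writeLines(lines, file.path(outdir, "manifest.tsv"), useBytes = TRUE)
  invisible(outdir)
}
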