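# Worked-example sentences: four short clinical sentences whose entity
# mentions each have one recorded near-synonym in the mini lexicon.

mk_sentence <- function(text, surfaces, types, sent_id = "s1") {
  starts <- map_int(surfaces, function(s) {
    as.integer(regexpr(s, text, fixed = TRUE)) - 1L
  })
  stopifnot(all(starts >= 0L))
  tibble::tibble(
    doc_id = sent_id, sent_index = 1L, sent_id = sent_id, text = text,
    entities = list(entity_spans(starts, starts + nchar(surfaces), types,
                                 text = text)),
    provenance = "original", parent_id = sent_id,
    substitutions = list(tibble::tibble(entity = integer(),
                                        segment = character(),
                                        replacement = character())))
}

worked_sentences <- function() {
  dplyr::bind_rows(
    mk_sentence("右手中指疼痛不适", "右手中指", "Body", "w1"),
    mk_sentence("主因头部外伤出血伴头昏3.5小时入院", "头昏", "Symptom", "w2"),
    mk_sentence("心电图,颈动脉彩超等检查",
                c("心电图", "颈动脉彩超"), c("Exam", "Exam"), "w3"),
    mk_sentence("给予静点头孢哌酮,炎琥宁联合抗感染",
                c("头孢哌酮", "炎琥宁"), c("Treatment", "Treatment"), "w4"))
}

# exactly the worked synonym pairs, nothing else
worked_lexicon <- function() {
  synonym_lexicon(list(
    "头昏" = "头晕",
    "右手中指" = "右中指",
    "颈动脉彩超" = "双侧颈动脉彩超",
    "头孢哌酮" = "头孢哌酮舒巴坦钠",
    "MRI" = "核磁共振检查"))
}

worked_expected_surfaces <- function() {
  c("右中指", "头晕", "双侧颈动脉彩超", "头孢哌酮舒巴坦钠")
}

# random corpora ------------------------------------------------------------

rand_char_pool <- c("安", "报", "常", "东", "发", "功", "红", "九", "口",
                    "蓝", "明", "能", "平", "奇", "人", "三", "天", "文",
                    "西", "义", "中", "升", "水", "火", "木", "金", "土",
                    "山", "川", "田")

rand_types <- c("Body", "Symptom", "Exam", "Disease")

# one random sentence with random non-overlapping spans, built by a
# left-to-right walk so span invariants hold by construction
rand_sentence <- function(sent_id, min_len = 5L, max_len = 30L) {
  len <- sample(min_len:max_len, 1L)
  text <- paste(sample(rand_char_pool, len, replace = TRUE), collapse = "")
  starts <- integer(0); ends <- integer(0); types <- character(0)
  pos <- 0L
  while (pos < len) {
    if (stats::runif(1) < 0.35 && pos + 1L <= len) {
      w <- sample(1:3, 1L)
      w <- min(w, len - pos)
      starts <- c(starts, pos); ends <- c(ends, pos + w)
      types <- c(types, sample(rand_types, 1L))
      pos <- pos + w
    }
    pos <- pos + sample(1:3, 1L)
  }
  mk <- mk_sentence(text, character(0), character(0), sent_id)
  mk$entities[[1]] <- entity_spans(starts, ends, types, text = text)
  mk
}

rand_corpus <- function(n, seed) {
  withr::with_seed(seed, {
    purrr::list_rbind(purrr::map(seq_len(n), function(i) {
      rand_sentence(sprintf("r%d", i))
    }))
  })
}

# a perturbed prediction corpus over the same texts: spans dropped, retyped,
# shifted, plus spurious spans in uncovered gaps
perturb_corpus <- function(gold, seed) {
  withr::with_seed(seed, {
    pred <- gold
    pred$entities <- purrr::map2(gold$text, gold$entities, function(txt, e) {
      n <- nchar(txt)
      keep <- e[stats::runif(nrow(e)) < 0.65, , drop = FALSE]
      if (nrow(keep)) {
        retype <- stats::runif(nrow(keep)) < 0.2
        keep$type[retype] <- sample(rand_types, sum(retype), replace = TRUE)
        shift <- stats::runif(nrow(keep)) < 0.15 & keep$end < n
        keep$end[shift] <- keep$end[shift] + 1L
      }
      # drop any overlaps introduced by boundary shifts
      keep <- keep[order(keep$start), , drop = FALSE]
      if (nrow(keep) > 1L) {
        ok <- c(TRUE, keep$start[-1L] >= cummax(keep$end[-nrow(keep)]))
        keep <- keep[ok, , drop = FALSE]
      }
      # spurious predictions in gaps
      covered <- rep(FALSE, n)
      for (j in seq_len(nrow(keep))) covered[(keep$start[j] + 1L):keep$end[j]] <- TRUE
      extra_s <- integer(0); extra_e <- integer(0)
      pos <- 0L
      while (pos < n) {
        if (!covered[pos + 1L] && stats::runif(1) < 0.1) {
          w <- 1L
          while (pos + w < n && w < 3L && !covered[pos + w + 1L] &&
                 stats::runif(1) < 0.5) w <- w + 1L
          extra_s <- c(extra_s, pos); extra_e <- c(extra_e, pos + w)
          pos <- pos + w
        } else {
          pos <- pos + 1L
        }
      }
      entity_spans(c(keep$start, extra_s), c(keep$end, extra_e),
                   c(keep$type,
                     sample(rand_types, length(extra_s), replace = TRUE)),
                   text = txt)
    })
    pred
  })
}

# synthesis fixtures with known segments/synonyms ---------------------------

# Entities are concatenations of known two-character dictionary words over
# disjoint characters, so forward maximum matching must recover exactly the
# construction; each word k gets a known number of synonyms built from a
# separate character pool. Expected variant counts/texts follow in closed
# form from the construction.
rand_synthesis_fixture <- function(seed) {
  word_pool <- c("甲乙", "丙丁", "戊己", "庚辛", "壬癸", "子丑", "寅卯", "辰巳")
  syn_chars <- c("阿", "吧", "次", "的", "额", "分", "给", "好", "及", "看",
                 "了", "吗", "呢", "哦", "片", "去", "然", "所", "图", "无")
  ctx_chars <- c("一", "二", "四", "五", "六", "七", "八", "十")
  withr::with_seed(seed, {
    words <- sample(word_pool, sample(3:5, 1L))
    syn_words <- paste0(rep(syn_chars, each = length(syn_chars)), syn_chars)
    syn_words <- sample(syn_words[substr(syn_words, 1, 1) !=
                                    substr(syn_words, 2, 2)])
    groups <- list()
    take <- 0L
    for (w in words) {
      k <- sample(0:3, 1L)
      groups[[w]] <- if (k > 0L) syn_words[take + seq_len(k)] else character(0)
      take <- take + k
    }
    lex <- synonym_lexicon(groups)
    # 1-2 entities, each 1-3 segments drawn without reuse across entities
    n_ent <- sample(1:2, 1L)
    avail <- sample(words)
    ent_words <- list()
    for (i in seq_len(n_ent)) {
      m <- min(sample(1:3, 1L), length(avail) - (n_ent - i))
      ent_words[[i]] <- avail[seq_len(m)]
      avail <- avail[-seq_len(m)]
    }
    ctx <- function(k) paste(sample(ctx_chars, k, replace = TRUE), collapse = "")
    text <- ctx(2)
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n_ent)) {
      surf <- paste(ent_words[[i]], collapse = "")
      starts <- c(starts, nchar(text))
      text <- paste0(text, surf)
      ends <- c(ends, nchar(text))
      text <- paste0(text, ctx(2))
    }
    sen <- mk_sentence(text, character(0), character(0), "f1")
    sen$entities[[1]] <- entity_spans(starts, ends,
                                      rep("Entity", n_ent), text = text)
    list(sentence = sen, lexicon = lex, ent_words = ent_words,
         groups = groups)
  })
}

# brute-force enumeration of single-substitution variant texts from the
# fixture's known construction (pure string surgery, no package calls)
oracle_variant_texts <- function(fix) {
  sen <- fix$sentence
  ents <- sen$entities[[1]]
  out <- character(0)
  for (i in seq_len(nrow(ents))) {
    off <- ents$start[i]
    within <- 0L
    for (w in fix$ent_words[[i]]) {
      for (syn in fix$groups[[w]]) {
        s <- off + within
        out <- c(out, paste0(substr(sen$text, 1, s), syn,
                             substring(sen$text, s + nchar(w) + 1L)))
      }
      within <- within + nchar(w)
    }
  }
  unique(out)
}
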