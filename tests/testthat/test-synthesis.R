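test_that("project_span shifts following spans by the length difference", {
  txt <- "心电图,颈动脉彩超等检查"
  sen <- mk_sentence(txt, c("心电图", "颈动脉彩超"), c("Exam", "Exam"))
  out <- project_span(sen, 4, 9, "双侧颈动脉彩超")
  expect_equal(out$text, "心电图,双侧颈动脉彩超等检查")
  e <- out$entities[[1]]
  expect_equal(e$surface, c("心电图", "双侧颈动脉彩超"))
  expect_equal(e$start, c(0L, 4L))
  expect_equal(e$end, c(3L, 11L))
  # characters after the region shifted by +2
  expect_equal(substring(out$text, 12), "等检查")
})

test_that("project_span with equal-length replacement keeps all offsets", {
  sen <- mk_sentence("主因头部外伤出血伴头昏3.5小时入院", "头昏", "Symptom")
  out <- project_span(sen, 9, 11, "头晕")
  expect_equal(out$entities[[1]]$start, sen$entities[[1]]$start)
  expect_equal(out$entities[[1]]$end, sen$entities[[1]]$end)
  expect_equal(out$entities[[1]]$surface, "头晕")
  # identity replacement reproduces the sentence
  same <- project_span(sen, 9, 11, "头昏")
  expect_equal(same$text, sen$text)
  expect_equal(same$entities, sen$entities)
})

test_that("project_span rejects invalid regions", {
  sen <- mk_sentence("头昏头晕并发", c("头昏", "头晕"), c("Symptom", "Symptom"))
  expect_error(project_span(sen, 1, 3, "某某"), "crosses entity span")
  expect_error(project_span(sen, 4, 6, "某某"), "outside every entity span")
  # context substitution must be opted into
  out <- project_span(sen, 4, 6, "某某", substitute_context = TRUE)
  expect_equal(out$text, "头昏头晕某某")
  expect_error(project_span(sen, 0, 2, ""), "non-empty")
})

test_that("synthesize_sentence reproduces the single-substitution worked case", {
  sen <- mk_sentence("主因头部外伤出血伴头昏3.5小时入院", "头昏", "Symptom")
  lex <- synonym_lexicon(list("头昏" = "头晕"))
  got <- synthesize_sentence(sen, lex)
  expect_equal(nrow(got), 1L)
  expect_equal(got$text, "主因头部外伤出血伴头晕3.5小时入院")
  expect_equal(got$entities[[1]]$surface, "头晕")
  expect_equal(got$entities[[1]]$type, "Symptom")
  expect_equal(got$provenance, "synthesized")
  expect_equal(got$parent_id, sen$sent_id)
  expect_equal(got$substitutions[[1]]$replacement, "头晕")
})

test_that("segment-level substitution rebuilds compound mentions", {
  sen <- mk_sentence("行盆腔MRI检查", "盆腔MRI", "Exam")
  lex <- synonym_lexicon(list("MRI" = "核磁共振检查", "盆腔" = character(0)))
  got <- synthesize_sentence(sen, lex)
  expect_equal(nrow(got), 1L)
  expect_equal(got$entities[[1]]$surface, "盆腔核磁共振检查")
  expect_true(grepl("盆腔核磁共振检查", got$text, fixed = TRUE))
})

test_that("variant counts follow the single-substitution emission rule", {
  # one entity of 2 segments, each with 2 candidates: exactly 4 variants
  sen <- mk_sentence("零甲乙丙丁壹", "甲乙丙丁", "Entity")
  lex <- synonym_lexicon(list("甲乙" = c("拉圾", "垃娃"),
                              "丙丁" = c("多哦", "名字")))
  got <- synthesize_sentence(sen, lex)
  expect_equal(nrow(got), 4L)
  expect_equal(length(unique(got$text)), 4L)
  # min_segments above the segment count disables the entity
  conf <- augment_config(min_segments = 3)
  expect_equal(nrow(synthesize_sentence(sen, lex, conf)), 0L)
})

test_that("cross-product policy adds per-entity combinations", {
  sen <- mk_sentence("零甲乙丙丁壹", "甲乙丙丁", "Entity")
  lex <- synonym_lexicon(list("甲乙" = "拉圾", "丙丁" = "多哦"))
  single <- synthesize_sentence(sen, lex, augment_config(policy = "single"))
  crossed <- synthesize_sentence(sen, lex, augment_config(policy = "cross"))
  expect_equal(nrow(single), 2L)
  expect_equal(nrow(crossed), 3L)  # two singles plus the double substitution
  expect_true("零拉圾多哦壹" %in% crossed$text)
})

test_that("variants conserve labels and leave context untouched", {
  for (seed in 1:25) {
    fix <- rand_synthesis_fixture(seed)
    got <- synthesize_sentence(fix$sentence, fix$lexicon)
    parent <- fix$sentence$entities[[1]]
    for (i in seq_len(nrow(got))) {
      e <- got$entities[[i]]
      expect_equal(nrow(e), nrow(parent))
      expect_equal(sort(e$type), sort(parent$type))
      expect_equal(e$surface, str_slice(got$text[i], e$start, e$end))
      # context: text outside entity spans identical to the parent's
      strip <- function(txt, spans) {
        kept <- setdiff(seq_len(nchar(txt)) - 1L,
                        unlist(purrr::map2(spans$start, spans$end - 1L, `:`)))
        paste(strsplit(txt, "")[[1]][kept + 1L], collapse = "")
      }
      expect_equal(strip(got$text[i], e), strip(fix$sentence$text, parent))
    }
  }
})

test_that("max_variants caps by seeded sampling without losing determinism", {
  fix <- rand_synthesis_fixture(3)
  all_v <- synthesize_sentence(fix$sentence, fix$lexicon)
  expect_gte(nrow(all_v), 3L)  # fixture seed 3 yields enough variants to cap
  conf <- augment_config(max_variants = 2, seed = 9)
  capped <- synthesize_sentence(fix$sentence, fix$lexicon, conf)
  expect_equal(nrow(capped), 2L)
  expect_true(all(capped$text %in% all_v$text))
  expect_identical(capped$text,
                   synthesize_sentence(fix$sentence, fix$lexicon, conf)$text)
  # a different stream gives a (possibly) different but deterministic draw
  other <- synthesize_sentence(fix$sentence, fix$lexicon, conf, .stream = 2)
  expect_identical(other$text,
                   synthesize_sentence(fix$sentence, fix$lexicon, conf,
                                       .stream = 2)$text)
})

test_that("augment_corpus without synonyms returns originals with factor 1", {
  sen <- dplyr::bind_rows(mk_sentence("心电图检查", "心电图", "Exam", "a#1"),
                          mk_sentence("头部正常", "头部", "Body", "b#1"))
  aug <- augment_corpus(sen, synonym_lexicon(list()))
  expect_equal(aug$corpus$text, sen$text)
  expect_true(all(tidy(aug)$factor == 1))
  expect_equal(glance(aug)$n_entities_post, 2L)
})

test_that("augment_corpus report counts match the emitted corpus exactly", {
  sen <- worked_sentences()
  aug <- augment_corpus(sen, worked_lexicon())
  by_type <- tidy(aug)
  post_recount <- dplyr::count(
    purrr::list_rbind(purrr::map(aug$corpus$entities, tibble::as_tibble)),
    type, name = "post")
  expect_equal(by_type[, c("type", "post")], post_recount)
  expect_equal(sum(aug$by_sentence$n_variants),
               sum(aug$corpus$provenance == "synthesized"))
  expect_true(all(by_type$post >= by_type$pre))
})

test_that("augmentation is byte-identical across reruns", {
  sen <- worked_sentences()
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  conf <- augment_config(max_variants = 3, seed = 21)
  write_records(augment_corpus(sen, worked_lexicon(), conf)$corpus, f1)
  write_records(augment_corpus(sen, worked_lexicon(), conf)$corpus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
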