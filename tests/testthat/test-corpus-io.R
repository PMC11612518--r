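test_that("read_records parses the JSONL dialect and validates spans", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"r1","text":"心电图等检查。","entities":[{"start":0,"end":3,"type":"Exam"}]}',
    '{"id":"r2","text":"头昏3小时","entities":[]}'),
    f, useBytes = TRUE)
  recs <- read_records(f)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$entities[[1]]$surface, "心电图")
  expect_equal(recs$entities[[1]]$type, "Exam")
  expect_equal(nrow(recs$entities[[2]]), 0L)
})

test_that("read_records handles empty files, bad JSON, and bad spans", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f)
  expect_equal(nrow(read_records(f)), 0L)

  writeLines('{"id":"r1","text": broken', f, useBytes = TRUE)
  expect_error(read_records(f), "line 1.*malformed JSON")

  writeLines('{"id":"rX","text":"头昏","entities":[{"start":0,"end":9,"type":"S"}]}',
             f, useBytes = TRUE)
  expect_error(read_records(f), "rX")

  writeLines(paste0('{"id":"rY","text":"头昏头晕","entities":',
                    '[{"start":0,"end":3,"type":"S"},{"start":2,"end":4,"type":"S"}]}'),
             f, useBytes = TRUE)
  expect_error(read_records(f), "overlapping")
})

test_that("read_records remaps key names and converts inclusive offsets", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"doc":"r1","content":"心电图等","spans":',
                    '[{"s":0,"e":2,"label":"Exam"}]}'), f, useBytes = TRUE)
  recs <- read_records(f, keys = list(id = "doc", text = "content",
                                      entities = "spans", start = "s",
                                      end = "e", type = "label"),
                       span_convention = "inclusive")
  expect_equal(recs$entities[[1]]$end, 3L)
  expect_equal(recs$entities[[1]]$surface, "心电图")
})

test_that("write_records then read_records is the identity", {
  recs <- tibble::tibble(
    record_id = c("a", "b"),
    text = c("头昏。心电图。", "盆腔MRI平扫"),
    entities = list(entity_spans(c(0, 3), c(2, 6), c("Symptom", "Exam"),
                                 text = "头昏。心电图。"),
                    entity_spans(0, 5, "Exam", text = "盆腔MRI平扫")))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_records(recs, f)
  back <- read_records(f)
  expect_equal(back$text, recs$text)
  expect_equal(back$entities, recs$entities)
})

test_that("split_sentences re-bases offsets and conserves characters", {
  txt <- "头部正常。主因头昏入院。"
  rec <- tibble::tibble(record_id = "r1", text = txt,
                        entities = list(entity_spans(c(0, 7), c(2, 9),
                                                     c("Body", "Symptom"),
                                                     text = txt)))
  sen <- split_sentences(rec)
  expect_equal(nrow(sen), 2L)
  expect_equal(paste(sen$text, collapse = ""), txt)
  expect_equal(sen$entities[[2]]$start, 2L)
  expect_equal(sen$entities[[2]]$surface, "头昏")
  expect_true(all(sen$provenance == "original"))
})

test_that("split_sentences edge cases follow the conventions", {
  # no separator: one sentence identical to the record
  rec <- tibble::tibble(record_id = "r1", text = "头昏不止",
                        entities = list(entity_spans(0, 2, "Symptom",
                                                     text = "头昏不止")))
  sen <- split_sentences(rec)
  expect_equal(nrow(sen), 1L)
  expect_equal(sen$text, rec$text)

  # trailing period: no empty trailing sentence
  rec2 <- tibble::tibble(record_id = "r2", text = "头昏。",
                         entities = list(entity_spans()))
  expect_equal(nrow(split_sentences(rec2)), 1L)

  # entity straddling a boundary: error, or keep-record fallback
  txt <- "头昏。头晕。"
  rec3 <- tibble::tibble(record_id = "r3", text = txt,
                         entities = list(entity_spans(2, 4, "Symptom",
                                                      text = txt)))
  expect_error(split_sentences(rec3), "crosses a sentence boundary")
  kept <- split_sentences(rec3, split_policy = "keep-record")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$text, txt)
})

test_that("spans_to_bio produces the expected tag sequences", {
  sen <- mk_sentence("头昏3小时", "头昏", "Symptom")
  bio <- spans_to_bio(sen)
  expect_equal(bio$tag, c("B-Symptom", "I-Symptom", "O", "O", "O"))
  expect_equal(paste(bio$char, collapse = ""), "头昏3小时")

  none <- mk_sentence("无异常发现", character(0), character(0))
  expect_true(all(spans_to_bio(none)$tag == "O"))

  adj <- mk_sentence("头昏头晕", character(0), character(0))
  adj$entities[[1]] <- entity_spans(c(0, 2), c(2, 4), c("Symptom", "Symptom"),
                                    text = "头昏头晕")
  expect_equal(spans_to_bio(adj)$tag,
               c("B-Symptom", "I-Symptom", "B-Symptom", "I-Symptom"))
})

test_that("bio_to_spans inverts spans_to_bio and handles orphan I-tags", {
  sen <- mk_sentence("心电图等", "心电图", "Exam")
  back <- bio_to_spans(spans_to_bio(sen))
  expect_equal(back$entities[[1]], sen$entities[[1]])

  allo <- tibble::tibble(sent_id = "s1", pos = 0:2,
                         char = c("无", "异", "常"), tag = rep("O", 3))
  expect_equal(nrow(bio_to_spans(allo)$entities[[1]]), 0L)

  orphan <- tibble::tibble(sent_id = "s1", pos = 0:2,
                           char = c("阿", "司", "林"),
                           tag = c("I-Drug", "I-Drug", "O"))
  expect_error(bio_to_spans(orphan), "orphan I-tag")
  repaired <- bio_to_spans(orphan, strict = FALSE)
  expect_equal(repaired$entities[[1]],
               entity_spans(0, 2, "Drug", text = "阿司林"))
})

test_that("span/BIO round trip is the identity on random sentences", {
  sen <- rand_corpus(150, seed = 11)
  back <- bio_to_spans(spans_to_bio(sen))
  expect_equal(back$text, sen$text)
  expect_equal(back$entities, sen$entities)
})

test_that("BIO files round-trip byte-identically and reject bad input", {
  sen <- dplyr::bind_rows(mk_sentence("头昏3小时", "头昏", "Symptom", "s1"),
                          mk_sentence("心电图等", "心电图", "Exam", "s2"))
  bio <- spans_to_bio(sen)
  f1 <- withr::local_tempfile(fileext = ".bio")
  f2 <- withr::local_tempfile(fileext = ".bio")
  write_bio(bio, f1)
  back <- read_bio(f1)
  expect_equal(back$char, bio$char)
  expect_equal(back$tag, bio$tag)
  write_bio(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  writeLines(character(0), f1)
  expect_equal(nrow(read_bio(f1)), 0L)

  writeLines(c("头\tB-Symptom\textra"), f1, useBytes = TRUE)
  expect_error(read_bio(f1), "line 1.*2 tab-separated")

  writeLines(c("头\tB_Symptom"), f1, useBytes = TRUE)
  expect_error(read_bio(f1), "malformed tag")
})
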