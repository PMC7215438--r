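rules <- default_rules()

test_that("the default rule file loads with unique ids and known lexicons", {
  expect_s3_class(rules, "ruleset")
  expect_length(rules$rules, 6L)
  targets <- vapply(rules$rules, `[[`, character(1), "target")
  expect_setequal(targets, c("segmentation", "primary_site", "lesion_size",
                             "metastasis_site", "special_case",
                             "lesion_conditional"))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("lexicons: {a: [x]}", "rules:",
               "  - {rule_id: r1, target: primary_site, any_of: [nope]}"), bad)
  expect_error(load_rules(bad), "unknown lexicon")
})

test_that("segment_sentences splits on terminators and enumeration starts", {
  expect_equal(segment_sentences("A。B；C"), c("A", "B", "C"))
  expect_equal(segment_sentences("no delimiters"), "no delimiters")
  expect_equal(segment_sentences("finding 2.liver shows"),
               c("finding", "2.liver shows"))
  ## decimal points are not sentence boundaries
  expect_equal(segment_sentences("mass 2.3cm seen；next"),
               c("mass 2.3cm seen", "next"))
  expect_equal(segment_sentences("一、first。二、second"),
               c("一、first", "二、second"))
  expect_equal(segment_sentences(""), character(0))
  expect_equal(segment_sentences("。；"), character(0))
})

test_that("select_candidates applies the keyword rules", {
  s <- function(...) tagged_sentence(c(...))
  sents <- list(s("q1", "cancer", "f2"),            # primary
                s("2.3cm", "shadow", "f1"),         # lesion (unit AND density)
                s("2.3cm", "f1", "f2"),             # unit alone: nothing
                s("metastasis", "q1"),              # metastasis, full region
                s("q2", "cancer", "metastasis", "q1"), # both; region after kw
                s("f1", "f2"))                      # nothing
  cands <- select_candidates(sents, rules)
  cats <- vapply(cands, `[[`, character(1), "category")
  idx <- vapply(cands, `[[`, integer(1), "index")
  expect_equal(cats[idx == 1], "primary_site")
  expect_equal(cats[idx == 2], "lesion_size")
  expect_false(3 %in% idx)
  expect_equal(cats[idx == 4], "metastasis_site")
  expect_setequal(cats[idx == 5], c("primary_site", "metastasis_site"))
  expect_false(6 %in% idx)

  ## metastasis region starts after the primary keyword
  meta5 <- cands[[which(idx == 5 & cats == "metastasis_site")]]
  expect_equal(meta5$region, c(3L, 5L))
  meta4 <- cands[[which(idx == 4)]]
  expect_equal(meta4$region, c(1L, 3L))

  ## Latin keywords match case-insensitively
  expect_equal(vapply(select_candidates(list(s("q1", "CANCER")), rules),
                      `[[`, character(1), "category"), "primary_site")

  ## monotonicity: appending sentences only adds candidates
  more <- select_candidates(c(sents, list(s("q9", "cancer"))), rules)
  expect_equal(length(more), length(cands) + 1L)
})

test_that("apply_special_cases extends incomplete parts over lymph nodes", {
  s <- tagged_sentence(c("f1", "mediastinum", "lymphnode", "f2"),
                       c("O", "S-body", "O", "O"))
  sp <- data.frame(start = 2L, end = 3L, category = "body")
  out <- apply_special_cases(sp, s, rules)
  expect_equal(out$end, 4L)
  expect_equal(cwdner:::span_surface(s, out$start, out$end),
               "mediastinumlymphnode")

  ## not in the incomplete list: unchanged
  s2 <- tagged_sentence(c("q1", "lymphnode"), c("S-body", "O"))
  expect_equal(apply_special_cases(
    data.frame(start = 1L, end = 2L, category = "body"), s2, rules)$end, 2L)

  ## at sentence end with nothing following: unchanged
  s3 <- tagged_sentence(c("f1", "mediastinum"), c("O", "S-body"))
  expect_equal(apply_special_cases(
    data.frame(start = 2L, end = 3L, category = "body"), s3, rules)$end, 3L)
})

test_that("dictionary_correct completes, trims, and is idempotent", {
  d <- domain_dictionary(list(body = c("内乳淋巴结", "右肺下叶", "肝")))
  ## exact member: identity
  expect_equal(dictionary_correct("肝", d), "肝")
  ## unique superstring present in the sentence: completed
  expect_equal(dictionary_correct("内乳淋巴", d,
                                  sentence_text = "见内乳淋巴结肿大"),
               "内乳淋巴结")
  ## no sentence evidence: left alone
  expect_equal(dictionary_correct("内乳淋巴", d, sentence_text = "见肝影"),
               "内乳淋巴")
  ## dictionary entry inside the entity: trimmed to the longest one
  expect_equal(dictionary_correct("右肺下叶炎", d), "右肺下叶")
  ## idempotence over all branches
  for (e in c("肝", "内乳淋巴", "右肺下叶炎", "unrelated")) {
    once <- dictionary_correct(e, d, sentence_text = "见内乳淋巴结肿大")
    expect_equal(dictionary_correct(once, d,
                                    sentence_text = "见内乳淋巴结肿大"), once)
  }
})

test_that("extract_task_entities runs the full pipeline with the conditional", {
  d <- domain_dictionary(list(body = c("q1", "q2", "mediastinumlymphnode")))
  doc <- ner_document(list(
    tagged_sentence(c("q1", "cancer", "f1"), c("S-body", "O", "O"), "s1"),
    tagged_sentence(c("q2", "2.3cm", "shadow"), c("S-body", "S-size", "O"), "s2"),
    tagged_sentence(c("f1", "4.5cm", "shadow"), c("O", "S-size", "O"), "s3"),
    tagged_sentence(c("metastasis", "q2", "f1"), c("O", "S-body", "O"), "s4"),
    tagged_sentence(c("mediastinum", "lymphnode", "cancer"),
                    c("S-body", "O", "O"), "s5")
  ), "doc1")
  out <- extract_task_entities(doc, oracle_tagger(), d, rules)
  expect_setequal(out$primary_site, c("q1", "mediastinumlymphnode"))
  expect_equal(out$lesion_size, "2.3cm")   # s3 lacks a site: conditional drops it
  expect_equal(out$metastasis_site, "q2")

  empty <- extract_task_entities(ner_document(list(), "e"), oracle_tagger(),
                                 d, rules)
  expect_equal(lengths(empty),
               c(primary_site = 0L, lesion_size = 0L, metastasis_site = 0L))

  ## raw-text entry point: segmentation + whitespace tokenization
  toy_tagger <- function(sentence)
    ifelse(sentence$tokens == "q1", "S-body", "O")
  out2 <- extract_task_entities("q1 cancer f1。f2 f3", toy_tagger, d, rules)
  expect_equal(out2$primary_site, "q1")
})

test_that("rule evaluation is pure and the subset sweep reports per-subset F", {
  td <- generate_task_documents(task_doc_spec(n_documents = 6, seed = 3))
  p1 <- lapply(td$documents, extract_task_entities, tagger = oracle_tagger(),
               dictionary = td$dictionary, rules = rules)
  p2 <- lapply(td$documents, extract_task_entities, tagger = oracle_tagger(),
               dictionary = td$dictionary, rules = rules)
  expect_identical(p1, p2)

  sweep <- rule_subset_sweep(td$documents, td$gold, oracle_tagger(),
                             td$dictionary, rules)
  expect_true(is.data.frame(sweep))
  expect_equal(nrow(sweep), 2^5)      # five optional rules
  expect_true(all(sweep$F >= 0 & sweep$F <= 1))
  full <- sweep$F[vapply(strsplit(sweep$rules, ","), length, integer(1)) == 5]
  expect_equal(max(sweep$F), full)
})
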