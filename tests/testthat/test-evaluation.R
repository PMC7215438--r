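span_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             category = m[, 3], stringsAsFactors = FALSE)
}

test_that("count_matches is strict: partial overlap is one FP plus one FN", {
  cm <- count_matches(span_df(1, 4, "b"), span_df(1, 4, "b"))
  expect_equal(cm[c("TP", "FP", "FN")], list(TP = 1L, FP = 0L, FN = 0L))

  cm <- count_matches(span_df(1, 4, "b"), span_df(1, 3, "b"))
  expect_equal(cm[c("TP", "FP", "FN")], list(TP = 0L, FP = 1L, FN = 1L))

  cm <- count_matches(span_df(1, 4, "b", 6, 7, "b"),
                      span_df(1, 4, "b", 5, 7, "b", 8, 9, "b"))
  expect_equal(cm[c("TP", "FP", "FN")], list(TP = 1L, FP = 2L, FN = 1L))

  ## category mismatch on identical boundaries is wrong on both sides
  cm <- count_matches(span_df(1, 3, "b"), span_df(1, 3, "t"))
  expect_equal(cm[c("TP", "FP", "FN")], list(TP = 0L, FP = 1L, FN = 1L))
})

test_that("count_matches swaps FP and FN when gold and pred swap", {
  set.seed(61)
  for (i in 1:30) {
    mk <- function() {
      sets <- enumerate_span_sets(6, max_span = 2)
      sets[[sample(length(sets), 1)]]
    }
    g <- mk(); p <- mk()
    a <- count_matches(g, p); b <- count_matches(p, g)
    expect_equal(a$TP, b$TP)
    expect_equal(a$FP, b$FN)
    expect_equal(a$FN, b$FP)
  }
})

test_that("prf computes the published formulas with the zero convention", {
  expect_equal(prf(list(TP = 1, FP = 0, FN = 0)), c(P = 1, R = 1, F = 1))
  expect_equal(prf(list(TP = 2, FP = 1, FN = 2)),
               c(P = 2 / 3, R = 1 / 2, F = 4 / 7))
  expect_equal(prf(list(TP = 0, FP = 3, FN = 2)), c(P = 0, R = 0, F = 0))
  expect_equal(prf(list(TP = 0, FP = 0, FN = 0)), c(P = 0, R = 0, F = 0))
  ## F never exceeds the arithmetic mean of P and R
  set.seed(62)
  for (i in 1:50) {
    v <- prf(list(TP = sample(0:9, 1), FP = sample(0:9, 1),
                  FN = sample(0:9, 1)))
    expect_lte(v["F"], (v["P"] + v["R"]) / 2 + 1e-12)
  }
})

test_that("weighted_prf applies the task weights and validates them", {
  pc <- list(primary_site = c(P = 0.8, R = 0.8, F = 0.8),
             lesion_size = c(P = 0.8, R = 0.8, F = 0.8),
             metastasis_site = c(P = 0.8, R = 0.8, F = 0.8))
  w <- c(primary_site = 0.2, lesion_size = 0.3, metastasis_site = 0.5)
  expect_equal(weighted_prf(pc, w), c(P = 0.8, R = 0.8, F = 0.8))

  pc2 <- list(primary_site = c(P = 0.8, R = 0.8, F = 0.8),
              lesion_size = c(P = 0.6, R = 0.6, F = 0.6),
              metastasis_site = c(P = 0.4, R = 0.4, F = 0.4))
  expect_equal(unname(weighted_prf(pc2, w)["F"]), 0.54)
  expect_error(weighted_prf(pc2, c(primary_site = 0.2, lesion_size = 0.3,
                                   metastasis_site = 0.4)), "sum to 1")
})

test_that("evaluate_predictions aggregates counts across sentences", {
  s_gold <- tagged_sentence(letters[1:9],
                            spans_to_tags(span_df(1, 4, "b", 6, 7, "b"), 9))
  s_pred <- tagged_sentence(letters[1:9],
                            spans_to_tags(span_df(1, 4, "b", 5, 7, "b", 8, 9, "b"), 9))
  gold <- list(ner_document(list(s_gold), "d"))
  pred <- list(ner_document(list(s_pred), "d"))
  ev <- evaluate_predictions(gold, pred)
  expect_equal(unname(ev$micro), c(1 / 3, 1 / 2, 2 / 5))

  ev2 <- evaluate_predictions(gold, gold)
  expect_equal(unname(ev2$micro), c(1, 1, 1))

  s_none <- tagged_sentence(letters[1:9])
  ev3 <- evaluate_predictions(gold, list(ner_document(list(s_none), "d")))
  expect_equal(unname(ev3$micro), c(0, 0, 0))

  expect_error(evaluate_predictions(gold, list()), "counts differ")
  bad <- list(ner_document(list(tagged_sentence(letters[1:3])), "d"))
  expect_error(evaluate_predictions(gold, bad), "alignment")
})

test_that("stratify_by_frequency assigns by minimum training count", {
  ent <- function(surface, n_rep, prefix) {
    lapply(seq_len(n_rep), function(i) {
      tagged_sentence(c("x", surface, "y"), c("O", "S-b", "O"),
                      sprintf("%s%d", prefix, i))
    })
  }
  train <- list(ner_document(c(ent("aaa", 3, "a"), ent("bbb", 7, "b")), "tr"))
  test_doc <- list(ner_document(list(
    ent("aaa", 1, "t")[[1]],            # 3 occurrences -> low
    ent("bbb", 1, "u")[[1]],            # 7 occurrences -> high
    ent("ccc", 1, "v")[[1]],            # unseen -> unknown
    tagged_sentence(c("x", "y"))        # no entities -> excluded
  ), "te"))
  st <- stratify_by_frequency(train, test_doc)
  expect_equal(lengths(st), c(unknown = 1L, low = 1L, high = 1L))
  expect_equal(st$low[[1]]$tokens[2], "aaa")
  expect_equal(st$high[[1]]$tokens[2], "bbb")
  expect_equal(st$unknown[[1]]$tokens[2], "ccc")

  ## empty training corpus: everything entity-bearing is unknown
  st0 <- stratify_by_frequency(list(), test_doc)
  expect_equal(lengths(st0), c(unknown = 3L, low = 0L, high = 0L))

  ## exactly five occurrences goes to high, with a log note
  train5 <- list(ner_document(ent("ddd", 5, "d"), "tr"))
  expect_message(
    st5 <- stratify_by_frequency(train5, list(ner_document(ent("ddd", 1, "t"), "te"))),
    "exactly 5")
  expect_length(st5$high, 1L)
})

test_that("stratified subsets partition the entity-bearing test sentences", {
  cp <- generate_corpus(corpus_spec(n_sentences = 200, oov_entity_fraction = 0.3,
                                    frequency_skew = 1.4, seed = 77))
  st <- stratify_by_frequency(cp$train, cp$test)
  test_sents <- cwdner:::corpus_sentences(cp$test)
  n_entity_bearing <- sum(vapply(test_sents, function(s)
    nrow(tags_to_spans(s$tags)) > 0, logical(1)))
  expect_equal(sum(lengths(st)), n_entity_bearing)
  ids <- unlist(lapply(st, function(g) vapply(g, `[[`, character(1),
                                              "sentence_id")))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("inject_noise perturbs exactly the requested sentences, reproducibly", {
  cp <- generate_corpus(corpus_spec(n_sentences = 100, seed = 31))
  all_docs <- c(cp$train, cp$test)
  sents0 <- cwdner:::corpus_sentences(all_docs)

  same <- inject_noise(all_docs, 0, lexicon = cp$filler_vocab, seed = 2)
  expect_equal(attr(same, "n_modified"), 0L)
  expect_identical(cwdner:::corpus_sentences(same), sents0)

  for (mode in c("add", "delete", "modify", "mixed")) {
    noisy <- inject_noise(all_docs, 0.1, mode, cp$filler_vocab, seed = 3)
    sents1 <- cwdner:::corpus_sentences(noisy)
    ndiff <- sum(!mapply(function(a, b) identical(a$tokens, b$tokens),
                         sents0, sents1))
    expect_equal(ndiff, 10L)
    expect_equal(attr(noisy, "n_modified"), 10L)
    ## annotations survive: every noisy sentence is still tag-valid and its
    ## entity surfaces are unchanged
    for (i in seq_along(sents1)) {
      expect_true(is_valid_tag_sequence(sents1[[i]]$tags))
      expect_equal(cwdner:::sentence_entity_keys(sents1[[i]]),
                   cwdner:::sentence_entity_keys(sents0[[i]]))
    }
    noisy2 <- inject_noise(all_docs, 0.1, mode, cp$filler_vocab, seed = 3)
    expect_identical(noisy, noisy2)
  }
})
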