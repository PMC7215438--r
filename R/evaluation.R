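## Strict entity-level evaluation: a prediction counts only on exact
## (start, end, category) agreement; a partial overlap is both one false
## positive and one false negative. Plus weighted category scoring,
## frequency-stratified test subsets, and the sentence-noise protocol.

#' Count strict span matches
#'
#' @param gold,pred data.frames of spans (`start`, `end`, `category`), each
#'   internally non-overlapping.
#' @return list with `TP`, `FP`, `FN` and a per-category data.frame `by_category`.
#' @export
count_matches <- function(gold, pred) {
  key <- function(s) if (nrow(s) == 0) character(0) else
    paste(s$start, s$end, s$category, sep = "|")
  gk <- key(gold); pk <- key(pred)
  tp_keys <- intersect(gk, pk)
  cats <- sort(unique(c(gold$category, pred$category)))
  by_cat <- do.call(rbind, lapply(cats, function(ct) {
    g <- gk[gold$category == ct]; p <- pk[pred$category == ct]
    tp <- length(intersect(g, p))
    data.frame(category = ct, TP = tp, FP = length(p) - tp,
               FN = length(g) - tp, stringsAsFactors = FALSE)
  }))
  if (is.null(by_cat)) {
    by_cat <- data.frame(category = character(0), TP = integer(0),
                         FP = integer(0), FN = integer(0))
  }
  list(TP = length(tp_keys), FP = length(pk) - length(tp_keys),
       FN = length(gk) - length(tp_keys), by_category = by_cat)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`; a zero denominator
#' yields 0 by convention.
#'
#' @param counts list with `TP`, `FP`, `FN` (e.g. from [count_matches()]).
#' @return named numeric vector `c(P, R, F)`.
#' @export
prf <- function(counts) {
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  P <- safe_div(counts$TP, counts$TP + counts$FP)
  R <- safe_div(counts$TP, counts$TP + counts$FN)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F = F1)
}

#' Weighted category scoring
#'
#' Each of P, R, F is the weight-sum of the per-category values; the weights
#' must sum to 1 over the evaluated categories (the task's published weights
#' are primary site 0.2, lesion size 0.3, metastasis site 0.5).
#'
#' @param per_category named list mapping category to a `c(P, R, F)` vector.
#' @param weights named numeric vector of category weights summing to 1.
#' @return named numeric vector `c(P, R, F)`.
#' @export
weighted_prf <- function(per_category, weights) {
  cats <- names(weights)
  if (is.null(cats) || !all(cats %in% names(per_category))) {
    stop("weights must be named by evaluated categories")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("weights must sum to 1 (got %.10f)", sum(weights)))
  }
  out <- c(P = 0, R = 0, F = 0)
  for (ct in cats) {
    out <- out + weights[[ct]] * per_category[[ct]][c("P", "R", "F")]
  }
  out
}

#' Evaluate predicted documents against gold documents
#'
#' Aggregates strict span matches over all aligned sentences and reports
#' per-category, micro (pooled), and optionally weighted P/R/F.
#'
#' @param gold_docs,pred_docs aligned lists of [ner_document()] (same
#'   sentence counts and token sequences).
#' @param weights optional named category weight vector for [weighted_prf()].
#' @return list of class `eval_report` with `counts`, `per_category`, `micro`
#'   and (when weights are given) `weighted`.
#' @export
evaluate_predictions <- function(gold_docs, pred_docs, weights = NULL) {
  gs <- corpus_sentences(gold_docs); ps <- corpus_sentences(pred_docs)
  if (length(gs) != length(ps)) stop("sentence counts differ")
  TP <- 0L; FP <- 0L; FN <- 0L
  cat_counts <- list()
  for (i in seq_along(gs)) {
    if (length(gs[[i]]$tokens) != length(ps[[i]]$tokens)) {
      stop(sprintf("token alignment mismatch at sentence %d", i))
    }
    cm <- count_matches(tags_to_spans(gs[[i]]$tags), tags_to_spans(ps[[i]]$tags))
    TP <- TP + cm$TP; FP <- FP + cm$FP; FN <- FN + cm$FN
    for (r in seq_len(nrow(cm$by_category))) {
      ct <- cm$by_category$category[r]
      prev <- cat_counts[[ct]]
      if (is.null(prev)) prev <- c(TP = 0L, FP = 0L, FN = 0L)
      cat_counts[[ct]] <- prev + c(TP = cm$by_category$TP[r],
                                   FP = cm$by_category$FP[r],
                                   FN = cm$by_category$FN[r])
    }
  }
  per_category <- lapply(cat_counts, function(cc) {
    prf(list(TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]]))
  })
  out <- list(counts = list(TP = TP, FP = FP, FN = FN,
                            by_category = cat_counts),
              per_category = per_category,
              micro = prf(list(TP = TP, FP = FP, FN = FN)))
  if (!is.null(weights)) out$weighted <- weighted_prf(per_category, weights)
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: TP %d FP %d FN %d>\n",
              x$counts$TP, x$counts$FP, x$counts$FN))
  cat(sprintf("  micro    P %.4f R %.4f F %.4f\n",
              x$micro["P"], x$micro["R"], x$micro["F"]))
  for (ct in names(x$per_category)) {
    v <- x$per_category[[ct]]
    cat(sprintf("  %-8s P %.4f R %.4f F %.4f\n", ct, v["P"], v["R"], v["F"]))
  }
  if (!is.null(x$weighted)) {
    cat(sprintf("  weighted P %.4f R %.4f F %.4f\n",
                x$weighted["P"], x$weighted["R"], x$weighted["F"]))
  }
  invisible(x)
}

## entity surface (concatenated token surfaces) + category keys of a sentence
sentence_entity_keys <- function(sentence) {
  spans <- tags_to_spans(sentence$tags)
  if (nrow(spans) == 0) return(character(0))
  vapply(seq_len(nrow(spans)), function(r) {
    paste0(paste(sentence$tokens[spans$start[r]:(spans$end[r] - 1L)],
                 collapse = ""), "\r", spans$category[r])
  }, character(1))
}

#' Split a test corpus by training-set entity frequency
#'
#' Counts occurrences of each (entity surface, category) pair in the training
#' corpus. Each entity-bearing test sentence is assigned by the minimum count
#' among its entities: 0 -> `unknown`, 1-4 -> `low`, >= 5 -> `high` (entities
#' occurring exactly five times go to `high` and are flagged via `message()`).
#' Sentences without entities are excluded; the three subsets partition the
#' included sentences.
#'
#' @param train_docs,test_docs lists of [ner_document()], tag-valid.
#' @return list with sentence lists `unknown`, `low`, `high`.
#' @export
stratify_by_frequency <- function(train_docs, test_docs) {
  train_keys <- unlist(lapply(corpus_sentences(train_docs),
                              sentence_entity_keys))
  counts <- table(train_keys)
  unknown <- list(); low <- list(); high <- list()
  flagged5 <- 0L
  for (s in corpus_sentences(test_docs)) {
    keys <- sentence_entity_keys(s)
    if (length(keys) == 0) next
    kc <- vapply(keys, function(k) {
      if (k %in% names(counts)) as.integer(counts[[k]]) else 0L
    }, integer(1))
    m <- min(kc)
    if (m == 0L) unknown[[length(unknown) + 1L]] <- s
    else if (m < 5L) low[[length(low) + 1L]] <- s
    else {
      if (m == 5L) flagged5 <- flagged5 + 1L
      high[[length(high) + 1L]] <- s
    }
  }
  if (flagged5 > 0L) {
    message(sprintf(
      "stratify_by_frequency: %d sentence(s) with minimum count exactly 5 assigned to 'high'",
      flagged5))
  }
  list(unknown = unknown, low = low, high = high)
}

#' Inject sentence-level noise into a corpus
#'
#' Selects exactly `round(ratio * n_sentences)` sentences without replacement
#' and makes one word-level edit per selected sentence at an O-tagged token
#' position: `add` inserts a lexicon token tagged O, `delete` removes the
#' token, `modify` replaces its surface (with a token differing from the
#' original), `mixed` picks one of the three at random. Gold annotations stay
#' aligned and valid; the edit is deterministic under `seed`. A drawn sentence
#' with no editable O position is skipped (with a `message()`) and another is
#' drawn, so the requested count is preserved whenever enough editable
#' sentences exist.
#'
#' @param documents list of [ner_document()].
#' @param ratio fraction of sentences to perturb, in `[0, 1]`.
#' @param mode one of `"add"`, `"delete"`, `"modify"`, `"mixed"`.
#' @param lexicon character vector of replacement/insertion tokens.
#' @param seed integer seed.
#' @return documents with noisy sentences (attribute `"n_modified"`).
#' @export
inject_noise <- function(documents, ratio,
                         mode = c("mixed", "add", "delete", "modify"),
                         lexicon, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(ratio >= 0, ratio <= 1, length(lexicon) > 0)
  sents <- corpus_sentences(documents)
  ns <- length(sents)
  target <- round(ratio * ns)
  if (target == 0L) {
    attr(documents, "n_modified") <- 0L
    return(documents)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  ## per-sentence edit mode, fixed up front so redraws are fair
  modes <- if (mode == "mixed") {
    sample(c("add", "delete", "modify"), ns, replace = TRUE)
  } else rep(mode, ns)

  order_all <- sample.int(ns)   # redraw order
  chosen <- integer(0)
  for (i in order_all) {
    if (length(chosen) >= target) break
    s <- sents[[i]]
    md <- modes[i]
    o_pos <- which(s$tags == "O")
    if (md == "delete" && length(s$tokens) <= 1L) o_pos <- integer(0)
    if (length(o_pos) == 0L) {
      message(sprintf("inject_noise: sentence %d has no editable position; redrawing", i))
      next
    }
    pos <- if (length(o_pos) == 1L) o_pos else sample(o_pos, 1L)
    if (md == "add") {
      ## inserting next to an O token can never split an entity run
      tok <- sample(lexicon, 1L)
      s$tokens <- append(s$tokens, tok, after = pos)
      s$tags <- append(s$tags, "O", after = pos)
    } else if (md == "delete") {
      s$tokens <- s$tokens[-pos]; s$tags <- s$tags[-pos]
    } else {
      repl <- sample(lexicon, 1L)
      tries <- 0L
      while (repl == s$tokens[pos] && tries < 50L) {
        repl <- sample(lexicon, 1L); tries <- tries + 1L
      }
      if (repl == s$tokens[pos]) next  # lexicon cannot produce a change here
      s$tokens[pos] <- repl
    }
    sents[[i]] <- s
    chosen <- c(chosen, i)
  }
  if (length(chosen) < target) {
    message(sprintf("inject_noise: only %d of %d requested sentences were editable",
                    length(chosen), target))
  }

  ## write edited sentences back into the document structure
  k <- 0L
  out <- lapply(documents, function(doc) {
    doc$sentences <- lapply(doc$sentences, function(s) {
      k <<- k + 1L
      sents[[k]]
    })
    doc
  })
  attr(out, "n_modified") <- length(chosen)
  out
}
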