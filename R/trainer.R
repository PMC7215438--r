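## Training loop (Adam, mini-batches, gradient clipping, best-epoch selection
## by dev entity F1) and document-level prediction.

#' Training configuration
#'
#' Defaults follow the method's published hyperparameters: batch size 64,
#' learning rate 0.005, 10 epochs, dropout 0.5, Adam optimizer.
#'
#' @param batch_size sentences per parameter update.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training corpus.
#' @param seed integer seed controlling initialization, data order and dropout.
#' @param constraints_on apply the hard BIEOS transition mask during training
#'   and decoding.
#' @param clip_norm global gradient-norm clipping threshold.
#' @param encoder an [encoder_config()] (its `dropout` is the model's dropout).
#' @param verbose print one line per epoch.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 0.005, epochs = 10L,
                         seed = 42L, constraints_on = TRUE, clip_norm = 5,
                         encoder = encoder_config(), verbose = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), constraints_on = constraints_on,
                 clip_norm = clip_norm, encoder = encoder, verbose = verbose),
            class = "train_config")
}

flatten_params <- function(params) unlist(params, use.names = FALSE)
unflatten_params <- function(flat, skeleton) utils::relist(flat, skeleton)

corpus_tag_alphabet <- function(documents) {
  tags <- unique(unlist(lapply(corpus_sentences(documents), `[[`, "tags")))
  sort(unique(c(tags, "O")))
}

## Assemble an untrained model from corpora + dictionary + config.
build_model <- function(train_docs, dictionary, config) {
  sents <- corpus_sentences(train_docs)
  tag_alphabet <- corpus_tag_alphabet(train_docs)
  tokens <- unique(unlist(lapply(sents, `[[`, "tokens")))
  chars <- unique(unlist(strsplit(tokens, "")))
  char_items <- unique(c(chars, "<unk>"))
  word_items <- unique(c(tokens, "<unk>"))
  char_vocab <- stats::setNames(seq_along(char_items), char_items)
  word_vocab <- stats::setNames(seq_along(word_items), word_items)
  K <- length(tag_alphabet)
  n_dictfeat <- 7L * length(dictionary$categories)
  enc <- config$encoder
  params <- init_encoder_params(enc, length(char_items), length(word_items),
                                n_dictfeat, K)
  structure(list(
    schema_version = 1L,
    config = c(enc, list(constraints_on = config$constraints_on)),
    params = params,
    char_vocab = char_vocab, char_unk = unname(char_vocab[["<unk>"]]),
    word_vocab = word_vocab, word_unk = unname(word_vocab[["<unk>"]]),
    tag_alphabet = tag_alphabet,
    categories = dictionary$categories,
    dict_fp = dict_fingerprint(dictionary),
    constraint_mask = build_constraint_mask(tag_alphabet)
  ), class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model: %d tags, %d words, %d chars, %s mode%s>\n",
              length(x$tag_alphabet), length(x$word_vocab),
              length(x$char_vocab), x$config$fusion_mode,
              if (isTRUE(x$config$constraints_on)) ", constrained" else ""))
  invisible(x)
}

#' Train the character-word-dictionary Bi-LSTM-CRF tagger
#'
#' Minimizes the mean CRF negative log-likelihood per sentence with Adam,
#' mini-batches bucketed by sentence length, global-norm gradient clipping,
#' and best-epoch selection by micro entity-level F1 on the dev corpus.
#' Identical seeds and inputs give identical reports.
#'
#' @param train_docs,dev_docs lists of [ner_document()] (tag-valid).
#' @param dictionary a [domain_dictionary()] driving the gazetteer features.
#' @param config a [train_config()].
#' @return list with `model` (class `ner_model`, parameters of the best epoch)
#'   and `report` (per-epoch `loss`, `dev_f1`, and `best_epoch`).
#' @export
train_tagger <- function(train_docs, dev_docs, dictionary,
                         config = train_config()) {
  stopifnot(length(train_docs) > 0)
  train_alpha <- corpus_tag_alphabet(train_docs)
  dev_tags <- unique(unlist(lapply(corpus_sentences(dev_docs), `[[`, "tags")))
  missing <- setdiff(dev_tags, train_alpha)
  if (length(missing) > 0) {
    stop(sprintf("dev corpus has tags absent from training alphabet: %s",
                 paste(missing, collapse = ", ")))
  }

  set.seed(config$seed)
  model <- build_model(train_docs, dictionary, config)
  sents <- corpus_sentences(train_docs)
  dfeats <- lapply(sents, dict_features, dictionary = dictionary)
  y_idx <- lapply(sents, function(s) match(s$tags, model$tag_alphabet))

  if (config$epochs == 0L) {
    return(list(model = model,
                report = list(loss = numeric(0), dev_f1 = numeric(0),
                              best_epoch = NA_integer_)))
  }

  skeleton <- model$params
  theta <- flatten_params(skeleton)
  m_adam <- numeric(length(theta)); v_adam <- numeric(length(theta))
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  loss_hist <- numeric(0); f1_hist <- numeric(0)
  best_f1 <- -Inf; best_theta <- theta; best_epoch <- NA_integer_

  ns <- length(sents)
  for (epoch in seq_len(config$epochs)) {
    ## length-bucketed batches in shuffled order
    perm <- sample.int(ns)
    perm <- perm[order(vapply(sents[perm], function(s) length(s$tokens),
                              integer(1)))]
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    batches <- batches[sample.int(length(batches))]

    epoch_loss <- 0
    for (batch in batches) {
      model$params <- unflatten_params(theta, skeleton)
      gacc <- numeric(length(theta))
      bloss <- 0
      for (si in batch) {
        sg <- sentence_loss_grad(model, sents[[si]], dfeats[[si]],
                                 y_idx[[si]], train_mode = TRUE)
        bloss <- bloss + sg$loss
        gacc <- gacc + flatten_params(sg$grads)
      }
      gacc <- gacc / length(batch)
      epoch_loss <- epoch_loss + bloss
      gn <- sqrt(sum(gacc^2))
      if (is.finite(gn) && gn > config$clip_norm) {
        gacc <- gacc * (config$clip_norm / gn)
      }
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * gacc
      v_adam <- b2 * v_adam + (1 - b2) * gacc^2
      mhat <- m_adam / (1 - b1^step)
      vhat <- v_adam / (1 - b2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    loss_hist <- c(loss_hist, epoch_loss / ns)

    model$params <- unflatten_params(theta, skeleton)
    f1 <- if (length(dev_docs) > 0) {
      pred <- predict_tags(model, dev_docs, dictionary)
      evaluate_predictions(dev_docs, pred)$micro["F"]
    } else NA_real_
    f1_hist <- c(f1_hist, unname(f1))
    if (!is.na(f1) && f1 > best_f1) {
      best_f1 <- f1; best_theta <- theta; best_epoch <- epoch
    }
    if (isTRUE(config$verbose)) {
      message(sprintf("epoch %d: loss %.4f dev F1 %.4f", epoch,
                      loss_hist[epoch], f1_hist[epoch]))
    }
  }

  if (is.na(best_epoch)) { best_theta <- theta; best_epoch <- config$epochs }
  model$params <- unflatten_params(best_theta, skeleton)
  list(model = model,
       report = list(loss = loss_hist, dev_f1 = f1_hist,
                     best_epoch = best_epoch))
}

#' Predict tags for documents
#'
#' Viterbi decoding of every sentence. With transition constraints on, the
#' decoded sequences are structurally valid by construction; with constraints
#' off, [validate_and_repair()] is applied and the total repair count is
#' attached as attribute `"repairs"`. Inference is deterministic.
#'
#' @param model a trained `ner_model`.
#' @param documents list of [ner_document()] (tags ignored).
#' @param dictionary the [domain_dictionary()]; a fingerprint mismatch with
#'   the model's training dictionary triggers a warning.
#' @return list of documents with predicted tags.
#' @export
predict_tags <- function(model, documents, dictionary) {
  stopifnot(inherits(model, "ner_model"))
  if (!identical(model$dict_fp, dict_fingerprint(dictionary))) {
    warning("dictionary fingerprint differs from the one used in training")
  }
  A <- model$params$trans
  if (isTRUE(model$config$constraints_on)) {
    A <- apply_constraint_mask(A, model$constraint_mask)
  }
  total_repairs <- 0L
  out <- lapply(documents, function(doc) {
    doc$sentences <- lapply(doc$sentences, function(s) {
      dfeat <- dict_features(s, dictionary)
      emis <- encoder_forward(model, s, dfeat)$emissions
      path <- viterbi_decode(emis, A)$path
      tags <- model$tag_alphabet[path]
      if (!isTRUE(model$config$constraints_on)) {
        rep <- validate_and_repair(tags)
        tags <- rep$tags
        total_repairs <<- total_repairs + rep$repairs
      }
      s$tags <- tags
      s
    })
    doc
  })
  if (total_repairs > 0L) attr(out, "repairs") <- total_repairs
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all parameter groups,
#' vocabulary tables, tag alphabet, dictionary fingerprint and configuration,
#' under a versioned schema.
#'
#' @param model a `ner_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ner_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ner_model") || !identical(model$schema_version, 1L)) {
    stop("not a recognized model checkpoint (schema version mismatch)")
  }
  model
}

#' Load pretrained word embeddings
#'
#' Reads the standard whitespace-separated text format (`word v1 v2 ...`, one
#' word per line) and overwrites the rows of the model's word embedding table
#' for words present in its vocabulary.
#'
#' @param model a `ner_model`.
#' @param path embedding file path.
#' @return the model with updated word embeddings; attribute `"n_loaded"`
#'   counts the vocabulary words found in the file.
#' @export
load_pretrained_embeddings <- function(model, path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_loaded <- 0L
  for (line in lines) {
    fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
    w <- fields[1L]
    if (!w %in% names(model$word_vocab)) next
    vec <- as.numeric(fields[-1L])
    if (length(vec) != ncol(model$params$word_emb)) {
      stop(sprintf("embedding dimension %d does not match model word_dim %d",
                   length(vec), ncol(model$params$word_emb)))
    }
    model$params$word_emb[model$word_vocab[[w]], ] <- vec
    n_loaded <- n_loaded + 1L
  }
  attr(model, "n_loaded") <- n_loaded
  model
}
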