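# Independent brute-force / scalar-arithmetic oracles used to pin down the
# CRF, the neural primitives and the gazetteer features.

# all K^n tag paths as a matrix (rows = paths)
enumerate_paths <- function(K, n) {
  as.matrix(expand.grid(rep(list(seq_len(K)), n)))
}

# log sum over all paths of exp(path score), by direct enumeration
enum_log_partition <- function(P, A) {
  paths <- enumerate_paths(ncol(P), nrow(P))
  s <- apply(paths, 1L, function(y) sequence_score(P, A, as.integer(y)))
  m <- max(s)
  m + log(sum(exp(s - m)))
}

# argmax path by enumeration (first = lowest-index order of expand.grid)
enum_viterbi <- function(P, A) {
  paths <- enumerate_paths(ncol(P), nrow(P))
  s <- apply(paths, 1L, function(y) sequence_score(P, A, as.integer(y)))
  list(path = as.integer(paths[which.max(s), ]), score = max(s))
}

# literal per-element LSTM equations on plain numbers
scalar_lstm_oracle <- function(e, h, c, W_f, W_i, W_c, W_o,
                               U_f, U_i, U_c, U_o, b_f, b_i, b_c, b_o) {
  sig <- function(x) 1 / (1 + exp(-x))
  f <- sig(W_f %*% e + U_f %*% h + b_f)
  i <- sig(W_i %*% e + U_i %*% h + b_i)
  g <- tanh(W_c %*% e + U_c %*% h + b_c)
  o <- sig(W_o %*% e + U_o %*% h + b_o)
  ct <- f * c + i * g
  list(h = as.numeric(o * tanh(ct)), c = as.numeric(ct))
}

# literal highway equations
scalar_highway_oracle <- function(w_char, w_word, W_t, W_k, b_t, b_k) {
  sig <- function(x) 1 / (1 + exp(-x))
  x <- c(w_char, w_word)
  t <- sig(as.numeric(W_t %*% x) + b_t)
  as.numeric(t * tanh(as.numeric(W_k %*% x) + b_k) + (1 - t) * x)
}

# brute-force gazetteer features: every (position, template, category) triple
brute_dict_features <- function(tokens, dictionary) {
  cats <- dictionary$categories
  n <- length(tokens)
  m <- matrix(0, n, 7L * length(cats))
  offsets <- list(c(0, 0), c(-1, 0), c(0, 1), c(-2, 0), c(0, 2), c(-3, 0),
                  c(0, 3))
  for (t in seq_len(n)) for (ci in seq_along(cats)) for (k in 1:7) {
    lo <- t + offsets[[k]][1]; hi <- t + offsets[[k]][2]
    if (lo >= 1 && hi <= n) {
      seg <- paste(tokens[lo:hi], collapse = "")
      if (seg %in% dictionary$entries[[cats[ci]]]) {
        m[t, 7L * (ci - 1L) + k] <- 1
      }
    }
  }
  m
}

# all non-overlapping span sets over a sentence of the given length, with
# span length capped; categories cycled from `cats`
enumerate_span_sets <- function(len, max_span = 3L, cats = c("b", "t")) {
  spans <- list()
  for (s in seq_len(len)) for (e in (s + 1):(len + 1)) {
    if (e - s <= max_span && e <= len + 1) {
      spans[[length(spans) + 1L]] <- c(s, e)
    }
  }
  sets <- list(list())
  for (sp in spans) {
    for (idx in seq_along(sets)) {
      cur <- sets[[idx]]
      ok <- all(vapply(cur, function(q) sp[2] <= q[1] || sp[1] >= q[2],
                       logical(1)))
      if (ok) sets[[length(sets) + 1L]] <- c(cur, list(sp))
    }
  }
  lapply(sets, function(cur) {
    if (length(cur) == 0) {
      return(data.frame(start = integer(0), end = integer(0),
                        category = character(0)))
    }
    cur <- cur[order(vapply(cur, `[`, integer(1), 1))]
    data.frame(start = vapply(cur, `[`, integer(1), 1),
               end = vapply(cur, `[`, integer(1), 2),
               category = cats[(seq_along(cur) - 1L) %% length(cats) + 1L],
               stringsAsFactors = FALSE)
  })
}

random_tagged_sentence <- function(n_tokens, vocab = letters) {
  tagged_sentence(vapply(seq_len(n_tokens), function(i)
    paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = ""),
    character(1)))
}
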