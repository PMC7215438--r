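## Sentence encoder: character Bi-LSTM -> highway fusion with word embeddings,
## dictionary-feature projection + Bi-LSTM, context Bi-LSTM, linear projection
## to per-tag emission scores. Two wirings:
##   fused  — w_i = highway(char, word); e_i = w_i (+) d_i -> one context Bi-LSTM
##   triple — three independent Bi-LSTMs over the char, word and dictionary
##            streams; hidden states concatenated before the linear layer.

#' Encoder configuration
#'
#' Defaults follow the method's published hyperparameters (word embedding 200,
#' dictionary feature vector 100, hidden layer 300, dropout 0.5); character
#' dimensions are free choices since the source leaves them unstated.
#'
#' @param word_dim word embedding dimension.
#' @param char_dim character embedding dimension.
#' @param char_hidden per-direction hidden size of the character Bi-LSTM.
#' @param dict_dim dictionary feature vector dimension (output of the
#'   dictionary Bi-LSTM; must be even).
#' @param hidden_dim per-direction hidden size of the context Bi-LSTM.
#' @param dropout dropout rate in `[0, 1)` applied at training time to the
#'   concatenated input and the context hidden states.
#' @param fusion_mode `"fused"` (highway combination, the default) or
#'   `"triple"` (three independent Bi-LSTMs).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(word_dim = 200L, char_dim = 50L, char_hidden = 25L,
                           dict_dim = 100L, hidden_dim = 300L, dropout = 0.5,
                           fusion_mode = c("fused", "triple")) {
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(word_dim > 0, char_dim > 0, char_hidden > 0, dict_dim > 0,
            hidden_dim > 0, dropout >= 0, dropout < 1, dict_dim %% 2 == 0)
  structure(list(word_dim = as.integer(word_dim),
                 char_dim = as.integer(char_dim),
                 char_hidden = as.integer(char_hidden),
                 dict_dim = as.integer(dict_dim),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, fusion_mode = fusion_mode),
            class = "encoder_config")
}

#' Construct an embedding table
#'
#' @param items character vector of vocabulary items (the unknown marker
#'   `"<unk>"` is appended if absent).
#' @param dim embedding dimension.
#' @param scale half-width of the uniform initialization.
#' @return list with `vocab` (named index vector), `vectors`
#'   (`|V| x dim` matrix) and `unk` (index of the unknown item).
#' @export
embedding_table <- function(items, dim, scale = 0.1) {
  items <- unique(c(items, "<unk>"))
  vocab <- stats::setNames(seq_along(items), items)
  list(vocab = vocab,
       vectors = init_embedding(length(items), dim, scale),
       unk = unname(vocab[["<unk>"]]))
}

lookup_indices <- function(vocab, unk, keys) {
  idx <- unname(vocab[keys])
  idx[is.na(idx)] <- unk
  idx
}

#' Character-level encoding of one token
#'
#' Runs a Bi-LSTM over the token's character sequence (unknown characters map
#' to the table's unk index) and returns the concatenation of the forward
#' pass's final hidden state and the backward pass's final hidden state.
#'
#' @param token token surface string (non-empty).
#' @param char_table an [embedding_table()] over characters.
#' @param char_fwd,char_bwd character LSTM parameter sets.
#' @return numeric vector of length `2 * char_hidden`.
#' @export
char_encode <- function(token, char_table, char_fwd, char_bwd) {
  stopifnot(nzchar(token))
  chars <- strsplit(token, "")[[1L]]
  idx <- lookup_indices(char_table$vocab, char_table$unk, chars)
  X <- char_table$vectors[idx, , drop = FALSE]
  m <- nrow(X)
  ff <- lstm_forward(X, char_fwd)
  fb <- lstm_forward(X[m:1, , drop = FALSE], char_bwd)
  c(ff$H[m, ], fb$H[m, ])
}

## ---- full model construction ------------------------------------------------

init_encoder_params <- function(config, n_chars, n_words, n_dictfeat, K,
                                scale = 0.1) {
  ch <- config$char_hidden
  D <- 2L * ch + config$word_dim          # highway / fused word-vector dim
  dhd <- config$dict_dim %/% 2L           # dictionary Bi-LSTM per-direction
  dp <- config$dict_dim                   # dictionary projection dim
  hid <- config$hidden_dim
  p <- list(
    char_emb = init_embedding(n_chars, config$char_dim, scale),
    word_emb = init_embedding(n_words, config$word_dim, scale),
    char_f = init_lstm(config$char_dim, ch),
    char_b = init_lstm(config$char_dim, ch),
    dict_proj = init_linear(n_dictfeat, dp)
  )
  if (config$fusion_mode == "fused") {
    p$hw <- init_highway(D, scale)
    p$dict_f <- init_lstm(dp, dhd)
    p$dict_b <- init_lstm(dp, dhd)
    p$ctx_f <- init_lstm(D + 2L * dhd, hid)
    p$ctx_b <- init_lstm(D + 2L * dhd, hid)
    p$out <- init_linear(2L * hid, K)
  } else {
    p$s1_f <- init_lstm(2L * ch, hid)
    p$s1_b <- init_lstm(2L * ch, hid)
    p$s2_f <- init_lstm(config$word_dim, hid)
    p$s2_b <- init_lstm(config$word_dim, hid)
    p$s3_f <- init_lstm(dp, hid)
    p$s3_b <- init_lstm(dp, hid)
    p$out <- init_linear(6L * hid, K)
  }
  p$trans <- matrix(stats::runif((K + 2L) * (K + 2L), -scale, scale),
                    K + 2L, K + 2L)
  p
}

drop_mask <- function(nr, nc, rate) {
  keep <- 1 - rate
  matrix((stats::runif(nr * nc) < keep) / keep, nr, nc)
}

## Forward pass over one sentence. Returns emissions (n x K) and, when
## want_cache, everything needed for the analytic backward pass.
encoder_forward <- function(model, sentence, dfeat, train_mode = FALSE,
                            want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  tokens <- sentence$tokens
  n <- length(tokens)
  stopifnot(nrow(dfeat) == n)
  rate <- if (train_mode) cfg$dropout else 0

  ## character stream
  ch <- cfg$char_hidden
  char_caches <- vector("list", n)
  CharReps <- matrix(0, n, 2L * ch)
  for (t in seq_len(n)) {
    chars <- strsplit(tokens[t], "")[[1L]]
    idx <- lookup_indices(model$char_vocab, model$char_unk, chars)
    X <- p$char_emb[idx, , drop = FALSE]
    m <- length(idx)
    ff <- lstm_forward(X, p$char_f)
    fb <- lstm_forward(X[m:1, , drop = FALSE], p$char_b)
    CharReps[t, ] <- c(ff$H[m, ], fb$H[m, ])
    if (want_cache) char_caches[[t]] <- list(idx = idx, m = m,
                                             fwd = ff$cache, bwd = fb$cache)
  }

  ## word stream
  widx <- lookup_indices(model$word_vocab, model$word_unk, tokens)
  Xw <- p$word_emb[widx, , drop = FALSE]

  ## dictionary stream: linear projection of the binary features
  Dproj <- dfeat %*% p$dict_proj$W +
    matrix(p$dict_proj$b, n, length(p$dict_proj$b), byrow = TRUE)

  if (cfg$fusion_mode == "fused") {
    hwf <- highway_forward(cbind(CharReps, Xw), p$hw)
    dict_bi <- bilstm_forward(Dproj, p$dict_f, p$dict_b)
    E <- cbind(hwf$Y, dict_bi$H)
    mask_e <- if (rate > 0) drop_mask(n, ncol(E), rate) else NULL
    if (!is.null(mask_e)) E <- E * mask_e
    ctx <- bilstm_forward(E, p$ctx_f, p$ctx_b)
    H <- ctx$H
    mask_h <- if (rate > 0) drop_mask(n, ncol(H), rate) else NULL
    if (!is.null(mask_h)) H <- H * mask_h
    emis <- H %*% p$out$W + matrix(p$out$b, n, ncol(p$out$W), byrow = TRUE)
    cache <- if (want_cache) {
      list(char_caches = char_caches, widx = widx, dfeat = dfeat,
           hw = hwf$cache, dict_bi = dict_bi$cache, ctx = ctx$cache,
           E = E, H = H, mask_e = mask_e, mask_h = mask_h, n = n)
    }
  } else {
    mask_1 <- if (rate > 0) drop_mask(n, ncol(CharReps), rate) else NULL
    mask_2 <- if (rate > 0) drop_mask(n, ncol(Xw), rate) else NULL
    mask_3 <- if (rate > 0) drop_mask(n, ncol(Dproj), rate) else NULL
    X1 <- if (is.null(mask_1)) CharReps else CharReps * mask_1
    X2 <- if (is.null(mask_2)) Xw else Xw * mask_2
    X3 <- if (is.null(mask_3)) Dproj else Dproj * mask_3
    s1 <- bilstm_forward(X1, p$s1_f, p$s1_b)
    s2 <- bilstm_forward(X2, p$s2_f, p$s2_b)
    s3 <- bilstm_forward(X3, p$s3_f, p$s3_b)
    H <- cbind(s1$H, s2$H, s3$H)
    mask_h <- if (rate > 0) drop_mask(n, ncol(H), rate) else NULL
    if (!is.null(mask_h)) H <- H * mask_h
    emis <- H %*% p$out$W + matrix(p$out$b, n, ncol(p$out$W), byrow = TRUE)
    cache <- if (want_cache) {
      list(char_caches = char_caches, widx = widx, dfeat = dfeat,
           s1 = s1$cache, s2 = s2$cache, s3 = s3$cache, H = H,
           mask_1 = mask_1, mask_2 = mask_2, mask_3 = mask_3,
           mask_h = mask_h, n = n)
    }
  }
  list(emissions = emis, cache = cache)
}

## zero-filled gradient skeleton congruent with params
zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else numeric(length(x))
}

## Backward pass: gradient of the scalar loss w.r.t. every encoder parameter
## given dEmis (n x K). Returns a list congruent with model$params (the
## `trans` entry is left zero; the CRF supplies it).
encoder_backward <- function(model, cache, dEmis) {
  cfg <- model$config
  p <- model$params
  g <- zero_like(p)
  n <- cache$n
  H <- cache$H

  g$out$W <- t(H) %*% dEmis
  g$out$b <- colSums(dEmis)
  dH <- dEmis %*% t(p$out$W)

  if (cfg$fusion_mode == "fused") {
    if (!is.null(cache$mask_h)) dH <- dH * cache$mask_h
    bctx <- bilstm_backward(p$ctx_f, p$ctx_b, cache$ctx, dH)
    g$ctx_f <- bctx$fwd; g$ctx_b <- bctx$bwd
    dE <- bctx$dX
    if (!is.null(cache$mask_e)) dE <- dE * cache$mask_e
    Dhw <- ncol(cache$hw$X)
    dY_hw <- dE[, 1:Dhw, drop = FALSE]
    dDh <- dE[, (Dhw + 1):ncol(dE), drop = FALSE]
    ## dictionary Bi-LSTM
    bdict <- bilstm_backward(p$dict_f, p$dict_b, cache$dict_bi, dDh)
    g$dict_f <- bdict$fwd; g$dict_b <- bdict$bwd
    dDproj <- bdict$dX
    ## highway
    bhw <- highway_backward(p$hw, cache$hw, dY_hw)
    g$hw$W_t <- bhw$dW_t; g$hw$W_k <- bhw$dW_k
    g$hw$b_t <- bhw$db_t; g$hw$b_k <- bhw$db_k
    nch <- 2L * cfg$char_hidden
    dCharReps <- bhw$dX[, 1:nch, drop = FALSE]
    dXw <- bhw$dX[, (nch + 1):ncol(bhw$dX), drop = FALSE]
  } else {
    if (!is.null(cache$mask_h)) dH <- dH * cache$mask_h
    hid2 <- 2L * cfg$hidden_dim
    b1 <- bilstm_backward(p$s1_f, p$s1_b, cache$s1,
                          dH[, 1:hid2, drop = FALSE])
    b2 <- bilstm_backward(p$s2_f, p$s2_b, cache$s2,
                          dH[, (hid2 + 1):(2 * hid2), drop = FALSE])
    b3 <- bilstm_backward(p$s3_f, p$s3_b, cache$s3,
                          dH[, (2 * hid2 + 1):(3 * hid2), drop = FALSE])
    g$s1_f <- b1$fwd; g$s1_b <- b1$bwd
    g$s2_f <- b2$fwd; g$s2_b <- b2$bwd
    g$s3_f <- b3$fwd; g$s3_b <- b3$bwd
    dCharReps <- b1$dX; dXw <- b2$dX; dDproj <- b3$dX
    if (!is.null(cache$mask_1)) dCharReps <- dCharReps * cache$mask_1
    if (!is.null(cache$mask_2)) dXw <- dXw * cache$mask_2
    if (!is.null(cache$mask_3)) dDproj <- dDproj * cache$mask_3
  }

  ## rename lstm gradient fields (dW/dU/db -> W/U/b) for congruence
  fix <- function(gl) list(W = gl$dW, U = gl$dU, b = gl$db)
  for (nm in names(g)) {
    if (is.list(g[[nm]]) && !is.null(g[[nm]]$dW)) g[[nm]] <- fix(g[[nm]])
  }

  ## dictionary projection
  g$dict_proj$W <- t(cache$dfeat) %*% dDproj
  g$dict_proj$b <- colSums(dDproj)

  ## word embeddings (sparse row accumulation)
  for (t in seq_len(n)) {
    w <- cache$widx[t]
    g$word_emb[w, ] <- g$word_emb[w, ] + dXw[t, ]
  }

  ## character stream
  ch <- cfg$char_hidden
  acc_cf <- zero_like(p$char_f); acc_cb <- zero_like(p$char_b)
  for (t in seq_len(n)) {
    cc <- cache$char_caches[[t]]
    m <- cc$m
    dHf <- matrix(0, m, ch); dHb <- matrix(0, m, ch)
    dHf[m, ] <- dCharReps[t, 1:ch]
    dHb[m, ] <- dCharReps[t, (ch + 1):(2 * ch)]
    bf <- lstm_backward(p$char_f, cc$fwd, dHf)
    bb <- lstm_backward(p$char_b, cc$bwd, dHb)
    acc_cf$W <- acc_cf$W + bf$dW; acc_cf$U <- acc_cf$U + bf$dU
    acc_cf$b <- acc_cf$b + bf$db
    acc_cb$W <- acc_cb$W + bb$dW; acc_cb$U <- acc_cb$U + bb$dU
    acc_cb$b <- acc_cb$b + bb$db
    dX <- bf$dX + bb$dX[m:1, , drop = FALSE]
    for (k in seq_len(m)) {
      ci <- cc$idx[k]
      g$char_emb[ci, ] <- g$char_emb[ci, ] + dX[k, ]
    }
  }
  g$char_f <- acc_cf; g$char_b <- acc_cb
  g
}

#' Encode a sentence into emission scores
#'
#' Maps a sentence plus its dictionary features through the configured
#' encoder to an `n x K` emission score matrix (the CRF's input). Inference
#' (`train_mode = FALSE`) is deterministic; dropout applies only in training
#' mode.
#'
#' @param sentence a [tagged_sentence()].
#' @param dict_feats matrix from [dict_features()] with one row per token.
#' @param model a model as returned by [train_tagger()].
#' @param train_mode apply dropout.
#' @return `n x K` emission matrix with tag alphabet as column names.
#' @export
encode_sentence <- function(sentence, dict_feats, model, train_mode = FALSE) {
  if (nrow(dict_feats) != length(sentence$tokens)) {
    stop("dict_feats rows must equal sentence length")
  }
  emis <- encoder_forward(model, sentence, dict_feats,
                          train_mode = train_mode)$emissions
  colnames(emis) <- model$tag_alphabet
  emis
}

## Loss (CRF negative log-likelihood) and full gradient for one sentence.
sentence_loss_grad <- function(model, sentence, dfeat, y_idx,
                               train_mode = FALSE) {
  fw <- encoder_forward(model, sentence, dfeat, train_mode = train_mode,
                        want_cache = TRUE)
  A <- model$params$trans
  if (isTRUE(model$config$constraints_on)) {
    A <- apply_constraint_mask(A, model$constraint_mask)
  }
  cg <- crf_loss_grad(fw$emissions, A, y_idx)
  g <- encoder_backward(model, fw$cache, cg$dP)
  g$trans <- cg$dA
  list(loss = cg$loss, grads = g)
}

sentence_loss <- function(model, sentence, dfeat, y_idx) {
  fw <- encoder_forward(model, sentence, dfeat, train_mode = FALSE)
  A <- model$params$trans
  if (isTRUE(model$config$constraints_on)) {
    A <- apply_constraint_mask(A, model$constraint_mask)
  }
  -log_likelihood(fw$emissions, A, y_idx)
}
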