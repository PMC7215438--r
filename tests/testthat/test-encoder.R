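tiny_lstm <- function(d_in, d_h, seed = 1) {
  set.seed(seed)
  lstm_params(W_f = matrix(stats::rnorm(d_h * d_in), d_h, d_in),
              W_i = matrix(stats::rnorm(d_h * d_in), d_h, d_in),
              W_c = matrix(stats::rnorm(d_h * d_in), d_h, d_in),
              W_o = matrix(stats::rnorm(d_h * d_in), d_h, d_in),
              U_f = matrix(stats::rnorm(d_h * d_h), d_h, d_h),
              U_i = matrix(stats::rnorm(d_h * d_h), d_h, d_h),
              U_c = matrix(stats::rnorm(d_h * d_h), d_h, d_h),
              U_o = matrix(stats::rnorm(d_h * d_h), d_h, d_h),
              b_f = stats::rnorm(d_h), b_i = stats::rnorm(d_h),
              b_c = stats::rnorm(d_h), b_o = stats::rnorm(d_h))
}

zero_lstm <- function(d_in, d_h) {
  list(W = matrix(0, 4 * d_h, d_in), U = matrix(0, 4 * d_h, d_h),
       b = rep(0, 4 * d_h))
}

test_that("lstm_step matches the gate equations", {
  ## zero everything: tanh kills both the candidate and the output
  z <- zero_lstm(2, 3)
  out <- lstm_step(c(0, 0), rep(0, 3), rep(0, 3), z)
  expect_equal(out$h, rep(0, 3))
  expect_equal(out$c, rep(0, 3))

  ## saturated gates carry the cell: f ~ 1, i ~ 0
  p <- zero_lstm(1, 1)
  p$b <- c(20, -20, 0, 0)   # f, i, c, o biases
  out <- lstm_step(0.3, 0.1, 0.8, p)
  expect_equal(out$c, 0.8, tolerance = 1e-6)

  ## random 1-3 dim parameters against the scalar-arithmetic oracle
  set.seed(10)
  for (i in 1:20) {
    d_in <- sample(1:3, 1); d_h <- sample(1:3, 1)
    M <- function() matrix(stats::rnorm(d_h * d_in), d_h, d_in)
    U <- function() matrix(stats::rnorm(d_h * d_h), d_h, d_h)
    v <- function() stats::rnorm(d_h)
    W_f <- M(); W_i <- M(); W_c <- M(); W_o <- M()
    U_f <- U(); U_i <- U(); U_c <- U(); U_o <- U()
    b_f <- v(); b_i <- v(); b_c <- v(); b_o <- v()
    e <- stats::rnorm(d_in); h <- v(); cc <- v()
    got <- lstm_step(e, h, cc,
                     lstm_params(W_f, W_i, W_c, W_o, U_f, U_i, U_c, U_o,
                                 b_f, b_i, b_c, b_o))
    want <- scalar_lstm_oracle(e, h, cc, W_f, W_i, W_c, W_o,
                               U_f, U_i, U_c, U_o, b_f, b_i, b_c, b_o)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
  expect_error(lstm_step(c(1, 2, 3), 0, 0, zero_lstm(2, 1)), "dimension")
})

test_that("highway_combine gates between transform and carry paths", {
  set.seed(11)
  W <- matrix(stats::rnorm(16), 4, 4)
  x_char <- stats::rnorm(2); x_word <- stats::rnorm(2)
  closed <- list(W_t = matrix(0, 4, 4), b_t = rep(-30, 4), W_k = W,
                 b_k = rep(0, 4))
  expect_equal(highway_combine(x_char, x_word, closed), c(x_char, x_word),
               tolerance = 1e-10)
  open <- list(W_t = matrix(0, 4, 4), b_t = rep(30, 4), W_k = W,
               b_k = rep(0.2, 4))
  expect_equal(highway_combine(x_char, x_word, open),
               tanh(as.numeric(W %*% c(x_char, x_word)) + 0.2),
               tolerance = 1e-10)

  for (i in 1:20) {
    d <- sample(1:3, 1)
    W_t <- matrix(stats::rnorm(4 * d * d), 2 * d, 2 * d)
    W_k <- matrix(stats::rnorm(4 * d * d), 2 * d, 2 * d)
    b_t <- stats::rnorm(2 * d); b_k <- stats::rnorm(2 * d)
    wc <- stats::rnorm(d); ww <- stats::rnorm(d)
    expect_equal(highway_combine(wc, ww, list(W_t = W_t, W_k = W_k,
                                              b_t = b_t, b_k = b_k)),
                 scalar_highway_oracle(wc, ww, W_t, W_k, b_t, b_k),
                 tolerance = 1e-10)
  }
})

test_that("bilstm concatenates directional passes with the right symmetry", {
  set.seed(12)
  fwd <- tiny_lstm(2, 3, seed = 21); bwd <- tiny_lstm(2, 3, seed = 22)
  x <- matrix(stats::rnorm(2), 1, 2)
  h <- bilstm(x, fwd, bwd)
  expect_equal(dim(h), c(1L, 6L))
  ## single input from zero state: both halves are one lstm_step
  sf <- lstm_step(x[1, ], rep(0, 3), rep(0, 3), fwd)
  sb <- lstm_step(x[1, ], rep(0, 3), rep(0, 3), bwd)
  expect_equal(h[1, ], c(sf$h, sb$h))

  ## reversing inputs and swapping directions reverses and swaps the output
  X <- matrix(stats::rnorm(10), 5, 2)
  H <- bilstm(X, fwd, bwd)
  Hr <- bilstm(X[5:1, , drop = FALSE], bwd, fwd)
  expect_equal(Hr[5:1, c(4:6, 1:3)], H, ignore_attr = TRUE)

  expect_equal(bilstm(X, zero_lstm(2, 3), zero_lstm(2, 3)),
               matrix(0, 5, 6))
  expect_error(bilstm(X[0, , drop = FALSE], fwd, bwd), "empty")
})

test_that("char_encode returns final bidirectional states over characters", {
  set.seed(13)
  tab <- embedding_table(c("a", "b", "c"), dim = 2)
  fwd <- tiny_lstm(2, 2, seed = 31); bwd <- tiny_lstm(2, 2, seed = 32)
  ## single character token = one bilstm position
  h1 <- char_encode("a", tab, fwd, bwd)
  x <- tab$vectors[tab$vocab[["a"]], , drop = FALSE]
  expect_equal(h1, bilstm(x, fwd, bwd)[1, ])
  ## all-unseen characters equal an unk token of the same length
  expect_equal(char_encode("xyz", tab, fwd, bwd),
               char_encode("qqq", tab, fwd, bwd))
  expect_equal(char_encode("ab", tab, zero_lstm(2, 2), zero_lstm(2, 2)),
               rep(0, 4))
})

test_that("encode_sentence has the right shape, is deterministic, and only
           sees the dictionary through the projection stream", {
  spec <- corpus_spec(n_sentences = 12, sentence_length = c(3, 6), seed = 19)
  cp <- generate_corpus(spec)
  cfg <- train_config(encoder = encoder_config(
    word_dim = 4, char_dim = 3, char_hidden = 2, dict_dim = 4,
    hidden_dim = 3, dropout = 0.5), seed = 5)
  set.seed(5)
  model <- cwdner:::build_model(cp$train, cp$dictionary, cfg)
  s <- cwdner:::corpus_sentences(cp$train)[[1]]
  df <- dict_features(s, cp$dictionary)

  e1 <- encode_sentence(s, df, model)
  expect_equal(dim(e1), c(length(s$tokens), length(model$tag_alphabet)))
  expect_identical(e1, encode_sentence(s, df, model))
  expect_error(encode_sentence(s, df[-1, , drop = FALSE], model), "length")

  ## zero the dictionary projection: emissions become dictionary-invariant
  model$params$dict_proj$W[] <- 0
  other_df <- matrix(1, nrow(df), ncol(df))
  expect_equal(encode_sentence(s, df, model),
               encode_sentence(s, other_df, model))
})

test_that("triple-mode gradients match central finite differences", {
  spec <- corpus_spec(n_sentences = 8, sentence_length = c(3, 4), seed = 23)
  cp <- generate_corpus(spec)
  cfg <- train_config(encoder = encoder_config(
    word_dim = 2, char_dim = 2, char_hidden = 2, dict_dim = 2,
    hidden_dim = 2, dropout = 0, fusion_mode = "triple"), seed = 7)
  set.seed(7)
  model <- cwdner:::build_model(cp$train, cp$dictionary, cfg)
  s <- cwdner:::corpus_sentences(cp$train)[[2]]
  df <- dict_features(s, cp$dictionary)
  y <- match(s$tags, model$tag_alphabet)

  ana <- cwdner:::flatten_params(
    cwdner:::sentence_loss_grad(model, s, df, y)$grads)
  theta <- cwdner:::flatten_params(model$params)
  lossfun <- function(th) {
    m2 <- model; m2$params <- cwdner:::unflatten_params(th, model$params)
    cwdner:::sentence_loss(m2, s, df, y)
  }
  eps <- 1e-5
  num <- vapply(seq_along(theta), function(i) {
    t1 <- theta; t2 <- theta
    t1[i] <- t1[i] + eps; t2[i] <- t2[i] - eps
    (lossfun(t1) - lossfun(t2)) / (2 * eps)
  }, numeric(1))
  relerr <- abs(num - ana) / pmax(abs(num) + abs(ana), 1)
  expect_lt(max(relerr), 1e-4)
})
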