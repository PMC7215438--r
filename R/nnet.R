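## Neural primitives: LSTM cell and sequence passes, bidirectional wrapper,
## highway fusion, linear projection — forward passes with caches and the
## matching analytic backward passes (verified against finite differences).
##
## An LSTM parameter set stacks the four gates row-wise in the order
## f, i, g (candidate), o:  W: (4*dh) x din, U: (4*dh) x dh, b: length 4*dh.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct LSTM parameters from per-gate matrices
#'
#' @param W_f,W_i,W_c,W_o input weight matrices (`dh x din`).
#' @param U_f,U_i,U_c,U_o recurrent weight matrices (`dh x dh`).
#' @param b_f,b_i,b_c,b_o bias vectors (length `dh`).
#' @return list with stacked `W`, `U`, `b` and dims `din`, `dh`.
#' @export
lstm_params <- function(W_f, W_i, W_c, W_o, U_f, U_i, U_c, U_o,
                        b_f, b_i, b_c, b_o) {
  W <- rbind(W_f, W_i, W_c, W_o)
  U <- rbind(U_f, U_i, U_c, U_o)
  b <- c(b_f, b_i, b_c, b_o)
  dh <- nrow(as.matrix(W_f))
  stopifnot(ncol(U) == dh, length(b) == 4L * dh)
  list(W = W, U = U, b = b)
}

## orthogonal square matrix (recurrent init)
init_orthogonal <- function(d) {
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
}

init_lstm <- function(din, dh, scale = NULL) {
  # Glorot-scaled inputs, orthogonal recurrent blocks, forget bias +1
  # (standard LSTM practice: remember by default)
  s <- if (is.null(scale)) sqrt(6 / (din + dh)) else scale
  U <- do.call(rbind, lapply(1:4, function(k) init_orthogonal(dh)))
  list(W = matrix(stats::runif(4 * dh * din, -s, s), 4 * dh, din),
       U = U,
       b = c(rep(1, dh), rep(0, 3 * dh)))
}

init_linear <- function(din, dout, scale = NULL) {
  s <- if (is.null(scale)) sqrt(6 / (din + dout)) else scale
  list(W = matrix(stats::runif(din * dout, -s, s), din, dout),
       b = rep(0, dout))
}

init_embedding <- function(vocab_size, dim, scale = 0.1) {
  matrix(stats::runif(vocab_size * dim, -scale, scale), vocab_size, dim)
}

#' One LSTM step
#'
#' Gate equations: `f = sigma(W_f e + U_f h + b_f)` (and likewise `i`, `o`),
#' candidate `g = tanh(W_c e + U_c h + b_c)`, cell `c_t = f*c + i*g`, output
#' `h_t = o * tanh(c_t)`.
#'
#' @param e_t input vector.
#' @param h_prev,c_prev previous hidden and cell state (length `dh`).
#' @param params parameters from [lstm_params()] or `init_lstm()`.
#' @return list with `h` and `c`.
#' @export
lstm_step <- function(e_t, h_prev, c_prev, params) {
  dh <- ncol(params$U)
  if (length(e_t) != ncol(params$W) || length(h_prev) != dh ||
      length(c_prev) != dh) {
    stop("lstm_step: dimension mismatch")
  }
  a <- as.numeric(params$W %*% e_t + params$U %*% h_prev + params$b)
  f <- sigmoid(a[1:dh])
  i <- sigmoid(a[(dh + 1):(2 * dh)])
  g <- tanh(a[(2 * dh + 1):(3 * dh)])
  o <- sigmoid(a[(3 * dh + 1):(4 * dh)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

## Full unidirectional pass over X (n x din), zero initial state.
## Returns hidden states and the cache needed for backprop.
lstm_forward <- function(X, params) {
  n <- nrow(X); dh <- ncol(params$U)
  H <- matrix(0, n, dh); C <- matrix(0, n, dh)
  Fg <- matrix(0, n, dh); Ig <- Fg; Gg <- Fg; Og <- Fg; TanhC <- Fg
  h <- rep(0, dh); cc <- rep(0, dh)
  tW <- params$W; tU <- params$U; b <- params$b
  i1 <- 1:dh; i2 <- (dh + 1):(2 * dh); i3 <- (2 * dh + 1):(3 * dh)
  i4 <- (3 * dh + 1):(4 * dh)
  for (t in seq_len(n)) {
    a <- as.numeric(tW %*% X[t, ] + tU %*% h + b)
    f <- sigmoid(a[i1]); i <- sigmoid(a[i2]); g <- tanh(a[i3]); o <- sigmoid(a[i4])
    cprev <- cc
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    h <- o * tc
    H[t, ] <- h; C[t, ] <- cc
    Fg[t, ] <- f; Ig[t, ] <- i; Gg[t, ] <- g; Og[t, ] <- o; TanhC[t, ] <- tc
  }
  list(H = H, cache = list(X = X, H = H, C = C, Fg = Fg, Ig = Ig, Gg = Gg,
                           Og = Og, TanhC = TanhC))
}

## Backward pass: dH is n x dh gradient w.r.t. each hidden state.
## Returns dX and parameter gradients.
lstm_backward <- function(params, cache, dH) {
  X <- cache$X; n <- nrow(X); dh <- ncol(params$U)
  din <- ncol(params$W)
  dW <- matrix(0, 4 * dh, din)
  dU <- matrix(0, 4 * dh, dh)
  db <- rep(0, 4 * dh)
  dX <- matrix(0, n, din)
  dh_carry <- rep(0, dh); dc_carry <- rep(0, dh)
  for (t in rev(seq_len(n))) {
    f <- cache$Fg[t, ]; i <- cache$Ig[t, ]; g <- cache$Gg[t, ]
    o <- cache$Og[t, ]; tc <- cache$TanhC[t, ]
    cprev <- if (t > 1L) cache$C[t - 1L, ] else rep(0, dh)
    hprev <- if (t > 1L) cache$H[t - 1L, ] else rep(0, dh)
    dht <- dH[t, ] + dh_carry
    do <- dht * tc
    dc <- dc_carry + dht * o * (1 - tc^2)
    df <- dc * cprev
    di <- dc * g
    dg <- dc * i
    dc_carry <- dc * f
    da <- c(df * f * (1 - f), di * i * (1 - i), dg * (1 - g^2), do * o * (1 - o))
    dW <- dW + da %o% X[t, ]
    dU <- dU + da %o% hprev
    db <- db + da
    dX[t, ] <- as.numeric(crossprod(params$W, da))
    dh_carry <- as.numeric(crossprod(params$U, da))
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

#' Bidirectional LSTM over a sequence
#'
#' Runs a forward LSTM from position 1 and a backward LSTM from position n
#' (both from zero state) and concatenates per-position hidden states
#' `h_t = h_fwd_t (+) h_bwd_t`, so the output dimension is `2 * dh`.
#'
#' @param inputs `n x din` matrix (rows are positions), `n >= 1`.
#' @param fwd,bwd forward and backward LSTM parameter sets.
#' @return `n x (2*dh)` matrix of hidden states.
#' @export
bilstm <- function(inputs, fwd, bwd) {
  bilstm_forward(inputs, fwd, bwd)$H
}

bilstm_forward <- function(inputs, fwd, bwd) {
  X <- as.matrix(inputs)
  if (nrow(X) == 0L) stop("bilstm: empty input sequence")
  n <- nrow(X)
  ff <- lstm_forward(X, fwd)
  fb <- lstm_forward(X[n:1, , drop = FALSE], bwd)
  H <- cbind(ff$H, fb$H[n:1, , drop = FALSE])
  list(H = H, cache = list(fwd = ff$cache, bwd = fb$cache, n = n,
                           dh_f = ncol(fwd$U)))
}

bilstm_backward <- function(fwd, bwd, cache, dH) {
  n <- cache$n; dh_f <- cache$dh_f
  dHf <- dH[, 1:dh_f, drop = FALSE]
  dHb <- dH[, (dh_f + 1):ncol(dH), drop = FALSE][n:1, , drop = FALSE]
  bf <- lstm_backward(fwd, cache$fwd, dHf)
  bb <- lstm_backward(bwd, cache$bwd, dHb)
  dX <- bf$dX + bb$dX[n:1, , drop = FALSE]
  list(dX = dX,
       fwd = bf[c("dW", "dU", "db")],
       bwd = bb[c("dW", "dU", "db")])
}

#' Highway fusion of character and word representations
#'
#' With `x = [w_char, w_word]`, computes gate `t = sigma(W_t x + b_t)` and
#' output `t * tanh(W_k x + b_k) + (1 - t) * x`; the output keeps the
#' concatenated input dimension (W_t, W_k are square).
#'
#' @param w_char character-level representation vector.
#' @param w_word word embedding vector.
#' @param params list with square matrices `W_t`, `W_k` and bias vectors
#'   `b_t`, `b_k` over the concatenated dimension.
#' @return fused vector of the concatenated dimension.
#' @export
highway_combine <- function(w_char, w_word, params) {
  x <- c(w_char, w_word)
  if (length(x) != ncol(params$W_t)) stop("highway_combine: dimension mismatch")
  tg <- sigmoid(as.numeric(params$W_t %*% x) + params$b_t)
  tr <- tanh(as.numeric(params$W_k %*% x) + params$b_k)
  tg * tr + (1 - tg) * x
}

## vectorized highway over rows of X (n x D); caches for backward
highway_forward <- function(X, params) {
  Tg <- sigmoid(X %*% t(params$W_t) +
                  matrix(params$b_t, nrow(X), length(params$b_t), byrow = TRUE))
  Tr <- tanh(X %*% t(params$W_k) +
               matrix(params$b_k, nrow(X), length(params$b_k), byrow = TRUE))
  Y <- Tg * Tr + (1 - Tg) * X
  list(Y = Y, cache = list(X = X, Tg = Tg, Tr = Tr))
}

highway_backward <- function(params, cache, dY) {
  X <- cache$X; Tg <- cache$Tg; Tr <- cache$Tr
  dTg <- dY * (Tr - X)
  dTr <- dY * Tg
  dA_t <- dTg * Tg * (1 - Tg)       # pre-activation of gate
  dA_k <- dTr * (1 - Tr^2)          # pre-activation of transform
  dW_t <- t(dA_t) %*% X
  dW_k <- t(dA_k) %*% X
  db_t <- colSums(dA_t)
  db_k <- colSums(dA_k)
  dX <- dY * (1 - Tg) + dA_t %*% params$W_t + dA_k %*% params$W_k
  list(dX = dX, dW_t = dW_t, dW_k = dW_k, db_t = db_t, db_k = db_k)
}

init_highway <- function(dim, scale = 0.1, gate_bias = -1) {
  # slight negative gate bias: start near the carry path
  list(W_t = matrix(stats::runif(dim * dim, -scale, scale), dim, dim),
       W_k = matrix(stats::runif(dim * dim, -scale, scale), dim, dim),
       b_t = rep(gate_bias, dim), b_k = rep(0, dim))
}
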