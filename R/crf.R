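## Linear-chain CRF: path scoring, exact log-partition via the forward
## recursion in log space, log-likelihood, Viterbi decoding, posterior
## gradients (forward-backward), and the BIEOS transition constraint mask.
##
## Conventions: emissions P are n x K (position x tag, 1-based tag indices);
## transitions A are (K+2) x (K+2) with virtual tags START = K+1 (no incoming)
## and STOP = K+2 (no outgoing). A path y_1..y_n is scored as
##   A[START, y_1] + sum_t P[t, y_t] + sum_t A[y_t, y_{t+1}] + A[y_n, STOP].

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_crf_inputs <- function(P, A, y = NULL) {
  P <- as.matrix(P); A <- as.matrix(A)
  K <- ncol(P)
  if (nrow(P) < 1L) stop("empty sentence: emission matrix needs n >= 1 rows")
  if (nrow(A) != K + 2L || ncol(A) != K + 2L) {
    stop(sprintf("transition matrix must be (K+2) x (K+2) = %d x %d", K + 2L, K + 2L))
  }
  if (!is.null(y)) {
    if (length(y) != nrow(P)) stop("tag sequence length must equal n")
    if (any(y < 1L | y > K)) stop("tag index out of range 1..K")
  }
  list(P = P, A = A, K = K, n = nrow(P))
}

#' Score one tag path under a linear-chain CRF
#'
#' @param P `n x K` emission score matrix.
#' @param A `(K+2) x (K+2)` transition score matrix with virtual START
#'   (`K+1`) and STOP (`K+2`) tags.
#' @param y integer tag index sequence (1-based, length `n`).
#' @return the path score (emissions plus transitions including boundary
#'   transitions).
#' @export
sequence_score <- function(P, A, y) {
  z <- check_crf_inputs(P, A, y)
  K <- z$K; n <- z$n
  path <- c(K + 1L, y, K + 2L)
  trans <- sum(z$A[cbind(path[-length(path)], path[-1L])])
  trans + sum(z$P[cbind(seq_len(n), y)])
}

#' Log-partition function of a linear-chain CRF
#'
#' Log of the sum over all `K^n` paths of the exponentiated path score,
#' computed by the forward recursion with per-step log-sum-exp (numerically
#' stable for scores up to about 1e3).
#'
#' @inheritParams sequence_score
#' @return log-partition value (always >= any single path score).
#' @export
log_partition <- function(P, A) {
  z <- check_crf_inputs(P, A)
  P <- z$P; A <- z$A; K <- z$K; n <- z$n
  alpha <- A[K + 1L, 1:K] + P[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      alpha <- vapply(1:K, function(j) logsumexp(alpha + A[1:K, j]),
                      numeric(1)) + P[t, ]
    }
  }
  logsumexp(alpha + A[1:K, K + 2L])
}

#' Log-likelihood of a tag path
#'
#' `sequence_score(P, A, y) - log_partition(P, A)`; always <= 0, and the
#' exponentials over all paths sum to one.
#'
#' @inheritParams sequence_score
#' @return log-probability of `y`.
#' @export
log_likelihood <- function(P, A, y) {
  sequence_score(P, A, y) - log_partition(P, A)
}

#' Viterbi decoding
#'
#' Returns the tag path maximizing the CRF path score, with deterministic
#' tie-breaking toward the lowest tag index at each backtracking step.
#'
#' @inheritParams sequence_score
#' @return list with `path` (integer tag indices) and `score`
#'   (its [sequence_score()]).
#' @export
viterbi_decode <- function(P, A) {
  z <- check_crf_inputs(P, A)
  P <- z$P; A <- z$A; K <- z$K; n <- z$n
  delta <- A[K + 1L, 1:K] + P[1L, ]
  back <- matrix(0L, n, K)
  if (n > 1L) {
    for (t in 2:n) {
      newdelta <- numeric(K)
      for (j in 1:K) {
        s <- delta + A[1:K, j]
        b <- which.max(s)         # which.max takes the lowest index on ties
        back[t, j] <- b
        newdelta[j] <- s[b] + P[t, j]
      }
      delta <- newdelta
    }
  }
  final <- delta + A[1:K, K + 2L]
  if (!any(is.finite(final))) stop("viterbi_decode: all paths are infeasible")
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- back[t, path[t]]
  }
  list(path = path, score = sequence_score(P, A, path))
}

## Negative log-likelihood and its analytic gradients w.r.t. P and A,
## by the forward-backward algorithm in log space.
## Returns loss = -(score - logZ), dP (n x K), dA ((K+2) x (K+2)).
crf_loss_grad <- function(P, A, y) {
  z <- check_crf_inputs(P, A, y)
  P <- z$P; A <- z$A; K <- z$K; n <- z$n
  START <- K + 1L; STOP <- K + 2L
  ## forward
  alpha <- matrix(-Inf, n, K)
  alpha[1L, ] <- A[START, 1:K] + P[1L, ]
  if (n > 1L) for (t in 2:n) {
    for (j in 1:K) alpha[t, j] <- logsumexp(alpha[t - 1L, ] + A[1:K, j]) + P[t, j]
  }
  logZ <- logsumexp(alpha[n, ] + A[1:K, STOP])
  ## backward
  beta <- matrix(-Inf, n, K)
  beta[n, ] <- A[1:K, STOP]
  if (n > 1L) for (t in (n - 1L):1L) {
    for (i in 1:K) {
      beta[t, i] <- logsumexp(A[i, 1:K] + P[t + 1L, ] + beta[t + 1L, ])
    }
  }
  ## marginals -> dP
  marg <- exp(alpha + beta - logZ)
  dP <- marg
  dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
  ## expected transition counts -> dA
  dA <- matrix(0, K + 2L, K + 2L)
  dA[START, 1:K] <- exp(A[START, 1:K] + P[1L, ] + beta[1L, ] - logZ)
  dA[1:K, STOP] <- exp(alpha[n, ] + A[1:K, STOP] - logZ)
  if (n > 1L) for (t in 1:(n - 1L)) {
    M <- outer(alpha[t, ], P[t + 1L, ] + beta[t + 1L, ], `+`) + A[1:K, 1:K]
    dA[1:K, 1:K] <- dA[1:K, 1:K] + exp(M - logZ)
  }
  ## observed counts
  path <- c(START, y, STOP)
  for (t in seq_len(length(path) - 1L)) {
    dA[path[t], path[t + 1L]] <- dA[path[t], path[t + 1L]] - 1
  }
  loss <- logZ - sequence_score(P, A, y)
  list(loss = loss, dP = dP, dA = dA)
}

#' BIEOS transition constraint mask
#'
#' Allowed transitions over a BIEOS x category tag alphabet plus virtual
#' START/STOP: START -> B-c / S-c / O; B-c and I-c -> I-c / E-c (same
#' category); E-c, S-c and O -> B-c' / S-c' / O / STOP. Everything else is
#' disallowed.
#'
#' @param tag_alphabet character vector of tags ("O" or "{B|I|E|S}-{cat}").
#' @return `(K+2) x (K+2)` logical matrix (`TRUE` = allowed) with dimnames
#'   `c(tag_alphabet, "START", "STOP")`.
#' @export
build_constraint_mask <- function(tag_alphabet) {
  p <- parse_tags(tag_alphabet)   # errors on malformed tags
  K <- length(tag_alphabet)
  labs <- c(tag_alphabet, "START", "STOP")
  allowed <- matrix(FALSE, K + 2L, K + 2L, dimnames = list(labs, labs))
  opens <- p$symbol %in% c("B", "S") | p$symbol == "O"   # valid path starts
  closes <- p$symbol %in% c("E", "S") | p$symbol == "O"  # valid path ends
  for (i in seq_len(K)) {
    si <- p$symbol[i]; ci <- p$category[i]
    for (j in seq_len(K)) {
      sj <- p$symbol[j]; cj <- p$category[j]
      ok <- if (si %in% c("B", "I")) {
        sj %in% c("I", "E") && identical(ci, cj)
      } else {
        sj %in% c("B", "S") || sj == "O"
      }
      allowed[i, j] <- ok
    }
  }
  allowed["START", seq_len(K)] <- opens
  allowed[seq_len(K), "STOP"] <- closes
  allowed
}

## Apply a constraint mask to a transition matrix as an additive penalty in
## score space (soft -inf; keeps gradients finite).
apply_constraint_mask <- function(A, mask, penalty = -1e4) {
  A + (!mask) * penalty
}
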