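#' Adjacency-constrained rate matrix over an ordered state space
#'
#' Transitions are permitted only between numerically adjacent categories;
#' all other off-diagonal entries are structural zeros that no constructor
#' argument can perturb. A one-rate model shares a single rate across every
#' allowed directed transition; a multi-rate model has one rate per allowed
#' directed transition, `2(K-1)` in total, ordered as all forward rates
#' (1->2, ..., K-1->K) followed by all backward rates (2->1, ..., K->K-1).
#'
#' @param space A [state_space()].
#' @param kind `"one-rate"` or `"multi-rate"`.
#' @param rates Non-negative rate vector: length 1 (one-rate) or `2(K-1)`
#'   (multi-rate).
#' @return An object of class `rate_model` with the assembled generator `Q`
#'   (rows sum to zero).
#' @export
build_rate_matrix <- function(space, kind = c("one-rate", "multi-rate"), rates) {
  stopifnot(inherits(space, "state_space"))
  kind <- match.arg(kind)
  K <- space$K
  n_expected <- if (kind == "one-rate") 1L else 2L * (K - 1L)
  if (length(rates) != n_expected)
    stopf("%s model over %d states needs %d rate(s), got %d",
          kind, K, n_expected, length(rates))
  if (any(!is.finite(rates)) || any(rates < 0))
    stopf("rates must be finite and non-negative")
  Q <- matrix(0, K, K, dimnames = list(space$labels, space$labels))
  if (kind == "one-rate") {
    for (i in seq_len(K - 1L)) {
      Q[i, i + 1L] <- rates[1L]
      Q[i + 1L, i] <- rates[1L]
    }
  } else {
    for (i in seq_len(K - 1L)) {
      Q[i, i + 1L] <- rates[i]            # forward i -> i+1
      Q[i + 1L, i] <- rates[K - 1L + i]   # backward i+1 -> i
    }
  }
  diag(Q) <- -rowSums(Q)
  structure(list(space = space, kind = kind, rates = as.numeric(rates),
                 n_free = n_expected, Q = Q),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Ordered %s Mk model over %d states (%s)\n", x$kind,
              x$space$K, x$space$kind))
  print(round(x$Q, 4))
  invisible(x)
}

#' Transition probabilities over a branch
#'
#' Computes `P = exp(Q t)` by matrix exponential. Structural zeros of `Q`
#' do not force zeros in `P` at `t > 0`: multi-step paths connect
#' non-adjacent categories.
#'
#' @param model A [build_rate_matrix()] model.
#' @param t Branch length (time units), `t >= 0`.
#' @return A `K x K` stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.finite(t) || t < 0) stopf("branch length must be finite and >= 0")
  K <- model$space$K
  if (t == 0) {
    P <- diag(K)
  } else {
    P <- ape::matexpo(model$Q * t)
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- dimnames(model$Q)
  P
}

# Bare generator used in the MCMC hot path (no S3/dimnames overhead);
# mirrors build_rate_matrix exactly.
ordered_q <- function(K, kind, rates) {
  Q <- matrix(0, K, K)
  if (kind == "one-rate") {
    for (i in seq_len(K - 1L)) {
      Q[i, i + 1L] <- rates[1L]
      Q[i + 1L, i] <- rates[1L]
    }
  } else {
    for (i in seq_len(K - 1L)) {
      Q[i, i + 1L] <- rates[i]
      Q[i + 1L, i] <- rates[K - 1L + i]
    }
  }
  diag(Q) <- -.rowSums(Q, K, K)
  Q
}

#' Stationary frequencies of an ordered rate model
#'
#' Detailed-balance solution for the birth-death (path-graph) chain;
#' requires all allowed rates to be strictly positive.
#'
#' @param model A `rate_model`.
#' @return Probability vector over the ordered states.
#' @export
equilibrium_frequencies <- function(model) {
  Q <- model$Q
  K <- nrow(Q)
  if (any(Q[cbind(seq_len(K - 1L), seq.int(2L, K))] <= 0) ||
      any(Q[cbind(seq.int(2L, K), seq_len(K - 1L))] <= 0))
    stopf("equilibrium frequencies need strictly positive adjacent rates")
  pi <- numeric(K)
  pi[1] <- 1
  for (i in seq_len(K - 1L)) pi[i + 1L] <- pi[i] * Q[i, i + 1L] / Q[i + 1L, i]
  setNames(pi / sum(pi), model$space$labels)
}
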