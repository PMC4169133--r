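# Per-tree bundle consumed by the C pruning kernel.
mk_tree_data <- function(tree, tips) {
  tr <- ape::reorder.phylo(tree, "postorder")
  st <- tips[match(tr$tip.label, names(tips))]
  st[is.na(st)] <- 0L
  list(edge = tr$edge, el = tr$edge.length, ntip = ape::Ntip(tr),
       tipstate = as.integer(st), root = ape::Ntip(tr) + 1L)
}

#' Pruning log-likelihood of an ordered Mk model
#'
#' Felsenstein post-order pruning with per-node scaling, so likelihoods stay
#' finite on 100-tip trees. Tips absent from `tips` or coded `NA` contribute
#' all-ones partial likelihoods (missing data). A node may be fossilized:
#' its partial-likelihood vector is restricted to the fixed state in every
#' evaluation, scoring that ancestral-state hypothesis.
#'
#' @param tree A `phylo` chronogram.
#' @param tips Named integer vector of 1-based tip states (`NA` = missing).
#' @param model A [build_rate_matrix()] model.
#' @param root_freqs Root state frequencies; default uniform.
#' @param fossil Optional constraint: a list or list of lists with `node`
#'   (ape node id) and `state` (1-based index).
#' @return The log-likelihood (scalar).
#' @export
prune_log_likelihood <- function(tree, tips, model, root_freqs = NULL,
                                 fossil = NULL) {
  stopifnot(inherits(model, "rate_model"))
  K <- model$space$K
  obs <- tips[!is.na(tips)]
  if (any(obs < 1L | obs > K)) stopf("tip states outside 1..%d", K)
  root_freqs <- root_freqs %||% rep(1 / K, K)
  if (abs(sum(root_freqs) - 1) > 1e-8) stopf("root frequencies must sum to 1")
  if (ape::Ntip(tree) == 1L) {
    s <- tips[[tree$tip.label]]
    if (is.na(s)) return(0) # no data: likelihood 1
    t <- sum(tree$edge.length)
    P <- transition_probabilities(model, t)
    return(log(sum(root_freqs * P[, s])))
  }
  if (length(obs) == 0L) stopf("all tips are missing; likelihood undefined")
  td <- mk_tree_data(tree, tips)
  fnodes <- integer(0); fstates <- integer(0)
  if (!is.null(fossil)) {
    if (!is.null(fossil$node)) fossil <- list(fossil)
    fnodes <- vapply(fossil, function(f) as.integer(f$node), integer(1))
    fstates <- vapply(fossil, function(f) as.integer(f$state), integer(1))
    if (any(fstates < 1L | fstates > K)) stopf("fossil states outside 1..%d", K)
  }
  mk_loglik_cpp(td$edge, td$el, td$ntip, td$tipstate, model$Q,
                as.numeric(root_freqs), fnodes, fstates)
}

#' Maximum-likelihood fit of an ordered Mk model
#'
#' Maximizes the pruning likelihood over transition rates bounded in
#' `(0, 100]` (matching the support of the uniform prior used by the MCMC
#' analyses, so ML and Bayesian rates stay comparable), with seeded
#' multi-start L-BFGS-B on the log-rate scale.
#'
#' @param tree A `phylo` chronogram (a single summary tree; see
#'   [compare_aic()] for why model selection uses one tree).
#' @param tips Named tip-state vector as in [prune_log_likelihood()].
#' @param space A [state_space()].
#' @param kind `"one-rate"` or `"multi-rate"`.
#' @param root_freqs Root frequencies; default uniform.
#' @param n_starts Number of optimizer starts (at least 5 recommended).
#' @param seed Seed for the start points.
#' @return An object of class `model_fit` with the fitted `model`, `logLik`,
#'   parameter count `k`, `AIC`, and optimizer metadata.
#' @export
fit_ml <- function(tree, tips, space, kind = c("one-rate", "multi-rate"),
                   root_freqs = NULL, n_starts = 5L, seed = 1L) {
  kind <- match.arg(kind)
  npar <- if (kind == "one-rate") 1L else 2L * (space$K - 1L)
  lower <- log(1e-8); upper <- log(100)
  negll <- function(theta) {
    m <- build_rate_matrix(space, kind, exp(theta))
    -prune_log_likelihood(tree, tips, m, root_freqs)
  }
  starts <- with_seed(seed, {
    s <- matrix(runif(n_starts * npar, log(1e-3), log(10)), n_starts, npar)
    s[1, ] <- log(0.1)  # deterministic anchor start
    s
  })
  best <- NULL
  trace <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    trace[[i]] <- fit
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stopf("optimizer failed on all %d starts; see trace", n_starts)
  model <- build_rate_matrix(space, kind, exp(best$par))
  logLik <- -best$value
  structure(list(model = model, logLik = logLik, k = npar,
                 AIC = 2 * npar - 2 * logLik,
                 convergence = best$convergence,
                 tips = tips, n_starts = n_starts, trace = trace),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s Mk fit: logL = %.4f, k = %d, AIC = %.4f\n",
              x$model$kind, x$logLik, x$k, x$AIC))
  cat("rates:", signif(x$model$rates, 4), "\n")
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Ranks fits of alternative models on the same data by AIC and labels the
#' differences: dAIC below 3 is negligible, 3 or more is moderately strong,
#' and 10 or more is very strong support for rejecting the worse model.
#'
#' @param fits List of [fit_ml()] objects fitted to identical data.
#' @param names Optional model names.
#' @return A data frame of class `model_comparison` with `model`, `k`,
#'   `logLik`, `AIC`, `dAIC`, `verdict`.
#' @export
compare_aic <- function(fits, names = NULL) {
  if (length(fits) < 2L) stopf("need at least two fits to compare")
  ref <- fits[[1]]$tips
  for (f in fits[-1])
    if (!identical(f$tips, ref)) stopf("fits were made on different data")
  names <- names %||% vapply(fits, function(f) f$model$kind, character(1))
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  d <- aic - min(aic)
  out <- data.frame(model = names,
                    k = vapply(fits, function(f) f$k, integer(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = aic, dAIC = d,
                    verdict = evidence_label(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  rownames(out) <- NULL
  attr(out, "tie") <- sum(out$dAIC < .Machine$double.eps ^ 0.5) > 1L
  class(out) <- c("model_comparison", "data.frame")
  out
}

# Shared evidence scale for dAIC and Log Bayes factors.
evidence_label <- function(delta) {
  ifelse(delta < 3, "negligible",
         ifelse(delta < 10, "moderately strong", "very strong"))
}
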