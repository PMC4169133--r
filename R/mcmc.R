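#' MCMC run configuration
#'
#' Defaults mirror the study design: 5 million generations sampled every
#' 1,000 with the first 1 million discarded as burnin (4,000 retained
#' samples), uniform(0, `prior_max`) priors on each rate, and a target
#' acceptance window of 20--40% for rate proposals. Proposal windows are
#' tuned during burnin only and frozen afterwards, preserving the target
#' distribution.
#'
#' @param generations Total chain length.
#' @param thinning Sampling interval in generations.
#' @param burnin Generations discarded before sampling starts.
#' @param prior_max Upper bound of the uniform rate prior (and of sigma^2
#'   for the continuous model).
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param tree_prob Probability of proposing a tree swap (uniform draw from
#'   the posterior set, accepted by likelihood ratio) instead of a rate move.
#' @param accept_window Target window for realized rate-move acceptance.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(generations = 5e6, thinning = 1000, burnin = 1e6,
                        prior_max = 100, seed = 1L, tree_prob = 0.25,
                        accept_window = c(0.2, 0.4)) {
  if (burnin >= generations) stopf("burnin must be smaller than generations")
  if ((generations - burnin) %% thinning != 0)
    stopf("(generations - burnin) must be a multiple of thinning")
  if (tree_prob < 0 || tree_prob >= 1) stopf("tree_prob must lie in [0, 1)")
  structure(list(generations = as.numeric(generations),
                 thinning = as.numeric(thinning),
                 burnin = as.numeric(burnin),
                 prior_max = prior_max, seed = as.integer(seed),
                 tree_prob = tree_prob, accept_window = accept_window,
                 n_retained = as.integer((generations - burnin) / thinning)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf(
    "MCMC config: %g generations, thin %g, burnin %g -> %d samples (seed %d)\n",
    x$generations, x$thinning, x$burnin, x$n_retained, x$seed))
  invisible(x)
}

# Resolve addresses once per tree; returns per-tree node ids.
resolve_addresses <- function(posterior, addresses) {
  lapply(posterior$trees, function(tr)
    vapply(addresses, function(a) resolve_mrca(tr, a)$node, integer(1)))
}

# Metropolis-Hastings engine shared by the plain, fossilized and
# power-posterior (stepping-stone) multistate runs.
#
# Rate proposals are sliding windows on the log scale (symmetric in theta,
# reflected at log(prior_max); the uniform-on-rate prior contributes the
# exp(theta' - theta) Jacobian to the acceptance ratio). Tree proposals swap
# the current chronogram for a uniform draw from the posterior set.
mk_chain <- function(posterior, tips, space, kind, config,
                     constraint = NULL, focal = list(),
                     root_freqs = c("uniform", "equilibrium"),
                     fix_rates = NULL, power = 1) {
  root_freqs <- match.arg(root_freqs)
  K <- space$K
  npar <- if (kind == "one-rate") 1L else 2L * (K - 1L)
  ntrees <- length(posterior)
  trees <- posterior$trees
  td <- lapply(trees, mk_tree_data, tips = tips)

  cnodes <- if (!is.null(constraint))
    vapply(trees, function(tr) resolve_mrca(tr, constraint$address)$node, integer(1))
  fnode_mat <- if (length(focal))
    do.call(rbind, resolve_addresses(posterior, focal)) # ntrees x nfocal
  cstate <- if (!is.null(constraint)) constraint$state else NULL

  rf <- rep(1 / K, K)
  root_f <- function(Q) {
    if (root_freqs != "equilibrium") return(rf)
    pi <- numeric(K); pi[1] <- 1
    for (i in seq_len(K - 1L)) pi[i + 1L] <- pi[i] * Q[i, i + 1L] / Q[i + 1L, i]
    pi / sum(pi)
  }
  loglik <- function(j, Q) {
    fn <- integer(0); fs <- integer(0)
    if (!is.null(constraint)) { fn <- cnodes[j]; fs <- cstate }
    mk_loglik_cpp(td[[j]]$edge, td[[j]]$el, td[[j]]$ntip, td[[j]]$tipstate,
                  Q, root_f(Q), fn, fs)
  }
  build_q <- function(theta) ordered_q(K, kind, exp(theta))

  node_draw <- function(j, Q, node) {
    rfj <- root_f(Q)
    fn0 <- integer(0); fs0 <- integer(0)
    if (!is.null(constraint)) { fn0 <- cnodes[j]; fs0 <- cstate }
    ll <- vapply(seq_len(K), function(s)
      mk_loglik_cpp(td[[j]]$edge, td[[j]]$el, td[[j]]$ntip, td[[j]]$tipstate,
                    Q, rfj, c(fn0, node), c(fs0, s)), numeric(1))
    p <- exp(ll - logsumexp(ll))
    sample.int(K, 1L, prob = p)
  }

  upper <- log(config$prior_max)
  nfocal <- length(focal)
  fnames <- vapply(focal, function(a) a$name, character(1))
  nret <- config$n_retained

  out <- with_seed(config$seed, {
    theta <- if (!is.null(fix_rates)) log(fix_rates)
             else runif(npar, log(0.01), log(1))
    j <- sample.int(ntrees, 1L)
    Q <- build_q(theta)
    ll <- loglik(j, Q)
    if (!is.finite(ll)) {
      for (jj in seq_len(ntrees)) {
        ll <- loglik(jj, Q)
        if (is.finite(ll)) { j <- jj; break }
      }
      if (!is.finite(ll))
        stopf("constraint state has zero likelihood on every tree")
    }
    w <- rep(1, npar)
    acc <- list(rate_prop = 0, rate_acc = 0, tree_prop = 0, tree_acc = 0,
                tune_prop = 0, tune_acc = 0)
    samples <- matrix(NA_real_, nret, npar + 3L + nfocal)
    ridx <- 0L
    tune_every <- 500
    for (gen in seq_len(config$generations)) {
      in_burnin <- gen <= config$burnin
      if (ntrees > 1L && runif(1) < config$tree_prob) {
        jp <- sample.int(ntrees, 1L)
        llp <- loglik(jp, Q)
        if (!in_burnin) acc$tree_prop <- acc$tree_prop + 1
        if (log(runif(1)) < power * (llp - ll)) {
          j <- jp; ll <- llp
          if (!in_burnin) acc$tree_acc <- acc$tree_acc + 1
        }
      } else if (is.null(fix_rates)) {
        i <- if (npar == 1L) 1L else sample.int(npar, 1L)
        thp <- theta
        thp[i] <- thp[i] + runif(1, -w[i], w[i])
        while (thp[i] > upper) thp[i] <- 2 * upper - thp[i]
        Qp <- build_q(thp)
        llp <- loglik(j, Qp)
        if (in_burnin) acc$tune_prop <- acc$tune_prop + 1
        else acc$rate_prop <- acc$rate_prop + 1
        if (log(runif(1)) < power * (llp - ll) + (thp[i] - theta[i])) {
          theta <- thp; Q <- Qp; ll <- llp
          if (in_burnin) acc$tune_acc <- acc$tune_acc + 1
          else acc$rate_acc <- acc$rate_acc + 1
        }
      }
      if (in_burnin && gen %% tune_every == 0 && acc$tune_prop > 0) {
        r <- acc$tune_acc / acc$tune_prop
        if (r > config$accept_window[2]) w <- w * 1.5
        else if (r < config$accept_window[1]) w <- w / 1.5
        acc$tune_prop <- 0; acc$tune_acc <- 0
      }
      if (!in_burnin && (gen - config$burnin) %% config$thinning == 0) {
        ridx <- ridx + 1L
        draws <- if (nfocal)
          vapply(seq_len(nfocal), function(f)
            node_draw(j, Q, fnode_mat[j, f]), integer(1)) else integer(0)
        samples[ridx, ] <- c(gen, exp(theta), ll, j, draws)
      }
    }
    list(samples = samples, acc = acc, w = w)
  })

  rate_names <- if (npar == 1L) "rate" else paste0("rate", seq_len(npar))
  df <- as.data.frame(out$samples)
  names(df) <- c("generation", rate_names, "logL", "tree_index",
                 if (nfocal) paste0("node_", fnames))
  rate_rate <- if (out$acc$rate_prop > 0) out$acc$rate_acc / out$acc$rate_prop else NA_real_
  tree_rate <- if (out$acc$tree_prop > 0) out$acc$tree_acc / out$acc$tree_prop else NA_real_
  if (is.null(fix_rates) && !is.na(rate_rate) &&
      (rate_rate < config$accept_window[1] || rate_rate > config$accept_window[2]))
    warnf("post-burnin rate-move acceptance %.3f outside [%.2f, %.2f]",
          rate_rate, config$accept_window[1], config$accept_window[2])
  structure(list(samples = df, space = space, kind = kind, config = config,
                 constraint = constraint, focal = focal,
                 focal_names = fnames,
                 acceptance = c(rate = rate_rate, tree = tree_rate),
                 proposal_windows = out$w, power = power,
                 monophyly = if (nfocal)
                   setNames(vapply(focal, function(a)
                     mrca_monophyly_fraction(posterior, a), numeric(1)), fnames)),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("Posterior trace: %d samples (%s model, %d states)\n",
              nrow(x$samples), x$kind, x$space$K))
  cat(sprintf("  acceptance: rate %.3f, tree %.3f\n",
              x$acceptance["rate"], x$acceptance["tree"]))
  if (length(x$focal_names))
    cat("  focal nodes:", paste(x$focal_names, collapse = ", "), "\n")
  invisible(x)
}

#' Bayesian multistate reconstruction over a tree posterior
#'
#' Metropolis-Hastings MCMC for the ordered Mk model, integrating over both
#' transition rates (uniform priors on `(0, prior_max]`) and the posterior
#' sample of chronograms (uniform tree-swap proposals accepted by likelihood
#' ratio). At every retained sample the state of each focal node -- located
#' per tree as the MRCA of its taxon set -- is drawn from its exact
#' conditional marginal given the current rates and tree. An optional
#' fossilization constraint restricts a node to a fixed state in every
#' likelihood evaluation.
#'
#' @param trees A [tree_posterior()].
#' @param tips Named tip-state vector (see [tip_states()]).
#' @param space A [state_space()].
#' @param kind `"one-rate"` or `"multi-rate"`.
#' @param config An [mcmc_config()].
#' @param constraint Optional `list(address = node_address, state = label or
#'   index)` fossilizing a node.
#' @param focal List of [node_address()] objects whose states are sampled.
#' @param root_freqs `"uniform"` (default) or `"equilibrium"`.
#' @param fix_rates Optional fixed rate vector; disables rate moves (useful
#'   for validating node marginals against exact conditionals).
#' @return A `posterior_trace` with `$samples` (generation, rates, logL,
#'   tree index, focal-node state draws), realized acceptance rates, and the
#'   fraction of trees in which each focal clade is exactly monophyletic.
#' @export
run_multistate_mcmc <- function(trees, tips, space,
                                kind = c("one-rate", "multi-rate"),
                                config = mcmc_config(),
                                constraint = NULL, focal = list(),
                                root_freqs = c("uniform", "equilibrium"),
                                fix_rates = NULL) {
  stopifnot(inherits(trees, "tree_posterior"), inherits(space, "state_space"))
  kind <- match.arg(kind)
  if (!is.null(constraint)) {
    constraint$state <- match_state(constraint$state, space)
    stopifnot(inherits(constraint$address, "node_address"))
  }
  if (inherits(focal, "node_address")) focal <- list(focal)
  obs <- tips[!is.na(tips)]
  if (length(obs) == 0L) stopf("all tips missing")
  if (any(obs < 1L | obs > space$K)) stopf("tip states outside the state space")
  mk_chain(trees, tips, space, kind, config, constraint, focal,
           match.arg(root_freqs), fix_rates)
}

match_state <- function(state, space) {
  if (is.character(state)) {
    idx <- match(state, space$labels)
    if (is.na(idx)) stopf("state '%s' not in the state space", state)
    return(idx)
  }
  state <- as.integer(state)
  if (state < 1L || state > space$K) stopf("state index outside 1..%d", space$K)
  state
}

#' Posterior state probabilities of a focal node
#'
#' Empirical frequency of each state among the retained node draws -- the
#' "prob." reported beside pie diagrams in ancestral-state figures.
#'
#' @param trace A `posterior_trace` from [run_multistate_mcmc()].
#' @param address A [node_address()] tracked during the run, or its name.
#' @return An object of class `node_state_estimate` with `probs` (named,
#'   summing to 1) and the sample count.
#' @export
node_state_probabilities <- function(trace, address) {
  name <- if (inherits(address, "node_address")) address$name else address
  col <- paste0("node_", name)
  if (!col %in% names(trace$samples))
    stopf("node '%s' was not tracked during the run", name)
  draws <- trace$samples[[col]]
  K <- trace$space$K
  probs <- tabulate(draws, nbins = K) / length(draws)
  taxa <- NULL
  for (a in trace$focal) if (a$name == name) taxa <- a$taxa
  node_state_estimate(name, setNames(probs, trace$space$labels),
                      n = length(draws), taxa = taxa)
}

#' Construct a node state estimate
#'
#' @param name Node display name.
#' @param probs Named per-state posterior probabilities (sum to 1).
#' @param n Number of posterior samples behind the estimate.
#' @param taxa Optional taxon set addressing the node.
#' @return An object of class `node_state_estimate`.
#' @export
node_state_estimate <- function(name, probs, n, taxa = NULL) {
  if (abs(sum(probs) - 1) > 1e-9) stopf("state probabilities must sum to 1")
  if (any(probs < 0)) stopf("state probabilities must be non-negative")
  structure(list(name = name, probs = probs, n = as.integer(n), taxa = taxa),
            class = "node_state_estimate")
}

#' @export
print.node_state_estimate <- function(x, ...) {
  cat(sprintf("Node '%s' (n = %d):\n", x$name, x$n))
  print(round(x$probs, 2))
  invisible(x)
}

#' Modal state of a node state estimate
#'
#' Ties are broken toward the lowest state index.
#' @param estimate A `node_state_estimate`.
#' @return Named length-1 vector: modal state label with its probability.
#' @export
modal_state <- function(estimate) {
  i <- which.max(estimate$probs)
  setNames(estimate$probs[i], names(estimate$probs)[i])
}

#' Fossilize a node and summarize the constrained run
#'
#' Runs the constrained chain (the node's partial-likelihood vector is
#' restricted to `state` in every evaluation, with the root prior applied
#' unchanged) and returns its harmonic-mean log marginal likelihood.
#'
#' @inheritParams run_multistate_mcmc
#' @param address The [node_address()] to fossilize.
#' @param state State label or 1-based index the node is fixed to.
#' @return An object of class `model_run_summary` with `description`, `hm`,
#'   and the full `trace`.
#' @export
fossilize_and_summarize <- function(trees, tips, space,
                                    kind = c("one-rate", "multi-rate"),
                                    config = mcmc_config(),
                                    address, state) {
  kind <- match.arg(kind)
  sidx <- match_state(state, space)
  trace <- run_multistate_mcmc(trees, tips, space, kind, config,
                               constraint = list(address = address, state = sidx))
  hm <- harmonic_mean(trace$samples$logL)
  structure(list(description = sprintf("node '%s' fixed to %s", address$name,
                                       space$labels[sidx]),
                 address = address, state = space$labels[sidx],
                 hm = hm, trace = trace),
            class = "model_run_summary")
}

#' @export
print.model_run_summary <- function(x, ...) {
  cat(sprintf("%s: hm = %.2f\n", x$description, x$hm))
  invisible(x)
}

#' Fossilization sweep over all states of a node
#'
#' Runs one constrained chain per state of the space and assembles the
#' harmonic means into a Log Bayes factor table (the per-node test of
#' alternative ancestral states). Each run derives its own seed from the
#' base config and the state label.
#'
#' @inheritParams fossilize_and_summarize
#' @param states States to sweep; defaults to the whole space.
#' @return List with `runs` (per-state `model_run_summary`) and `lbf`
#'   (a [lbf_table()]).
#' @export
fossilize_states <- function(trees, tips, space,
                             kind = c("one-rate", "multi-rate"),
                             config = mcmc_config(), address,
                             states = NULL) {
  kind <- match.arg(kind)
  states <- states %||% space$labels
  runs <- list()
  for (s in states) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0(address$name, "::", s))
    runs[[s]] <- fossilize_and_summarize(trees, tips, space, kind, cfg,
                                         address, s)
  }
  hms <- vapply(runs, function(r) r$hm, numeric(1))
  list(runs = runs, lbf = lbf_table(hms))
}

#' Stepping-stone log marginal likelihood
#'
#' Power-posterior (stepping-stone) estimator provided as a numerically
#' stable cross-check on the conventional harmonic-mean estimator; the two
#' should broadly agree, with stepping stone the more trustworthy when they
#' do not. Rungs are spaced as quantiles of a Beta(`shape`, 1) distribution,
#' concentrating them near the prior.
#'
#' @inheritParams run_multistate_mcmc
#' @param n_rungs Number of power-posterior rungs.
#' @param shape Beta shape controlling rung spacing.
#' @return The estimated log marginal likelihood (scalar).
#' @export
stepping_stone_log_marginal <- function(trees, tips, space,
                                        kind = c("one-rate", "multi-rate"),
                                        config = mcmc_config(),
                                        constraint = NULL,
                                        n_rungs = 8L, shape = 0.3) {
  kind <- match.arg(kind)
  if (!is.null(constraint)) constraint$state <- match_state(constraint$state, space)
  betas <- ((0:n_rungs) / n_rungs) ^ (1 / shape)
  total <- 0
  for (k in seq_len(n_rungs)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("ss-rung-", k))
    chain <- mk_chain(trees, tips, space, kind, cfg, constraint,
                      power = betas[k])
    logl <- chain$samples$logL
    dbeta_k <- betas[k + 1L] - betas[k]
    total <- total + (logsumexp(dbeta_k * logl) - log(length(logl)))
  }
  total
}
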