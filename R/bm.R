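#' Brownian-motion parameters
#'
#' @param sigma2 Diffusion rate (trait-units squared per unit branch length,
#'   e.g. months^2 per Myr); must be non-negative.
#' @param root_mean Trait value at the root (months).
#' @return An object of class `bm_params`.
#' @export
bm_params <- function(sigma2, root_mean = 0) {
  if (!is.finite(sigma2) || sigma2 < 0) stopf("sigma2 must be finite and >= 0")
  structure(list(sigma2 = sigma2, root_mean = root_mean), class = "bm_params")
}

# Felsenstein contrasts pruning. Returns sufficient statistics that make the
# likelihood an O(1) function of (sigma2, root_mean): contrast sum of
# squares (in units of C), log-determinant contribution, and the root's GLS
# mean with its C-scale variance. Polytomies are folded sequentially, which
# is likelihood-equivalent.
bm_prune_stats <- function(tree, x) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  m <- numeric(nn); d <- numeric(nn); seen <- logical(nn)
  m[seq_len(ntip)] <- x[tr$tip.label]
  ssq <- 0; logdet <- 0; k <- 0L; degenerate <- FALSE
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    V <- d[ch] + tr$edge.length[i]
    if (!seen[par]) {
      m[par] <- m[ch]; d[par] <- V; seen[par] <- TRUE
    } else {
      S <- d[par] + V
      contrast <- m[par] - m[ch]
      if (S <= 0) {
        if (abs(contrast) > 0) degenerate <- TRUE
        # identical zero-variance observations carry no extra information
      } else {
        ssq <- ssq + contrast ^ 2 / S
        logdet <- logdet + log(S)
        k <- k + 1L
        m[par] <- (m[par] * V + m[ch] * d[par]) / S
        d[par] <- d[par] * V / S
      }
    }
  }
  root <- ntip + 1L
  list(n = ntip, k = k, ssq = ssq, logdet = logdet,
       m_root = m[root], d_root = d[root], degenerate = degenerate)
}

# Observed-value bookkeeping shared by the likelihood and the sampler:
# taxa with NA are excluded and the tree is pruned to the observed taxa,
# keeping track of the stem depth from the original root down to the
# pruned subtree's root (the pruned root is still centred on root_mean
# with that extra variance).
bm_observed <- function(tree, values) {
  obs <- values[!is.na(values)]
  obs <- obs[names(obs) %in% tree$tip.label]
  if (length(obs) == 0L) stopf("no observed tip values")
  if (length(obs) == length(tree$tip.label)) {
    return(list(obs = obs, pruned = tree, stem = 0))
  }
  if (length(obs) == 1L) {
    depth <- ape::node.depth.edgelength(tree)[match(names(obs), tree$tip.label)]
    return(list(obs = obs, pruned = NULL, stem = depth, single = TRUE))
  }
  pruned <- ape::keep.tip(tree, names(obs))
  mrca_node <- if (length(obs) == ape::Ntip(tree)) ape::Ntip(tree) + 1L
               else ape::getMRCA(tree, names(obs))
  stem <- ape::node.depth.edgelength(tree)[mrca_node]
  list(obs = obs, pruned = pruned, stem = stem, single = FALSE)
}

bm_loglik_from_stats <- function(st, stem, sigma2, root_mean) {
  if (st$degenerate) return(-Inf)
  v_root <- st$d_root + stem
  resid <- st$m_root - root_mean
  if (sigma2 == 0) {
    return(if (st$ssq > 0 || abs(resid) > 0) -Inf else Inf)
  }
  -0.5 * (st$k * log(2 * pi * sigma2) + st$logdet + st$ssq / sigma2) -
    0.5 * (log(2 * pi * sigma2 * v_root) + resid ^ 2 / (sigma2 * v_root))
}

#' Brownian-motion log-likelihood of tip values
#'
#' Multivariate-normal log density with mean `root_mean` and covariance
#' `sigma2` times the shared-path-length matrix, evaluated by phylogenetic
#' independent contrasts (linear time; equals the dense evaluation exactly).
#' Taxa with `NA` values are pruned from the tree, and the stem below the
#' observed clade's MRCA is retained as extra root variance.
#'
#' @param tree A `phylo` chronogram.
#' @param values Named numeric vector of tip values (months); `NA` = missing.
#' @param params A [bm_params()].
#' @return The log-likelihood; `-Inf` when `sigma2 = 0` with non-constant
#'   values.
#' @export
bm_log_likelihood <- function(tree, values, params) {
  stopifnot(inherits(params, "bm_params"))
  ob <- bm_observed(tree, values)
  if (isTRUE(ob$single)) {
    if (params$sigma2 == 0)
      return(if (ob$obs == params$root_mean) Inf else -Inf)
    return(dnorm(ob$obs, params$root_mean,
                 sqrt(params$sigma2 * ob$stem), log = TRUE))
  }
  st <- bm_prune_stats(ob$pruned, ob$obs)
  bm_loglik_from_stats(st, ob$stem, params$sigma2, params$root_mean)
}

#' Exact Gaussian conditionals of ancestral values
#'
#' For each requested interior node, the conditional distribution of its
#' value given the observed tip values and the BM parameters, obtained by
#' joint-normal conditioning on the tree covariance.
#'
#' Under `root_prior = "flat"` (the default, matching the reconstruction
#' model in which the root state is itself estimated under an improper flat
#' prior) the root value is marginalized analytically: the root's
#' conditional mean is the GLS phylogenetic mean of the tips, and with all
#' tip values equal every node's conditional mean equals that value.
#' `root_prior = "fixed"` conditions on the root being exactly
#' `params$root_mean`; this is the conditional the MCMC sampler draws from
#' given its current root-mean parameter. Conditional means do not depend
#' on `sigma2`; conditional variances scale with it.
#'
#' @param tree A `phylo` chronogram.
#' @param values Named tip values; `NA` = missing (those taxa are not
#'   conditioned on).
#' @param params A [bm_params()].
#' @param nodes Integer ape node ids, a list of [node_address()] objects, or
#'   `NULL` for all interior nodes.
#' @param root_prior `"flat"` or `"fixed"` (see above).
#' @return Data frame with `node`, `name`, `mean`, `var`.
#' @export
ancestral_conditional <- function(tree, values, params, nodes = NULL,
                                  root_prior = c("flat", "fixed")) {
  stopifnot(inherits(params, "bm_params"))
  root_prior <- match.arg(root_prior)
  obs <- values[!is.na(values)]
  obs <- obs[names(obs) %in% tree$tip.label]
  if (length(obs) < 1L) stopf("no observed tip values")
  ntip <- ape::Ntip(tree)
  if (is.null(nodes)) {
    nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
    nm <- as.character(nodes)
  } else if (is.list(nodes) || inherits(nodes, "node_address")) {
    if (inherits(nodes, "node_address")) nodes <- list(nodes)
    nm <- vapply(nodes, function(a) a$name, character(1))
    nodes <- vapply(nodes, function(a) resolve_mrca(tree, a)$node, integer(1))
  } else {
    nodes <- as.integer(nodes)
    nm <- as.character(nodes)
  }
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  tip_idx <- match(names(obs), tree$tip.label)
  Ctt <- matrix(depth[M[tip_idx, tip_idx]], length(tip_idx))
  sol <- tryCatch(solve(Ctt), error = function(e)
    stopf("degenerate tree covariance: %s", conditionMessage(e)))
  out <- data.frame(node = nodes, name = nm, mean = NA_real_, var = NA_real_,
                    stringsAsFactors = FALSE)
  ones <- rep(1, length(tip_idx))
  sol1 <- as.numeric(sol %*% ones)
  prec <- sum(sol1)                 # 1' C^-1 1
  mu_gls <- sum(sol1 * obs) / prec  # GLS phylogenetic mean
  centered <- obs - params$root_mean
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    cvt <- depth[M[v, tip_idx]]
    w <- as.numeric(sol %*% cvt)
    vfree <- max(depth[v] - sum(w * cvt), 0)
    if (root_prior == "fixed") {
      out$mean[i] <- params$root_mean + sum(w * centered)
      out$var[i] <- params$sigma2 * vfree
    } else {
      q <- sum(w)                   # c_v' C^-1 1
      out$mean[i] <- (1 - q) * mu_gls + sum(w * obs)
      out$var[i] <- params$sigma2 * (vfree + (1 - q) ^ 2 / prec)
    }
  }
  out
}

#' Construct a continuous node value estimate
#'
#' @param name Node display name.
#' @param samples Posterior samples of the ancestral value (months).
#' @param mass HPD credibility mass.
#' @return An object of class `node_value_estimate` with `mean`, `hpd`
#'   (lower, upper), and the raw samples.
#' @export
node_value_estimate <- function(name, samples, mass = 0.95) {
  structure(list(name = name, samples = samples, n = length(samples),
                 mean = mean(samples), hpd = hpd_interval(samples, mass)),
            class = "node_value_estimate")
}

#' @export
print.node_value_estimate <- function(x, ...) {
  cat(sprintf("Node '%s': mean %.1f, 95%% HPD (%.1f, %.1f), n = %d\n",
              x$name, x$mean, x$hpd[1], x$hpd[2], x$n))
  invisible(x)
}

#' Bayesian continuous ancestral reconstruction under Brownian motion
#'
#' Metropolis-Hastings MCMC over the diffusion rate `sigma2`
#' (uniform(0, `prior_max`) prior), the root mean (flat prior implemented as
#' uniform on (-1e6, 1e6)), and the posterior set of chronograms (uniform
#' swap proposals). At each retained sample the value of every focal node is
#' drawn from its exact Gaussian conditional given the current parameters
#' and tree, so node posteriors integrate over rate and tree uncertainty.
#'
#' @param trees A [tree_posterior()].
#' @param values Named tip values in months; `NA` taxa are pruned for the
#'   likelihood (but focal addresses are resolved on the full trees).
#' @param config An [mcmc_config()].
#' @param focal List of [node_address()] objects to reconstruct.
#' @param log_scale Analyze `log(values)`; estimates are then on the log
#'   scale (off by default: months are reported raw).
#' @return List of class `bm_trace`: `samples` data frame (sigma2, alpha,
#'   logL, tree index, node value draws), `estimates` (one
#'   [node_value_estimate()] per focal node), realized acceptance rates.
#' @export
run_bm_mcmc <- function(trees, values, config = mcmc_config(),
                        focal = list(), log_scale = FALSE) {
  stopifnot(inherits(trees, "tree_posterior"))
  if (inherits(focal, "node_address")) focal <- list(focal)
  if (log_scale) {
    if (any(values <= 0, na.rm = TRUE)) stopf("log scale needs positive values")
    values <- log(values)
  }
  ntrees <- length(trees)
  prep <- lapply(trees$trees, function(tr) {
    ob <- bm_observed(tr, values)
    if (isTRUE(ob$single)) stopf("need at least two observed taxa")
    st <- bm_prune_stats(ob$pruned, ob$obs)
    cond <- if (length(focal)) {
      # cache sigma2/alpha-free pieces: mean = alpha + sum(w (x - alpha)),
      # var = sigma2 * vfree
      depth <- ape::node.depth.edgelength(tr)
      M <- ape::mrca(tr, full = TRUE)
      tip_idx <- match(names(ob$obs), tr$tip.label)
      Ctt <- matrix(depth[M[tip_idx, tip_idx]], length(tip_idx))
      sol <- solve(Ctt)
      lapply(seq_along(focal), function(i) {
        v <- resolve_mrca(tr, focal[[i]])$node
        cvt <- depth[M[v, tip_idx]]
        w <- as.numeric(sol %*% cvt)
        list(w = w, vfree = max(depth[v] - sum(w * cvt), 0))
      })
    }
    list(st = st, stem = ob$stem, x = ob$obs, cond = cond)
  })
  obs1 <- prep[[1]]$x
  loglik <- function(j, s2, a)
    bm_loglik_from_stats(prep[[j]]$st, prep[[j]]$stem, s2, a)

  nfocal <- length(focal)
  fnames <- vapply(focal, function(a) a$name, character(1))
  nret <- config$n_retained
  upper_s <- log(config$prior_max)
  alpha_bound <- 1e6

  out <- with_seed(config$seed, {
    a <- mean(obs1)
    s2 <- min(max(var(obs1) / max(prep[[1]]$st$d_root, 1e-8), 1e-4),
              config$prior_max)
    theta <- log(s2)
    j <- sample.int(ntrees, 1L)
    ll <- loglik(j, exp(theta), a)
    w_s <- 1; w_a <- max(stats::sd(obs1), 1)
    acc <- c(s_prop = 0, s_acc = 0, a_prop = 0, a_acc = 0,
             t_prop = 0, t_acc = 0, tune_sp = 0, tune_sa = 0,
             tune_ap = 0, tune_aa = 0)
    samples <- matrix(NA_real_, nret, 4L + nfocal)
    ridx <- 0L
    for (gen in seq_len(config$generations)) {
      in_burnin <- gen <= config$burnin
      u <- runif(1)
      if (ntrees > 1L && u < config$tree_prob) {
        jp <- sample.int(ntrees, 1L)
        llp <- loglik(jp, exp(theta), a)
        if (!in_burnin) acc["t_prop"] <- acc["t_prop"] + 1
        if (log(runif(1)) < llp - ll) {
          j <- jp; ll <- llp
          if (!in_burnin) acc["t_acc"] <- acc["t_acc"] + 1
        }
      } else if (runif(1) < 0.5) {
        thp <- theta + runif(1, -w_s, w_s)
        while (thp > upper_s) thp <- 2 * upper_s - thp
        llp <- loglik(j, exp(thp), a)
        if (in_burnin) acc["tune_sp"] <- acc["tune_sp"] + 1
        else acc["s_prop"] <- acc["s_prop"] + 1
        if (log(runif(1)) < llp - ll + (thp - theta)) {
          theta <- thp; ll <- llp
          if (in_burnin) acc["tune_sa"] <- acc["tune_sa"] + 1
          else acc["s_acc"] <- acc["s_acc"] + 1
        }
      } else {
        ap <- a + runif(1, -w_a, w_a)
        while (ap > alpha_bound) ap <- 2 * alpha_bound - ap
        while (ap < -alpha_bound) ap <- -2 * alpha_bound - ap
        llp <- loglik(j, exp(theta), ap)
        if (in_burnin) acc["tune_ap"] <- acc["tune_ap"] + 1
        else acc["a_prop"] <- acc["a_prop"] + 1
        if (log(runif(1)) < llp - ll) {
          a <- ap; ll <- llp
          if (in_burnin) acc["tune_aa"] <- acc["tune_aa"] + 1
          else acc["a_acc"] <- acc["a_acc"] + 1
        }
      }
      if (in_burnin && gen %% 500 == 0) {
        if (acc["tune_sp"] > 0) {
          r <- acc["tune_sa"] / acc["tune_sp"]
          if (r > config$accept_window[2]) w_s <- w_s * 1.5
          else if (r < config$accept_window[1]) w_s <- w_s / 1.5
          acc["tune_sp"] <- 0; acc["tune_sa"] <- 0
        }
        if (acc["tune_ap"] > 0) {
          r <- acc["tune_aa"] / acc["tune_ap"]
          if (r > config$accept_window[2]) w_a <- w_a * 1.5
          else if (r < config$accept_window[1]) w_a <- w_a / 1.5
          acc["tune_ap"] <- 0; acc["tune_aa"] <- 0
        }
      }
      if (!in_burnin && (gen - config$burnin) %% config$thinning == 0) {
        ridx <- ridx + 1L
        draws <- if (nfocal) vapply(seq_len(nfocal), function(i) {
          cn <- prep[[j]]$cond[[i]]
          mu <- a + sum(cn$w * (prep[[j]]$x - a))
          rnorm(1, mu, sqrt(exp(theta) * cn$vfree))
        }, numeric(1)) else numeric(0)
        samples[ridx, ] <- c(exp(theta), a, ll, j, draws)
      }
    }
    list(samples = samples, acc = acc, w = c(sigma2 = w_s, alpha = w_a))
  })

  df <- as.data.frame(out$samples)
  names(df) <- c("sigma2", "alpha", "logL", "tree_index",
                 if (nfocal) paste0("node_", fnames))
  rate_acc <- c(
    sigma2 = if (out$acc["s_prop"] > 0) out$acc[["s_acc"]] / out$acc[["s_prop"]] else NA,
    alpha = if (out$acc["a_prop"] > 0) out$acc[["a_acc"]] / out$acc[["a_prop"]] else NA,
    tree = if (out$acc["t_prop"] > 0) out$acc[["t_acc"]] / out$acc[["t_prop"]] else NA)
  if (!is.na(rate_acc["sigma2"]) &&
      (rate_acc["sigma2"] < config$accept_window[1] ||
       rate_acc["sigma2"] > config$accept_window[2]))
    warnf("post-burnin sigma2 acceptance %.3f outside [%.2f, %.2f]",
          rate_acc["sigma2"], config$accept_window[1], config$accept_window[2])
  estimates <- if (nfocal)
    setNames(lapply(fnames, function(nm)
      node_value_estimate(nm, df[[paste0("node_", nm)]])), fnames)
  structure(list(samples = df, estimates = estimates, focal = focal,
                 acceptance = rate_acc, config = config,
                 log_scale = log_scale, proposal_windows = out$w),
            class = "bm_trace")
}

#' @export
print.bm_trace <- function(x, ...) {
  cat(sprintf("BM trace: %d samples; sigma2 mean %.3f\n",
              nrow(x$samples), mean(x$samples$sigma2)))
  for (e in x$estimates) print(e)
  invisible(x)
}
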