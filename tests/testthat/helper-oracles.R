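# Independent oracles used to validate the fast implementations.

# High-accuracy matrix exponential (scaling-and-squaring Taylor) so the
# enumeration oracle is precise to ~1e-13.
expm_series <- function(M) {
  s <- max(0, ceiling(log2(max(1, norm(M, "1")))))
  A <- M / 2 ^ s
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in 1:24) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Mk likelihood by explicit summation over all interior-node (and missing
# tip) state assignments.
enum_mk_loglik <- function(tree, tips, Q, rootfreq) {
  tr <- ape::reorder.phylo(tree, "postorder")
  K <- nrow(Q)
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)),
              function(i) expm_series(Q * tr$edge.length[i]))
  st <- tips[tr$tip.label]
  free <- c(which(is.na(st)), (ntip + 1L):nn)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), length(free)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[seq_len(ntip)] <- st
    s[free] <- unlist(grid[g, ])
    p <- rootfreq[s[ntip + 1L]]
    for (i in seq_len(nrow(tr$edge)))
      p <- p * P[[i]][s[tr$edge[i, 1L]], s[tr$edge[i, 2L]]]
    tot <- tot + p
  }
  log(tot)
}

# Exact marginal distribution of one interior node's state, by enumeration.
enum_node_marginal <- function(tree, tips, Q, rootfreq, node) {
  K <- nrow(Q)
  lls <- vapply(seq_len(K), function(s) {
    tr2 <- tree
    # enumeration with the node clamped: drop assignments not matching s
    enum_mk_loglik_clamped(tr2, tips, Q, rootfreq, node, s)
  }, numeric(1))
  p <- exp(lls - max(lls))
  p / sum(p)
}

enum_mk_loglik_clamped <- function(tree, tips, Q, rootfreq, node, state) {
  tr <- ape::reorder.phylo(tree, "postorder")
  K <- nrow(Q)
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)),
              function(i) expm_series(Q * tr$edge.length[i]))
  st <- tips[tr$tip.label]
  free <- c(which(is.na(st)), (ntip + 1L):nn)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), length(free)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[seq_len(ntip)] <- st
    s[free] <- unlist(grid[g, ])
    if (s[node] != state) next
    p <- rootfreq[s[ntip + 1L]]
    for (i in seq_len(nrow(tr$edge)))
      p <- p * P[[i]][s[tr$edge[i, 1L]], s[tr$edge[i, 2L]]]
    tot <- tot + p
  }
  log(tot)
}

# Dense multivariate-normal BM log-likelihood (shared-path covariance from
# the original root; missing taxa simply excluded).
dense_bm_loglik <- function(tree, values, sigma2, root_mean) {
  obs <- values[!is.na(values)]
  C <- ape::vcv(tree)[names(obs), names(obs)] * sigma2
  r <- obs - root_mean
  as.numeric(-0.5 * (length(obs) * log(2 * pi) +
                       determinant(C)$modulus +
                       t(r) %*% solve(C, r)))
}

# Ancestral conditionals by brute-force joint-normal conditioning with the
# dense covariance; the flat root prior is approximated by adding a huge
# shared variance tau to every entry (an independent route from the
# implementation's GLS algebra).
dense_conditional <- function(tree, values, sigma2, node, tau = 1e10) {
  obs <- values[!is.na(values)]
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  tip_idx <- match(names(obs), tree$tip.label)
  Ctt <- (matrix(depth[M[tip_idx, tip_idx]], length(tip_idx)) + tau) * sigma2
  cvt <- (depth[M[node, tip_idx]] + tau) * sigma2
  cvv <- (depth[node] + tau) * sigma2
  w <- solve(Ctt, cvt)
  list(mean = sum(w * obs), var = as.numeric(cvv - sum(w * cvt)))
}

# Brute-force HPD: scan every contiguous window of ceiling(mass n) sorted
# samples.
brute_hpd <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    lo <- xs[i]; hi <- xs[i + m - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# One verdict-recovery replicate: a study-shaped dataset with (progenesis
# arm) or without (neoteny arm) a -12-month maturation shift planted on the
# paedomorphosis branch, analyzed across that transition with the
# biphasic-clade ancestor as the uncontaminated parent reference.
verdict_recovery_arm <- function(i, shift, generations = 15000,
                                 burnin = 3000, thinning = 25) {
  base <- sim_config(seed = 500 + i)
  ds0 <- make_study_dataset(base)
  cfg <- base
  if (shift)
    cfg$planted_shifts <- list(list(trait = "male_mat_months",
                                    taxa = ds0$truth$pd_clade$taxa,
                                    offset = -12))
  ds <- make_study_dataset(cfg)
  parent <- node_address(ds$truth$biphasic_clade$taxa, "parent")
  child <- node_address(ds$truth$pd_clade$taxa, "child")
  mat6 <- state_space("maturation-6")
  tips <- tip_states(ds$traits, "male_mat_months", mat6)
  mc <- mcmc_config(generations = generations, thinning = thinning,
                    burnin = burnin, seed = 900 + i)
  swp <- suppressWarnings(
    fossilize_states(ds$posterior, tips, mat6, "one-rate", mc, parent))
  swc <- suppressWarnings(
    fossilize_states(ds$posterior, tips, mat6, "one-rate", mc, child))
  vals <- setNames(ds$traits$male_mat_months, ds$traits$taxon)
  bm <- suppressWarnings(run_bm_mcmc(
    ds$posterior, vals,
    mcmc_config(generations = generations, thinning = thinning,
                burnin = burnin, seed = 950 + i),
    focal = list(parent, child)))
  progenesis_neoteny_test(swp$lbf, swc$lbf,
                          bm$estimates$parent, bm$estimates$child,
                          transition_on_branch = TRUE, sex = "male")$verdict
}

# Short MCMC profile used across the suite (chains stay exact, just short).
quick_config <- function(seed, generations = 20000, thinning = 50,
                         burnin = 4000, ...) {
  mcmc_config(generations = generations, thinning = thinning,
              burnin = burnin, seed = seed, ...)
}

balanced_tree4 <- function() {
  ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
}
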