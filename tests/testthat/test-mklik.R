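test_that("pruning equals interior-state enumeration on small random instances", {
  set.seed(101)
  sp <- state_space("metamorph-4")
  worst <- 0
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    tr <- simulate_yule(n, depth = runif(1, 0.5, 3), seed = rep)
    kind <- sample(c("one-rate", "multi-rate"), 1)
    m <- build_rate_matrix(sp, kind, runif(if (kind == "one-rate") 1 else 6,
                                           0.05, 1.5))
    st <- setNames(sample(c(1:4, NA), n, replace = TRUE), tr$tip.label)
    if (all(is.na(st))) st[1] <- 2L
    a <- prune_log_likelihood(tr, st, m)
    b <- enum_mk_loglik(tr, st, m$Q, rep(0.25, 4))
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-10)
})

test_that("single-tip likelihoods reduce to their closed forms", {
  tr <- ape::read.tree(text = "(a:1);")
  sp <- state_space("metamorph-4")
  m <- build_rate_matrix(sp, "one-rate", 0.3)
  # symmetric generator + uniform root: marginal tip distribution is uniform
  expect_equal(prune_log_likelihood(tr, c(a = 2L), m), log(1 / 4),
               tolerance = 1e-12)
  expect_equal(prune_log_likelihood(tr, c(a = NA_integer_), m), 0)
})

test_that("likelihood is invariant to tip ordering and node rotation", {
  sp <- state_space("life-history-3")
  m <- build_rate_matrix(sp, "one-rate", 0.2)
  tr <- simulate_yule(8, seed = 21)
  st <- setNames(sample(c(1:3, NA), 8, replace = TRUE), tr$tip.label)
  st[1] <- 1L
  base <- prune_log_likelihood(tr, st, m)
  expect_equal(prune_log_likelihood(tr, st[sample(8)], m), base)
  expect_equal(prune_log_likelihood(ape::ladderize(tr), st, m), base,
               tolerance = 1e-12)
})

test_that("with one observed tip the likelihood equals the single-tip form", {
  sp <- state_space("metamorph-4")
  m <- build_rate_matrix(sp, "one-rate", 0.15)
  tr <- simulate_yule(6, depth = 2, seed = 4)
  st <- setNames(rep(NA_integer_, 6), tr$tip.label)
  st["t3"] <- 3L
  # symmetric chain + uniform root: the observed tip is marginally uniform
  expect_equal(prune_log_likelihood(tr, st, m), log(1 / 4), tolerance = 1e-12)
})

test_that("likelihoods stay finite on deep 100-tip trees (scaling works)", {
  sp <- state_space("maturation-6")
  m <- build_rate_matrix(sp, "one-rate", 2)
  tr <- simulate_yule(100, depth = 73, seed = 31)
  sim <- simulate_mk(tr, m, 3L, seed = 1)
  ll <- prune_log_likelihood(tr, sim$tip_states, m)
  expect_true(is.finite(ll))
})

test_that("ML fitting: parameter counts, nesting, and rate recovery", {
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(64, depth = 73, seed = 55)
  truth <- build_rate_matrix(sp, "one-rate", 0.05)
  sim <- simulate_mk(tr, truth, 2L, seed = 55)
  one <- fit_ml(tr, sim$tip_states, sp, "one-rate", seed = 1)
  multi <- fit_ml(tr, sim$tip_states, sp, "multi-rate", seed = 1)
  expect_equal(one$k, 1L)
  expect_equal(multi$k, 6L) # 2(K-1) with K = 4
  expect_gte(multi$logLik, one$logLik - 1e-6) # nested models
  rates <- vapply(1:20, function(s) {
    si <- simulate_mk(tr, truth, 2L, seed = s)
    fit_ml(tr, si$tip_states, sp, "one-rate", seed = s)$model$rates
  }, numeric(1))
  expect_lt(abs(log2(median(rates) / 0.05)), 1) # within a factor of 2
})

test_that("AIC comparison labels follow the published thresholds", {
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(16, depth = 10, seed = 2)
  sim <- simulate_mk(tr, build_rate_matrix(sp, "one-rate", 0.1), 2L, seed = 3)
  f1 <- fit_ml(tr, sim$tip_states, sp, "one-rate", seed = 1)
  f2 <- fit_ml(tr, sim$tip_states, sp, "multi-rate", seed = 1)
  cmp <- compare_aic(list(f1, f2))
  expect_equal(cmp$dAIC[1], 0)
  expect_true(all(cmp$dAIC >= 0))
  # threshold labels
  expect_equal(heterochron:::evidence_label(c(2.9, 3, 9.99, 10)),
               c("negligible", "moderately strong", "moderately strong",
                 "very strong"))
  # refusing to compare fits on different data
  other <- simulate_mk(tr, build_rate_matrix(sp, "one-rate", 0.1), 2L, seed = 9)
  f3 <- fit_ml(tr, other$tip_states, sp, "one-rate", seed = 1)
  expect_error(compare_aic(list(f1, f3)), "different data")
})

test_that("the generating one-rate model usually wins AIC selection", {
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(64, depth = 73, seed = 77)
  truth <- build_rate_matrix(sp, "one-rate", 0.05)
  wins <- 0
  for (s in 1:20) {
    sim <- simulate_mk(tr, truth, 2L, seed = 100 + s)
    f1 <- fit_ml(tr, sim$tip_states, sp, "one-rate", seed = s, n_starts = 3)
    f2 <- fit_ml(tr, sim$tip_states, sp, "multi-rate", seed = s, n_starts = 3)
    if (f1$AIC <= f2$AIC) wins <- wins + 1
  }
  expect_gte(wins, 15)
})

test_that("fossilization partitions the unconstrained likelihood", {
  sp <- state_space("metamorph-4")
  m <- build_rate_matrix(sp, "multi-rate", runif(6, 0.1, 1))
  tr <- simulate_yule(6, depth = 3, seed = 13)
  st <- setNames(c(1L, 2L, 2L, 3L, 4L, NA), tr$tip.label)
  full <- prune_log_likelihood(tr, st, m)
  for (node in (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)) {
    parts <- vapply(1:4, function(s)
      prune_log_likelihood(tr, st, m, fossil = list(node = node, state = s)),
      numeric(1))
    expect_equal(exp(full), sum(exp(parts)), tolerance = 1e-10)
  }
})
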