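test_that("config arithmetic: default run yields exactly 4,000 samples", {
  cfg <- mcmc_config()
  expect_equal(cfg$generations, 5e6)
  expect_equal(cfg$thinning, 1000)
  expect_equal(cfg$burnin, 1e6)
  expect_equal(cfg$n_retained, 4000L)
  expect_error(mcmc_config(generations = 1000, burnin = 2000), "burnin")
  expect_error(mcmc_config(generations = 1100, burnin = 100, thinning = 300),
               "multiple")
})

test_that("retained sample count and reproducibility of seeded runs", {
  sp <- state_space("life-history-3")
  tr <- simulate_yule(8, seed = 3)
  m <- build_rate_matrix(sp, "one-rate", 0.05)
  sim <- simulate_mk(tr, m, 2L, seed = 5)
  tp <- tree_posterior(tr)
  cfg <- quick_config(11, generations = 10000, thinning = 25, burnin = 2000)
  addr <- node_address(tr$tip.label[1:3], "X")
  t1 <- run_multistate_mcmc(tp, sim$tip_states, sp, "one-rate", cfg,
                            focal = list(addr))
  t2 <- run_multistate_mcmc(tp, sim$tip_states, sp, "one-rate", cfg,
                            focal = list(addr))
  expect_equal(nrow(t1$samples), cfg$n_retained)
  expect_identical(t1$samples, t2$samples) # bit-reproducible
})

test_that("post-burnin rate acceptance lands inside the 20-40% window", {
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(64, depth = 73, seed = 9)
  m <- build_rate_matrix(sp, "one-rate", 0.05)
  sim <- simulate_mk(tr, m, 2L, seed = 9)
  trace <- run_multistate_mcmc(tree_posterior(tr), sim$tip_states, sp,
                               "one-rate",
                               quick_config(4, generations = 40000,
                                            thinning = 100, burnin = 10000))
  expect_gte(trace$acceptance[["rate"]], 0.2)
  expect_lte(trace$acceptance[["rate"]], 0.4)
})

test_that("root of a symmetric two-tip problem is a coin flip", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  sp <- state_space("custom", labels = c("s1", "s2"))
  tp <- tree_posterior(tr)
  tips <- c(a = 1L, b = 2L)
  addr <- node_address(c("a", "b"), "root")
  trace <- run_multistate_mcmc(tp, tips, sp, "one-rate",
                               quick_config(2, generations = 24000,
                                            thinning = 20, burnin = 4000),
                               focal = list(addr))
  est <- node_state_probabilities(trace, "root")
  expect_equal(sum(est$probs), 1)
  mc_se <- sqrt(0.25 / est$n)
  expect_lt(abs(est$probs[["s1"]] - 0.5), 3 * mc_se + 0.01)
})

test_that("sampled node states match exact conditional marginals (fixed tree, fixed rates)", {
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(5, depth = 2, seed = 17)
  m <- build_rate_matrix(sp, "one-rate", 0.4)
  tips <- setNames(c(1L, 2L, 4L, 3L, NA), tr$tip.label)
  node <- ape::Ntip(tr) + 1L # the root
  addr <- node_address(tr$tip.label, "root")
  trace <- run_multistate_mcmc(tree_posterior(tr), tips, sp, "one-rate",
                               quick_config(6, generations = 42000,
                                            thinning = 20, burnin = 2000),
                               focal = list(addr), fix_rates = 0.4)
  est <- node_state_probabilities(trace, "root")
  exact <- enum_node_marginal(tr, tips, m$Q, rep(0.25, 4), node)
  for (s in 1:4) {
    se <- sqrt(max(exact[s] * (1 - exact[s]), 1e-4) / est$n)
    expect_lt(abs(est$probs[[s]] - exact[s]), 3 * se + 0.005)
  }
})

test_that("fossilizing the supported state wins; an unsupported state loses badly", {
  sp <- state_space("life-history-3")
  tr <- simulate_yule(10, depth = 1, seed = 23)
  tp <- tree_posterior(tr)
  tips <- setNames(rep(1L, 10), tr$tip.label) # every tip direct-developing
  addr <- node_address(tr$tip.label, "root")
  cfg <- quick_config(8, generations = 12000, thinning = 20, burnin = 2000)
  # constrained chains can sit outside the acceptance window; that warning
  # is expected here
  sweep <- suppressWarnings(fossilize_states(tp, tips, sp, "one-rate", cfg, addr))
  expect_equal(attr(sweep$lbf, "best"), "DD")
  expect_equal(sweep$lbf$lbf[sweep$lbf$state == "DD"], 0)
  expect_gte(sweep$lbf$lbf[sweep$lbf$state == "PD"], 3)
  # table ordering consistency: lbf is monotone decreasing in hm
  expect_equal(order(sweep$lbf$hm), order(-sweep$lbf$lbf))
})

test_that("with a flat likelihood the rate posterior reproduces its uniform prior", {
  # one observed tip in a symmetric one-rate chain with uniform root: the
  # likelihood is 1/K for every rate, so the chain must sample the prior
  sp <- state_space("metamorph-4")
  tr <- simulate_yule(6, depth = 2, seed = 31)
  tips <- setNames(c(2L, rep(NA_integer_, 5)), tr$tip.label)
  trace <- run_multistate_mcmc(tree_posterior(tr), tips, sp, "one-rate",
                               mcmc_config(generations = 302000, thinning = 300,
                                           burnin = 2000, seed = 12))
  expect_equal(nrow(trace$samples), 1000L)
  ks <- suppressWarnings(stats::ks.test(trace$samples$rate, "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
  expect_equal(trace$samples$logL, rep(log(1 / 4), 1000L), tolerance = 1e-9)
})

test_that("stepping stone and harmonic mean agree on an analytic case", {
  # constant likelihood 1/K: the marginal likelihood is exactly 1/K
  sp <- state_space("life-history-3")
  tr <- simulate_yule(4, depth = 2, seed = 37)
  tp <- tree_posterior(tr)
  tips <- setNames(c(1L, NA, NA, NA), tr$tip.label)
  cfg <- quick_config(3, generations = 6000, thinning = 20, burnin = 2000)
  ss <- stepping_stone_log_marginal(tp, tips, sp, "one-rate", cfg, n_rungs = 4)
  expect_equal(ss, log(1 / 3), tolerance = 1e-9)
  trace <- run_multistate_mcmc(tp, tips, sp, "one-rate", cfg)
  expect_equal(harmonic_mean(trace$samples$logL), log(1 / 3), tolerance = 1e-9)
})

test_that("a constraint with zero likelihood on every tree is rejected", {
  # with the rate fixed at 0 the chain cannot leave the tip states, so
  # fossilizing the root away from the tips' shared state is impossible
  sp <- state_space("life-history-3")
  tr <- balanced_tree4()
  tips <- c(a = 1L, b = 1L, c = 1L, d = 1L)
  cfg <- quick_config(5, generations = 4000, thinning = 20, burnin = 2000)
  expect_error(
    run_multistate_mcmc(tree_posterior(tr), tips, sp, "one-rate", cfg,
                        constraint = list(address = node_address(c("a", "d")),
                                          state = 3L),
                        fix_rates = 0),
    "zero likelihood")
})
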