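test_that("Yule simulator: tip counts, ultrametry, determinism", {
  tr <- simulate_yule(63, seed = 2)
  expect_equal(ape::Ntip(tr), 63L)
  v <- validate_chronogram(tr)
  expect_true(v$pass)
  expect_equal(v$root_depth, 73, tolerance = 1e-9)
  expect_identical(ape::write.tree(simulate_yule(20, seed = 9)),
                   ape::write.tree(simulate_yule(20, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_yule(20, seed = 9)),
                         ape::write.tree(simulate_yule(20, seed = 10))))
})

test_that("unscaled Yule root depth matches waiting-time theory", {
  # E[depth] = sum_{k=2}^{n} 1/(lambda k) when sampling at the (n+1)-th birth
  set.seed(99)
  n <- 10; lambda <- 1
  depths <- vapply(1:500, function(i)
    max(ape::node.depth.edgelength(simulate_yule(n, lambda, depth = NULL))),
    numeric(1))
  expected <- sum(1 / (lambda * 2:n))
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("Mk simulation: zero rate freezes, jumps respect adjacency", {
  sp <- state_space("maturation-6")
  tr <- simulate_yule(12, depth = 5, seed = 3)
  frozen <- simulate_mk(tr, build_rate_matrix(sp, "one-rate", 0), 4L, seed = 1)
  expect_true(all(frozen$tip_states == 4L))
  expect_equal(nrow(frozen$events), 0L)
  busy <- simulate_mk(tr, build_rate_matrix(sp, "one-rate", 1.5), 3L, seed = 2)
  expect_gt(nrow(busy$events), 0L)
  expect_true(all(abs(busy$events$from - busy$events$to) == 1L))
})

test_that("single-branch end-state frequencies match the matrix exponential", {
  sp <- state_space("metamorph-4")
  m <- build_rate_matrix(sp, "one-rate", 0.3)
  tr <- ape::read.tree(text = "(a:1,b:0);") # one branch of length 1
  ends <- vapply(1:20000, function(i)
    simulate_mk(tr, m, 2L, seed = i)$tip_states[["a"]], integer(1))
  freq <- tabulate(ends, nbins = 4) / length(ends)
  expected <- transition_probabilities(m, 1)[2, ]
  for (s in 1:4) {
    bound <- 2.58 * sqrt(expected[s] * (1 - expected[s]) / length(ends))
    expect_lt(abs(freq[s] - expected[s]), bound + 0.004)
  }
})

test_that("BM simulation obeys the variance and covariance laws", {
  star <- ape::multi2di(ape::read.tree(text = "(a:4,b:4,c:4,d:4);"),
                        random = FALSE)
  p <- bm_params(1.5, 0)
  reps <- vapply(1:2000, function(i)
    simulate_bm(star, p, seed = i)$tip_values[["a"]], numeric(1))
  v <- stats::var(reps)
  se <- v * sqrt(2 / (length(reps) - 1))
  expect_lt(abs(v - 1.5 * 4), 3 * se)

  sisters <- ape::read.tree(text = "((a:1,b:1):3,c:4);")
  pair <- vapply(1:2000, function(i) {
    tv <- simulate_bm(sisters, p, seed = 10000 + i)$tip_values
    c(tv[["a"]], tv[["b"]])
  }, numeric(2))
  cv <- stats::cov(pair[1, ], pair[2, ])
  expect_lt(abs(cv - 1.5 * 3), 0.5) # shared path length 3
})

test_that("ground-truth node values are consistent with the emitted tips", {
  tr <- simulate_yule(10, depth = 5, seed = 7)
  sim <- simulate_bm(tr, bm_params(2, 10), seed = 7)
  # re-simulating from a recorded interior node's value reproduces the
  # subtree root exactly: check parent-child increments have the right scale
  tr2 <- ape::reorder.phylo(tr, "cladewise")
  all_vals <- c(sim$tip_values[tr2$tip.label], sim$node_values)
  inc <- (all_vals[tr2$edge[, 2]] - all_vals[tr2$edge[, 1]]) /
    sqrt(pmax(tr2$edge.length, 1e-12))
  expect_lt(abs(stats::sd(inc) - sqrt(2)), 0.5)
})

test_that("jittered pseudo-posteriors keep topology and ultrametry", {
  tr <- simulate_yule(15, seed = 12)
  tp0 <- jitter_tree_posterior(tr, 5, sd = 0, seed = 1)
  for (cp in tp0$trees)
    expect_equal(cp$edge.length, tr$edge.length, tolerance = 1e-12)
  tp <- jitter_tree_posterior(tr, 8, sd = 0.1, seed = 4)
  expect_length(tp, 8)
  for (cp in tp$trees) {
    expect_true(ape::all.equal.phylo(cp, tr, use.edge.length = FALSE))
    expect_true(validate_chronogram(cp, tolerance = 1e-8)$pass)
  }
  expect_false(isTRUE(all.equal(tp$trees[[1]]$edge.length,
                                tp$trees[[2]]$edge.length)))
})

test_that("study-shaped datasets encode the design conventions", {
  ds <- make_study_dataset(sim_config(seed = 21, n_posterior = 3))
  tt <- ds$traits
  expect_equal(nrow(tt), 63L)
  expect_true(all(is.na(tt$metamorph_months[tt$life_history == "PD"])))
  expect_true(all(tt$metamorph_months[tt$life_history == "DD"] == 2))
  expect_false(any(is.na(tt$male_mat_months)))
  # the paedomorphic taxa form a clade nested in the biphasic clade
  pd <- ds$truth$pd_clade
  expect_true(resolve_mrca(ds$tree, node_address(pd$taxa, "pd"))$monophyletic)
  expect_true(all(pd$taxa %in% ds$truth$biphasic_clade$taxa))
  expect_length(ds$posterior, 3)
  # same seed, same dataset
  ds2 <- make_study_dataset(sim_config(seed = 21, n_posterior = 3))
  expect_identical(ds$traits, ds2$traits)
  expect_identical(ape::write.tree(ds$tree), ape::write.tree(ds2$tree))
})

test_that("planted shifts are applied to the emitted tip values", {
  base <- make_study_dataset(sim_config(seed = 31))
  clade <- base$truth$pd_clade$taxa
  shifted <- make_study_dataset(
    sim_config(seed = 31,
               planted_shifts = list(list(trait = "male_mat_months",
                                          taxa = clade, offset = -12))))
  delta <- shifted$traits$male_mat_months - base$traits$male_mat_months
  names(delta) <- base$traits$taxon
  expect_true(all(delta[clade] <= 0))
  expect_true(all(delta[setdiff(base$traits$taxon, clade)] == 0))
  expect_error(make_study_dataset(
    sim_config(seed = 31,
               planted_shifts = list(list(trait = "male_mat_months",
                                          taxa = "not_a_tip", offset = -12)))),
    "not_a_tip")
})

test_that("explicitly requested non-clade taxa trigger the bounded retry error", {
  tr <- make_study_dataset(sim_config(seed = 41))$tree
  # two tips that are almost surely not sisters across every retry
  expect_error(
    make_study_dataset(sim_config(seed = 41, n_taxa = 40,
                                  pd_taxa = c("t1", "t40"),
                                  biphasic_taxa = NULL, max_retries = 3)),
    "did not form clades")
})
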