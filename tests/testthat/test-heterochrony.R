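ref_estimate <- function(lo = 7.1, hi = 25.1, name = "A") {
  # synthetic posterior samples whose 95% HPD is approximately (lo, hi)
  set.seed(1)
  x <- runif(4000, lo, hi)
  x[1:2] <- c(lo, hi)
  node_value_estimate(name, x)
}

test_that("tip classification against an ancestral HPD follows the rule", {
  ref <- ref_estimate()
  expect_equal(classify_tip(36, ref)$call, "decelerated")
  expect_equal(classify_tip(5, ref)$call, "accelerated")
  expect_equal(classify_tip(16, ref)$call, "stasis")
  # boundary ages are conservatively stasis
  expect_equal(classify_tip(ref$hpd[1], ref)$call, "stasis")
  expect_equal(classify_tip(ref$hpd[2], ref)$call, "stasis")
  expect_error(classify_tip(NA, ref), "missing")
})

test_that("classification partitions the age axis monotonically", {
  ref <- ref_estimate()
  ages <- seq(0, 60, by = 0.5)
  calls <- vapply(ages, function(a) classify_tip(a, ref)$call, character(1))
  expect_true(all(calls %in% c("accelerated", "stasis", "decelerated")))
  rank <- c(accelerated = 1, stasis = 2, decelerated = 3)
  expect_true(all(diff(rank[calls]) >= 0)) # raising age never moves left
})

test_that("classify_all counts categories and skips missing ages", {
  ref <- ref_estimate()
  traits <- data.frame(
    taxon = c("slow", "fast", "mid", "pd"),
    life_history = c("BI", "BI", "BI", "PD"),
    metamorph_months = c(40, 3, 16, NA),
    male_mat_months = 1:4, female_mat_months = 1:4)
  res <- suppressMessages(classify_all(traits, "metamorph_months", ref))
  expect_equal(nrow(res$calls), 3L)
  expect_equal(unname(res$counts[c("accelerated", "stasis", "decelerated")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(res$skipped, "pd")
  all_in <- traits[traits$taxon != "slow" & !is.na(traits$metamorph_months), ]
  all_in$metamorph_months <- c(10, 16)
  expect_true(all(suppressMessages(
    classify_all(all_in, "metamorph_months", ref))$calls$call == "stasis"))
})

make_est <- function(name, probs, taxa = NULL)
  node_state_estimate(name, probs, n = 1000, taxa = taxa)

test_that("transition localization flags modal-state changes along the path", {
  lab <- c(DD = 0, BI = 0, PD = 0)
  est <- list(
    make_est("C", c(DD = 0.0, BI = 0.75, PD = 0.25), taxa = letters[1:6]),
    make_est("D", c(DD = 0.0, BI = 0.00, PD = 1.00), taxa = letters[1:3]))
  loc <- localize_transition(est)
  expect_equal(nrow(loc$flagged), 1L)
  expect_equal(loc$flagged$parent, "C")
  expect_equal(loc$flagged$child, "D")
  expect_equal(loc$flagged$to, "PD")

  flat <- list(make_est("A", c(DD = 0.1, BI = 0.8, PD = 0.1)),
               make_est("B", c(DD = 0.2, BI = 0.7, PD = 0.1)))
  expect_equal(nrow(localize_transition(flat)$flagged), 0L)

  two <- list(make_est("A", c(DD = 0.9, BI = 0.1, PD = 0)),
              make_est("B", c(DD = 0.2, BI = 0.7, PD = 0.1)),
              make_est("C", c(DD = 0.0, BI = 0.2, PD = 0.8)))
  expect_equal(nrow(localize_transition(two)$flagged), 2L)

  bad <- list(make_est("A", c(DD = 1, BI = 0, PD = 0), taxa = c("a", "b")),
              make_est("B", c(DD = 1, BI = 0, PD = 0), taxa = c("a", "z")))
  expect_error(localize_transition(bad), "not nested")
})

cat6 <- function(hms) {
  names(hms) <- c("0-11", "12-23", "24-35", "36-47", "48-59", "60+")
  lbf_table(hms)
}
cont <- function(name, center, half) {
  set.seed(5)
  node_value_estimate(name, c(center - half, center + half,
                              runif(998, center - half, center + half)))
}

test_that("progenesis requires a real maturation drop across the branch", {
  # categorical prong: child best category younger, parent's best rejected
  parent <- cat6(c(-101, -100.2, -100.0, -104, -110, -112)) # best 24-35
  child <- cat6(c(-100.0, -103.2, -106, -110, -112, -112))  # best 0-11
  v <- progenesis_neoteny_test(parent, child,
                               cont("C", 28, 6), cont("D", 20, 6),
                               transition_on_branch = TRUE, sex = "male")
  expect_equal(v$verdict, "progenesis")
  expect_true(v$prong_categorical)

  # continuous prong alone: disjoint HPDs, child younger
  same_cat <- cat6(c(-100.0, -100.5, -103, -108, -111, -112))
  v2 <- progenesis_neoteny_test(same_cat, same_cat,
                                cont("C", 30, 3), cont("D", 15, 3),
                                transition_on_branch = TRUE, sex = "female")
  expect_equal(v2$verdict, "progenesis")
  expect_false(v2$prong_categorical)
  expect_true(v2$prong_continuous)
})

test_that("flat maturation across the transition is neoteny", {
  flat <- cat6(c(-100.0, -100.6, -103, -108, -111, -112))
  v <- progenesis_neoteny_test(flat, flat, cont("C", 16, 6), cont("D", 15, 6),
                               transition_on_branch = TRUE, sex = "male")
  expect_equal(v$verdict, "neoteny")

  # published-style evidence: ~1 month decrease, overlapping HPDs,
  # best category unchanged -> neoteny
  parent <- cat6(c(-100.58, -101.17, -104.83, -111.80, -112.65, -112.73))
  child <- cat6(c(-100.58, -102.10, -108.61, -112.55, -112.769, -112.79))
  v2 <- progenesis_neoteny_test(parent, child,
                                cont("C", 15.8, 8), cont("D", 14.8, 8),
                                transition_on_branch = TRUE, sex = "male")
  expect_equal(v2$verdict, "neoteny")
  expect_false(v2$prong_categorical)
  expect_false(v2$prong_continuous)
})

test_that("without the transition on the branch the verdict is ambiguous", {
  flat <- cat6(c(-100.0, -100.6, -103, -108, -111, -112))
  v <- progenesis_neoteny_test(flat, flat, cont("B", 16, 6), cont("C", 15, 6),
                               transition_on_branch = FALSE)
  expect_equal(v$verdict, "ambiguous")
})

test_that("a categorical increase can never trigger the categorical prong", {
  older <- cat6(c(-104, -100.0, -101, -108, -111, -112))  # best 12-23
  oldest <- cat6(c(-108, -104, -100.0, -106, -111, -112)) # best 24-35
  v <- progenesis_neoteny_test(older, oldest, cont("C", 18, 6), cont("D", 26, 6),
                               transition_on_branch = TRUE)
  expect_equal(v$verdict, "neoteny")
  expect_false(v$prong_categorical)
})
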