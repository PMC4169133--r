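#' Simulate a Yule (pure-birth) chronogram
#'
#' Gillespie simulation of the Yule process: starting from the root split,
#' each of the `k` extant lineages splits at rate `birth`; the tree is
#' sampled at the moment the `(n+1)`-th lineage would have been born, so
#' the expected unscaled root depth is `sum_{k=2}^{n} 1/(birth k)`.
#' The result is ultrametric and, when `depth` is given, rescaled to that
#' root depth (default 73 time units, a plausible crown age in Myr for the
#' salamander clades this emulates, keeping simulated rates on an
#' empirically sensible scale).
#'
#' @param n Number of tips (`>= 2`).
#' @param birth Speciation rate (`> 0`).
#' @param depth Target root depth after rescaling; `NULL` keeps the
#'   simulated depth.
#' @param seed Integer seed; same seed, same Newick string.
#' @return A `phylo` chronogram with tips `t1..tn`.
#' @export
simulate_yule <- function(n, birth = 1, depth = 73, seed = NULL) {
  if (n < 2L) stopf("need at least two tips")
  if (birth <= 0) stopf("birth rate must be positive")
  with_seed(seed, {
    nmax <- 2L * n - 2L
    parent <- integer(nmax); t_start <- numeric(nmax); t_end <- numeric(nmax)
    nl <- 2L; alive <- c(1L, 2L); t <- 0
    while (length(alive) < n) {
      k <- length(alive)
      t <- t + rexp(1, birth * k)
      i <- alive[sample.int(k, 1L)]
      t_end[i] <- t
      c1 <- nl + 1L; c2 <- nl + 2L
      parent[c(c1, c2)] <- i
      t_start[c(c1, c2)] <- t
      nl <- nl + 2L
      alive <- c(alive[alive != i], c1, c2)
    }
    t <- t + rexp(1, birth * n)
    t_end[alive] <- t

    tips <- sort(alive)
    internal <- setdiff(seq_len(nl), tips)
    internal <- internal[order(t_end[internal])] # parents split before children
    node_id <- integer(nl)
    node_id[tips] <- seq_len(n)
    node_id[internal] <- n + 1L + seq_along(internal)
    edge <- matrix(0L, nl, 2L)
    for (i in seq_len(nl)) {
      edge[i, 1L] <- if (parent[i] == 0L) n + 1L else node_id[parent[i]]
      edge[i, 2L] <- node_id[i]
    }
    el <- t_end[seq_len(nl)] - t_start[seq_len(nl)]
    phy <- structure(list(edge = edge, edge.length = el,
                          tip.label = paste0("t", seq_len(n)),
                          Nnode = n - 1L),
                     class = "phylo")
    phy <- ape::reorder.phylo(phy, "cladewise")
    if (!is.null(depth)) phy$edge.length <- phy$edge.length * depth / t
    phy
  })
}

#' Simulate an ordered discrete trait along a chronogram
#'
#' Gillespie simulation of the continuous-time chain of a [build_rate_matrix()] model down
#' every branch, recording each internal node's state and the full jump
#' log. Because the generator carries structural zeros, every recorded jump
#' is between numerically adjacent categories.
#'
#' @param tree A `phylo` chronogram.
#' @param model A [build_rate_matrix()] model.
#' @param root_state 1-based root state index.
#' @param seed Integer seed.
#' @return List with `tip_states` (named), `node_states` (by ape node id),
#'   and `events` data frame (edge, time along branch, from, to).
#' @export
simulate_mk <- function(tree, model, root_state, seed = NULL) {
  stopifnot(inherits(model, "rate_model"))
  K <- model$space$K
  root_state <- match_state(root_state, model$space)
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- ape::Ntip(tr)
    state <- integer(ntip + tr$Nnode)
    state[ntip + 1L] <- root_state
    ev <- list()
    for (i in seq_len(nrow(tr$edge))) {
      s <- state[tr$edge[i, 1L]]
      len <- tr$edge.length[i]
      pos <- 0
      repeat {
        rate <- -model$Q[s, s]
        if (rate <= 0) break
        pos <- pos + rexp(1, rate)
        if (pos >= len) break
        probs <- model$Q[s, ]; probs[s] <- 0
        s_new <- sample.int(K, 1L, prob = probs)
        ev[[length(ev) + 1L]] <- c(i, pos, s, s_new)
        s <- s_new
      }
      state[tr$edge[i, 2L]] <- s
    }
    events <- if (length(ev)) {
      m <- do.call(rbind, ev)
      data.frame(edge = as.integer(m[, 1]), time = m[, 2],
                 from = as.integer(m[, 3]), to = as.integer(m[, 4]))
    } else data.frame(edge = integer(0), time = numeric(0),
                      from = integer(0), to = integer(0))
    list(tip_states = setNames(state[seq_len(ntip)], tr$tip.label),
         node_states = setNames(state[(ntip + 1L):(ntip + tr$Nnode)],
                                (ntip + 1L):(ntip + tr$Nnode)),
         events = events)
  })
}

#' Simulate a continuous trait under Brownian motion
#'
#' Recursive Gaussian increments from the root: each branch adds
#' `Normal(0, sigma2 * length)`.
#'
#' @param tree A `phylo` chronogram.
#' @param params A [bm_params()].
#' @param seed Integer seed.
#' @return List with `tip_values` (named) and `node_values` (by ape node id).
#' @export
simulate_bm <- function(tree, params, seed = NULL) {
  stopifnot(inherits(params, "bm_params"))
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- ape::Ntip(tr)
    val <- numeric(ntip + tr$Nnode)
    val[ntip + 1L] <- params$root_mean
    for (i in seq_len(nrow(tr$edge))) {
      val[tr$edge[i, 2L]] <- val[tr$edge[i, 1L]] +
        rnorm(1, 0, sqrt(params$sigma2 * tr$edge.length[i]))
    }
    list(tip_values = setNames(val[seq_len(ntip)], tr$tip.label),
         node_values = setNames(val[(ntip + 1L):(ntip + tr$Nnode)],
                                (ntip + 1L):(ntip + tr$Nnode)))
  })
}

#' Jitter a chronogram into a pseudo-posterior
#'
#' Stand-in for a Bayesian posterior tree sample: `n` copies of one
#' chronogram whose internal node ages are perturbed by lognormal noise and
#' re-straightened to exact ultrametry (ages are made monotone along every
#' root-to-tip path). Topology is never changed; only branch-length
#' uncertainty is emulated.
#'
#' @param tree A `phylo` chronogram.
#' @param n Number of copies.
#' @param sd Lognormal sdlog of the age perturbation; 0 gives identical
#'   copies.
#' @param seed Integer seed.
#' @return A [tree_posterior()].
#' @export
jitter_tree_posterior <- function(tree, n, sd = 0.05, seed = NULL) {
  if (sd < 0) stopf("sd must be >= 0")
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  depth <- ape::node.depth.edgelength(tr)
  ages <- max(depth[seq_len(ntip)]) - depth
  ages[seq_len(ntip)] <- 0
  post_edges <- ape::reorder.phylo(tr, "postorder")$edge
  copies <- with_seed(seed, lapply(seq_len(n), function(i) {
    a <- ages
    if (sd > 0) {
      idx <- (ntip + 1L):nn
      a[idx] <- a[idx] * exp(rnorm(length(idx), 0, sd))
      for (j in seq_len(nrow(post_edges))) {
        par <- post_edges[j, 1L]; ch <- post_edges[j, 2L]
        if (a[par] < a[ch]) a[par] <- a[ch]
      }
    }
    out <- tr
    out$edge.length <- a[tr$edge[, 1L]] - a[tr$edge[, 2L]]
    out
  }))
  tree_posterior(copies, source = sprintf("jittered pseudo-posterior (sd = %g)", sd))
}

#' Configuration for a study-shaped synthetic dataset
#'
#' Defaults emulate the empirical design this package targets: a 63-taxon
#' chronogram of depth 73 scaled time units with a biphasic clade of about
#' 26 taxa containing a paedomorphic subclade of about 8; direct developers
#' metamorphose at about 2 months (within the egg); paedomorphic taxa have
#' missing metamorphic age; metamorphic and maturation ages evolve under
#' Brownian motion.
#'
#' @param n_taxa Number of tips.
#' @param birth Yule speciation rate.
#' @param depth Root depth (time units).
#' @param biphasic_clade_size,pd_clade_size Target clade sizes used when
#'   explicit taxa are not supplied.
#' @param biphasic_taxa,pd_taxa Optional explicit taxon sets; each must be
#'   a clade of the simulated tree (resimulated up to `max_retries` times,
#'   then an error).
#' @param metamorph,maturation Lists with `root` (months) and `sigma2`
#'   (months^2 per time unit) for the two Brownian traits.
#' @param dd_metamorph_months Metamorphic age assigned to direct developers.
#' @param min_age Lower clamp (months) keeping simulated ages positive.
#' @param planted_shifts List of `list(trait =, taxa =, offset =)` entries:
#'   `offset` months added to `trait` for every listed taxon (taxa must
#'   resolve to tips of the tree).
#' @param n_posterior Number of jittered pseudo-posterior trees (1 = the
#'   true tree only).
#' @param jitter_sd Lognormal age-jitter sdlog for the pseudo-posterior.
#' @param seed Global seed; all stage seeds derive from it.
#' @param max_retries Resimulation attempts when requested taxa are not a
#'   clade.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 63, birth = 1, depth = 73,
                       biphasic_clade_size = 26, pd_clade_size = 8,
                       biphasic_taxa = NULL, pd_taxa = NULL,
                       metamorph = list(root = 8, sigma2 = 2),
                       maturation = list(root = 30, sigma2 = 1.5),
                       dd_metamorph_months = 2, min_age = 0.5,
                       planted_shifts = list(),
                       n_posterior = 1, jitter_sd = 0.05,
                       seed = 1L, max_retries = 20L) {
  stopifnot(n_taxa >= 4, birth > 0, depth > 0,
            metamorph$sigma2 >= 0, maturation$sigma2 >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Find a clade of approximately a given size
#'
#' Returns the non-root internal node of `tree` whose tip count is closest
#' to `target`, optionally restricted to clades nested within a taxon set
#' and to fewer than `upper` tips. Useful for constructing [node_address()]
#' fixtures and planted-shift taxon sets on simulated trees.
#'
#' @param tree A `phylo`.
#' @param target Desired clade size.
#' @param within Optional taxon superset the clade must fall inside.
#' @param upper Exclusive upper bound on clade size.
#' @return List with `node` (ape id) and `taxa`.
#' @export
find_clade <- function(tree, target, within = NULL, upper = Inf) {
  ntip <- ape::Ntip(tree)
  nodes <- seq.int(ntip + 2L, ntip + tree$Nnode) # exclude the root
  best <- NULL; best_d <- Inf
  for (v in nodes) {
    taxa <- clade_tips(tree, v)
    sz <- length(taxa)
    if (sz < 2L || sz >= upper) next
    if (!is.null(within) && !all(taxa %in% within)) next
    d <- abs(sz - target)
    if (d < best_d) { best <- list(node = v, taxa = taxa); best_d <- d }
  }
  if (is.null(best)) stopf("no suitable clade of about %d tips found", target)
  best
}

#' Generate a full study-shaped synthetic dataset
#'
#' One seeded call produces a chronogram (optionally a jittered
#' pseudo-posterior), a trait table in the format the pipeline consumes,
#' and the complete ground truth (interior-node trait values, true
#' parameters, clade assignments, planted shifts).
#'
#' Life-history states are assigned structurally so the transition to
#' paedomorphosis sits on a known branch: tips of the paedomorphic subclade
#' are `PD` (metamorphic age set missing), the rest of the biphasic clade
#' `BI`, and everything else `DD` (metamorphic age about 2 months).
#' Metamorphic and maturation ages evolve under Brownian motion; male and
#' female maturation are independent replicates of the same process.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_dataset`: `tree`, `posterior`,
#'   `traits`, and `truth`.
#' @export
make_study_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    tree <- simulate_yule(cfg$n_taxa, cfg$birth, cfg$depth,
                          seed = derive_seed(cfg$seed, paste0("tree", attempt)))
    ok <- TRUE
    if (!is.null(cfg$biphasic_taxa)) {
      res <- resolve_mrca(tree, node_address(cfg$biphasic_taxa, "biphasic"))
      if (!res$monophyletic) ok <- FALSE
      bi <- list(node = res$node, taxa = cfg$biphasic_taxa)
    } else {
      bi <- find_clade(tree, cfg$biphasic_clade_size, upper = cfg$n_taxa - 1L)
    }
    if (ok) {
      if (!is.null(cfg$pd_taxa)) {
        res <- resolve_mrca(tree, node_address(cfg$pd_taxa, "paedomorphic"))
        if (!res$monophyletic || !all(cfg$pd_taxa %in% bi$taxa)) ok <- FALSE
        pd <- list(node = res$node, taxa = cfg$pd_taxa)
      } else {
        pd <- find_clade(tree, cfg$pd_clade_size, within = bi$taxa,
                         upper = length(bi$taxa))
      }
    }
    if (ok) break
    if (attempt >= cfg$max_retries)
      stopf("requested taxa did not form clades in %d simulated trees", attempt)
  }

  lh <- setNames(rep("DD", cfg$n_taxa), tree$tip.label)
  lh[bi$taxa] <- "BI"
  lh[pd$taxa] <- "PD"

  meta_sim <- simulate_bm(tree,
                          bm_params(cfg$metamorph$sigma2, cfg$metamorph$root),
                          seed = derive_seed(cfg$seed, "metamorph"))
  male_sim <- simulate_bm(tree,
                          bm_params(cfg$maturation$sigma2, cfg$maturation$root),
                          seed = derive_seed(cfg$seed, "male"))
  female_sim <- simulate_bm(tree,
                            bm_params(cfg$maturation$sigma2, cfg$maturation$root),
                            seed = derive_seed(cfg$seed, "female"))
  clamp <- function(x) pmax(x, cfg$min_age)
  meta <- clamp(meta_sim$tip_values)
  male <- clamp(male_sim$tip_values)
  female <- clamp(female_sim$tip_values)

  meta[lh == "DD"] <- cfg$dd_metamorph_months

  shifts <- cfg$planted_shifts
  cols <- list(metamorph_months = "meta", male_mat_months = "male",
               female_mat_months = "female")
  for (s in shifts) {
    if (!s$trait %in% names(cols)) stopf("unknown shift trait '%s'", s$trait)
    absent <- setdiff(s$taxa, tree$tip.label)
    if (length(absent))
      stopf("planted-shift taxa not in tree: %s", paste(absent, collapse = ", "))
    v <- get(cols[[s$trait]])
    v[s$taxa] <- clamp(v[s$taxa] + s$offset)
    assign(cols[[s$trait]], v)
  }
  meta[lh == "PD"] <- NA_real_

  traits <- data.frame(taxon = tree$tip.label,
                       life_history = unname(lh),
                       metamorph_months = unname(meta[tree$tip.label]),
                       male_mat_months = unname(male[tree$tip.label]),
                       female_mat_months = unname(female[tree$tip.label]),
                       stringsAsFactors = FALSE)

  posterior <- if (cfg$n_posterior > 1L)
    jitter_tree_posterior(tree, cfg$n_posterior, cfg$jitter_sd,
                          seed = derive_seed(cfg$seed, "posterior"))
  else tree_posterior(tree, source = "simulated chronogram")

  ntip <- ape::Ntip(tree)
  node_lh <- setNames(rep("DD", tree$Nnode), (ntip + 1L):(ntip + tree$Nnode))
  in_clade <- function(node) {
    v <- names(node_lh)[vapply(as.integer(names(node_lh)), function(u)
      all(clade_tips(tree, u) %in% clade_tips(tree, node)), logical(1))]
    v
  }
  node_lh[in_clade(bi$node)] <- "BI"
  node_lh[in_clade(pd$node)] <- "PD"

  # the branch on which the biphasic -> paedomorphic transition is planted
  # runs from the pd clade's immediate parent node to the pd clade MRCA
  pd_parent_node <- tree$edge[tree$edge[, 2L] == pd$node, 1L]
  truth <- list(params = list(metamorph = cfg$metamorph,
                              maturation = cfg$maturation),
                transition_parent = list(node = pd_parent_node,
                                         taxa = clade_tips(tree, pd_parent_node)),
                node_values = list(metamorph = meta_sim$node_values,
                                   male = male_sim$node_values,
                                   female = female_sim$node_values),
                node_life_history = node_lh,
                biphasic_clade = bi, pd_clade = pd,
                transition_branch = c(parent = "biphasic", child = "paedomorphic"),
                planted_shifts = shifts)
  structure(list(tree = tree, posterior = posterior, traits = traits,
                 truth = truth, config = cfg),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d taxa (BI clade %d, PD subclade %d), %d tree(s)\n",
    nrow(x$traits), length(x$truth$biphasic_clade$taxa),
    length(x$truth$pd_clade$taxa), length(x$posterior)))
  invisible(x)
}
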