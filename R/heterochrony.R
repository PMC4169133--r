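#' Classify one tip against an ancestral credibility interval
#'
#' Polarity rule for developmental timing: a tip age above the ancestral
#' 95% HPD is a deceleration, below it an acceleration, and inside it
#' stasis (more precisely "stasis/undetected": a shift too small for this
#' method to resolve). Ages exactly on an endpoint are conservatively
#' called stasis -- a shift must be strictly outside the interval.
#'
#' @param age Observed minimum age in months (not `NA`).
#' @param reference A [node_value_estimate()] for the ancestral node.
#' @param taxon Optional taxon label carried into the call record.
#' @return An object of class `heterochrony_call` with `taxon`, `age`,
#'   `reference`, `hpd`, and `call` in
#'   `{"accelerated", "decelerated", "stasis"}`.
#' @export
classify_tip <- function(age, reference, taxon = NA_character_) {
  stopifnot(inherits(reference, "node_value_estimate"))
  if (is.na(age)) stopf("age is missing; nothing to classify")
  lo <- reference$hpd[1]; hi <- reference$hpd[2]
  call <- if (age > hi) "decelerated" else if (age < lo) "accelerated" else "stasis"
  structure(list(taxon = taxon, age = age, reference = reference$name,
                 hpd = c(lo, hi), call = call),
            class = "heterochrony_call")
}

#' @export
print.heterochrony_call <- function(x, ...) {
  cat(sprintf("%s: %.1f months vs %s HPD (%.1f, %.1f) -> %s\n",
              x$taxon, x$age, x$reference, x$hpd[1], x$hpd[2], x$call))
  invisible(x)
}

#' Classify every observed tip against an ancestral HPD
#'
#' @param traits Trait table (see [read_trait_table()]).
#' @param trait Age column to classify, e.g. `"metamorph_months"`.
#' @param reference A [node_value_estimate()].
#' @return List of class `heterochrony_calls`: `calls` data frame (taxon,
#'   age, call), `counts` by category, `skipped` taxa with missing ages.
#' @export
classify_all <- function(traits, trait, reference) {
  stopifnot(is.data.frame(traits), trait %in% names(traits))
  ages <- as.numeric(traits[[trait]])
  keep <- !is.na(ages)
  if (!any(keep)) stopf("no classifiable tips: all '%s' values missing", trait)
  skipped <- traits$taxon[!keep]
  if (length(skipped))
    message(sprintf("skipping %d taxa with missing '%s': %s",
                    length(skipped), trait,
                    paste(utils::head(skipped, 5), collapse = ", ")))
  calls <- vapply(ages[keep], function(a)
    classify_tip(a, reference)$call, character(1))
  df <- data.frame(taxon = traits$taxon[keep], age = ages[keep],
                   reference = reference$name, call = calls,
                   stringsAsFactors = FALSE)
  counts <- table(factor(calls, levels = c("accelerated", "stasis", "decelerated")))
  structure(list(calls = df, counts = counts, skipped = skipped,
                 reference = reference),
            class = "heterochrony_calls")
}

#' @export
print.heterochrony_calls <- function(x, ...) {
  cat(sprintf("Heterochrony calls vs %s HPD (%.1f, %.1f):\n",
              x$reference$name, x$reference$hpd[1], x$reference$hpd[2]))
  print(x$counts)
  invisible(x)
}

#' Localize a discrete transition along a root-to-clade node path
#'
#' Given posterior state estimates for a nested series of nodes, flags each
#' branch whose parent and child modal states differ -- the branches on
#' which a life-history transition most likely occurred.
#'
#' @param estimates List of [node_state_estimate()] objects ordered from the
#'   rootmost to the cladewardmost node. When the estimates carry taxon
#'   sets, nesting is validated.
#' @return List of class `transition_localization`: `path` data frame (node,
#'   modal state, probability), `flagged` data frame of parent/child pairs
#'   with differing modal states.
#' @export
localize_transition <- function(estimates) {
  if (length(estimates) < 2L) stopf("need at least two path nodes")
  for (e in estimates) stopifnot(inherits(e, "node_state_estimate"))
  taxa <- lapply(estimates, function(e) e$taxa)
  if (all(!vapply(taxa, is.null, logical(1)))) {
    for (i in seq_len(length(taxa) - 1L))
      if (!all(taxa[[i + 1L]] %in% taxa[[i]]))
        stopf("path nodes are not nested: '%s' is not inside '%s'",
              estimates[[i + 1L]]$name, estimates[[i]]$name)
  }
  modal <- lapply(estimates, modal_state)
  path <- data.frame(node = vapply(estimates, function(e) e$name, character(1)),
                     modal = vapply(modal, names, character(1)),
                     prob = vapply(modal, as.numeric, numeric(1)),
                     stringsAsFactors = FALSE)
  idx <- which(path$modal[-1] != path$modal[-nrow(path)])
  flagged <- data.frame(parent = path$node[idx], child = path$node[idx + 1L],
                        from = path$modal[idx], to = path$modal[idx + 1L],
                        stringsAsFactors = FALSE)
  structure(list(path = path, flagged = flagged),
            class = "transition_localization")
}

#' @export
print.transition_localization <- function(x, ...) {
  print(x$path)
  if (nrow(x$flagged) == 0) cat("no modal-state change along the path\n")
  else for (i in seq_len(nrow(x$flagged)))
    cat(sprintf("transition %s -> %s on branch %s -> %s\n",
                x$flagged$from[i], x$flagged$to[i],
                x$flagged$parent[i], x$flagged$child[i]))
  invisible(x)
}

#' Progenesis-versus-neoteny test across a life-history transition
#'
#' Tests whether paedomorphosis arose by advancing maturation (progenesis)
#' or by delaying metamorphosis with maturation unchanged (neoteny), using
#' maturation-age evidence at the parent and child of the branch carrying
#' the biphasic-to-paedomorphic transition.
#'
#' The verdict is PROGENESIS when either prong indicates a significant
#' maturation reduction across the branch: (a) the child's best-fit
#' maturation category is younger than the parent's and the parent's best
#' category is rejected at the child with `LBf >= lbf_threshold`; or (b)
#' the continuous 95% HPDs are disjoint with the child younger. If neither
#' prong holds and the life-history transition did occur on the branch, the
#' verdict is NEOTENY; otherwise AMBIGUOUS. Both prongs are reported
#' separately so other criteria can be applied.
#'
#' @param cat_parent,cat_child [lbf_table()]s of maturation categories
#'   fossilized at the parent and child nodes (rows in state-space order).
#' @param cont_parent,cont_child [node_value_estimate()]s of continuous
#'   maturation age at the two nodes.
#' @param transition_on_branch Logical: did the life-history transition to
#'   paedomorphosis occur on this branch (see [localize_transition()])?
#' @param sex Label carried into the report (`"male"`/`"female"`).
#' @param lbf_threshold Log Bayes factor threshold for prong (a); default 3
#'   (moderately strong evidence).
#' @return An object of class `heterochrony_verdict`: `verdict` in
#'   `{"progenesis", "neoteny", "ambiguous"}`, the per-prong results, and an
#'   evidence table.
#' @export
progenesis_neoteny_test <- function(cat_parent, cat_child,
                                    cont_parent, cont_child,
                                    transition_on_branch = TRUE,
                                    sex = "unspecified", lbf_threshold = 3) {
  stopifnot(inherits(cat_parent, "bayes_factor_table"),
            inherits(cat_child, "bayes_factor_table"),
            inherits(cont_parent, "node_value_estimate"),
            inherits(cont_child, "node_value_estimate"))
  best_parent <- which.max(cat_parent$hm)
  best_child <- which.max(cat_child$hm)
  lbf_parent_best_at_child <- cat_child$lbf[best_parent]
  prong_categorical <- (best_child < best_parent) &&
    (lbf_parent_best_at_child >= lbf_threshold)
  prong_continuous <- cont_child$hpd[2] < cont_parent$hpd[1]
  verdict <- if (prong_categorical || prong_continuous) "progenesis"
             else if (transition_on_branch) "neoteny"
             else "ambiguous"
  evidence <- data.frame(
    node = c(cont_parent$name, cont_child$name),
    role = c("parent", "child"),
    best_category = c(cat_parent$state[best_parent], cat_child$state[best_child]),
    cont_mean = c(cont_parent$mean, cont_child$mean),
    hpd_lower = c(cont_parent$hpd[1], cont_child$hpd[1]),
    hpd_upper = c(cont_parent$hpd[2], cont_child$hpd[2]),
    stringsAsFactors = FALSE)
  structure(list(verdict = verdict, sex = sex,
                 prong_categorical = prong_categorical,
                 prong_continuous = prong_continuous,
                 lbf_parent_best_at_child = lbf_parent_best_at_child,
                 transition_on_branch = transition_on_branch,
                 evidence = evidence,
                 cat_parent = cat_parent, cat_child = cat_child),
            class = "heterochrony_verdict")
}

#' @export
print.heterochrony_verdict <- function(x, ...) {
  cat(sprintf("Verdict (%s maturation): %s\n", x$sex, toupper(x$verdict)))
  cat(sprintf("  categorical prong: %s (parent best rejected at child with LBf %.2f)\n",
              x$prong_categorical, x$lbf_parent_best_at_child))
  cat(sprintf("  continuous prong (disjoint HPDs, child younger): %s\n",
              x$prong_continuous))
  print(x$evidence)
  invisible(x)
}
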