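#' Construct a posterior sample of chronograms
#'
#' Bundles an ordered collection of ultrametric, time-calibrated trees
#' (`phylo` objects sharing one taxon set) with provenance metadata. Trees
#' are validated for label consistency; polytomies are resolved
#' deterministically into zero-length branches.
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param source Character label recording where the trees came from.
#' @param burnin_removed Logical; has burnin already been discarded?
#' @param burnin_count Number of trees previously discarded as burnin.
#' @return An object of class `tree_posterior`.
#' @export
tree_posterior <- function(trees, source = "in-memory", burnin_removed = FALSE,
                           burnin_count = 0L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  if (length(trees) == 0L) stopf("a tree posterior must contain at least one tree")
  trees <- lapply(trees, normalize_chronogram)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(lab, ref)) {
      diff <- c(setdiff(ref, lab), setdiff(lab, ref))
      stopf("tree %d does not share the posterior taxon set; differing taxa: %s",
            i, paste(diff, collapse = ", "))
    }
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 source = source,
                 burnin_removed = burnin_removed,
                 burnin_count = as.integer(burnin_count)),
            class = "tree_posterior")
}

#' @export
length.tree_posterior <- function(x) length(x$trees)

#' @export
print.tree_posterior <- function(x, ...) {
  cat(sprintf("Tree posterior: %d chronograms, %d taxa (source: %s)\n",
              length(x), length(x$trees[[1]]$tip.label), x$source))
  cat(sprintf("  burnin removed: %s (%d trees)\n", x$burnin_removed, x$burnin_count))
  invisible(x)
}

# Strip quoting/whitespace from labels, require rootedness, resolve
# polytomies left-to-right into zero-length branches.
normalize_chronogram <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("expected a 'phylo' object")
  tree$tip.label <- gsub("^['\" ]+|['\" ]+$", "", tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stopf("duplicated tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tree)) stopf("chronograms must be rooted")
  if (!ape::is.binary(tree)) {
    message("resolving polytomies deterministically into zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$edge.length)) stopf("chronograms must carry branch lengths")
  ape::reorder.phylo(tree, "cladewise")
}

#' Read a posterior sample of trees
#'
#' Reads plain Newick (one tree per line) or NEXUS (TREES block, with an
#' optional TRANSLATE table resolved back to taxon labels) files and returns
#' all trees in file order as a [tree_posterior()].
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (by extension), `"newick"`, or `"nexus"`.
#' @return A `tree_posterior`.
#' @export
read_tree_samples <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|trees|nxs)$", tolower(path))) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stopf("could not parse %s as %s: %s", path, format,
                              conditionMessage(e)))
  if (is.null(trees)) stopf("could not parse %s as %s", path, format)
  tree_posterior(trees, source = path)
}

#' Write a tree posterior as Newick
#'
#' @param posterior A `tree_posterior`.
#' @param path Output file; one Newick string per line.
#' @export
write_tree_samples <- function(posterior, path) {
  stopifnot(inherits(posterior, "tree_posterior"))
  ape::write.tree(posterior$trees, file = path)
  invisible(path)
}

#' Validate a chronogram
#'
#' Checks branch lengths and ultrametricity. Negative branch lengths are a
#' hard error; tip-depth spread beyond `tolerance` (relative to root depth)
#' is flagged, or escalated to an error when `error_on_spread` is set,
#' because empirical posterior trees often carry rounding-induced spread.
#'
#' @param tree A `phylo` chronogram.
#' @param tolerance Allowed tip-depth spread as a fraction of root depth.
#' @param error_on_spread Treat excess spread as an error instead of a flag.
#' @return A list with `pass`, `max_spread`, `relative_spread`, `flagged`.
#' @export
validate_chronogram <- function(tree, tolerance = 1e-6, error_on_spread = FALSE) {
  tree <- normalize_chronogram(tree)
  if (any(tree$edge.length < 0))
    stopf("negative branch length (%.6g)", min(tree$edge.length))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  root_depth <- max(depths)
  spread <- diff(range(depths))
  rel <- if (root_depth > 0) spread / root_depth else 0
  flagged <- rel > tolerance
  if (flagged && error_on_spread)
    stopf("tree is non-ultrametric: relative tip-depth spread %.3g > %.3g", rel, tolerance)
  list(pass = !flagged, max_spread = spread, relative_spread = rel,
       root_depth = root_depth, flagged = flagged)
}

#' Address a node by the MRCA of a taxon set
#'
#' @param taxa Character vector of at least two tip labels.
#' @param name Display name for reports (e.g. `"Node A: focal clade"`).
#' @return An object of class `node_address`.
#' @export
node_address <- function(taxa, name = NULL) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) < 2L) stopf("a node address needs at least two taxa")
  structure(list(taxa = taxa, name = name %||% paste(taxa[1:2], collapse = "+")),
            class = "node_address")
}

#' @export
print.node_address <- function(x, ...) {
  cat(sprintf("Node address '%s': MRCA of %d taxa\n", x$name, length(x$taxa)))
  invisible(x)
}

#' Resolve a node address to a node of one tree
#'
#' Returns the most recent common ancestor of the address taxa together with
#' a flag recording whether the clade under that node contains exactly the
#' address taxa. When the flag is `FALSE` the node subtends extra taxa; the
#' MRCA is still used, mirroring MRCA-tagging of nodes across a posterior.
#'
#' @param tree A `phylo`.
#' @param address A [node_address()].
#' @return List with `node` (ape node id) and `monophyletic`.
#' @export
resolve_mrca <- function(tree, address) {
  stopifnot(inherits(address, "node_address"))
  missing_taxa <- setdiff(address$taxa, tree$tip.label)
  if (length(missing_taxa) > 0L)
    stopf("address '%s' names taxa absent from the tree: %s",
          address$name, paste(missing_taxa, collapse = ", "))
  ntip <- ape::Ntip(tree)
  if (length(address$taxa) == ntip) {
    node <- ntip + 1L
  } else {
    node <- ape::getMRCA(tree, address$taxa)
  }
  node <- as.integer(node)
  clade <- clade_tips(tree, node)
  list(node = node, monophyletic = setequal(clade, address$taxa))
}

# Tip labels descending from a node (the node itself if a tip).
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  stack <- node
  tips <- integer(0)
  while (length(stack) > 0L) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[sort(tips)]
}

#' Fraction of posterior trees in which an address is exactly monophyletic
#'
#' @param posterior A `tree_posterior`.
#' @param address A [node_address()].
#' @return Fraction in `[0, 1]`.
#' @export
mrca_monophyly_fraction <- function(posterior, address) {
  flags <- vapply(posterior$trees,
                  function(tr) resolve_mrca(tr, address)$monophyletic,
                  logical(1))
  mean(flags)
}

#' Discard leading burnin trees
#'
#' Drops the leading `ceiling(fraction * N)` trees (capped so at least one
#' tree survives) and updates the posterior metadata.
#'
#' @param posterior A `tree_posterior`.
#' @param fraction Burnin fraction in `[0, 1)`.
#' @return The filtered `tree_posterior`.
#' @export
burnin_filter <- function(posterior, fraction) {
  stopifnot(inherits(posterior, "tree_posterior"))
  if (fraction < 0 || fraction >= 1) stopf("burnin fraction must lie in [0, 1)")
  n <- length(posterior)
  drop <- min(ceiling(fraction * n), n - 1L)
  kept <- posterior$trees[seq.int(drop + 1L, n)]
  if (length(kept) == 0L) stopf("burnin filtering removed every tree")
  out <- tree_posterior(kept, source = posterior$source,
                        burnin_removed = TRUE,
                        burnin_count = posterior$burnin_count + drop)
  out
}
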