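#' Ordered state spaces for discrete developmental traits
#'
#' Three built-in spaces cover the study design: the ordered life-history
#' triplet (direct development, biphasic, paedomorphic; biphasic central),
#' four 12-month metamorphic age bins, and six 12-month maturation age bins
#' (last bin unbounded above). `custom` accepts any ordered label vector.
#'
#' @param kind One of `"life-history-3"`, `"metamorph-4"`, `"maturation-6"`,
#'   `"custom"`.
#' @param labels For `custom`, the ordered state labels.
#' @param bin_months Bin width in months for age spaces (fixed at 12 for the
#'   built-in age spaces).
#' @return An object of class `state_space` with `labels`, `K`, `kind`, and
#'   (for age spaces) `bin_edges` (lower edges, months).
#' @export
state_space <- function(kind = c("life-history-3", "metamorph-4",
                                 "maturation-6", "custom"),
                        labels = NULL, bin_months = 12) {
  kind <- match.arg(kind)
  if (kind == "life-history-3") {
    labels <- c("DD", "BI", "PD")
    edges <- NULL
  } else if (kind == "metamorph-4") {
    labels <- c("0-11", "12-23", "24-35", "36+")
    edges <- bin_months * 0:3
  } else if (kind == "maturation-6") {
    labels <- c("0-11", "12-23", "24-35", "36-47", "48-59", "60+")
    edges <- bin_months * 0:5
  } else {
    if (is.null(labels) || length(labels) < 2L)
      stopf("a custom state space needs at least two ordered labels")
    edges <- NULL
  }
  structure(list(labels = as.character(labels), K = length(labels),
                 kind = kind, bin_edges = edges, bin_months = bin_months),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("Ordered state space (%s): %s\n", x$kind,
              paste(x$labels, collapse = " < ")))
  invisible(x)
}

is_age_space <- function(space) !is.null(space$bin_edges)

#' Bin a continuous age (months) into an ordered age category
#'
#' Bins are half-open 12-month intervals `[12(k-1), 12k)`; the last bin is
#' unbounded above, so exact multiples of 12 fall in the next category
#' (16 months is category 2, 36 months is category 4 of the four-state
#' metamorphic space). `NA` ages pass through as `NA`.
#'
#' @param age Numeric vector of ages in months (may contain `NA`).
#' @param space An age `state_space` (`metamorph-4` or `maturation-6`).
#' @return Integer vector of 1-based state indices.
#' @export
bin_age <- function(age, space) {
  stopifnot(inherits(space, "state_space"))
  if (!is_age_space(space)) stopf("'%s' is not an age space", space$kind)
  if (any(age < 0, na.rm = TRUE)) stopf("ages must be non-negative")
  idx <- ifelse(is.na(age), NA_integer_,
                pmin(floor(age / space$bin_months) + 1L, space$K))
  as.integer(idx)
}

#' Build a tip-state vector from a trait table
#'
#' @param traits Trait data frame with a `taxon` column (see
#'   [read_trait_table()]).
#' @param trait Column to use: `"life_history"`, `"metamorph_months"`,
#'   `"male_mat_months"` or `"female_mat_months"`.
#' @param space The matching `state_space`; ages are binned with
#'   [bin_age()], life-history labels matched against the space labels.
#' @return Named integer vector (taxon -> 1-based state, `NA` = missing).
#' @export
tip_states <- function(traits, trait, space) {
  stopifnot(is.data.frame(traits), "taxon" %in% names(traits))
  if (!trait %in% names(traits)) stopf("trait column '%s' not in table", trait)
  v <- traits[[trait]]
  if (trait == "life_history") {
    idx <- match(as.character(v), space$labels)
    if (any(!is.na(v) & is.na(idx)))
      stopf("life-history codes outside the state space: %s",
            paste(unique(v[!is.na(v) & is.na(idx)]), collapse = ", "))
  } else {
    idx <- bin_age(as.numeric(v), space)
  }
  out <- setNames(as.integer(idx), traits$taxon)
  if (all(is.na(out))) stopf("all tips are missing for trait '%s'", trait)
  out
}
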