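#' Harmonic-mean estimator of the log marginal likelihood
#'
#' `hm = log(n / sum(exp(-logL_i)))`, evaluated in log space through
#' log-sum-exp. This estimator is known to be unstable (it is dominated by
#' the smallest sampled likelihoods) but is the conventional quantity behind
#' fossilization Bayes-factor tables; see
#' [stepping_stone_log_marginal()] for a more stable cross-check.
#'
#' @param logl Numeric vector of sampled log-likelihoods.
#' @return The harmonic-mean log marginal likelihood (scalar).
#' @export
harmonic_mean <- function(logl) {
  logl <- logl[is.finite(logl)]
  if (length(logl) == 0L) stopf("no finite log-likelihood samples")
  log(length(logl)) - logsumexp(-logl)
}

#' Log Bayes factor table from per-state harmonic means
#'
#' For each alternative fixed-state model, `LBf = 2 (hm_best - hm_alt)`;
#' the best-supported state has `LBf = 0`. Differences below 3 are
#' negligible, 3 or more moderately strong, 10 or more very strong evidence
#' against the alternative.
#'
#' @param hms Named numeric vector: state label -> harmonic mean.
#' @return A data frame of class `bayes_factor_table` with `state`, `hm`,
#'   `lbf`, `verdict`, ordered as given; attribute `best` holds the
#'   best-supported state (ties reported via attribute `tie`).
#' @export
lbf_table <- function(hms) {
  if (length(hms) < 2L) stopf("need harmonic means for at least two states")
  if (any(!is.finite(hms))) stopf("non-finite harmonic mean")
  if (is.null(names(hms))) names(hms) <- paste0("state", seq_along(hms))
  lbf <- 2 * (max(hms) - hms)
  out <- data.frame(state = names(hms), hm = as.numeric(hms),
                    lbf = as.numeric(lbf),
                    verdict = ifelse(lbf == 0, "best", evidence_label(lbf)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "best") <- names(hms)[which.max(hms)]
  attr(out, "tie") <- sum(lbf < .Machine$double.eps ^ 0.5) > 1L
  class(out) <- c("bayes_factor_table", "data.frame")
  out
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted samples containing
#' `ceiling(mass * n)` samples; among tied windows the one with the lowest
#' lower bound is returned.
#'
#' @param samples Numeric vector (at least 2 values).
#' @param mass Credibility mass in `(0, 1)`; default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stopf("need at least two samples for an HPD interval")
  if (mass <= 0 || mass >= 1) stopf("mass must lie in (0, 1)")
  xs <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[m:n] - xs[seq_len(n - m + 1L)]
  i <- which.min(widths)  # which.min takes the first minimum: lowest lower bound
  c(xs[i], xs[i + m - 1L])
}
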