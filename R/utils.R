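#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a temporary RNG state; NULL seed leaves the global
# stream untouched so callers can manage reproducibility themselves.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a stage-specific seed from a global seed
#'
#' Hashes a stage name into a 31-bit offset so pipeline stages can be rerun
#' in isolation while remaining reproducible from one global seed.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629 + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
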