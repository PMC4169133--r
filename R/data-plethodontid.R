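#' Published fossilization summaries for plethodontid salamanders
#'
#' Per-node, per-state fossilization summaries -- posterior probability
#' ("prob"), harmonic-mean log marginal likelihood ("hm"), and Log Bayes
#' factor ("lbf") -- from a published Bayesian comparative analysis of
#' plethodontid salamander developmental timing: the ordered three-state
#' life-history reconstruction (root plus five spelerpine nodes A--E) and
#' the six-category male/female maturation-age tests at nodes A--E.
#' Values are transcribed at their printed precision; the `lbf` column can
#' be recomputed from the `hm` column via [lbf_table()], which is how the
#' package validates its Bayes-factor arithmetic against published numbers.
#'
#' @return Data frame with columns `analysis` (`life_history` or
#'   `maturation`), `node`, `sex` (`NA` for life history), `state`, `prob`,
#'   `hm`, `lbf`.
#' @export
plethodontid_hm_table <- function() {
  path <- system.file("extdata", "plethodontid_fossilization_hm.tsv",
                      package = "heterochron", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
}
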