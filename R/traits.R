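trait_columns <- c("taxon", "life_history", "metamorph_months",
                   "male_mat_months", "female_mat_months")

#' Read a developmental-timing trait table
#'
#' Tab-delimited with header columns `taxon`, `life_history` (`DD` = direct
#' development, `BI` = biphasic, `PD` = paedomorphic), and minimum ages in
#' months: `metamorph_months`, `male_mat_months`, `female_mat_months`.
#' Missing values are `NA` (paedomorphic taxa are conventionally coded with
#' missing metamorphic age).
#'
#' @param path Path to the TSV file.
#' @return Data frame with the five columns above.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stopf("trait table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA")
  missing_cols <- setdiff(trait_columns, names(df))
  if (length(missing_cols))
    stopf("trait table lacks columns: %s", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$life_history[!is.na(df$life_history)]),
                 c("DD", "BI", "PD"))
  if (length(bad))
    stopf("unknown life-history codes: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(df$taxon))
    stopf("duplicated taxa in trait table: %s",
          paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  for (cl in trait_columns[-(1:2)]) df[[cl]] <- as.numeric(df[[cl]])
  df[trait_columns]
}

#' Write a trait table
#'
#' @param traits Trait data frame (see [read_trait_table()]).
#' @param path Output TSV path.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(all(trait_columns %in% names(traits)))
  write.table(traits[trait_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
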