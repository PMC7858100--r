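#' Write per-sample calls and a cohort summary
#'
#' Writes the call table as a delimited file (one row per sample) and, next
#' to it, a JSON cohort summary (total / not-evaluable / per-tier /
#' skipping-positive counts and every cutoff value used).  Re-reading the
#' table with [read_calls()] reproduces the calls exactly.
#'
#' @param fit A \code{met_call} object, or a calls data frame as found in
#'   \code{fit$calls} (then \code{summary_json} must be NULL or cutoffs are
#'   omitted from the summary).
#' @param path Output path for the table (.csv comma-separated, else tab).
#' @param summary_json Path for the JSON summary; default replaces the
#'   table extension with \code{_summary.json}.  \code{NA} skips it.
#' @return Invisibly, the table path.
#' @export
write_calls <- function(fit, path, summary_json = NULL) {
  calls <- if (inherits(fit, "met_call")) fit$calls else fit
  if (is.null(calls) || nrow(calls) == 0) stop("empty call table")
  df <- calls
  df$expression_tier <- as.character(df$expression_tier)
  df$dex14_call <- as.character(df$dex14_call)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!isTRUE(is.na(summary_json))) {
    if (is.null(summary_json))
      summary_json <- sub("\\.[^.]+$", "_summary.json", path)
    s <- if (inherits(fit, "met_call")) cohort_summary(fit)
    else list(n_total = nrow(calls),
              n_not_evaluable = sum(!calls$qc_pass),
              n_evaluable = sum(calls$qc_pass),
              n_dex14_positive = sum(calls$dex14_call == "positive"),
              n_very_high = sum(calls$expression_tier == "very_high"),
              n_mod_elevated = sum(calls$expression_tier == "mod_elevated"))
    jsonlite::write_json(s, summary_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Re-read a call table written by [write_calls()]
#'
#' @param path Path to the table.
#' @return Calls data frame with the same column types as produced by
#'   [met_call()].
#' @export
read_calls <- function(path) {
  df <- read_delim_auto(path)
  df$sample_id <- as.character(df$sample_id)
  df$qc_pass <- as.logical(df$qc_pass)
  df$expression_tier <- factor(df$expression_tier,
                               levels = c("not_evaluable", "normal",
                                          "mod_elevated", "very_high"))
  df$dex14_call <- factor(df$dex14_call,
                          levels = c("not_evaluable", "negative", "positive"))
  for (col in c("hk_geomean", "log_met", "dex14_log_ratio"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
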