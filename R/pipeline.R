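#' Run the full calling pipeline on files or objects
#'
#' Orchestrates QC, normalization, log transform, skipping calling and
#' expression tiering, optionally followed by concordance against annotated
#' orthogonal assays, and (when \code{out_dir} is given) writes
#' \code{calls.tsv}, \code{summary.json}, \code{concordance.tsv} and
#' \code{manifest.json}.
#'
#' @param counts A \code{met_counts} object, a count-table path, or a
#'   character vector of RCC paths.
#' @param codeset A \code{met_codeset} or a codeset file path.  Ignored when
#'   \code{counts} is already a \code{met_counts}.
#' @param annotations Optional annotation data frame or TSV path (see
#'   [read_annotations()]).  Columns whose names end in \code{_call} (or
#'   equal \code{rtpcr}, \code{ngs_dex14}, \code{fish}, \code{ngs_amp}) with
#'   positive/negative values are compared against the matching pipeline
#'   call: \code{dex14_*} columns against the skipping call, \code{amp_*} /
#'   \code{fish} / \code{ngs_amp} columns against the very-high tier.
#' @param out_dir Optional output directory.
#' @param ... Passed to [met_call()] (thresholds, log base, detect mode...).
#' @return List of class \code{met_pipeline}: \code{fit} (the
#'   \code{met_call}), \code{summary}, \code{concordance} (data frame or
#'   NULL), \code{manifest}.
#' @export
run_pipeline <- function(counts, codeset = NULL, annotations = NULL,
                         out_dir = NULL, ...) {
  if (is.character(codeset)) codeset <- read_codeset(codeset)
  if (is.character(counts)) {
    dialect <- if (length(counts) > 1 ||
                   grepl("\\.rcc$", counts[1], ignore.case = TRUE))
      "rcc" else "table"
    counts <- read_counts(counts, codeset, dialect = dialect)
  }
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  fit <- met_call(counts, ...)
  conc <- NULL
  if (!is.null(annotations))
    conc <- run_concordance(fit$calls, annotations)
  s <- cohort_summary(fit)
  manifest <- list(
    package = "metcall",
    version = as.character(utils::packageVersion("metcall")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = fit$config,
    codeset_hash = codeset_hash(counts$codeset),
    n_samples = s$n_total, n_evaluable = s$n_evaluable,
    n_not_evaluable = s$n_not_evaluable,
    cutoffs = s$cutoffs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(fit, file.path(out_dir, "calls.tsv"),
                summary_json = file.path(out_dir, "summary.json"))
    if (!is.null(conc))
      utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(fit = fit, summary = s, concordance = conc,
                 manifest = manifest), class = "met_pipeline")
}

#' @export
print.met_pipeline <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$concordance)) {
    cat("\nConcordance vs orthogonal assays:\n")
    print(x$concordance, digits = 3)
  }
  invisible(x)
}

# content hash of the codeset definition, for the run manifest
# (small deterministic polynomial hash; avoids a digest dependency)
codeset_hash <- function(cs) {
  txt <- paste(cs$probe, cs$class, cs$met_role, sep = ":", collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Concordance of pipeline calls with annotated orthogonal assays
#'
#' Builds one comparison per recognized annotation column: columns named
#' \code{dex14_<assay>} are compared against the nCounter skipping call;
#' columns named \code{amp_<assay>} (or \code{fish}, \code{ngs_amp}) against
#' the very-high expression tier.  Samples lacking either call are excluded
#' from that comparison's denominator.
#'
#' @param calls Calls data frame (from a fit or [read_calls()]).
#' @param annotations Annotation data frame with \code{sample_id} (see
#'   [read_annotations()]).
#' @param conf,ci_method Passed to [agreement_report()].
#' @return Agreement report data frame (one row per assay).
#' @export
run_concordance <- function(calls, annotations, conf = 0.95,
                            ci_method = "wilson") {
  idx <- match(calls$sample_id, annotations$sample_id)
  cols <- setdiff(names(annotations), "sample_id")
  test_dex <- ifelse(calls$dex14_call == "not_evaluable", NA,
                     as.character(calls$dex14_call))
  test_vh <- ifelse(calls$expression_tier == "not_evaluable", NA,
                    ifelse(calls$expression_tier == "very_high",
                           "positive", "negative"))
  pairs <- list()
  for (col in cols) {
    ref <- annotations[[col]][idx]
    if (all(is.na(as_binary_call(ref)))) next
    test <- if (grepl("^(amp|fish|ngs_amp)", col)) test_vh else test_dex
    pairs[[col]] <- list(test = test, ref = ref)
  }
  if (length(pairs) == 0)
    stop("no annotation column overlaps the calls with known values")
  agreement_report(pairs, conf = conf, ci_method = ci_method)
}
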