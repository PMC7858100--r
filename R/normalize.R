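#' Geometric mean of housekeeping counts
#'
#' The per-sample geometric mean of the raw housekeeping-gene counts gates
#' sample evaluability.  By the usual convention the geomean is zero whenever
#' any housekeeping count is zero (such a lane carries no usable signal).
#'
#' @param counts Numeric vector of one sample's raw counts, named by probe,
#'   or a samples-x-probes matrix (then a vector of geomeans is returned).
#' @param codeset A \code{met_codeset}.
#' @return Non-negative geometric mean(s) of the housekeeping counts.
#' @export
hk_geomean <- function(counts, codeset) {
  hk <- cs_probes(codeset, "housekeeping")
  geomean_rows(counts, hk)
}

geomean_rows <- function(counts, probes) {
  if (is.matrix(counts)) {
    sub <- counts[, probes, drop = FALSE]
    apply(sub, 1, geomean)
  } else {
    geomean(counts[probes])
  }
}

geomean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Flag evaluable samples by the housekeeping-geomean rule
#'
#' A sample is not evaluable when the geometric mean of its raw housekeeping
#' counts is lower than \code{threshold} (default 100); the rule is strict,
#' so a geomean of exactly 100 passes.  The threshold applies to raw counts,
#' before any normalization.
#'
#' @param x A \code{met_counts} object.
#' @param threshold Positive QC threshold (default 100 counts).
#' @return Data frame with columns \code{sample_id}, \code{hk_geomean},
#'   \code{qc_pass}.
#' @export
qc_filter <- function(x, threshold = 100) {
  stopifnot(threshold > 0)
  g <- hk_geomean(x$counts, x$codeset)
  data.frame(sample_id = rownames(x$counts), hk_geomean = as.numeric(g),
             qc_pass = g >= threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-step positive-control and housekeeping normalization
#'
#' Step 1 scales every sample by the ratio of the cohort reference (the
#' arithmetic mean over QC-passing samples of the per-sample geometric means
#' of the positive-control counts) to the sample's own positive-control
#' geomean; this removes lane-to-lane hybridization efficiency.  Step 2
#' repeats the construction on the step-1-scaled housekeeping counts,
#' removing differences in RNA input/quality.  Both factors multiply all
#' probes of the sample, so within-sample probe ratios — in particular the
#' delta-ex14 / wild-type ratio — are unchanged by normalization.
#'
#' Rows for QC-failing samples carry \code{NA} normalized values; their
#' factors are not computed and they do not contribute to the cohort
#' references.
#'
#' @param x A \code{met_counts} object.
#' @param qc Data frame from [qc_filter()] (computed at default threshold if
#'   omitted).
#' @param ref Optional list with elements \code{pos} and \code{hk}: frozen
#'   cohort reference means from a previous fit, enabling prospective
#'   normalization of new samples on the original scale.
#' @return List of class \code{met_normalized}: \code{values} (normalized
#'   matrix), \code{pos_factor}, \code{hk_factor}, \code{qc}, \code{ref}.
#' @export
normalize_two_step <- function(x, qc = qc_filter(x), ref = NULL) {
  cs <- x$codeset
  pos <- cs_probes(cs, "positive_control")
  hk <- cs_probes(cs, "housekeeping")
  if (length(pos) < 1) stop("codeset has no positive-control probes")
  counts <- x$counts
  pass <- qc$qc_pass[match(rownames(counts), qc$sample_id)]

  pos_g <- geomean_rows(counts, pos)
  if (any(pass & pos_g == 0)) {
    bad <- rownames(counts)[which(pass & pos_g == 0)[1]]
    stop("QC-passing sample '", bad,
         "' has zero positive-control geomean (corrupt lane)")
  }
  ref_pos <- if (!is.null(ref)) ref$pos else mean(pos_g[pass])
  pos_factor <- ifelse(pass, ref_pos / pos_g, NA_real_)

  step1 <- sweep(counts, 1, pos_factor, `*`)
  hk_g1 <- geomean_rows(step1[pass, , drop = FALSE], hk)
  hk_g_all <- rep(NA_real_, nrow(counts))
  hk_g_all[pass] <- hk_g1
  if (any(pass & hk_g_all == 0)) {
    bad <- rownames(counts)[which(pass & hk_g_all == 0)[1]]
    stop("QC-passing sample '", bad, "' has zero housekeeping geomean after ",
         "positive-control scaling")
  }
  ref_hk <- if (!is.null(ref)) ref$hk else mean(hk_g_all[pass])
  hk_factor <- ifelse(pass, ref_hk / hk_g_all, NA_real_)

  values <- sweep(step1, 1, hk_factor, `*`)
  values[!pass, ] <- NA_real_
  structure(list(values = values, pos_factor = pos_factor,
                 hk_factor = hk_factor, qc = qc,
                 ref = list(pos = ref_pos, hk = ref_hk)),
            class = "met_normalized")
}

#' Elementwise logarithm of normalized values
#'
#' @param values Positive numeric vector/matrix (\code{NA}s pass through).
#' @param base Logarithm base: 2 (default), 10, or \code{exp(1)}.  Downstream
#'   tier and skipping calls are invariant to the base, which only sets the
#'   reporting scale.
#' @return Log-scale values.
#' @export
log_transform <- function(values, base = 2) {
  if (any(values < 0, na.rm = TRUE)) stop("negative value in log transform")
  if (any(values == 0, na.rm = TRUE)) {
    idx <- which(values == 0, arr.ind = is.matrix(values))
    lab <- if (is.matrix(values)) rownames(values)[idx[1, 1]] else idx[1]
    stop("zero value entering log transform (sample '", lab,
         "'): zero MET-wt signal in a QC-passing sample indicates data ",
         "corruption")
  }
  log(values, base = base)
}
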