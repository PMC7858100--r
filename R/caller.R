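#' Cohort-adaptive mean + k*SD cutoff
#'
#' The calling thresholds are self-referential: the cutoff is the arithmetic
#' mean of the cohort's values plus \code{k} sample standard deviations
#' (n - 1 denominator).  With zero variance the cutoff degenerates to the
#' mean and is flagged.
#'
#' @param values Numeric vector (NAs dropped).
#' @param k Non-negative multiplier (2 for skipping positivity and very-high
#'   expression, 1 for moderately elevated expression).
#' @return List with \code{mean}, \code{sd}, \code{cutoff}, \code{n},
#'   \code{k}, \code{degenerate}.
#' @export
estimate_cutoff <- function(values, k) {
  stopifnot(k >= 0)
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("cohort cutoffs require >= 2 values (got ", length(values), ")")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s, cutoff = m + k * s, n = length(values), k = k,
       degenerate = s == 0)
}

#' Per-sample delta-ex14 / wild-type log-ratio
#'
#' The skipping statistic is the log of normalized METdelta-ex14 counts over
#' normalized MET-wt counts.  Detectability of the delta-ex14 probe is judged
#' on raw counts: under the default \code{raw_zero} rule a raw count of zero
#' leaves the log-ratio undefined and the sample is directly called negative;
#' under \code{background} the probe must additionally exceed the sample's
#' negative-control background (mean + 2 SD of the raw negative-control
#' counts).  Because both MET probes share the sample's normalization
#' factors, the ratio is identical on raw and normalized counts.
#'
#' @param norm A \code{met_normalized} object.
#' @param x The matching \code{met_counts}.
#' @param detect_mode \code{"raw_zero"} (default) or \code{"background"}.
#' @param base Log base (default 2).
#' @return Data frame: \code{sample_id}, \code{dex14_log_ratio} (NA when
#'   undefined), \code{detectable}.
#' @export
dex14_log_ratio <- function(norm, x, detect_mode = c("raw_zero", "background"),
                            base = 2) {
  detect_mode <- match.arg(detect_mode)
  cs <- x$codeset
  wt_p <- cs_wt(cs); dx_p <- cs_dex14(cs)
  pass <- norm$qc$qc_pass[match(rownames(x$counts), norm$qc$sample_id)]
  wt_v <- norm$values[, wt_p]
  dx_v <- norm$values[, dx_p]
  if (any(pass & wt_v == 0, na.rm = TRUE)) {
    bad <- rownames(x$counts)[which(pass & wt_v == 0)[1]]
    stop("QC-passing sample '", bad, "' has zero MET-wt signal")
  }
  raw_dx <- x$counts[, dx_p]
  detectable <- raw_dx > 0
  if (detect_mode == "background") {
    neg <- cs_probes(cs, "negative_control")
    if (length(neg) < 1)
      stop("background detectability needs negative-control probes")
    nc <- x$counts[, neg, drop = FALSE]
    bg <- apply(nc, 1, mean) + 2 * apply(nc, 1, stats::sd)
    bg[is.na(bg)] <- 0  # single negative probe: SD undefined, use its mean
    detectable <- raw_dx > bg
  }
  lr <- ifelse(pass & detectable, log(dx_v / wt_v, base = base), NA_real_)
  data.frame(sample_id = rownames(x$counts), dex14_log_ratio = lr,
             detectable = detectable & pass, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call METdelta-ex14 skipping across a cohort
#'
#' Samples with a defined log-ratio enter the cohort mean + \code{k} SD
#' threshold (default k = 2); a sample is positive when its log-ratio lies
#' strictly above the cutoff.  Samples with undetectable delta-ex14 counts
#' are directly negative; QC-failing samples are not evaluable.  With fewer
#' than two defined log-ratios no cutoff can be estimated and all evaluable
#' samples are negative.
#'
#' @inheritParams dex14_log_ratio
#' @param k SD multiplier for the positivity cutoff.
#' @param strict Use strict ">" for positivity (default TRUE; set FALSE
#'   for ">=").
#' @param cutoffs Optional frozen cutoff list (from a previous fit's
#'   \code{lr} element) to apply instead of re-estimating.
#' @return List: \code{calls} (factor not_evaluable/negative/positive),
#'   \code{log_ratio} data frame, \code{cutoff} (list as from
#'   [estimate_cutoff()], or NULL when not estimable).
#' @export
call_skipping <- function(norm, x, k = 2,
                          detect_mode = c("raw_zero", "background"),
                          base = 2, strict = TRUE, cutoffs = NULL) {
  lrd <- dex14_log_ratio(norm, x, detect_mode = detect_mode, base = base)
  pass <- norm$qc$qc_pass[match(lrd$sample_id, norm$qc$sample_id)]
  lr <- lrd$dex14_log_ratio
  cut <- cutoffs
  if (is.null(cut)) {
    cut <- if (sum(!is.na(lr)) >= 2) estimate_cutoff(lr, k) else NULL
  }
  calls <- rep("negative", length(lr))
  if (!is.null(cut)) {
    above <- if (strict) lr > cut$cutoff else lr >= cut$cutoff
    calls[!is.na(lr) & above] <- "positive"
  }
  calls[!pass] <- "not_evaluable"
  list(calls = factor(calls, levels = c("not_evaluable", "negative",
                                        "positive")),
       log_ratio = lrd, cutoff = cut)
}

#' Tier MET mRNA expression across a cohort
#'
#' log-MET is the log-normalized MET-wt probe count.  Tiers are
#' cohort-adaptive: moderately elevated at or above mean + 1 SD, very high at
#' or above mean + 2 SD (">=" convention at both boundaries), estimated over
#' all QC-passing samples.  A zero-variance cohort degenerates to all-normal.
#'
#' @inheritParams call_skipping
#' @param k_mod,k_high SD multipliers for the two tier boundaries.
#' @param cutoffs Optional frozen cutoff list (a previous fit's \code{lm}
#'   element with \code{mean}, \code{sd}, \code{cut_mod}, \code{cut_high}).
#' @return List: \code{tier} (factor), \code{log_met} (numeric, NA for
#'   QC-fail), \code{cutoff} (list with \code{mean}, \code{sd},
#'   \code{cut_mod}, \code{cut_high}, \code{n}, \code{degenerate}).
#' @export
categorize_expression <- function(norm, x, k_mod = 1, k_high = 2, base = 2,
                                  cutoffs = NULL) {
  cs <- x$codeset
  wt_v <- norm$values[, cs_wt(cs)]
  pass <- norm$qc$qc_pass[match(rownames(x$counts), norm$qc$sample_id)]
  log_met <- rep(NA_real_, length(wt_v))
  log_met[pass] <- log_transform(wt_v[pass], base = base)
  cut <- cutoffs
  if (is.null(cut)) {
    lo <- estimate_cutoff(log_met, k_mod)
    hi <- estimate_cutoff(log_met, k_high)
    cut <- list(mean = lo$mean, sd = lo$sd, cut_mod = lo$cutoff,
                cut_high = hi$cutoff, n = lo$n, degenerate = lo$degenerate)
  }
  tier <- rep("normal", length(log_met))
  if (!isTRUE(cut$degenerate)) {
    tier[!is.na(log_met) & log_met >= cut$cut_mod] <- "mod_elevated"
    tier[!is.na(log_met) & log_met >= cut$cut_high] <- "very_high"
  }
  tier[!pass] <- "not_evaluable"
  list(tier = factor(tier, levels = c("not_evaluable", "normal",
                                      "mod_elevated", "very_high")),
       log_met = log_met, cutoff = cut)
}

#' Rank-based group comparison of expression values
#'
#' Compares log-MET between each driver group and a reference group with the
#' two-sided Wilcoxon rank-sum (Mann-Whitney U) test.  Groups with fewer
#' than \code{min_n} samples are skipped with a warning.  No multiplicity
#' adjustment is applied by default; set \code{p_adjust} to any
#' [stats::p.adjust()] method to add one.
#'
#' @param values Numeric vector (e.g. log-MET per sample).
#' @param groups Character/factor of group labels, same length; NAs dropped.
#' @param reference Label of the reference group (default \code{"none"}).
#' @param min_n Minimum per-group size (default 3).
#' @param p_adjust Multiplicity correction method, default \code{"none"}.
#' @return Data frame: \code{group}, \code{n}, \code{n_ref}, \code{statistic}
#'   (Mann-Whitney U), \code{p_value}, and \code{p_adj} if adjusted.
#' @export
compare_groups <- function(values, groups, reference = "none", min_n = 3,
                           p_adjust = "none") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (!reference %in% groups)
    stop("reference group '", reference, "' absent")
  ref_v <- values[groups == reference]
  others <- setdiff(unique(groups), reference)
  rows <- list()
  for (g in others) {
    gv <- values[groups == g]
    if (length(gv) < min_n || length(ref_v) < min_n) {
      warning("skipping comparison '", g, "' vs '", reference,
              "': fewer than ", min_n, " samples")
      next
    }
    wt <- stats::wilcox.test(gv, ref_v, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
    rows[[g]] <- data.frame(group = g, n = length(gv), n_ref = length(ref_v),
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(group = character(), n = integer(), n_ref = integer(),
                      statistic = numeric(), p_value = numeric()))
  rownames(out) <- NULL
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p_value, p_adjust)
  out
}
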