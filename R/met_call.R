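#' Fit the MET skipping and expression caller to a cohort
#'
#' Runs the full calling procedure on raw probe counts: housekeeping-geomean
#' QC, two-step normalization, log transform, the delta-ex14/wt log-ratio
#' with its cohort mean + 2 SD positivity cutoff, and expression tiering at
#' cohort mean + 1 SD (moderately elevated) and mean + 2 SD (very high).
#' Cutoffs are re-estimated from the analyzed cohort unless a frozen
#' \code{cutoffs} set is supplied (prospective mode, see
#' [predict.met_call()]).
#'
#' @param x A \code{met_counts} object (see [met_counts()], [read_counts()]).
#' @param hk_geomean_min QC threshold on the raw housekeeping geomean
#'   (default 100).
#' @param log_base Logarithm base for log-MET and the log-ratio (default 2;
#'   calls are base-invariant).
#' @param lr_k SD multiplier for skipping positivity (default 2).
#' @param lm_k_mod,lm_k_high SD multipliers for the expression tiers
#'   (defaults 1 and 2).
#' @param detect_mode Delta-ex14 detectability rule, \code{"raw_zero"}
#'   (default: raw count 0 means directly negative) or \code{"background"}
#'   (below negative-control mean + 2 SD means negative).
#' @param strict_gt Strict ">" for log-ratio positivity (default TRUE); the
#'   expression tiers always use ">=".
#' @param cutoffs Optional \code{met_cutoffs} object to apply frozen.
#' @param diagnostics Attach distribution diagnostics for the log-ratio and
#'   log-MET distributions (default TRUE; needs >= 8 values).
#' @return An object of class \code{met_call}: list with \code{calls} (the
#'   per-sample call table), \code{cutoffs} (a \code{met_cutoffs}),
#'   \code{qc}, \code{normalized}, \code{counts}, \code{diagnostics},
#'   \code{config}.
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_samples = 60, n_skipping = 2,
#'                                          n_very_high = 2,
#'                                          n_mod_elevated = 5, seed = 1))
#' fit <- met_call(sim$counts)
#' summary(fit)
#' @export
met_call <- function(x, hk_geomean_min = 100, log_base = 2, lr_k = 2,
                     lm_k_mod = 1, lm_k_high = 2,
                     detect_mode = c("raw_zero", "background"),
                     strict_gt = TRUE, cutoffs = NULL, diagnostics = TRUE) {
  stopifnot(inherits(x, "met_counts"))
  detect_mode <- match.arg(detect_mode)
  qc <- qc_filter(x, threshold = hk_geomean_min)
  n_eval <- sum(qc$qc_pass)
  if (n_eval < 2 && is.null(cutoffs))
    stop("cohort cutoffs require >= 2 evaluable samples; supply frozen ",
         "cutoffs for single-sample runs")
  norm <- normalize_two_step(x, qc = qc,
                             ref = if (!is.null(cutoffs)) cutoffs$ref)
  skip <- call_skipping(norm, x, k = lr_k, detect_mode = detect_mode,
                        base = log_base, strict = strict_gt,
                        cutoffs = if (!is.null(cutoffs)) cutoffs$lr)
  expr <- categorize_expression(norm, x, k_mod = lm_k_mod, k_high = lm_k_high,
                                base = log_base,
                                cutoffs = if (!is.null(cutoffs)) cutoffs$lm)
  calls <- data.frame(
    sample_id = qc$sample_id,
    qc_pass = qc$qc_pass,
    hk_geomean = qc$hk_geomean,
    log_met = expr$log_met,
    expression_tier = expr$tier,
    dex14_log_ratio = skip$log_ratio$dex14_log_ratio,
    dex14_call = skip$calls,
    row.names = NULL, stringsAsFactors = FALSE)
  cut <- structure(list(lr = skip$cutoff, lm = expr$cutoff, ref = norm$ref,
                        log_base = log_base, lr_k = lr_k,
                        lm_k_mod = lm_k_mod, lm_k_high = lm_k_high),
                   class = "met_cutoffs")
  diag <- NULL
  if (diagnostics) {
    diag <- list()
    lr_v <- calls$dex14_log_ratio[!is.na(calls$dex14_log_ratio)]
    lm_v <- calls$log_met[!is.na(calls$log_met)]
    if (length(lr_v) >= 8)
      diag$log_ratio <- distribution_diagnostics(lr_v)
    if (length(lm_v) >= 8)
      diag$log_met <- distribution_diagnostics(lm_v)
  }
  structure(list(calls = calls, cutoffs = cut, qc = qc, normalized = norm,
                 counts = x, diagnostics = diag,
                 config = list(hk_geomean_min = hk_geomean_min,
                               log_base = log_base, lr_k = lr_k,
                               lm_k_mod = lm_k_mod, lm_k_high = lm_k_high,
                               detect_mode = detect_mode,
                               strict_gt = strict_gt,
                               frozen = !is.null(cutoffs))),
            class = "met_call")
}

#' Cohort-level call summary
#'
#' @param fit A \code{met_call} object.
#' @return Named list of counts and the cutoff values used.
#' @export
cohort_summary <- function(fit) {
  cl <- fit$calls
  list(n_total = nrow(cl),
       n_not_evaluable = sum(!cl$qc_pass),
       n_evaluable = sum(cl$qc_pass),
       n_dex14_positive = sum(cl$dex14_call == "positive"),
       n_very_high = sum(cl$expression_tier == "very_high"),
       n_mod_elevated = sum(cl$expression_tier == "mod_elevated"),
       n_normal = sum(cl$expression_tier == "normal"),
       n_log_ratio_defined = sum(!is.na(cl$dex14_log_ratio)),
       cutoffs = unclass_cutoffs(fit$cutoffs))
}

unclass_cutoffs <- function(ct) {
  list(log_base = ct$log_base,
       lr_mean = ct$lr$mean, lr_sd = ct$lr$sd, lr_cutoff = ct$lr$cutoff,
       n_used_lr = ct$lr$n,
       lm_mean = ct$lm$mean, lm_sd = ct$lm$sd, lm_cut_mod = ct$lm$cut_mod,
       lm_cut_high = ct$lm$cut_high, n_used_lm = ct$lm$n)
}

#' @export
print.met_cutoffs <- function(x, ...) {
  cat("Cohort-adaptive cutoffs (log base ", x$log_base, "):\n", sep = "")
  if (!is.null(x$lr))
    cat(sprintf("  log-ratio: mean %.4f, SD %.4f, positivity > %.4f (n = %d)\n",
                x$lr$mean, x$lr$sd, x$lr$cutoff, x$lr$n))
  else cat("  log-ratio: not estimable (< 2 defined log-ratios)\n")
  cat(sprintf("  log-MET:   mean %.4f, SD %.4f, mod >= %.4f, very-high >= %.4f (n = %d)\n",
              x$lm$mean, x$lm$sd, x$lm$cut_mod, x$lm$cut_high, x$lm$n))
  invisible(x)
}

#' @export
print.met_call <- function(x, ...) {
  s <- cohort_summary(x)
  cat("MET skipping / expression calls\n")
  cat(sprintf("  %d samples: %d evaluable, %d failed QC (hk geomean < %g)\n",
              s$n_total, s$n_evaluable, s$n_not_evaluable,
              x$config$hk_geomean_min))
  cat(sprintf("  METdelta-ex14 positive: %d   very-high: %d   mod-elevated: %d\n",
              s$n_dex14_positive, s$n_very_high, s$n_mod_elevated))
  invisible(x)
}

#' @export
summary.met_call <- function(object, ...) {
  s <- cohort_summary(object)
  structure(list(summary = s, cutoffs = object$cutoffs,
                 diagnostics = object$diagnostics,
                 config = object$config), class = "summary.met_call")
}

#' @export
print.summary.met_call <- function(x, ...) {
  s <- x$summary
  cat("MET skipping / expression calls\n")
  cat(sprintf("  samples: %d total, %d evaluable, %d not evaluable\n",
              s$n_total, s$n_evaluable, s$n_not_evaluable))
  cat(sprintf("  METdelta-ex14: %d positive of %d with defined log-ratio\n",
              s$n_dex14_positive, s$n_log_ratio_defined))
  cat(sprintf("  expression tiers: %d very-high, %d mod-elevated, %d normal\n",
              s$n_very_high, s$n_mod_elevated, s$n_normal))
  print(x$cutoffs)
  if (!is.null(x$diagnostics)) {
    for (nm in names(x$diagnostics)) {
      d <- x$diagnostics[[nm]]
      cat(sprintf("  %s distribution: %s (Lilliefors P = %.3g)\n",
                  sub("_", "-", nm), d$verdict, d$ks$p_value))
    }
  }
  invisible(x)
}

#' Cutoffs actually used by a fit
#'
#' \code{coef()} on a \code{met_call} returns the estimated thresholds as a
#' named numeric vector, the natural "coefficients" of this calling model.
#'
#' @param object A \code{met_call}.
#' @param ... Unused.
#' @export
coef.met_call <- function(object, ...) {
  ct <- object$cutoffs
  out <- c(lr_mean = ct$lr$mean, lr_sd = ct$lr$sd, lr_cutoff = ct$lr$cutoff,
           lm_mean = ct$lm$mean, lm_sd = ct$lm$sd,
           lm_cut_mod = ct$lm$cut_mod, lm_cut_high = ct$lm$cut_high)
  out
}

#' Apply frozen cutoffs to new samples
#'
#' Prospective use: new samples are normalized against the fitted cohort's
#' reference means and classified with the fitted cutoffs, so a batch of any
#' size (even a single sample) can be called on the original scale without
#' re-estimating thresholds.
#'
#' @param object A fitted \code{met_call}.
#' @param newdata A \code{met_counts} object with the same codeset.
#' @param ... Unused.
#' @return A \code{met_call} on \code{newdata} with \code{config$frozen =
#'   TRUE}.
#' @export
predict.met_call <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "met_counts"))
  met_call(newdata,
           hk_geomean_min = object$config$hk_geomean_min,
           log_base = object$config$log_base,
           lr_k = object$config$lr_k,
           lm_k_mod = object$config$lm_k_mod,
           lm_k_high = object$config$lm_k_high,
           detect_mode = object$config$detect_mode,
           strict_gt = object$config$strict_gt,
           cutoffs = object$cutoffs, diagnostics = FALSE)
}

#' Plot the two calling distributions with their cutoffs
#'
#' Left: histogram of the delta-ex14/wt log-ratios with the positivity
#' cutoff; right: histogram of log-MET with the two tier boundaries.
#'
#' @param x A \code{met_call}.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.met_call <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  lr <- x$calls$dex14_log_ratio
  lm <- x$calls$log_met
  b <- x$config$log_base
  graphics::hist(lr[!is.na(lr)], breaks = 30, col = "grey80",
                 main = "METdelta-ex14 / MET-wt",
                 xlab = sprintf("log%s ratio", format(b)), ...)
  if (!is.null(x$cutoffs$lr))
    graphics::abline(v = x$cutoffs$lr$cutoff, col = "red", lwd = 2)
  graphics::hist(lm[!is.na(lm)], breaks = 30, col = "grey80",
                 main = "MET mRNA expression",
                 xlab = sprintf("log%s MET", format(b)), ...)
  graphics::abline(v = c(x$cutoffs$lm$cut_mod, x$cutoffs$lm$cut_high),
                   col = c("orange", "red"), lwd = 2)
  invisible(x)
}

#' Simulate cohorts matched to a fitted cohort's composition
#'
#' Parametric re-simulation: draws synthetic cohorts whose size, QC-failure
#' count and called composition (skipping positives, very-high, mod-elevated)
#' match the fit, using the package's generative model.  Useful for checking
#' the stability of the self-referential cutoffs.
#'
#' @param object A \code{met_call}.
#' @param nsim Number of cohorts (default 1).
#' @param seed Integer seed for the first cohort; cohort i uses
#'   \code{seed + i - 1}.
#' @param ... Passed to [cohort_sim_config()] to override fields.
#' @return List of \code{nsim} elements, each as returned by
#'   [simulate_cohort()].
#' @export
simulate.met_call <- function(object, nsim = 1, seed = 1, ...) {
  s <- cohort_summary(object)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- cohort_sim_config(
      n_samples = s$n_total,
      frac_qc_fail = s$n_not_evaluable / s$n_total,
      n_skipping = s$n_dex14_positive,
      n_very_high = s$n_very_high,
      n_mod_elevated = s$n_mod_elevated,
      seed = seed + i - 1L, ...)
    out[[i]] <- simulate_cohort(cfg)
  }
  if (nsim == 1) out[[1]] else out
}
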