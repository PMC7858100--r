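#' Build a 2x2 contingency table from paired binary calls
#'
#' Cell layout follows the diagnostic convention: \code{a} = test+/ref+,
#' \code{b} = test+/ref-, \code{c} = test-/ref+, \code{d} = test-/ref-.
#' Samples where either call is unknown (\code{NA} or a level other than the
#' recognized positive/negative labels) are dropped pairwise and counted in
#' \code{n_dropped}, which is how per-comparison denominators end up smaller
#' than the cohort.
#'
#' @param test_calls,ref_calls Vectors of paired calls, aligned by position
#'   (align by sample id before calling).  Logical vectors, or
#'   character/factor with levels \code{"positive"}/\code{"negative"}.
#' @return Object of class \code{met_table2x2}: list \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{n}, \code{n_dropped}.
#' @export
build_table <- function(test_calls, ref_calls) {
  if (length(test_calls) != length(ref_calls))
    stop("call vectors differ in length")
  t2 <- as_binary_call(test_calls)
  r2 <- as_binary_call(ref_calls)
  keep <- !is.na(t2) & !is.na(r2)
  if (!any(keep)) stop("no samples with both calls known")
  t2 <- t2[keep]; r2 <- r2[keep]
  structure(list(a = sum(t2 & r2), b = sum(t2 & !r2),
                 c = sum(!t2 & r2), d = sum(!t2 & !r2),
                 n = sum(keep), n_dropped = sum(!keep)),
            class = "met_table2x2")
}

as_binary_call <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("positive", "pos", "true", "1")] <- TRUE
  out[x %in% c("negative", "neg", "false", "0")] <- FALSE
  out
}

#' Construct a 2x2 table from its cell counts
#'
#' @param a,b,c,d Non-negative integers: test+/ref+, test+/ref-, test-/ref+,
#'   test-/ref-.
#' @export
table2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 n_dropped = 0L), class = "met_table2x2")
}

#' @export
print.met_table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  cat("n =", x$n, if (x$n_dropped > 0)
    paste0("(", x$n_dropped, " dropped: call unknown)"), "\n")
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named vector \code{estimate}, \code{lower}, \code{upper} (all in
#'   \[0, 1\]); for k = n the upper bound is exactly 1, for k = 0 the lower
#'   bound exactly 0.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  # the bounds are analytically exact at the extremes; avoid rounding wobble
  lower <- if (k == 0) 0 else max(0, centre - half)
  upper <- if (k == n) 1 else min(1, centre + half)
  c(estimate = p, lower = lower, upper = upper)
}

#' Clopper-Pearson exact interval
#'
#' Available as an alternative to [wilson_ci()] via the \code{ci_method}
#' argument of [percent_agreement()] and [sens_spec()].
#'
#' @inheritParams wilson_ci
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  c(estimate = k / n, lower = ci[1], upper = ci[2])
}

prop_ci <- function(k, n, conf, ci_method) {
  switch(ci_method,
         wilson = wilson_ci(k, n, conf),
         clopper_pearson = clopper_pearson_ci(k, n, conf),
         stop("unknown ci_method: ", ci_method))
}

#' Percent agreement with confidence interval
#'
#' @param t A \code{met_table2x2}.
#' @param conf Confidence level (default 0.95).
#' @param ci_method \code{"wilson"} (default) or \code{"clopper_pearson"}.
#' @return Named vector \code{proportion}, \code{lower}, \code{upper}
#'   (fractions in \[0, 1\]).
#' @export
percent_agreement <- function(t, conf = 0.95, ci_method = "wilson") {
  ci <- prop_ci(t$a + t$d, t$n, conf, ci_method)
  c(proportion = unname(ci["estimate"]), lower = unname(ci["lower"]),
    upper = unname(ci["upper"]))
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with observed
#' agreement p_o = (a + d)/n and expected agreement p_e from the marginals.
#' When p_e = 1 (a degenerate table where both raters are constant), kappa
#' is 1 if agreement is perfect and \code{NA} otherwise.
#'
#' @param t A \code{met_table2x2}.
#' @return Kappa in \[-1, 1\] (or \code{NA} in the degenerate case).
#' @export
cohens_kappa <- function(t) {
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Sensitivity and specificity against a reference assay
#'
#' Treats the reference method's calls as truth: sensitivity = a/(a + c),
#' specificity = d/(b + d), each with a confidence interval.  A component
#' with an empty denominator is returned as \code{NA}.
#'
#' @inheritParams percent_agreement
#' @return List with \code{sensitivity} and \code{specificity}, each a named
#'   vector \code{estimate}, \code{lower}, \code{upper}, plus
#'   \code{orientation = "reference-as-truth"}.
#' @export
sens_spec <- function(t, conf = 0.95, ci_method = "wilson") {
  sens <- if (t$a + t$c >= 1) prop_ci(t$a, t$a + t$c, conf, ci_method)
          else c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  spec <- if (t$b + t$d >= 1) prop_ci(t$d, t$b + t$d, conf, ci_method)
          else c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  list(sensitivity = sens, specificity = spec,
       orientation = "reference-as-truth")
}

#' Qualitative kappa band
#'
#' Conventional interpretation scale: <= 0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, > 0.80 almost perfect.
#'
#' @param kappa Numeric kappa value(s).
#' @return Character band(s).
#' @export
kappa_band <- function(kappa) {
  cut_pts <- c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf)
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  as.character(cut(kappa, cut_pts, labels = bands))
}

#' Multi-comparison agreement report
#'
#' One row per test-vs-reference comparison with n, percent agreement and
#' its confidence interval, Cohen's kappa with its qualitative band, and
#' sensitivity/specificity (reference as truth).  Proportions are reported
#' in percent.
#'
#' @param pairs Named list; each element either a \code{met_table2x2} or a
#'   list/pair with elements \code{test} and \code{ref} (call vectors passed
#'   to [build_table()]).
#' @param conf Confidence level.
#' @param ci_method See [percent_agreement()].
#' @return Data frame with one row per comparison.
#' @export
agreement_report <- function(pairs, conf = 0.95, ci_method = "wilson") {
  if (length(pairs) < 1) stop("agreement_report needs >= 1 comparison")
  if (is.null(names(pairs)) || any(names(pairs) == ""))
    names(pairs) <- paste0("comparison_", seq_along(pairs))
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    t <- if (inherits(p, "met_table2x2")) p else build_table(p$test, p$ref)
    pa <- percent_agreement(t, conf, ci_method)
    k <- cohens_kappa(t)
    ss <- sens_spec(t, conf, ci_method)
    data.frame(comparison = nm, n = t$n,
               a = t$a, b = t$b, c = t$c, d = t$d,
               agreement_pct = 100 * pa["proportion"],
               ci_low_pct = 100 * pa["lower"], ci_high_pct = 100 * pa["upper"],
               kappa = k, kappa_band = kappa_band(k),
               sensitivity_pct = 100 * ss$sensitivity["estimate"],
               specificity_pct = 100 * ss$specificity["estimate"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
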