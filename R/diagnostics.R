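#' Distribution diagnostics: normality and bimodality
#'
#' Reproduces the two distributional checks behind the calling strategy: the
#' cohort log-MET distribution is expected to be unimodal (possibly with a
#' heavy upper tail and non-normal), whereas the delta-ex14/wt log-ratio
#' distribution is expected to be bimodal with the positivity cutoff falling
#' between the modes.
#'
#' Three components are reported: (i) a Kolmogorov-Smirnov test of normality
#' with mean and SD estimated from the data, using the Lilliefors correction
#' (flagged in the output); (ii) a two-component equal-variance Gaussian
#' mixture fitted by EM (deterministic initialization: one-dimensional
#' k-means started from a split at the median, then up to \code{max_iter} EM
#' iterations at tolerance \code{tol}), with component means, weights, the
#' shared SD and the misclassification boundary where the two weighted
#' densities cross; (iii) a bimodality verdict — bimodal iff the mixture
#' improves the log-likelihood over a single Gaussian by more than
#' \code{margin_per_obs} nats per observation AND the component means are
#' separated by more than 2 pooled (shared) SDs.
#'
#' @param values Numeric vector, length >= 8.
#' @param margin_per_obs Log-likelihood improvement required per observation
#'   (default 0.25 nats): the raw improvement scales with n, so the margin is
#'   expressed per observation.
#' @param max_iter,tol EM iteration cap and convergence tolerance.
#' @return List of class \code{met_diagnostics}: \code{n}, \code{ks} (list
#'   with \code{statistic}, \code{p_value}, \code{lilliefors = TRUE}),
#'   \code{mixture} (means, weights, sd, boundary, loglik, loglik_1,
#'   delta_per_obs, separation_sd), \code{verdict} ("unimodal", "bimodal" or
#'   "degenerate").
#' @export
distribution_diagnostics <- function(values, margin_per_obs = 0.25,
                                     max_iter = 100, tol = 1e-8) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("distribution diagnostics need >= 8 values")
  if (stats::sd(values) == 0)
    return(structure(list(n = n, ks = NULL, mixture = NULL,
                          verdict = "degenerate"),
                     class = "met_diagnostics"))
  ks <- nortest::lillie.test(values)
  mix <- fit_mixture2(values, max_iter = max_iter, tol = tol)
  sep <- abs(mix$means[2] - mix$means[1]) / mix$sd
  dpo <- (mix$loglik - mix$loglik_1) / n
  verdict <- if (dpo > margin_per_obs && sep > 2) "bimodal" else "unimodal"
  structure(list(
    n = n,
    ks = list(statistic = unname(ks$statistic), p_value = ks$p.value,
              lilliefors = TRUE),
    mixture = c(mix, list(separation_sd = sep, delta_per_obs = dpo)),
    verdict = verdict), class = "met_diagnostics")
}

#' @export
print.met_diagnostics <- function(x, ...) {
  cat("Distribution diagnostics (n = ", x$n, "): ", x$verdict, "\n", sep = "")
  if (x$verdict != "degenerate") {
    cat(sprintf("  normality (Lilliefors KS): D = %.4f, P = %.4g\n",
                x$ks$statistic, x$ks$p_value))
    m <- x$mixture
    cat(sprintf("  mixture: means %.3f / %.3f, weights %.3f / %.3f, SD %.3f\n",
                m$means[1], m$means[2], m$weights[1], m$weights[2], m$sd))
    cat(sprintf("  boundary %.3f; separation %.2f pooled SD; dLL/n = %.3f\n",
                m$boundary, m$separation_sd, m$delta_per_obs))
  }
  invisible(x)
}

# 1-D two-means Lloyd clustering, deterministically seeded at the median split
kmeans2_1d <- function(x, max_iter = 100) {
  md <- stats::median(x)
  lower <- x <= md
  if (all(lower) || !any(lower)) lower <- x <= mean(range(x))
  ctr <- c(mean(x[lower]), mean(x[!lower]))
  for (i in seq_len(max_iter)) {
    assign1 <- abs(x - ctr[1]) <= abs(x - ctr[2])
    if (all(assign1) || !any(assign1)) break
    new_ctr <- c(mean(x[assign1]), mean(x[!assign1]))
    if (isTRUE(all.equal(new_ctr, ctr))) { ctr <- new_ctr; break }
    ctr <- new_ctr
    lower <- assign1
  }
  list(centers = ctr, lower = lower)
}

# equal-variance two-component Gaussian mixture by EM; deterministic
fit_mixture2 <- function(x, max_iter = 100, tol = 1e-8) {
  n <- length(x)
  km <- kmeans2_1d(x)
  mu <- sort(km$centers)
  lower <- x <= mean(mu)
  sg <- sqrt(mean((x - ifelse(lower, mu[1], mu[2]))^2))
  if (sg == 0) sg <- stats::sd(x) / 10
  w <- max(min(mean(lower), 1 - 1 / n), 1 / n)
  ll_old <- -Inf; ll <- ll_old
  for (i in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(x, mu[1], sg)
    d2 <- (1 - w) * stats::dnorm(x, mu[2], sg)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- mean(r)
    w <- max(min(w, 1 - 1e-9), 1e-9)
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sg <- sqrt(sum(r * (x - mu[1])^2 + (1 - r) * (x - mu[2])^2) / n)
    if (sg <= 0 || !is.finite(sg)) sg <- stats::sd(x) / 100
  }
  # single-Gaussian reference (MLE: n-denominator SD)
  sg1 <- sqrt(mean((x - mean(x))^2))
  ll1 <- sum(stats::dnorm(x, mean(x), sg1, log = TRUE))
  ord <- order(mu)
  mu <- mu[ord]
  wts <- c(w, 1 - w)[ord]
  # equal variances: weighted densities cross at a single boundary
  boundary <- if (mu[2] > mu[1])
    (mu[1] + mu[2]) / 2 + sg^2 * log(wts[1] / wts[2]) / (mu[2] - mu[1])
  else mean(mu)
  list(means = mu, weights = wts, sd = sg, boundary = boundary,
       loglik = ll, loglik_1 = ll1, iterations = i)
}
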