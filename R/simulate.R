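#' Default panel codeset used by the simulator
#'
#' Two MET probes (wild-type and the exon 13-exon 15 junction), three
#' housekeeping genes, a six-step positive-control titration and four
#' negative controls.
#'
#' @return A \code{met_codeset}.
#' @export
default_codeset <- function() {
  codeset(
    probe = c("MET_wt", "MET_dex14", "ACTB", "PSMC4", "MRPL19",
              paste0("POS_", LETTERS[1:6]), paste0("NEG_", LETTERS[1:4])),
    class = c("endogenous", "endogenous", rep("housekeeping", 3),
              rep("positive_control", 6), rep("negative_control", 4)),
    met_role = c("met_wt", "met_dex14", rep("none", 13)))
}

#' Simulation configuration for a synthetic cohort
#'
#' The generative model emulates the statistical structure the caller
#' assumes: a unimodal cohort log-MET distribution (SD calibrated to 1
#' natural-log unit) with a moderately elevated component and a very-high
#' component sitting \code{shift_mod} and \code{shift_very_high} cohort
#' log-SDs above the bulk; skipping-positive samples that keep total MET
#' output but reallocate \code{skipped_fraction} of it to the delta-ex14
#' isoform (hence a bimodal log-ratio distribution); per-sample lane scaling
#' removed by normalization; QC failures as globally degraded RNA
#' (housekeeping and endogenous means scaled by \code{qc_fail_scale},
#' positive controls untouched — they are synthetic spike-ins); and
#' negative-binomial counts throughout.
#'
#' Defaults reproduce the composition of a 474-sample NSCLC screening
#' cohort: 52 QC failures, 13 skipping-positive, 15 very-high and 36
#' moderately elevated samples.
#'
#' @param n_samples Cohort size.
#' @param frac_qc_fail Fraction of samples generated as QC failures;
#'   \code{round(n_samples * frac_qc_fail)} samples are degraded.
#' @param n_skipping,n_very_high,n_mod_elevated True label counts among the
#'   non-degraded samples (skipping positives are drawn from the normal
#'   expression component, disjoint from the elevated tiers).
#' @param skipped_fraction Fraction of MET transcripts lacking exon 14 in
#'   skipping-positive samples (default 0.5).
#' @param shift_very_high,shift_mod Component means in cohort log-SD units
#'   (defaults 4.0 and 1.5).
#' @param within_group_sd SD of the elevated components in the same units
#'   (default 0.25); the normal component's SD is solved so the cohort
#'   log-SD equals 1.
#' @param nb_dispersion Negative-binomial dispersion alpha with
#'   var = mu + alpha * mu^2 (default 0.1); 0 gives Poisson counts.
#' @param lane_factor_sd Log-scale SD of the per-sample lane scalar
#'   (default 0.2).
#' @param hk_mean,posctrl_mean,negctrl_mean,met_wt_mean Baseline probe means
#'   at lane factor 1 and z = 0.  \code{posctrl_mean} is the top of a
#'   two-fold titration across the six positive probes.
#' @param qc_fail_scale RNA-content scale applied to degraded samples
#'   (default 0.02, putting their housekeeping geomean far below 100).
#' @param seed Integer seed; all randomness flows from it (stream order:
#'   group shuffle, latent z, lane factors, then counts probe by probe in
#'   codeset order).
#' @return List of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n_samples = 474, frac_qc_fail = 52 / 474,
                              n_skipping = 13, n_very_high = 15,
                              n_mod_elevated = 36, skipped_fraction = 0.5,
                              shift_very_high = 4.0, shift_mod = 1.5,
                              within_group_sd = 0.25, nb_dispersion = 0.1,
                              lane_factor_sd = 0.2, hk_mean = 1500,
                              posctrl_mean = 5000, negctrl_mean = 2,
                              met_wt_mean = 8000, qc_fail_scale = 0.02,
                              seed = 7) {
  cfg <- as.list(environment())
  n_fail <- round(n_samples * frac_qc_fail)
  n_eval <- n_samples - n_fail
  if (frac_qc_fail < 0 || frac_qc_fail >= 1)
    stop("frac_qc_fail must be in [0, 1)")
  if (n_skipping + n_very_high + n_mod_elevated > n_eval)
    stop("labelled samples (", n_skipping + n_very_high + n_mod_elevated,
         ") exceed evaluable samples (", n_eval, ")")
  if (skipped_fraction <= 0 || skipped_fraction > 1)
    stop("skipped_fraction must be in (0, 1]")
  if (shift_very_high <= shift_mod || shift_mod < 0)
    stop("need shift_very_high > shift_mod >= 0")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  cfg$n_qc_fail <- n_fail
  cfg$n_evaluable <- n_eval
  structure(cfg, class = "cohort_sim_config")
}

# SD of the normal component such that the evaluable cohort's latent
# log-expression SD equals 1 (shifted components have within_group_sd)
normal_component_sd <- function(cfg) {
  n <- cfg$n_evaluable
  n_norm <- n - cfg$n_very_high - cfg$n_mod_elevated
  if (n_norm <= 0) stop("no normal-component samples in config")
  m <- (cfg$n_mod_elevated * cfg$shift_mod +
        cfg$n_very_high * cfg$shift_very_high) / n
  w2 <- cfg$within_group_sd^2
  s0sq <- (n * (1 + m^2) -
           cfg$n_mod_elevated * (w2 + cfg$shift_mod^2) -
           cfg$n_very_high * (w2 + cfg$shift_very_high^2)) / n_norm
  if (cfg$n_very_high + cfg$n_mod_elevated == 0) return(1)
  if (s0sq <= 0)
    stop("infeasible config: elevated components alone exceed the unit ",
         "cohort log-SD; reduce shifts or component counts")
  sqrt(s0sq)
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a raw count cohort with ground-truth labels
#'
#' @param config A [cohort_sim_config()].
#' @param codeset Panel codeset (default [default_codeset()]).
#' @return List with \code{counts} (a \code{met_counts}) and \code{truth}
#'   (data frame: \code{sample_id}, \code{qc_fail}, \code{skipping},
#'   \code{tier}).  Re-running with the same config is bit-identical.
#' @export
simulate_cohort <- function(config = cohort_sim_config(),
                            codeset = default_codeset()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  # stream draw 1: which samples fail QC / carry which label
  status <- c(rep("qc_fail", cfg$n_qc_fail),
              rep("very_high", cfg$n_very_high),
              rep("mod_elevated", cfg$n_mod_elevated),
              rep("skipping", cfg$n_skipping),
              rep("normal", n - cfg$n_qc_fail - cfg$n_very_high -
                    cfg$n_mod_elevated - cfg$n_skipping))
  status <- sample(status)
  s0 <- normal_component_sd(cfg)
  # stream draw 2: latent log-expression (cohort log-SD units)
  z <- ifelse(status == "very_high",
              stats::rnorm(n, cfg$shift_very_high, cfg$within_group_sd),
       ifelse(status == "mod_elevated",
              stats::rnorm(n, cfg$shift_mod, cfg$within_group_sd),
              stats::rnorm(n, 0, s0)))
  # stream draw 3: lane scalars
  lane <- exp(stats::rnorm(n, 0, cfg$lane_factor_sd))
  rna_scale <- ifelse(status == "qc_fail", cfg$qc_fail_scale, 1)
  mu_tot <- cfg$met_wt_mean * exp(z)
  f <- cfg$skipped_fraction
  is_skip <- status == "skipping"
  probe_mu <- function(p) {
    cls <- codeset$class[codeset$probe == p]
    role <- codeset$met_role[codeset$probe == p]
    if (role == "met_wt")
      ifelse(is_skip, (1 - f) * mu_tot, mu_tot) * rna_scale * lane
    else if (role == "met_dex14")
      ifelse(is_skip, f * mu_tot, cfg$negctrl_mean) * rna_scale * lane
    else if (cls == "housekeeping") cfg$hk_mean * rna_scale * lane
    else if (cls == "positive_control") {
      step <- which(cs_probes(codeset, "positive_control") == p) - 1L
      rep(cfg$posctrl_mean / 2^step, n) * lane   # spike-ins: no rna_scale
    } else if (cls == "negative_control") rep(cfg$negctrl_mean, n) * lane
    else cfg$hk_mean * rna_scale * lane          # other endogenous probes
  }
  # stream draw 4: counts, probe by probe in codeset order
  m <- matrix(0L, n, nrow(codeset), dimnames = list(ids, codeset$probe))
  for (p in codeset$probe)
    m[, p] <- rcounts(n, probe_mu(p), cfg$nb_dispersion)
  truth <- data.frame(
    sample_id = ids,
    qc_fail = status == "qc_fail",
    skipping = is_skip,
    tier = ifelse(status %in% c("very_high", "mod_elevated"), status,
                  "normal"),
    stringsAsFactors = FALSE)
  list(counts = met_counts(m, codeset), truth = truth, config = cfg)
}

# probe mean profiles of the three cell models used for spike-in mixtures:
# a MET-wt line (PC9-like), a skipping line with amplified, predominantly
# delta-ex14 MET (Hs746T-like), and an amplified high-expressor (E98-like)
cell_model <- function(cell, cfg) {
  base <- list(met_total = cfg$met_wt_mean, skipped_fraction = 0)
  switch(cell,
         wt_cell = base,
         skipping_cell = list(met_total = 8 * cfg$met_wt_mean,
                              skipped_fraction = 0.85),
         amplified_cell = list(met_total = 20 * cfg$met_wt_mean,
                               skipped_fraction = 0),
         stop("unknown cell model: ", cell))
}

#' Simulate in-silico cell-line spike-in mixtures
#'
#' Pseudo-samples whose MET probe means are convex mixtures of a
#' MET-dependent cell model and a wild-type diluent, emulating dilution
#' series used to characterize caller sensitivity.  At \code{mix_fraction}
#' 0 the sample is pure wild-type background; at 1 it is the pure cell
#' model, whose expected log-ratio is
#' \code{log(skipped_fraction / (1 - skipped_fraction))}.
#'
#' @param mix_fraction Fraction of spiked cells in \[0, 1\] (vector allowed;
#'   replicates are generated for each value).
#' @param cell \code{"wt_cell"}, \code{"skipping_cell"} or
#'   \code{"amplified_cell"}.
#' @param n_replicates Replicates per mixture level (default 3).
#' @param seed Integer seed.
#' @param config A [cohort_sim_config()] providing probe scales.
#' @param codeset Panel codeset.
#' @return List with \code{counts} (a \code{met_counts}) and \code{design}
#'   (data frame: \code{sample_id}, \code{mix_fraction}, \code{replicate},
#'   \code{cell}).
#' @export
simulate_spikein <- function(mix_fraction, cell = c("skipping_cell",
                                                    "amplified_cell",
                                                    "wt_cell"),
                             n_replicates = 3, seed = 1,
                             config = cohort_sim_config(),
                             codeset = default_codeset()) {
  cell <- match.arg(cell)
  stopifnot(all(mix_fraction >= 0 & mix_fraction <= 1))
  cfg <- config
  set.seed(seed)
  spike <- cell_model(cell, cfg)
  dilu <- cell_model("wt_cell", cfg)
  design <- expand.grid(replicate = seq_len(n_replicates),
                        mix_fraction = mix_fraction)
  nr <- nrow(design)
  ids <- sprintf("MIX_%03d_%02.0f_r%d", seq_len(nr),
                 100 * design$mix_fraction, design$replicate)
  x <- design$mix_fraction
  wt_mu <- x * spike$met_total * (1 - spike$skipped_fraction) +
    (1 - x) * dilu$met_total * (1 - dilu$skipped_fraction)
  dx_mu <- x * spike$met_total * spike$skipped_fraction +
    (1 - x) * dilu$met_total * dilu$skipped_fraction + cfg$negctrl_mean
  m <- matrix(0L, nr, nrow(codeset), dimnames = list(ids, codeset$probe))
  pos_probes <- cs_probes(codeset, "positive_control")
  for (p in codeset$probe) {
    mu <- if (codeset$met_role[codeset$probe == p] == "met_wt") wt_mu
    else if (codeset$met_role[codeset$probe == p] == "met_dex14") dx_mu
    else if (codeset$class[codeset$probe == p] == "housekeeping")
      rep(cfg$hk_mean, nr)
    else if (codeset$class[codeset$probe == p] == "positive_control")
      rep(cfg$posctrl_mean / 2^(which(pos_probes == p) - 1L), nr)
    else rep(cfg$negctrl_mean, nr)
    m[, p] <- rcounts(nr, mu, cfg$nb_dispersion)
  }
  list(counts = met_counts(m, codeset),
       design = data.frame(sample_id = ids,
                           mix_fraction = design$mix_fraction,
                           replicate = design$replicate, cell = cell,
                           stringsAsFactors = FALSE))
}
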