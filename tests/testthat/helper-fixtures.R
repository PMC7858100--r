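# shared fixture builders; everything is generated in code at test time

minimal_codeset <- function() {
  codeset(probe = c("MET_wt", "MET_d14", "ACTB", "NEG_A", "POS_A"),
          class = c("endogenous", "endogenous", "housekeeping",
                    "negative_control", "positive_control"),
          met_role = c("met_wt", "met_dex14", "none", "none", "none"))
}

# hand-built count matrix on the minimal codeset
tiny_counts <- function(m = NULL) {
  if (is.null(m)) {
    m <- rbind(A = c(500, 500, 400, 3, 200),
               B = c(400, 25, 400, 2, 200))
    colnames(m) <- c("MET_wt", "MET_d14", "ACTB", "NEG_A", "POS_A")
  }
  met_counts(m, minimal_codeset())
}

# small but feasible simulated cohort (very-high at 4 cohort-SDs caps the
# elevated fraction, so n must be a few dozen)
small_sim <- function(seed = 3, n = 40, n_skipping = 2, n_very_high = 1,
                      n_mod_elevated = 2, ...) {
  simulate_cohort(cohort_sim_config(
    n_samples = n, frac_qc_fail = 0, n_skipping = n_skipping,
    n_very_high = n_very_high, n_mod_elevated = n_mod_elevated,
    seed = seed, ...))
}

study_config <- function(seed = 7, ...) cohort_sim_config(seed = seed, ...)

write_codeset_file <- function(cs = minimal_codeset(),
                               path = tempfile(fileext = ".tsv")) {
  write_codeset(cs, path)
  path
}
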