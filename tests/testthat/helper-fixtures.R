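# Shared fixtures, built in code. The cohort is computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small multi-patient cohort with extracted + imputed features (easy noise).
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    sims <- simulate_patients(6, n_beats = 250, seed = 7, noise_sd = 0.02)
    fm <- impute_patient_mean(rbind_features(lapply(sims, extract_sim_features)))
    .fixture_env$cohort <- list(sims = sims, fm = fm)
  }
  .fixture_env$cohort
}

# Tiny deterministic two-lead record: lead1 a 1 Hz sine, lead2 a ramp.
tiny_record <- function(n = 720, fs = 360) {
  t <- (seq_len(n) - 1) / fs
  ecg_record("tiny", fs, cbind(sin(2 * pi * t), seq_len(n) / n),
             c("MLII", "V1"))
}

# Full fiducial row (0-based samples) for a beat with R at `r`.
full_fid_row <- function(r, fs = 360) {
  rel <- c(P_on = -0.28, P_peak = -0.22, P_off = -0.16, QRS_on = -0.06,
           Q = -0.03, R = 0, S = 0.03, QRS_off = 0.06, T_on = 0.14,
           T_peak = 0.30, T_off = 0.46)
  round(r + rel * fs)
}

# FiducialMap with full rows for the given R samples (both leads identical).
full_fid_map <- function(r_samples, fs = 360) {
  m <- t(vapply(r_samples, full_fid_row, numeric(11), fs = fs))
  colnames(m) <- c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S",
                   "QRS_off", "T_on", "T_peak", "T_off")
  fiducial_map(m, m)
}
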