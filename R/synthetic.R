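# Synthetic two-lead ECG generator with ground-truth fiducial points.
#
# Each beat is a sum of five Gaussian waves (P, Q, R, S, T) whose parameters
# depend on the AAMI class:
#   N: the patient template;
#   S: normal morphology, preceding R-R shortened (x U(0.5, 0.8)) with a
#      compensatory pause;
#   V: widened QRS (x U(1.8, 2.5)), absent P wave, inverted T, premature
#      (x U(0.45, 0.65), tighter coupling than S) with compensatory pause --
#      PVCs are premature by definition;
#   F: convex mix of the N and V wave parameters at normal timing.
# Beat-to-beat wave-amplitude jitter emulates respiration-driven morphology
# variability, and each patient gets their own wave template (per-wave
# amplitude and width factors) so that morphology is only consistent within
# a patient -- the interpatient setting the protocol is about.
# White noise and a sinusoidal baseline are added; the generative wave
# boundaries are the fiducial ground truth. Everything is driven by the
# single seed in the spec.

# template wave parameters, lead 1: amplitude (mV), center (s rel. R), width (s)
WAVE_TEMPLATE <- data.frame(
  row.names = c("P", "Q", "R", "S", "T"),
  amp = c(0.15, -0.12, 1.10, -0.25, 0.35),
  mu  = c(-0.22, -0.028, 0.000, 0.030, 0.300),
  sd  = c(0.025, 0.009, 0.011, 0.010, 0.055))
LEAD2_AMP <- c(P = 0.5, Q = 0.8, R = 0.65, S = 0.8, T = 0.6)

#' Simulation specification
#'
#' Defaults emulate the class prevalences of the ambulatory training corpus
#' the protocol targets (N/S/V/F at roughly 89.9/1.9/7.4/0.8%), a 360 Hz
#' sampling rate, and mild noise. Per-patient heart-rate and amplitude
#' offsets are drawn so that patient normalization has a real effect.
#'
#' @param n_beats Number of beats (>= 2).
#' @param fs Sampling rate, Hz.
#' @param class_probs Named probabilities over N, S, V, F; must sum to 1.
#' @param noise_sd White-noise standard deviation, mV.
#' @param baseline_amp Baseline-wander sinusoid amplitude, mV.
#' @param missing_fiducial_rate Probability that any single fiducial point
#'   is dropped (emulating delineation failures).
#' @param rr_mean Patient mean R-R, seconds; `NULL` draws U(0.7, 1.0).
#' @param rr_jitter Relative s.d. of beat-to-beat R-R variation.
#' @param amp_jitter Relative s.d. of beat-to-beat wave-amplitude variation.
#' @param amp_scale Patient amplitude factor; `NULL` draws U(0.85, 1.15).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_beats = 500L, fs = 360,
                     class_probs = c(N = 0.8991, S = 0.0185, V = 0.0743, F = 0.0081),
                     noise_sd = 0.05, baseline_amp = 0.10,
                     missing_fiducial_rate = 0.01,
                     rr_mean = NULL, rr_jitter = 0.04, amp_jitter = 0.15,
                     amp_scale = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for reproducibility")
  if (n_beats < 2L) stop("n_beats must be >= 2")
  if (is.null(names(class_probs)) || !setequal(names(class_probs), AAMI_CLASSES))
    stop("class_probs must be named over N, S, V, F")
  class_probs <- class_probs[AAMI_CLASSES]
  if (any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must be nonnegative and sum to 1")
  structure(list(n_beats = as.integer(n_beats), fs = fs,
                 class_probs = class_probs, noise_sd = noise_sd,
                 baseline_amp = baseline_amp,
                 missing_fiducial_rate = missing_fiducial_rate,
                 rr_mean = rr_mean, rr_jitter = rr_jitter,
                 amp_jitter = amp_jitter, amp_scale = amp_scale,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Patient-specific wave template: per-wave amplitude and width factors.
patient_template <- function() {
  w <- WAVE_TEMPLATE
  w$amp <- w$amp * stats::runif(5, 0.75, 1.3)
  w$sd <- w$sd * stats::runif(5, 0.85, 1.2)
  w
}

# Per-beat wave parameters for one class draw given the patient template.
# A zero amplitude marks an absent wave.
beat_wave_params <- function(label, tmpl) {
  w <- tmpl
  if (label == "V" || label == "F") {
    widen <- stats::runif(1, 1.8, 2.5)
    v <- tmpl
    v[c("Q", "R", "S"), "mu"] <- v[c("Q", "R", "S"), "mu"] * widen
    v[c("Q", "R", "S"), "sd"] <- v[c("Q", "R", "S"), "sd"] * widen
    v["P", "amp"] <- 0
    v["T", "amp"] <- -0.8 * v["T", "amp"]
    v["T", "mu"] <- 0.36
    w <- if (label == "V") v else (tmpl + v) / 2
  }
  w
}

#' Simulate a labeled two-lead ECG record
#'
#' @param spec A [sim_spec].
#' @return A list of class `sim_record`:
#'   `record` ([ecg_record]), `beats_ref` (reference [beat_annotations]),
#'   `beats_det` (list of two detected annotation sets, one per lead, R
#'   indices jittered by one sample with a 1% miss rate),
#'   `fiducials` ([fiducial_map] of the generative wave boundaries, points
#'   dropped at `missing_fiducial_rate`), `labels` (AAMI class per beat) and
#'   `truth` (per-beat generative parameters).
#' @export
simulate_record <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, simulate_record_impl(spec))
}

simulate_record_impl <- function(spec) {
  fs <- spec$fs; nb <- spec$n_beats
  rr_mean <- if (is.null(spec$rr_mean)) stats::runif(1, 0.7, 1.0) else spec$rr_mean
  amp_scale <- if (is.null(spec$amp_scale)) stats::runif(1, 0.85, 1.15) else spec$amp_scale
  tmpl <- patient_template()
  labels <- sample(AAMI_CLASSES, nb, replace = TRUE, prob = spec$class_probs)

  # R-R sequence with prematurity and compensatory pauses
  rr <- rr_mean * stats::rnorm(nb - 1, 1, spec$rr_jitter)  # rr[i]: beats i -> i+1
  comp <- rep(FALSE, nb - 1)
  for (i in 2:nb) {
    f <- if (labels[i] == "S") stats::runif(1, 0.5, 0.8)
    else if (labels[i] == "V") stats::runif(1, 0.45, 0.65) else NA
    if (!is.na(f)) {
      rr[i - 1] <- rr[i - 1] * f
      # compensatory pause, unless the next beat is itself premature
      if (i <= nb - 1 && labels[i + 1] == "N") comp[i] <- TRUE
    }
  }
  for (i in which(comp)) rr[i] <- max(2 * rr_mean - rr[i - 1], 0.4 * rr_mean)
  r_times <- 1.0 + c(0, cumsum(rr))
  n_samples <- ceiling((r_times[nb] + 1.0) * fs)
  tt <- (seq_len(n_samples) - 1) / fs

  sig <- matrix(0, n_samples, 2)
  fid <- list(empty_fiducials(nb), empty_fiducials(nb))
  params <- vector("list", nb)
  for (i in seq_len(nb)) {
    w <- beat_wave_params(labels[i], tmpl)
    params[[i]] <- w
    lo <- max(1L, floor((r_times[i] - 0.6) * fs)); hi <- min(n_samples, ceiling((r_times[i] + 0.7) * fs))
    tw <- tt[lo:hi] - r_times[i]
    jit <- stats::rnorm(nrow(w), 1, spec$amp_jitter)
    for (l in 1:2) {
      a <- w$amp * jit * amp_scale * (if (l == 2L) LEAD2_AMP else 1)
      for (k in seq_len(nrow(w))) if (a[k] != 0)
        sig[lo:hi, l] <- sig[lo:hi, l] + a[k] * exp(-(tw - w$mu[k])^2 / (2 * w$sd[k]^2))
    }
    # ground-truth fiducials (wave boundaries at +/- 3 sd)
    qrs_off <- w["S", "mu"] + 3 * w["S", "sd"]
    rel <- c(P_on = w["P", "mu"] - 3 * w["P", "sd"], P_peak = w["P", "mu"],
             P_off = w["P", "mu"] + 3 * w["P", "sd"],
             QRS_on = w["Q", "mu"] - 3 * w["Q", "sd"], Q = w["Q", "mu"],
             R = 0, S = w["S", "mu"], QRS_off = qrs_off,
             T_on = max(w["T", "mu"] - 3 * w["T", "sd"], qrs_off),
             T_peak = w["T", "mu"], T_off = w["T", "mu"] + 3 * w["T", "sd"])
    if (w["P", "amp"] == 0) rel[c("P_on", "P_peak", "P_off")] <- NA
    abs_idx <- round((r_times[i] + rel) * fs)
    for (l in 1:2) fid[[l]][i, ] <- abs_idx
  }
  drop <- matrix(stats::runif(2 * nb * length(FIDUCIAL_POINTS)) < spec$missing_fiducial_rate,
                 2 * nb)
  fid[[1]][drop[seq_len(nb), , drop = FALSE]] <- NA
  fid[[2]][drop[nb + seq_len(nb), , drop = FALSE]] <- NA

  sig <- sig + matrix(stats::rnorm(2 * n_samples, 0, spec$noise_sd), n_samples)
  phase <- stats::runif(2, 0, 2 * pi)
  for (l in 1:2)
    sig[, l] <- sig[, l] + spec$baseline_amp * sin(2 * pi * 0.25 * tt + phase[l])

  r_samples <- round(r_times * fs)
  symbols <- vapply(labels, function(lb) switch(lb,
    N = sample(c("N", "L", "R"), 1, prob = c(0.9, 0.05, 0.05)),
    S = "A", V = "V", F = "F"), character(1))
  rec_id <- sprintf("sim%05d", sample.int(99999L, 1))
  rec <- ecg_record(rec_id, fs, sig)
  beats_ref <- beat_annotations(r_samples, symbols, "reference",
                                n_samples = n_samples)
  beats_det <- lapply(1:2, function(l) {
    keep <- stats::runif(nb) >= 0.01
    if (sum(keep) < 2L) keep[1:2] <- TRUE
    s <- r_samples[keep] + sample(-1:1, sum(keep), replace = TRUE)
    beat_annotations(sort(s), rep("N", sum(keep)), "detected")
  })
  structure(list(record = rec, beats_ref = beats_ref, beats_det = beats_det,
                 fiducials = fiducial_map(fid[[1]], fid[[2]]),
                 labels = labels,
                 truth = list(rr_mean = rr_mean, amp_scale = amp_scale,
                              r_times = r_times, params = params)),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("sim_record:", x$record$record_id, "-", length(x$labels), "beats\n")
  print(table(factor(x$labels, levels = AAMI_CLASSES)))
  invisible(x)
}

#' Simulate a cohort of synthetic patients
#'
#' Draws one record per patient with independent per-patient heart rate and
#' amplitude offsets; the per-patient seeds are derived from `seed`.
#'
#' @param n_patients Number of patients.
#' @param n_beats Beats per patient.
#' @param seed Cohort seed.
#' @param ... Further arguments to [sim_spec()].
#' @return A list of `sim_record` objects named by record id.
#' @export
simulate_patients <- function(n_patients, n_beats = 300L, seed, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  out <- lapply(seq_len(n_patients), function(i)
    simulate_record(sim_spec(n_beats = n_beats,
                             seed = (as.numeric(seed) * 1009 + i * 7919) %% 2147483647, ...)))
  names(out) <- vapply(out, function(s) s$record$record_id, character(1))
  out
}

#' Filter a simulated record and assemble its feature matrix
#'
#' Convenience composition used throughout the pipeline: artifact filtering
#' followed by 249-column feature assembly.
#'
#' @param sim A `sim_record` (or a list with the same components).
#' @param fspec A [filter_spec].
#' @return A `feature_matrix`.
#' @export
extract_sim_features <- function(sim, fspec = filter_spec()) {
  rec <- filter_record(sim$record, fspec)
  assemble_matrix(rec, sim$beats_ref, sim$beats_det, sim$fiducials)
}

#' Write a simulated record to disk in either dialect (plus a truth JSON)
#'
#' @param sim A `sim_record`.
#' @param path Directory (csv) or record path prefix (wfdb).
#' @param dialect `"csv"` or `"wfdb"`.
#' @export
write_sim_record <- function(sim, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  write_record(sim$record, path, dialect)
  write_beats(sim$beats_ref, path, dialect)
  for (d in sim$beats_det[1]) write_beats(d, path, dialect)
  write_fiducials(sim$fiducials, path, dialect)
  truth <- list(labels = sim$labels, rr_mean = sim$truth$rr_mean,
                amp_scale = sim$truth$amp_scale)
  tpath <- if (dialect == "csv") file.path(path, "truth.json") else paste0(path, "_truth.json")
  jsonlite::write_json(truth, tpath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
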