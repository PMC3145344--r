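test_that("R-R features on a metronomic train are flat", {
  fs <- 360
  r <- seq(0, by = 0.8 * fs, length.out = 20)
  f <- rr_features(r, 10, fs)
  expect_equal(unname(f), rep(0.8, 4), tolerance = 1e-9)
})

test_that("a premature beat sees its short previous and long next interval", {
  fs <- 360
  rr <- c(rep(0.8, 5), 0.4, 1.2, rep(0.8, 5))
  r <- cumsum(c(1, rr)) * fs
  i <- 7                               # the beat ending the 0.4 s interval
  f <- rr_features(r, i, fs)
  expect_equal(unname(f["prev"]), 0.4, tolerance = 1e-9)
  expect_equal(unname(f["next"]), 1.2, tolerance = 1e-9)
  # boundary beats fall back to the signal mean for the missing side
  expect_equal(unname(rr_features(r, 1, fs)["prev"]), mean(rr), tolerance = 1e-9)
  expect_equal(unname(rr_features(r, length(r), fs)["next"]), mean(rr), tolerance = 1e-9)
  expect_error(rr_features_all(c(5), fs), "at least 2")
})

test_that("windowed R-R average equals a brute-force enumeration oracle", {
  fs <- 360
  set.seed(31)
  for (rep in 1:5) {
    r <- cumsum(c(1, runif(25, 0.5, 1.2))) * fs
    all <- rr_features_all(r, fs)
    for (i in c(1, 3, 13, 26)) {
      # oracle: take the beats i-5..i+5 that exist, enumerate their
      # consecutive intervals directly, average
      beats <- r[max(1, i - 5):min(length(r), i + 5)]
      expect_equal(unname(all[i, "avg10"]), mean(diff(beats) / fs),
                   tolerance = 1e-10)
    }
  }
})

test_that("normalized R-R features divide by the patient mean and drop the mean", {
  expect_equal(unname(normalized_rr_features(c(0.4, 1.2, 0.8, 0.8), 0.8)),
               c(0.5, 1.5, 1.0))
  expect_equal(unname(normalized_rr_features(c(0.8, 0.8, 0.8, 0.8), 0.8)),
               c(1, 1, 1))
  # homogeneity: scaling inputs and mean together changes nothing
  expect_equal(normalized_rr_features(c(0.4, 1.2, 0.8, 0.8) * 2, 1.6),
               normalized_rr_features(c(0.4, 1.2, 0.8, 0.8), 0.8))
  expect_error(normalized_rr_features(c(1, 1, 1, 1), 0), "positive")
})

test_that("segmentation features: 24 values, flat-signal and triangle cases", {
  fs <- 360
  fid <- full_fid_row(500, fs)
  flat <- ecgbeats::segmentation_features(fid, rep(0, 1000), fs)
  expect_length(flat$values, 24)
  expect_equal(unname(flat$values[c("qrs_area", "qrs_max", "qrs_min", "qrs_sd")]),
               rep(0, 4))
  # skewness/kurtosis undefined on zero variance: missing, not NaN
  expect_true(all(flat$missing[c("qrs_skew", "qrs_kurt")]))
  expect_equal(unname(flat$values[c("qrs_flag", "p_flag", "t_flag")]), c(1, 1, 1))
  # symmetric triangular QRS: zero skewness, length from the fiducials
  sig <- rep(0, 1000)
  on <- fid[["QRS_on"]]; off <- fid[["QRS_off"]]
  idx <- on:(off - 1)
  sig[idx + 1] <- 1 - abs(idx - 500) / 25
  tri <- ecgbeats::segmentation_features(fid, sig, fs)
  expect_equal(unname(tri$values["qrs_skew"]), 0, tolerance = 0.12)
  expect_equal(unname(tri$values["qrs_len"]), (off - on) / fs, tolerance = 1e-9)
  # closed-form moment oracle for the same window
  x <- sig[idx + 1]
  expect_equal(unname(tri$values["qrs_skew"]),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5, tolerance = 1e-12)
  # absent points flag the dependent features missing
  fid2 <- fid; fid2[["T_off"]] <- NA
  m <- ecgbeats::segmentation_features(fid2, sig, fs)
  expect_true(all(m$missing[c("t_area", "t_len", "qt_len")]))
  expect_equal(unname(m$values["t_flag"]), 0)
})

test_that("morphological features: 19 values, constant and ramp oracles", {
  fs <- 360
  const <- morphological_features(rep(3.5, 1000), 100, 150, 300, fs)
  expect_length(const$values, 19)
  expect_equal(unname(const$values), rep(3.5, 19))
  # linear ramp: interpolated samples equal the ramp at the sample times
  a <- 0.2; b <- 0.004
  sig <- a + b * (0:999)
  ramp <- morphological_features(sig, 100, 150, 300, fs)
  expect_equal(unname(ramp$values[1:10]), a + b * seq(100, 150, length.out = 10),
               tolerance = 1e-12)
  expect_equal(unname(ramp$values[11:19]), a + b * seq(150, 300, length.out = 9),
               tolerance = 1e-12)
  # absent boundary point: that window's features are missing
  miss <- morphological_features(sig, 100, 150, NA, fs)
  expect_true(all(miss$missing[11:19]))
  expect_false(any(miss$missing[1:10]))
})

test_that("Hermite expansion recovers a pure order-0 beat and its width", {
  fs <- 360
  grid <- hermite_sigma_grid()
  s_star <- grid[15]
  tt <- (-90:90) / fs
  a <- 0.7                                          # L2 norm of the beat
  beat <- a * pi^(-0.25) * exp(-(tt / s_star)^2 / 2) / sqrt(s_star)
  fit <- hermite_features(beat, fs)
  expect_s3_class(fit, "hermite_fit")
  expect_equal(fit$sigma, s_star)
  expect_equal(fit$coefficients[1], a, tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-6)
  expect_length(fit$coefficients, 20)
})

test_that("Hermite reconstruction error decreases with the expansion order", {
  sim <- shared_cohort()$sims[[1]]
  W <- beat_windows(sim$record$signals[, 1], sim$beats_ref$r_samples[1:20],
                    sim$record$fs)
  for (j in c(1, 7, 15)) {
    e5 <- hermite_features(W[, j], 360, order = 5L)$reconstruction_error
    e20 <- hermite_features(W[, j], 360, order = 20L)$reconstruction_error
    expect_lte(e20, e5 + 1e-12)
  }
})

test_that("degenerate all-zero beats get zero coefficients and the grid midpoint", {
  fit <- hermite_features(rep(0, 181), 360)
  expect_equal(fit$coefficients, rep(0, 20))
  expect_equal(fit$sigma, hermite_sigma_grid()[15])
  expect_equal(fit$reconstruction_error, 0)
})

test_that("HOS features: 30 values; 2nd order matches a direct lag-sum oracle", {
  set.seed(9)
  beat <- rnorm(181)
  v <- hos_features(beat, 360)
  expect_length(v, 30)
  lags <- hos_lags(360)
  x <- beat - mean(beat)
  for (k in seq_along(lags)) {
    tau <- lags[k]
    acc <- 0                     # brute-force truncated autocorrelation sum
    for (t in seq_along(x)) {
      u <- t + tau
      if (u >= 1 && u <= length(x)) acc <- acc + x[t] * x[u]
    }
    expect_equal(unname(v[k]), acc / length(x), tolerance = 1e-12)
  }
})

test_that("odd beats have a vanishing 3rd-order cumulant at lag zero", {
  tt <- -90:90
  odd <- sin(tt / 8)                               # odd around the center
  v <- hos_features(odd, 360, lags = 0L)
  expect_equal(unname(v["o3_l01"]), 0, tolerance = 1e-12)
})

test_that("normalized segmentation: 21 values, unit at the patient mean, scale-free", {
  fs <- 360
  fid <- full_fid_row(500, fs)
  sig <- rep(0, 1000); sig[480:520] <- 0.5 + 0.3 * sin((1:41) / 3)
  seg <- ecgbeats::segmentation_features(fid, sig, fs)$values
  pm <- seg                                         # patient mean == this beat
  ns <- normalized_segmentation_features(seg, pm)
  expect_length(ns$values, 21)
  expect_false(any(grepl("flag", names(ns$values))))
  expect_equal(unname(ns$values[!ns$missing]),
               rep(1, sum(!ns$missing)))
  # doubling beat and mean leaves ratios unchanged
  ns2 <- normalized_segmentation_features(seg * 2, pm * 2)
  expect_equal(ns2$values, ns$values)
  # zero patient mean makes the ratio missing
  pm0 <- pm; pm0["t_area"] <- 0
  expect_true(normalized_segmentation_features(seg, pm0)$missing["t_area"])
})

test_that("patient-mean imputation fills only the missing entries", {
  fm <- shared_cohort()$fm
  expect_false(anyNA(fm$x))                        # fully imputed cohort
  # hand-built case: single missing among {2, 4} imputes 3
  toy <- structure(list(
    x = matrix(c(2, 4, NA, 1, 1, 1), ncol = 2,
               dimnames = list(NULL, c("a", "b"))),
    mask = NULL, info = NULL,
    beats = data.frame(record = c("p", "p", "p"))), class = "feature_matrix")
  toy$mask <- is.na(toy$x)
  out <- impute_patient_mean(toy)
  expect_equal(unname(out$x[3, "a"]), 3)
  expect_equal(unname(out$x[1:2, "a"]), c(2, 4))   # untouched entries
  expect_true(out$mask[3, "a"])                    # mask preserved for audit
  # no missing values: identity
  expect_equal(impute_patient_mean(out)$x, out$x)
})

test_that("the feature catalogue is fixed and complete: 249 named columns", {
  info <- feature_names()
  expect_equal(nrow(info), 249)
  expect_false(any(duplicated(info$name)))
  counts <- table(info$group, info$lead)
  expect_equal(unname(counts["segmentation", c("l1", "l2")]), c(24, 24))
  expect_equal(unname(counts["morphological", c("l1", "l2")]), c(19, 19))
  expect_equal(unname(counts["hbf", c("l1", "l2")]), c(20, 20))
  expect_equal(unname(counts["hos", c("l1", "l2")]), c(30, 30))
  expect_equal(unname(counts["norm_segmentation", c("l1", "l2")]), c(21, 21))
  expect_equal(unname(counts["rr", c("ref", "l1", "l2")]), c(4, 4, 4))
  expect_equal(unname(counts["norm_rr", c("ref", "l1", "l2")]), c(3, 3, 3))
})

test_that("assembly drops excluded beats but never loses feature columns", {
  sim <- simulate_record(sim_spec(n_beats = 20, seed = 13))
  # poison some symbols to paced (excluded) beats
  sim$beats_ref$symbols[c(3, 8)] <- "/"
  sim$beats_ref$aami_labels[c(3, 8)] <- "Q"
  fm <- extract_sim_features(sim)
  expect_equal(ncol(fm$x), 249)
  expect_equal(nrow(fm$x), 18)
  expect_false("Q" %in% fm$beats$label)
  expect_equal(colnames(fm$x), feature_names()$name)
})

test_that("both leads run through the same code path", {
  sim <- simulate_record(sim_spec(n_beats = 15, seed = 17))
  sim$record$signals[, 2] <- sim$record$signals[, 1]   # identical leads
  sim$fiducials$lead2 <- sim$fiducials$lead1
  sim$beats_det[[2]] <- sim$beats_det[[1]]
  fm <- extract_sim_features(sim)
  info <- feature_names()
  for (g in c("segmentation", "morphological", "hbf", "hos", "norm_segmentation")) {
    c1 <- info$name[info$group == g & info$lead == "l1"]
    c2 <- info$name[info$group == g & info$lead == "l2"]
    expect_equal(unname(fm$x[, c1]), unname(fm$x[, c2]), tolerance = 1e-12)
  }
})

test_that("misaligned fiducial maps are rejected", {
  sim <- simulate_record(sim_spec(n_beats = 10, seed = 19))
  bad <- full_fid_map(sim$beats_ref$r_samples[1:5])
  expect_error(assemble_matrix(filter_record(sim$record), sim$beats_ref,
                               sim$beats_det, bad), "misaligned")
})

test_that("feature matrices round-trip through CSV + JSON sidecar", {
  d <- withr::local_tempdir()
  sim <- simulate_record(sim_spec(n_beats = 12, seed = 23))
  fm <- impute_patient_mean(extract_sim_features(sim))
  write_features(fm, file.path(d, "feat"))
  back <- read_features(file.path(d, "feat"))
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_equal(back$beats$label, fm$beats$label)
  expect_equal(back$info$name, fm$info$name)
})
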