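# Per-beat feature groups. All durations are in seconds, amplitudes in mV.
# Sample indices are 0-based; wave windows are half-open [on, off).

## ---- R-R interval features ----

#' R-R interval features for every beat
#'
#' For each R spike: the previous R-R interval, the next R-R interval, the
#' average R-R interval in a window of 10 surrounding R spikes (the up-to-10
#' intervals formed by the 5 beats before and 5 after, truncated at record
#' edges), and the signal mean R-R interval. Boundary beats fall back to the
#' signal mean for the interval they lack.
#'
#' @param r_samples Strictly increasing R-spike sample indices.
#' @param fs Sampling frequency, Hz.
#' @return `rr_features_all`: an n x 4 matrix (`prev`, `next`, `avg10`,
#'   `mean`), in seconds. `rr_features`: the 4-vector for beat `i`.
#' @export
rr_features_all <- function(r_samples, fs) {
  n <- length(r_samples)
  if (n < 2L) stop("need at least 2 beats for R-R features")
  if (any(diff(r_samples) <= 0)) stop("r_samples must be strictly increasing")
  rr <- diff(r_samples) / fs              # rr[j] = interval between beats j and j+1
  grand <- mean(rr)
  prv <- c(grand, rr)
  nxt <- c(rr, grand)
  avg10 <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - 5L):min(n - 1L, i + 4L)   # intervals touching beats i-5..i+5
    mean(rr[j])
  }, numeric(1))
  cbind(prev = prv, `next` = nxt, avg10 = avg10, mean = rep(grand, n))
}

#' @rdname rr_features_all
#' @param i Beat index (1-based).
#' @export
rr_features <- function(r_samples, i, fs) {
  n <- length(r_samples)
  if (i < 1L || i > n) stop("beat index out of range")
  rr_features_all(r_samples, fs)[i, ]
}

# R-R features of a detected annotation stream, aligned to reference beats:
# each reference beat takes the R-R context of the nearest detected spike, so
# detector misses never drop a beat row.
rr_features_detected <- function(ref_samples, det_samples, fs) {
  det <- rr_features_all(det_samples, fs)
  j <- vapply(ref_samples, function(s) which.min(abs(det_samples - s)), integer(1))
  det[j, , drop = FALSE]
}

#' Patient-normalized R-R features
#'
#' The previous, next and windowed-average R-R intervals divided by the
#' patient's mean R-R interval. The signal-mean feature itself is dropped:
#' it normalizes to the constant 1 and carries no information.
#'
#' @param rr4 The 4-vector (or n x 4 matrix) returned by the R-R extractor.
#' @param patient_mean Patient mean R-R interval, seconds (positive).
#' @return 3 values (or an n x 3 matrix): `prev`, `next`, `avg10` ratios.
#' @export
normalized_rr_features <- function(rr4, patient_mean) {
  if (!is.finite(patient_mean) || patient_mean <= 0)
    stop("patient mean R-R must be positive")
  if (is.matrix(rr4)) rr4[, 1:3, drop = FALSE] / patient_mean
  else rr4[1:3] / patient_mean
}

## ---- segmentation features ----

SEG_NAMES <- c("qrs_flag", "qrs_area", "qrs_max", "qrs_min", "qrs_pos_area",
               "qrs_neg_area", "qrs_sd", "qrs_skew", "qrs_kurt", "qrs_len",
               "qr_len", "rs_len",
               "p_flag", "p_area", "p_max", "p_min", "p_len",
               "t_flag", "t_area", "t_max", "t_min", "t_len", "qt_len", "st_len")

# signal values in half-open window [on, off), 0-based fractional bounds
wave_samples <- function(signal, on, off) {
  i0 <- ceiling(on); i1 <- ceiling(off) - 1
  if (is.na(i0) || is.na(i1) || i1 < i0) return(numeric(0))
  signal[(max(i0, 0):min(i1, length(signal) - 1)) + 1L]
}

#' Segmentation-interval features of one beat
#'
#' The 24 features computed from the delineated characteristic waves:
#' QRS flag, area, maximum, minimum, positive area, negative area, standard
#' deviation, skewness, kurtosis, length, QR length and RS length; P flag,
#' area, maximum, minimum and length; T flag, area, maximum, minimum,
#' length, QT length and ST length. A wave's flag is 1 when its onset/offset
#' pair was detected, else 0. Any feature whose required fiducial points are
#' absent is returned as `NA` and flagged missing (missingness is data, not
#' an error); skewness and kurtosis are also missing on zero-variance
#' windows. Areas are signed sums of amplitude times the sample period;
#' lengths are in seconds.
#'
#' @param fid_row Named numeric vector over the 11 canonical fiducial points
#'   (one row of a [fiducial_map] lead table); `NA` marks an absent point.
#' @param signal One lead's filtered samples, mV.
#' @param fs Sampling frequency, Hz.
#' @return A list with `values` (named 24-vector) and `missing` (logical 24).
#' @export
segmentation_features <- function(fid_row, signal, fs) {
  g <- function(p) unname(fid_row[[p]])
  v <- stats::setNames(rep(NA_real_, 24L), SEG_NAMES)
  dt <- 1 / fs
  sec <- function(a, b) (b - a) / fs

  wave_stats <- function(on, off, prefix) {
    if (is.na(on) || is.na(off)) return()
    x <- wave_samples(signal, on, off)
    if (!length(x)) return()
    v[[paste0(prefix, "_area")]] <<- sum(x) * dt
    v[[paste0(prefix, "_max")]] <<- max(x)
    v[[paste0(prefix, "_min")]] <<- min(x)
    v[[paste0(prefix, "_len")]] <<- sec(on, off)
    if (prefix == "qrs") {
      v[["qrs_pos_area"]] <<- sum(pmax(x, 0)) * dt
      v[["qrs_neg_area"]] <<- sum(pmin(x, 0)) * dt
      m <- mean(x); m2 <- mean((x - m)^2)
      v[["qrs_sd"]] <<- sqrt(m2 * length(x) / max(1L, length(x) - 1L))
      if (m2 > 0) {
        v[["qrs_skew"]] <<- mean((x - m)^3) / m2^1.5
        v[["qrs_kurt"]] <<- mean((x - m)^4) / m2^2 - 3
      }
    }
  }
  v[["qrs_flag"]] <- as.numeric(!is.na(g("QRS_on")) && !is.na(g("QRS_off")))
  v[["p_flag"]] <- as.numeric(!is.na(g("P_on")) && !is.na(g("P_off")))
  v[["t_flag"]] <- as.numeric(!is.na(g("T_on")) && !is.na(g("T_off")))
  wave_stats(g("QRS_on"), g("QRS_off"), "qrs")
  wave_stats(g("P_on"), g("P_off"), "p")
  wave_stats(g("T_on"), g("T_off"), "t")
  if (!is.na(g("Q")) && !is.na(g("R"))) v[["qr_len"]] <- sec(g("Q"), g("R"))
  if (!is.na(g("R")) && !is.na(g("S"))) v[["rs_len"]] <- sec(g("R"), g("S"))
  if (!is.na(g("QRS_on")) && !is.na(g("T_off"))) v[["qt_len"]] <- sec(g("QRS_on"), g("T_off"))
  if (!is.na(g("QRS_off")) && !is.na(g("T_on"))) v[["st_len"]] <- sec(g("QRS_off"), g("T_on"))
  list(values = v, missing = is.na(v))
}

#' Patient-normalized segmentation features
#'
#' The 21 non-flag segmentation features divided by the patient's mean value
#' of each feature (computed over the patient's non-missing beats). The
#' three boolean flags are excluded from normalization. A zero patient mean
#' makes the ratio undefined: the feature is flagged missing.
#'
#' @param seg24 Named 24-vector from [segmentation_features()].
#' @param patient_means Named vector of per-feature patient means (at least
#'   the 21 non-flag names).
#' @return A list with `values` (named 21-vector) and `missing`.
#' @export
normalized_segmentation_features <- function(seg24, patient_means) {
  keep <- setdiff(SEG_NAMES, c("qrs_flag", "p_flag", "t_flag"))
  den <- patient_means[keep]
  out <- ifelse(is.na(den) | den == 0, NA_real_, seg24[keep] / den)
  names(out) <- keep
  list(values = out, missing = is.na(out))
}

## ---- morphological features ----

#' Morphological features of one beat
#'
#' Ten features obtained by uniformly sampling the ECG amplitude in the
#' window from QRS onset to QRS offset, and nine more in the window from QRS
#' offset to T-wave offset; both windows include their endpoints and
#' intermediate amplitudes are linearly interpolated between stored samples.
#' An absent boundary point makes all features of that window missing.
#'
#' @param signal One lead's filtered samples, mV.
#' @param qrs_on,qrs_off,t_off Fiducial sample indices (0-based, may be
#'   fractional) or `NA`.
#' @param fs Sampling frequency, Hz (unused by the interpolation itself;
#'   kept for interface symmetry).
#' @return A list with `values` (named 19-vector) and `missing`.
#' @export
morphological_features <- function(signal, qrs_on, qrs_off, t_off, fs) {
  nm <- c(sprintf("qrs_%02d", 1:10), sprintf("t_%02d", 1:9))
  v <- stats::setNames(rep(NA_real_, 19L), nm)
  samp <- function(a, b, k) {
    q <- pmin(pmax(seq(a, b, length.out = k), 0), length(signal) - 1)
    i <- pmin(floor(q), length(signal) - 2)
    f <- q - i
    signal[i + 1L] * (1 - f) + signal[i + 2L] * f
  }
  if (!is.na(qrs_on) && !is.na(qrs_off) && qrs_off >= qrs_on)
    v[1:10] <- samp(qrs_on, qrs_off, 10L)
  if (!is.na(qrs_off) && !is.na(t_off) && t_off >= qrs_off)
    v[11:19] <- samp(qrs_off, t_off, 9L)
  list(values = v, missing = is.na(v))
}

## ---- Hermite basis expansion ----

# Orthonormal Hermite functions phi_0..phi_{order-1} evaluated at t (already
# divided by sigma); stable normalized recurrence.
hermite_basis <- function(t, order) {
  B <- matrix(0, length(t), order)
  B[, 1] <- pi^(-0.25) * exp(-t^2 / 2)
  if (order > 1) B[, 2] <- sqrt(2) * t * B[, 1]
  if (order > 2) for (n in 2:(order - 1))
    B[, n + 1] <- t * sqrt(2 / n) * B[, n] - sqrt((n - 1) / n) * B[, n - 1]
  B
}

#' Default geometric sigma grid for the Hermite expansion
#'
#' 30 geometrically spaced width values spanning 5--100 ms, covering
#' physiological QRS widths from narrow normal complexes to wide ventricular
#' ones.
#' @param n Number of grid points.
#' @param lo,hi Grid range in seconds.
#' @return Numeric vector of widths in seconds.
#' @export
hermite_sigma_grid <- function(n = 30, lo = 0.005, hi = 0.100) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Fit all beats (columns of X, centered on R) at every sigma; returns the
# per-beat best sigma, 20 coefficients and RMS reconstruction error.
# Coefficients are least-squares projections onto the sampled basis
# (identical to inner products when the sampled basis is orthonormal).
hermite_fit_all <- function(X, fs, order = 20L, sigma_grid = hermite_sigma_grid()) {
  n_samp <- nrow(X); n_beat <- ncol(X)
  if (n_samp < order) stop("beat window shorter than the Hermite order")
  half <- (n_samp - 1) / 2
  tt <- (seq_len(n_samp) - 1 - half) / fs        # seconds relative to R
  best_err <- rep(Inf, n_beat)
  best_sig <- rep(NA_real_, n_beat)
  best_coef <- matrix(0, order, n_beat)
  for (s in sigma_grid) {
    B <- hermite_basis(tt / s, order) / sqrt(s)
    sv <- svd(B)
    pos <- sv$d > max(sv$d) * 1e-10
    C <- sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% X) / sv$d[pos])
    R <- X - B %*% C
    err <- sqrt(colMeans(R^2))
    take <- err < best_err
    if (any(take)) {
      best_err[take] <- err[take]
      best_sig[take] <- s
      best_coef[, take] <- C[, take]
    }
  }
  zero <- colSums(X != 0) == 0L                   # degenerate all-zero beats
  if (any(zero)) {
    best_sig[zero] <- sigma_grid[ceiling(length(sigma_grid) / 2)]
    best_coef[, zero] <- 0; best_err[zero] <- 0
  }
  list(coefficients = best_coef, sigma = best_sig, error = best_err)
}

#' Hermite basis expansion of one beat
#'
#' Projects a beat window centered on the R spike onto the orthonormal
#' Hermite basis functions of orders 0..19, with the width parameter sigma
#' chosen from a geometric grid so as to minimize the root-mean-square
#' reconstruction error of the beat. The 20 expansion coefficients are the
#' HBF features.
#'
#' @param beat Numeric vector of amplitudes centered on R (odd length).
#' @param fs Sampling frequency, Hz.
#' @param order Expansion order (number of basis functions), default 20.
#' @param sigma_grid Candidate widths in seconds, default
#'   [hermite_sigma_grid()].
#' @return An object of class `hermite_fit`: `order`, `sigma` (seconds),
#'   `coefficients` (length `order`), `reconstruction_error` (RMS, mV).
#' @export
hermite_features <- function(beat, fs, order = 20L,
                             sigma_grid = hermite_sigma_grid()) {
  f <- hermite_fit_all(matrix(beat, ncol = 1), fs, order, sigma_grid)
  structure(list(order = order, sigma = f$sigma[1],
                 coefficients = as.numeric(f$coefficients[, 1]),
                 reconstruction_error = f$error[1]),
            class = "hermite_fit")
}

#' @export
print.hermite_fit <- function(x, ...) {
  cat(sprintf("hermite_fit: order %d, sigma %.1f ms, RMS error %.4g mV\n",
              x$order, 1000 * x$sigma, x$reconstruction_error))
  invisible(x)
}

## ---- higher-order statistics ----

#' Default cumulant lags: 10 equally spaced points in [-250, 250] ms
#' @param fs Sampling frequency, Hz.
#' @return Integer lags in samples.
#' @export
hos_lags <- function(fs) round(seq(-0.25, 0.25, length.out = 10) * fs)

#' Higher-order cumulant features of one beat
#'
#' Sample cumulant functions of order 2, 3 and 4 of the beat window
#' (mean-removed, treated as one realization), evaluated at 10 equally
#' spaced lags spanning -250 to +250 ms around the R spike. Diagonal slices
#' are used for orders 3 and 4: with `m_q(tau)` the biased (1/N) lagged
#' sample moments, `c2(tau) = m2(tau)` (the autocorrelation function),
#' `c3(tau) = E[x_t x_{t+tau}^2]` and
#' `c4(tau) = E[x_t x_{t+tau}^3] - 3 m2(tau) m2(0)`.
#' The 30 values are ordered by (order, lag).
#'
#' @param beat Numeric vector of amplitudes centered on R; must span at
#'   least the largest requested lag on each side.
#' @param fs Sampling frequency, Hz.
#' @param lags Integer lags in samples; default [hos_lags()].
#' @return Named numeric vector of length `3 * length(lags)`.
#' @export
hos_features <- function(beat, fs, lags = hos_lags(fs)) {
  n <- length(beat)
  if (n <= max(abs(lags))) stop("beat window shorter than the maximum lag")
  x <- beat - mean(beat)
  lagmom <- function(tau, p) {       # (1/N) sum x_t * x_{t+tau}^p, truncated
    t0 <- max(1L, 1L - tau); t1 <- min(n, n - tau)
    sum(x[t0:t1] * x[(t0:t1) + tau]^p) / n
  }
  c2 <- vapply(lags, lagmom, numeric(1), p = 1)
  c3 <- vapply(lags, lagmom, numeric(1), p = 2)
  c4 <- vapply(lags, lagmom, numeric(1), p = 3) - 3 * c2 * lagmom(0L, 1)
  stats::setNames(c(c2, c3, c4),
                  c(sprintf("o2_l%02d", seq_along(lags)),
                    sprintf("o3_l%02d", seq_along(lags)),
                    sprintf("o4_l%02d", seq_along(lags))))
}
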