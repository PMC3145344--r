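#' Construct a two-lead ECG record
#'
#' An `ecg_record` holds two synchronized leads of equal length, the sampling
#' frequency and a record identifier. Amplitudes are in millivolts; sample
#' indices throughout the package are 0-based and windows are half-open
#' `[on, off)`.
#'
#' @param record_id Character scalar identifying the record (patient).
#' @param fs Sampling frequency in samples per second (positive).
#' @param signals Numeric matrix with one column per lead (exactly 2), in mV.
#' @param lead_names Character vector of length 2.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, signals, lead_names = c("MLII", "V1")) {
  signals <- as.matrix(signals)
  if (ncol(signals) != 2L)
    stop("an ecg_record has exactly 2 leads, got ", ncol(signals))
  if (nrow(signals) < 1L) stop("empty signal")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(lead_names) != 2L) stop("lead_names must have length 2")
  storage.mode(signals) <- "double"
  colnames(signals) <- lead_names
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         signals = signals, lead_names = as.character(lead_names)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record '%s': %d samples x 2 leads (%s), fs = %g Hz, %.1f s\n",
              x$record_id, nrow(x$signals), paste(x$lead_names, collapse = ", "),
              x$fs, nrow(x$signals) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) nrow(x$signals)

#' Construct a beat annotation set
#'
#' Sorted R-spike sample indices (0-based), the raw beat symbols and their
#' AAMI class labels, plus the provenance of the annotations (`"reference"`
#' for database annotations, `"detected"` for the output of an automatic
#' detector).
#'
#' @param r_samples Strictly increasing integer vector of 0-based R-spike
#'   sample indices.
#' @param symbols Raw beat-type codes (MIT-BIH single-character symbols).
#' @param provenance `"reference"` or `"detected"`.
#' @param aami_labels Optional; computed from `symbols` via [map_aami()] when
#'   missing.
#' @param n_samples Optional record length used to validate indices.
#' @return An object of class `beat_annotations`.
#' @seealso [map_aami()]
#' @export
beat_annotations <- function(r_samples, symbols,
                             provenance = c("reference", "detected"),
                             aami_labels = NULL, n_samples = NULL) {
  provenance <- match.arg(provenance)
  r_samples <- as.integer(r_samples)
  if (length(r_samples) && any(diff(r_samples) <= 0L))
    stop("r_samples must be strictly increasing")
  if (any(r_samples < 0L)) stop("negative sample index")
  if (!is.null(n_samples) && length(r_samples) && max(r_samples) >= n_samples)
    stop("annotation beyond record length")
  symbols <- as.character(symbols)
  if (length(symbols) != length(r_samples))
    stop("symbols and r_samples lengths differ")
  if (is.null(aami_labels)) aami_labels <- map_aami(symbols)
  if (length(aami_labels) != length(r_samples))
    stop("aami_labels and r_samples lengths differ")
  structure(
    list(r_samples = r_samples, symbols = symbols,
         aami_labels = as.character(aami_labels), provenance = provenance),
    class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("beat_annotations (%s): %d beats\n", x$provenance, length(x$r_samples)))
  if (length(x$aami_labels)) print(table(x$aami_labels))
  invisible(x)
}

# Canonical fiducial point names, in temporal order within a beat.
FIDUCIAL_POINTS <- c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S",
                     "QRS_off", "T_on", "T_peak", "T_off")

#' Construct a per-beat fiducial map
#'
#' Holds, for every beat and each of the two leads, the sample indices of the
#' characteristic points of the P wave, QRS complex and T wave. A missing
#' (undetected) point is `NA` -- an explicit absent state, never a sentinel
#' index. Points present within one beat must be in temporal order
#' P_on <= ... <= T_off.
#'
#' @param lead1,lead2 Numeric matrices, one row per beat, columns named after
#'   the 11 canonical points (`P_on, P_peak, P_off, QRS_on, Q, R, S, QRS_off,
#'   T_on, T_peak, T_off`); entries are 0-based sample indices or `NA`.
#' @return An object of class `fiducial_map`.
#' @export
fiducial_map <- function(lead1, lead2) {
  check_one <- function(m, nm) {
    m <- as.matrix(m)
    if (is.null(colnames(m)) || !identical(colnames(m), FIDUCIAL_POINTS))
      stop(nm, ": columns must be the 11 canonical fiducial points in order")
    for (i in seq_len(nrow(m))) {
      v <- m[i, ][!is.na(m[i, ])]
      if (length(v) > 1L && any(diff(v) < 0))
        stop(nm, ": fiducials out of temporal order at beat ", i)
    }
    storage.mode(m) <- "double"
    m
  }
  lead1 <- check_one(lead1, "lead1"); lead2 <- check_one(lead2, "lead2")
  if (nrow(lead1) != nrow(lead2)) stop("per-lead fiducial tables differ in beat count")
  structure(list(lead1 = lead1, lead2 = lead2, n_beats = nrow(lead1)),
            class = "fiducial_map")
}

#' @export
print.fiducial_map <- function(x, ...) {
  na1 <- sum(is.na(x$lead1)); na2 <- sum(is.na(x$lead2))
  cat(sprintf("fiducial_map: %d beats, %d absent points (lead1 %d, lead2 %d)\n",
              x$n_beats, na1 + na2, na1, na2))
  invisible(x)
}

# Empty fiducial matrix with canonical columns.
empty_fiducials <- function(n_beats) {
  matrix(NA_real_, n_beats, length(FIDUCIAL_POINTS),
         dimnames = list(NULL, FIDUCIAL_POINTS))
}
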