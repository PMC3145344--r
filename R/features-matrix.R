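# Assembly of the 249-column per-beat feature matrix.
#
# Per lead (x2): 24 segmentation + 19 morphological + 20 HBF + 30 HOS +
# 21 normalized segmentation = 114. Shared: 4 reference R-R + 4 detected R-R
# per lead + 3 normalized reference R-R + 3 normalized detected R-R per
# lead. 2*114 + (4 + 8) + (3 + 6) = 249.

#' Canonical feature catalogue
#'
#' The 249 feature names with their group and lead, fixed by the feature
#' definitions alone (never by the data). Lead `ref` marks features computed
#' from the reference R-spike annotations, common to both leads; `l1`/`l2`
#' are lead-specific (for R-R groups, the per-lead detected annotations).
#'
#' @return A data.frame with columns `name`, `group`, `lead`.
#' @export
feature_names <- function() {
  per_lead <- function(l) {
    data.frame(
      name = c(paste0("seg.", SEG_NAMES, ".", l),
               paste0("morph.", c(sprintf("qrs_%02d", 1:10), sprintf("t_%02d", 1:9)), ".", l),
               paste0("hbf.", sprintf("c%02d", 0:19), ".", l),
               paste0("hos.", c(sprintf("o2_l%02d", 1:10), sprintf("o3_l%02d", 1:10),
                                sprintf("o4_l%02d", 1:10)), ".", l),
               paste0("nseg.", setdiff(SEG_NAMES, c("qrs_flag", "p_flag", "t_flag")), ".", l)),
      group = rep(c("segmentation", "morphological", "hbf", "hos", "norm_segmentation"),
                  c(24L, 19L, 20L, 30L, 21L)),
      lead = l)
  }
  rr <- data.frame(
    name = c(paste0("rr.", c("prev", "next", "avg10", "mean"), ".ref"),
             paste0("rr.", c("prev", "next", "avg10", "mean"), ".l1"),
             paste0("rr.", c("prev", "next", "avg10", "mean"), ".l2"),
             paste0("nrr.", c("prev", "next", "avg10"), ".ref"),
             paste0("nrr.", c("prev", "next", "avg10"), ".l1"),
             paste0("nrr.", c("prev", "next", "avg10"), ".l2")),
    group = rep(c("rr", "norm_rr"), c(12L, 9L)),
    lead = c(rep(c("ref", "l1", "l2"), each = 4L), rep(c("ref", "l1", "l2"), each = 3L)))
  out <- rbind(per_lead("l1"), per_lead("l2"), rr)
  rownames(out) <- NULL
  out
}

#' Extract beat windows centered on the R spikes
#'
#' Cuts a window of `half` seconds on each side of every R spike (so each
#' window spans at least +/-250 ms by default); samples falling outside the
#' record are zero-padded.
#'
#' @param signal One lead's samples.
#' @param r_samples 0-based R sample indices.
#' @param fs Sampling frequency, Hz.
#' @param half Half-width of the window, seconds.
#' @return Matrix with one column per beat, `2*round(half*fs)+1` rows.
#' @export
beat_windows <- function(signal, r_samples, fs, half = 0.25) {
  h <- round(half * fs)
  offs <- -h:h
  n <- length(signal)
  W <- vapply(r_samples, function(r) {
    idx <- r + offs + 1L
    ok <- idx >= 1L & idx <= n
    w <- numeric(length(offs)); w[ok] <- signal[idx[ok]]
    w
  }, numeric(length(offs)))
  matrix(W, nrow = length(offs))
}

# Per-lead feature block (seg + morph + hbf + hos + nseg), identical code
# path for both leads. Returns list(values, missing).
lead_feature_block <- function(signal, fid_lead, r_samples, fs) {
  nb <- length(r_samples)
  seg <- matrix(NA_real_, nb, 24L, dimnames = list(NULL, SEG_NAMES))
  mo <- matrix(NA_real_, nb, 19L)
  for (i in seq_len(nb)) {
    seg[i, ] <- segmentation_features(fid_lead[i, ], signal, fs)$values
    mo[i, ] <- morphological_features(signal, fid_lead[i, "QRS_on"],
                                      fid_lead[i, "QRS_off"],
                                      fid_lead[i, "T_off"], fs)$values
  }
  W <- beat_windows(signal, r_samples, fs)
  hb <- t(hermite_fit_all(W, fs)$coefficients)
  ho <- t(apply(W, 2, hos_features, fs = fs))
  if (nb == 0L) { hb <- matrix(0, 0L, 20L); ho <- matrix(0, 0L, 30L) }
  pm <- colMeans(seg, na.rm = TRUE)              # patient means, non-missing beats
  keep <- setdiff(SEG_NAMES, c("qrs_flag", "p_flag", "t_flag"))
  ns <- matrix(NA_real_, nb, 21L)
  for (i in seq_len(nb))
    ns[i, ] <- normalized_segmentation_features(seg[i, ], pm)$values
  vals <- cbind(seg, mo, hb, ho, ns)
  list(values = vals, missing = is.na(vals))
}

#' Assemble the 249-column feature matrix of one record
#'
#' Runs every feature group on both leads of a (filtered) record and builds
#' the per-beat feature matrix. Beats whose AAMI label is the excluded class
#' `"Q"` are dropped at this stage; R-R context is still computed on the full
#' R-spike train first, so excluded beats contribute to the rhythm of their
#' neighbours. Missing feature values (absent fiducials, undefined moments,
#' zero normalization means) are `NA` with the missingness mask kept
#' alongside; apply [impute_patient_mean()] before model fitting.
#'
#' @param rec A filtered [ecg_record].
#' @param beats_ref Reference [beat_annotations].
#' @param beats_det Detected annotations: a single [beat_annotations] (used
#'   for both leads) or a list of two (one per lead).
#' @param fid A [fiducial_map] aligned with `beats_ref` (same beat count).
#' @return An object of class `feature_matrix`: numeric matrix `x`
#'   (beats x 249), logical `mask` (pre-imputation missingness), the
#'   catalogue `info` (see [feature_names()]) and per-beat metadata `beats`
#'   (record, R sample, raw symbol, AAMI label).
#' @export
assemble_matrix <- function(rec, beats_ref, beats_det, fid) {
  stopifnot(inherits(rec, "ecg_record"), inherits(beats_ref, "beat_annotations"))
  if (inherits(beats_det, "beat_annotations")) beats_det <- list(beats_det, beats_det)
  if (length(beats_det) != 2L) stop("beats_det must be one or two annotation sets")
  if (fid$n_beats != length(beats_ref$r_samples))
    stop("misaligned inputs: fiducial map has ", fid$n_beats,
         " beats, annotations have ", length(beats_ref$r_samples))
  fs <- rec$fs
  info <- feature_names()
  keep <- beats_ref$aami_labels != "Q"
  nb <- sum(keep)
  r_all <- beats_ref$r_samples

  blocks <- lapply(1:2, function(l) {
    fl <- if (l == 1L) fid$lead1 else fid$lead2
    lead_feature_block(rec$signals[, l], fl[keep, , drop = FALSE],
                       r_all[keep], fs)
  })

  if (length(r_all) >= 2L) {
    rr_ref <- rr_features_all(r_all, fs)[keep, , drop = FALSE]
    rr_det <- lapply(1:2, function(l)
      rr_features_detected(r_all, beats_det[[min(l, length(beats_det))]]$r_samples,
                           fs)[keep, , drop = FALSE])
    nrr_ref <- normalized_rr_features(rr_ref, mean(diff(r_all) / fs))
    nrr_det <- lapply(1:2, function(l)
      normalized_rr_features(rr_det[[l]],
                             mean(diff(beats_det[[l]]$r_samples) / fs)))
  } else {
    rr_ref <- matrix(NA_real_, nb, 4L); rr_det <- list(rr_ref, rr_ref)
    nrr_ref <- matrix(NA_real_, nb, 3L); nrr_det <- list(nrr_ref, nrr_ref)
  }

  x <- cbind(blocks[[1]]$values, blocks[[2]]$values,
             rr_ref, rr_det[[1]], rr_det[[2]],
             nrr_ref, nrr_det[[1]], nrr_det[[2]])
  colnames(x) <- info$name
  stopifnot(ncol(x) == 249L)
  structure(
    list(x = x, mask = is.na(x), info = info,
         beats = data.frame(record = rec$record_id,
                            r_sample = r_all[keep],
                            symbol = beats_ref$symbols[keep],
                            label = beats_ref$aami_labels[keep])),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d beats x %d features, %d missing values (%.2f%%)\n",
              nrow(x$x), ncol(x$x), sum(x$mask),
              100 * mean(x$mask)))
  if (nrow(x$beats)) print(table(x$beats$label))
  invisible(x)
}

#' Combine feature matrices of several records
#' @param fms List of `feature_matrix` objects with identical catalogues.
#' @return A single `feature_matrix`.
#' @export
rbind_features <- function(fms) {
  stopifnot(length(fms) >= 1L)
  nm <- colnames(fms[[1]]$x)
  for (f in fms) stopifnot(identical(colnames(f$x), nm))
  structure(
    list(x = do.call(rbind, lapply(fms, `[[`, "x")),
         mask = do.call(rbind, lapply(fms, `[[`, "mask")),
         info = fms[[1]]$info,
         beats = do.call(rbind, lapply(fms, `[[`, "beats"))),
    class = "feature_matrix")
}

#' Impute missing feature values with the patient mean
#'
#' Missing entries are replaced by the patient's own mean of that feature
#' (over the patient's non-missing beats). If a patient has no observed
#' value for a feature, the global mean over all patients is used; if no
#' value exists at all, 0. Non-missing entries are never changed and the
#' missingness mask is preserved for audit.
#'
#' @param fm A `feature_matrix`.
#' @param patient_ids Patient id per beat; defaults to the record column.
#' @return The imputed `feature_matrix` (no `NA` left in `x`).
#' @export
impute_patient_mean <- function(fm, patient_ids = fm$beats$record) {
  stopifnot(inherits(fm, "feature_matrix"), length(patient_ids) == nrow(fm$x))
  x <- fm$x
  global <- colMeans(x, na.rm = TRUE)
  global[!is.finite(global)] <- 0
  for (p in unique(patient_ids)) {
    rows <- which(patient_ids == p)
    sub <- x[rows, , drop = FALSE]
    pm <- colMeans(sub, na.rm = TRUE)
    pm[!is.finite(pm)] <- global[!is.finite(pm)]
    miss <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(miss)) x[rows, ][miss] <- pm[miss[, 2]]
  }
  fm$x <- x
  fm
}

#' Write / read a feature matrix (CSV + JSON sidecar)
#'
#' The matrix goes to `<stem>.csv` with the canonical names as header and
#' the beat metadata as leading columns; group/lead metadata and per-column
#' missingness counts go to `<stem>.json`.
#'
#' @param fm A `feature_matrix`.
#' @param stem Output path without extension.
#' @return `stem`, invisibly (`read_features` returns the `feature_matrix`).
#' @export
write_features <- function(fm, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(fm$beats, as.data.frame(fm$x)),
                   paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(columns = fm$info,
               n_beats = nrow(fm$x),
               missing_per_column = as.list(colSums(fm$mask)))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_features
#' @export
read_features <- function(stem) {
  d <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  info <- as.data.frame(meta$columns)
  x <- as.matrix(d[, info$name, drop = FALSE])
  structure(list(x = x, mask = is.na(x), info = info,
                 beats = d[, c("record", "r_sample", "symbol", "label")]),
            class = "feature_matrix")
}
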