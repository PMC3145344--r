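# CSV dialect: a record is a directory holding
#   signals.csv   -- "# record_id=<id> fs=<Hz> leads=<l1>,<l2>" comment line,
#                    then sample,lead1_mV,lead2_mV
#   beats.csv     -- sample,symbol,provenance
#   fiducials.csv -- beat_idx,lead,point_name,sample  (sample "ABSENT" allowed)
# Sample indices are 0-based in all files.

#' Read an ECG record
#'
#' Reads a two-lead ECG record in either the CSV dialect (a directory with
#' `signals.csv`) or the WFDB-style dialect (a record path prefix with
#' `.hea`/`.dat` files, format 212). Amplitudes are returned in millivolts;
#' for the WFDB-style dialect the conversion uses the header gain and
#' baseline.
#'
#' @param path Directory (csv) or record path prefix without extension (wfdb).
#' @param dialect `"csv"` or `"wfdb"`.
#' @return An [ecg_record].
#' @seealso [write_record()], [read_beats()], [read_fiducials()]
#' @export
read_record <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_record_csv(path) else read_record_wfdb(path)
}

#' Write an ECG record
#' @param rec An [ecg_record].
#' @inheritParams read_record
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "ecg_record"))
  if (dialect == "csv") write_record_csv(rec, path) else write_record_wfdb(rec, path)
  invisible(path)
}

read_record_csv <- function(path) {
  f <- file.path(path, "signals.csv")
  if (!file.exists(f)) stop("no such file: ", f)
  hdr <- readLines(f, n = 1L)
  if (!startsWith(hdr, "#"))
    stop("parse error in ", f, " at line 1: expected '# record_id=... fs=... leads=...'")
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[A-Za-z_]+=", "", kv), sub("=.*$", "", kv))
  if (!all(c("record_id", "fs", "leads") %in% names(meta)))
    stop("parse error in ", f, " at line 1: missing record_id/fs/leads")
  d <- utils::read.csv(f, comment.char = "#")
  sigcols <- setdiff(names(d), "sample")
  if (length(sigcols) != 2L)
    stop("dialect error: expected 2 signal columns in ", f, ", got ", length(sigcols))
  ecg_record(meta[["record_id"]], as.numeric(meta[["fs"]]),
             as.matrix(d[sigcols]),
             strsplit(meta[["leads"]], ",", fixed = TRUE)[[1]])
}

write_record_csv <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(path, "signals.csv")
  con <- file(f, "w"); on.exit(close(con))
  writeLines(sprintf("# record_id=%s fs=%s leads=%s", rec$record_id,
                     format(rec$fs, digits = 15),
                     paste(rec$lead_names, collapse = ",")), con)
  d <- data.frame(sample = seq_len(nrow(rec$signals)) - 1L,
                  lead1_mV = rec$signals[, 1], lead2_mV = rec$signals[, 2])
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read or write beat annotations
#'
#' CSV dialect: `beats.csv` in the record directory. WFDB-style dialect: the
#' `<path>.atr` (reference) or `<path>.det` (detected) MIT binary annotation
#' file.
#'
#' @param path Record directory (csv) or record path prefix (wfdb).
#' @param dialect `"csv"` or `"wfdb"`.
#' @param provenance Which annotation stream to read or write.
#' @return [read_beats()] returns a [beat_annotations]; `write_beats`
#'   invisibly returns `path`.
#' @export
read_beats <- function(path, dialect = c("csv", "wfdb"),
                       provenance = c("reference", "detected")) {
  dialect <- match.arg(dialect); provenance <- match.arg(provenance)
  if (dialect == "wfdb") return(read_beats_wfdb(path, provenance))
  f <- file.path(path, "beats.csv")
  if (!file.exists(f)) stop("no such file: ", f)
  d <- utils::read.csv(f, colClasses = c("integer", "character", "character"))
  d <- d[d$provenance == provenance, , drop = FALSE]
  if (is.unsorted(d$sample, strictly = TRUE))
    stop("parse error: beat samples not strictly increasing in ", f)
  beat_annotations(d$sample, d$symbol, provenance)
}

#' @rdname read_beats
#' @param beats A [beat_annotations] to write.
#' @export
write_beats <- function(beats, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(beats, "beat_annotations"))
  if (dialect == "wfdb") return(write_beats_wfdb(beats, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(path, "beats.csv")
  new <- data.frame(sample = beats$r_samples, symbol = beats$symbols,
                    provenance = beats$provenance)
  if (file.exists(f)) {  # keep the other provenance stream if present
    old <- utils::read.csv(f, colClasses = c("integer", "character", "character"))
    old <- old[old$provenance != beats$provenance, , drop = FALSE]
    new <- rbind(old, new)
  }
  utils::write.csv(new, f, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write per-beat fiducial annotations
#'
#' CSV dialect: `fiducials.csv` with explicit beat indices; the `sample`
#' column uses the literal string `ABSENT` for undetected points. WFDB-style
#' dialect: `<path>.pu`, an MIT binary annotation stream sorted by sample
#' index in which each mark carries the lead in its `chan` field and the
#' fiducial point id in its `num` field; marks are assigned to beats by the
#' nearest enclosing R-spike window and unassignable marks are dropped with
#' a warning (beats are never dropped).
#'
#' @param path Record directory (csv) or record path prefix (wfdb).
#' @param dialect `"csv"` or `"wfdb"`.
#' @param beats A [beat_annotations] giving the beat list the map is indexed
#'   on (required for the wfdb dialect; for csv used to fix the beat count).
#' @return A [fiducial_map].
#' @export
read_fiducials <- function(path, dialect = c("csv", "wfdb"), beats = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "wfdb") return(read_fiducials_wfdb(path, beats))
  f <- file.path(path, "fiducials.csv")
  if (!file.exists(f)) stop("no such file: ", f)
  d <- utils::read.csv(f, colClasses = "character")
  n <- if (!is.null(beats)) length(beats$r_samples) else
    if (nrow(d)) max(as.integer(d$beat_idx)) + 1L else 0L
  m1 <- empty_fiducials(n); m2 <- empty_fiducials(n)
  bad <- !(d$point_name %in% FIDUCIAL_POINTS)
  if (any(bad)) {
    warning(sum(bad), " fiducial mark(s) with unknown point name dropped")
    d <- d[!bad, , drop = FALSE]
  }
  present <- d$sample != "ABSENT"
  for (ld in c(1L, 2L)) {
    sel <- present & d$lead == as.character(ld)
    idx <- cbind(as.integer(d$beat_idx[sel]) + 1L,
                 match(d$point_name[sel], FIDUCIAL_POINTS))
    if (ld == 1L) m1[idx] <- as.numeric(d$sample[sel]) else
      m2[idx] <- as.numeric(d$sample[sel])
  }
  fiducial_map(m1, m2)
}

#' @rdname read_fiducials
#' @param fid A [fiducial_map] to write.
#' @export
write_fiducials <- function(fid, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(fid, "fiducial_map"))
  if (dialect == "wfdb") return(write_fiducials_wfdb(fid, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(c(1L, 2L), function(ld) {
    m <- if (ld == 1L) fid$lead1 else fid$lead2
    if (!nrow(m)) return(NULL)
    data.frame(beat_idx = rep(seq_len(nrow(m)) - 1L, ncol(m)),
               lead = ld, point_name = rep(colnames(m), each = nrow(m)),
               sample = ifelse(is.na(c(m)), "ABSENT",
                               format(c(m), trim = TRUE, scientific = FALSE)))
  }))
  if (is.null(rows))
    rows <- data.frame(beat_idx = integer(), lead = integer(),
                       point_name = character(), sample = character())
  rows <- rows[order(rows$beat_idx, rows$lead,
                     match(rows$point_name, FIDUCIAL_POINTS)), ]
  utils::write.csv(rows, file.path(path, "fiducials.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
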