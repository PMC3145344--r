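# WFDB-style dialect: <rec>.hea header, <rec>.dat format-212 signals,
# <rec>.atr / <rec>.det MIT binary beat annotations (reference / detected),
# <rec>.pu MIT binary fiducial annotations. Scope is bounded to two-lead
# format-212 records; other layouts go through the CSV dialect.

# MIT annotation code -> display symbol (the subset this package emits/reads).
ANN_SYMBOLS <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/",
                 "Q", "~", "", "|", "", "s", "T", "*", "D", "\"", "=", "p",
                 "B", "^", "t", "+", "u", "?", "!", "[", "]", "e", "n", "@",
                 "x", "f", "(", ")", "r")
names(ANN_SYMBOLS) <- as.character(seq_along(ANN_SYMBOLS))

ann_code_for_symbol <- function(sym) {
  code <- match(sym, ANN_SYMBOLS)
  if (anyNA(code)) stop("no MIT annotation code for symbol(s): ",
                        paste(unique(sym[is.na(code)]), collapse = " "))
  code
}

# Symbols used for fiducial marks in .pu files; the num field carries the
# point id (0-based index into FIDUCIAL_POINTS) and chan carries the lead.
FIDUCIAL_SYMBOLS <- c(P_on = "(", P_peak = "p", P_off = ")",
                      QRS_on = "(", Q = "[", R = "N", S = "]",
                      QRS_off = ")", T_on = "(", T_peak = "t", T_off = ")")

## ---- MIT binary annotation stream ----

# Read an annotation file into data.frame(sample, code, chan, num).
read_mit_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bytes <- readBin(path, "integer", n = file.size(path), size = 1, signed = FALSE)
  if (length(bytes) %% 2L) stop("parse error in ", path, ": odd byte count")
  w <- bytes[c(TRUE, FALSE)] + 256L * bytes[c(FALSE, TRUE)]
  out_s <- integer(0); out_c <- integer(0); out_ch <- integer(0); out_nm <- integer(0)
  time <- 0; chan <- 0L; num <- 0L; i <- 1L; pend <- 0
  while (i <= length(w)) {
    code <- w[i] %/% 1024L; delta <- w[i] %% 1024L
    if (code == 0L && delta == 0L) break                      # EOF
    if (code == 59L) {                                        # SKIP: 4-byte interval
      if (i + 2L > length(w)) stop("parse error in ", path, ": truncated SKIP at word ", i)
      hi <- w[i + 1L]; lo <- w[i + 2L]
      v <- hi * 65536 + lo
      if (v >= 2147483648) v <- v - 4294967296
      pend <- pend + v; i <- i + 3L; next
    }
    if (code == 60L) { num <- delta; if (length(out_nm)) out_nm[length(out_nm)] <- delta }
    else if (code == 61L) { }                                 # SUB: ignored
    else if (code == 62L) { chan <- delta; if (length(out_ch)) out_ch[length(out_ch)] <- delta }
    else if (code == 63L) { i <- i + ceiling(delta / 2); }    # AUX: skip payload
    else {
      time <- time + pend + delta; pend <- 0
      out_s <- c(out_s, time); out_c <- c(out_c, code)
      out_ch <- c(out_ch, chan); out_nm <- c(out_nm, num)
    }
    i <- i + 1L
  }
  data.frame(sample = out_s, code = out_c, chan = out_ch, num = out_nm)
}

# ann: data.frame(sample, code, chan, num), sorted by sample.
write_mit_annotations <- function(ann, path) {
  if (is.unsorted(ann$sample)) stop("annotation stream must be sorted by sample")
  words <- integer(0); prev <- 0; chan <- 0L; num <- 0L
  for (i in seq_len(nrow(ann))) {
    delta <- ann$sample[i] - prev; prev <- ann$sample[i]
    if (delta > 1023) {
      words <- c(words, 59L * 1024L, delta %/% 65536, delta %% 65536)
      delta <- 0L
    }
    words <- c(words, ann$code[i] * 1024L + delta)
    if (ann$chan[i] != chan) { chan <- ann$chan[i]; words <- c(words, 62L * 1024L + chan) }
    if (ann$num[i] != num) { num <- ann$num[i]; words <- c(words, 60L * 1024L + num) }
  }
  words <- c(words, 0L)  # EOF
  bytes <- as.integer(rbind(words %% 256L, words %/% 256L))
  writeBin(as.raw(bytes), path)
  invisible(path)
}

## ---- header + format-212 signals ----

read_record_wfdb <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such file: ", hea)
  ln <- readLines(hea)
  ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  top <- strsplit(trimws(ln[1]), "[ \t]+")[[1]]
  if (length(top) < 4L) stop("parse error in ", hea, " at line 1: need 'name nsig fs nsamp'")
  nsig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(top[3]))
  nsamp <- suppressWarnings(as.integer(top[4]))
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stop("parse error in ", hea, " at line 1: non-numeric field")
  if (nsig != 2L) stop("dialect error: expected 2 leads, header declares ", nsig)
  gain <- numeric(2); base <- numeric(2); desc <- character(2); fmt <- character(2)
  for (k in 1:2) {
    f <- strsplit(trimws(ln[1 + k]), "[ \t]+")[[1]]
    if (length(f) < 3L) stop("parse error in ", hea, " at line ", 1 + k, ": short signal line")
    fmt[k] <- f[2]
    g <- f[3]
    m <- regmatches(g, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/.*)?$", g))[[1]]
    if (!length(m) || is.na(suppressWarnings(as.numeric(m[2]))))
      stop("parse error in ", hea, " at line ", 1 + k, ": bad gain field '", g, "'")
    gain[k] <- as.numeric(m[2])
    base[k] <- if (nzchar(m[4])) as.numeric(m[4]) else
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(base[k])) base[k] <- 0
    if (gain[k] == 0) gain[k] <- 200  # WFDB convention: 0 means default gain
    desc[k] <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else paste0("lead", k)
  }
  if (any(fmt != "212")) stop("dialect error: only format 212 is supported, got ", paste(fmt, collapse = "/"))
  dat <- paste0(path, ".dat")
  if (!file.exists(dat)) stop("no such file: ", dat)
  bytes <- readBin(dat, "integer", n = file.size(dat), size = 1, signed = FALSE)
  npairs <- length(bytes) %/% 3L
  b1 <- bytes[seq_len(npairs) * 3L - 2L]
  b2 <- bytes[seq_len(npairs) * 3L - 1L]
  b3 <- bytes[seq_len(npairs) * 3L]
  s1 <- b1 + 256L * (b2 %% 16L); s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- b3 + 256L * (b2 %/% 16L); s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  adu <- matrix(rbind(s1, s2), ncol = 2L, byrow = TRUE)[seq_len(nsamp), , drop = FALSE]
  mv <- sweep(sweep(adu, 2, base), 2, gain, "/")
  ecg_record(basename(path), fs, mv, desc)
}

write_record_wfdb <- function(rec, path, gain = 200) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  n <- nrow(rec$signals)
  adu <- round(rec$signals * gain)
  adu <- pmin(pmax(adu, -2048), 2047)
  hea <- c(sprintf("%s 2 %s %d", basename(path), format(rec$fs, digits = 15), n),
           sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 %s", basename(path), gain,
                   as.integer(adu[1, 1:2]), rec$lead_names))
  writeLines(hea, paste0(path, ".hea"))
  v <- as.integer(t(adu)) %% 4096L          # 12-bit two's complement
  s1 <- v[c(TRUE, FALSE)]; s2 <- v[c(FALSE, TRUE)]
  bytes <- as.integer(rbind(s1 %% 256L, s1 %/% 256L + 16L * (s2 %/% 256L), s2 %% 256L))
  writeBin(as.raw(bytes), paste0(path, ".dat"))
  invisible(path)
}

## ---- beats and fiducials ----

read_beats_wfdb <- function(path, provenance) {
  f <- paste0(path, if (provenance == "reference") ".atr" else ".det")
  ann <- read_mit_annotations(f)
  ann <- ann[ann$code <= length(ANN_SYMBOLS) & ANN_SYMBOLS[ann$code] %in% names(AAMI_TABLE), , drop = FALSE]
  beat_annotations(ann$sample, ANN_SYMBOLS[ann$code], provenance)
}

write_beats_wfdb <- function(beats, path) {
  f <- paste0(path, if (beats$provenance == "reference") ".atr" else ".det")
  ann <- data.frame(sample = beats$r_samples,
                    code = ann_code_for_symbol(beats$symbols),
                    chan = 0L, num = 0L)
  write_mit_annotations(ann, f)
  invisible(path)
}

read_fiducials_wfdb <- function(path, beats) {
  if (is.null(beats)) stop("the wfdb dialect needs the beat list to index fiducials on")
  ann <- read_mit_annotations(paste0(path, ".pu"))
  if (is.unsorted(ann$sample)) stop("parse error: fiducial stream not sorted by sample")
  r <- beats$r_samples
  n <- length(r)
  m <- list(empty_fiducials(n), empty_fiducials(n))
  dropped <- 0L
  # enclosing R-spike window: pre-R points (P_on..Q) belong to the next R
  # spike, post-R points (S..T_off) to the previous one, the R mark to the
  # nearest; waves of neighbouring beats may overlap around premature beats,
  # so conflicting or out-of-order marks are unassignable.
  r_idx <- match("R", FIDUCIAL_POINTS)
  for (i in seq_len(nrow(ann))) {
    pt <- ann$num[i] + 1L; ld <- ann$chan[i] + 1L
    s <- ann$sample[i]
    if (pt < 1L || pt > length(FIDUCIAL_POINTS) || ld > 2L) { dropped <- dropped + 1L; next }
    beat <- if (pt < r_idx) findInterval(s - 1, r) + 1L
    else if (pt > r_idx) findInterval(s, r)
    else which.min(abs(r - s))
    if (beat < 1L || beat > n || !is.na(m[[ld]][beat, pt])) { dropped <- dropped + 1L; next }
    m[[ld]][beat, pt] <- s
  }
  # enforce within-beat temporal order; offenders are unassignable too
  for (ld in 1:2) for (i in seq_len(n)) {
    run <- -Inf
    for (pt in seq_along(FIDUCIAL_POINTS)) {
      v <- m[[ld]][i, pt]
      if (is.na(v)) next
      if (v < run) { m[[ld]][i, pt] <- NA; dropped <- dropped + 1L }
      else run <- v
    }
  }
  if (dropped) warning(dropped, " unassignable fiducial mark(s) dropped")
  fiducial_map(m[[1]], m[[2]])
}

write_fiducials_wfdb <- function(fid, path) {
  rows <- do.call(rbind, lapply(1:2, function(ld) {
    m <- if (ld == 1L) fid$lead1 else fid$lead2
    idx <- which(!is.na(m), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(sample = m[idx],
               code = ann_code_for_symbol(unname(FIDUCIAL_SYMBOLS[idx[, 2]])),
               chan = ld - 1L, num = idx[, 2] - 1L)
  }))
  if (is.null(rows)) rows <- data.frame(sample = integer(), code = integer(),
                                        chan = integer(), num = integer())
  rows <- rows[order(rows$sample, rows$chan, rows$num), , drop = FALSE]
  write_mit_annotations(rows, paste0(path, ".pu"))
  invisible(path)
}
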