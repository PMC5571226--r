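#' Uniformly resample a segment onto 128 points
#'
#' Maps the segment onto 128 points spanning it end to end. The default
#' method is linear interpolation on the uniform grid (deterministic,
#' endpoint-preserving, and the identity for an input that is already 128
#' samples long). A polyphase FIR resampler is available when the `signal`
#' package is installed; it trades exactness at the endpoints for better
#' alias rejection on strongly oversampled segments.
#'
#' @param segment numeric vector, length >= 2.
#' @param method `"linear"` (default) or `"polyphase"`.
#' @return Numeric vector of length 128.
#' @export
resample_to_128 <- function(segment, method = c("linear", "polyphase")) {
  method <- match.arg(method)
  n <- length(segment)
  if (n < 2L) stop("segment must have at least 2 samples", call. = FALSE)
  if (method == "polyphase") {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("polyphase resampling requires the 'signal' package", call. = FALSE)
    out <- signal::resample(segment, p = beat_length(), q = n)
    return(as.numeric(out[seq_len(beat_length())]))
  }
  if (n == beat_length()) return(as.numeric(segment))
  stats::approx(x = seq(0, 1, length.out = n), y = segment,
                xout = seq(0, 1, length.out = beat_length()))$y
}

## internal: extract signal[lo..hi] (0-based, inclusive), zero-padding
## samples outside the record with a warning
extract_window <- function(record, lo, hi) {
  n <- length(record$signal)
  idx <- lo:hi
  inside <- idx >= 0L & idx < n
  if (!all(inside))
    warning(sprintf("window [%d, %d] of subject '%s' crosses record boundary; zero-padded",
                    lo, hi, record$subject_id), call. = FALSE)
  out <- numeric(length(idx))
  out[inside] <- record$signal[idx[inside] + 1L]
  out
}

## internal: default raw half-window — 0.35 s either side of the R peak,
## wide enough to cover P-QRS-T at normal rates
default_half_window <- function(fs) as.integer(round(0.35 * fs))

#' Cut one beat around its annotated R peak
#'
#' Takes `half_window` raw samples from each side of the R peak (window
#' `[r - half_window, r + half_window)`) and resamples the window to 128
#' samples, so the R peak lands at output index 64 (0-based). Windows that
#' cross the record boundary are zero-padded with a warning.
#'
#' @param record an [ecg_record()].
#' @param beat_index 1-based row index into `record$annotations`.
#' @param half_window raw samples per side; default `round(0.35 * fs)`.
#' @param method resampling method, see [resample_to_128()].
#' @return A single-mode [beat_vector()] labelled with the beat's class.
#' @export
segment_single_beat <- function(record, beat_index,
                                half_window = default_half_window(record$fs),
                                method = "linear") {
  half_window <- as.integer(half_window)
  if (length(half_window) != 1L || is.na(half_window) || half_window <= 0L)
    stop("half_window must be a positive integer", call. = FALSE)
  ann <- record$annotations
  if (beat_index < 1L || beat_index > nrow(ann))
    stop("beat_index ", beat_index, " out of range (record has ",
         nrow(ann), " beats)", call. = FALSE)
  r <- ann$r_sample[beat_index]
  seg <- extract_window(record, r - half_window, r + half_window - 1L)
  beat_vector(resample_to_128(seg, method), mode = "single",
              label = ann$label[beat_index], subject_id = record$subject_id,
              beat_index = beat_index)
}

#' Cut a beat-trio spanning the previous, center and next beat
#'
#' The raw span runs from the previous beat's window start to the next
#' beat's window end and is resampled uniformly to 128 samples, so the
#' relative timing of the three R peaks is preserved — a premature center
#' beat sits visibly left of the midpoint, which is what makes
#' supraventricular ectopy detectable in this channel. The label is the
#' center beat's label.
#'
#' @inheritParams segment_single_beat
#' @return A trio-mode [beat_vector()].
#' @export
segment_trio <- function(record, beat_index,
                         half_window = default_half_window(record$fs),
                         method = "linear") {
  ann <- record$annotations
  if (beat_index < 1L || beat_index > nrow(ann))
    stop("beat_index ", beat_index, " out of range", call. = FALSE)
  if (beat_index == 1L || beat_index == nrow(ann))
    stop("beat ", beat_index, " has no trio: first/last beat of record",
         call. = FALSE)
  half_window <- as.integer(half_window)
  if (half_window <= 0L) stop("half_window must be positive", call. = FALSE)
  lo <- ann$r_sample[beat_index - 1L] - half_window
  hi <- ann$r_sample[beat_index + 1L] + half_window - 1L
  seg <- extract_window(record, lo, hi)
  beat_vector(resample_to_128(seg, method), mode = "trio",
              label = ann$label[beat_index], subject_id = record$subject_id,
              beat_index = beat_index)
}

## internal: indices of annotations whose R peak falls in the first
## duration_s seconds
beats_in_window <- function(record, duration_s) {
  which(record$annotations$r_sample < duration_s * record$fs)
}

#' Select a subject's average normal beat (ANB)
#'
#' Computes the pointwise mean of all single-mode N beats in the first
#' `duration_s` seconds of the record, then returns the *real* N beat whose
#' single-beat representation is closest (Euclidean) to that mean, together
#' with its trio representation. Ties are broken by the earliest beat index.
#' The ANB is the sole input of degradation-filter design and of abnormal
#' beat synthesis for this subject.
#'
#' Beats that lack a trio (first/last beat of the record) contribute to the
#' mean but are not eligible for selection, since the ANB must exist in both
#' representations.
#'
#' @param record an [ecg_record()].
#' @param duration_s window length in seconds (default 300 — the first five
#'   minutes, the patient-specific part of the record).
#' @param half_window,method passed to the segmenters.
#' @return An object of class `average_normal_beat` with elements `single`,
#'   `trio` (both [beat_vector()]s from the same source beat) and
#'   `source_beat_index`.
#' @export
select_anb <- function(record, duration_s = 300,
                       half_window = default_half_window(record$fs),
                       method = "linear") {
  ann <- record$annotations
  in_win <- beats_in_window(record, duration_s)
  n_idx <- in_win[ann$label[in_win] == "N"]
  if (!length(n_idx))
    stop("no N beats in the first ", duration_s, " s of subject '",
         record$subject_id, "'", call. = FALSE)
  singles <- lapply(n_idx, function(i)
    segment_single_beat(record, i, half_window, method)$samples)
  mat <- do.call(rbind, singles)
  avg <- colMeans(mat)
  eligible <- n_idx > 1L & n_idx < nrow(ann)
  if (!any(eligible))
    stop("no N beat with a trio in the first ", duration_s, " s of subject '",
         record$subject_id, "'", call. = FALSE)
  d2 <- rowSums(sweep(mat, 2, avg)^2)
  d2[!eligible] <- Inf
  best <- which.min(d2)  # which.min takes the earliest on ties
  idx <- n_idx[best]
  structure(
    list(single = beat_vector(mat[best, ], mode = "single", label = "N",
                              subject_id = record$subject_id,
                              beat_index = idx),
         trio = segment_trio(record, idx, half_window, method),
         source_beat_index = idx),
    class = "average_normal_beat"
  )
}

#' @export
print.average_normal_beat <- function(x, ...) {
  cat(sprintf("<average_normal_beat> subject '%s', source beat %d\n",
              x$single$subject_id, x$source_beat_index))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Record I/O.  CSV is the fully supported interchange dialect: a signal file
# (sample_index, mV) and an annotation file (sample_index, aami_label), both
# with header rows, sample indices 0-based.  WFDB support covers the signal
# (.hea header + format-16 .dat) plus a plain-text annotation table
# (sample_index, wfdb_symbol) mapped to AAMI classes.

csv_paths <- function(prefix) {
  list(signal = paste0(prefix, ".signal.csv"),
       ann = paste0(prefix, ".annotations.csv"))
}

#' Read an ECG record from disk
#'
#' `format = "csv"`: reads `<path>.signal.csv` (columns `sample_index, mV`)
#' and `<path>.annotations.csv` (columns `sample_index, aami_label`); sample
#' indices are 0-based. `format = "wfdb"`: reads `<path>.hea` and a
#' format-16 `<path>.dat` (first channel by default) plus `<path>.ann.txt`,
#' a two-column text table (sample index, WFDB beat symbol) whose symbols
#' are mapped to AAMI classes via [wfdb_symbol_to_aami()]; unknown symbols
#' become Q.
#'
#' @param path path prefix (no extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param subject_id subject id; defaults to `basename(path)`.
#' @param fs sampling rate for CSV input (the CSV dialect does not carry it;
#'   default 360 Hz).
#' @param channel channel to extract from a multi-channel WFDB record
#'   (default 1, the modified-lead II position in MIT-BIH records).
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        subject_id = basename(path), fs = 360, channel = 1L) {
  format <- match.arg(format)
  if (format == "csv") {
    p <- csv_paths(path)
    for (f in unlist(p))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    sig <- utils::read.csv(p$signal)
    if (!all(c("sample_index", "mV") %in% names(sig)))
      stop("signal CSV ", p$signal, " must have columns sample_index, mV",
           call. = FALSE)
    if (nrow(sig) && !identical(as.integer(sig$sample_index),
                                seq_len(nrow(sig)) - 1L))
      stop("signal CSV ", p$signal,
           " sample_index must be 0..n-1 contiguous", call. = FALSE)
    ann <- utils::read.csv(p$ann, colClasses = c("integer", "character"))
    if (!all(c("sample_index", "aami_label") %in% names(ann)))
      stop("annotation CSV ", p$ann,
           " must have columns sample_index, aami_label", call. = FALSE)
    return(ecg_record(subject_id, sig$mV, fs,
                      data.frame(r_sample = ann$sample_index,
                                 label = ann$aami_label)))
  }
  read_record_wfdb(path, subject_id, channel)
}

#' Write an ECG record to disk
#'
#' Inverse of [read_record()]; both formats round-trip (the WFDB writer
#' quantizes to 16-bit ADC units at 200 adu/mV, the MIT-BIH gain).
#'
#' @param record an [ecg_record()].
#' @inheritParams read_record
#' @return Invisibly, the paths written.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    p <- csv_paths(path)
    utils::write.csv(
      data.frame(sample_index = seq_along(record$signal) - 1L,
                 mV = record$signal),
      p$signal, row.names = FALSE)
    utils::write.csv(
      data.frame(sample_index = record$annotations$r_sample,
                 aami_label = record$annotations$label),
      p$ann, row.names = FALSE)
    return(invisible(unlist(p)))
  }
  write_record_wfdb(record, path)
}

## WFDB gain used by the writer (MIT-BIH convention)
WFDB_GAIN <- 200

read_record_wfdb <- function(path, subject_id = basename(path), channel = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing file: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_fields) < 4L)
    stop("malformed WFDB header line: ", lines[1], call. = FALSE)
  n_sig <- as.integer(head_fields[2])
  fs <- as.numeric(head_fields[3])
  n_samp <- as.integer(head_fields[4])
  if (channel < 1L || channel > n_sig)
    stop("channel ", channel, " not in record (", n_sig, " signals)",
         call. = FALSE)
  sig_specs <- lapply(lines[1L + seq_len(n_sig)], function(l)
    strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(sig_specs, function(f) f[2], "")
  if (!all(fmts == "16"))
    stop("only WFDB format 16 is supported, found: ",
         paste(unique(fmts), collapse = ","), call. = FALSE)
  dat <- paste0(path, ".dat")
  if (!file.exists(dat)) stop("missing file: ", dat, call. = FALSE)
  raw <- readBin(dat, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samp)
    stop("WFDB .dat file shorter than header declares", call. = FALSE)
  m <- matrix(raw, nrow = n_sig)  # samples interleaved by channel
  spec <- sig_specs[[channel]]
  gain_field <- if (length(spec) >= 3L) spec[3] else as.character(WFDB_GAIN)
  gain <- as.numeric(sub("\\(.*", "", gain_field))  # strip (baseline)/unit
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field)) else 0
  if (!is.finite(gain) || gain == 0) gain <- WFDB_GAIN
  signal <- (m[channel, ] - baseline) / gain
  ann_file <- paste0(path, ".ann.txt")
  ann <- if (file.exists(ann_file)) {
    tab <- utils::read.table(ann_file, header = TRUE,
                             colClasses = c("integer", "character"))
    data.frame(r_sample = tab[[1]], label = wfdb_symbol_to_aami(tab[[2]]))
  } else data.frame(r_sample = integer(), label = character())
  ecg_record(subject_id, signal, fs, ann)
}

write_record_wfdb <- function(record, path) {
  n <- length(record$signal)
  adc <- as.integer(round(record$signal * WFDB_GAIN))
  adc <- pmin(pmax(adc, -32768L), 32767L)
  base <- basename(path)
  writeLines(c(
    sprintf("%s 1 %g %d", base, record$fs, n),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", base, WFDB_GAIN,
            if (n) adc[1] else 0L)
  ), paste0(path, ".hea"))
  writeBin(adc, paste0(path, ".dat"), size = 2L, endian = "little")
  ## AAMI classes are a subset of the WFDB symbol alphabet, so labels pass
  ## through unchanged on write
  utils::write.table(
    data.frame(sample_index = record$annotations$r_sample,
               symbol = record$annotations$label),
    paste0(path, ".ann.txt"), row.names = FALSE, quote = FALSE)
  invisible(paste0(path, c(".hea", ".dat", ".ann.txt")))
}
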