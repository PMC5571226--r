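#' AAMI heartbeat classes
#'
#' The five heartbeat classes of the AAMI EC57/ECAR recommended practice, in
#' the canonical reporting order used throughout this package: `N` (beats
#' originating in the sinus node), `S` (supraventricular ectopic), `V`
#' (ventricular ectopic), `F` (fusion of ventricular and normal), `Q`
#' (unclassifiable/paced).
#'
#' @return Character vector of the five class symbols.
#' @export
aami_classes <- function() c("N", "S", "V", "F", "Q")

#' Abnormal (non-N) AAMI classes
#' @return Character vector `c("S","V","F","Q")`.
#' @export
abnormal_classes <- function() c("S", "V", "F", "Q")

#' Map WFDB beat annotation symbols to AAMI classes
#'
#' Standard AAMI grouping of the MIT-BIH beat annotation alphabet: `N,L,R,e,j`
#' map to N; `A,a,J,S` to S; `V,E` to V; `F` to F; everything else (paced,
#' fusion-of-paced, unclassifiable, unknown symbols) to Q.
#'
#' @param symbols character vector of single-character WFDB beat symbols.
#' @return Character vector of AAMI class symbols, same length.
#' @export
#' @examples
#' wfdb_symbol_to_aami(c("N", "A", "V", "F", "/", "x"))
wfdb_symbol_to_aami <- function(symbols) {
  map <- c(
    "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
    "A" = "S", "a" = "S", "J" = "S", "S" = "S",
    "V" = "V", "E" = "V",
    "F" = "F"
  )
  out <- unname(map[symbols])
  out[is.na(out)] <- "Q"
  out
}

#' Number of samples in every beat representation
#' @return The integer 128.
#' @export
beat_length <- function() 128L

## internal: stop unless label is a single valid AAMI symbol
assert_aami <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% aami_classes()))
    stop("label must be one of ", paste(aami_classes(), collapse = ", "),
         call. = FALSE)
  invisible(label)
}

#' Construct a 128-sample beat vector
#'
#' The atomic unit of the pipeline: one beat (or beat-trio) resampled to
#' exactly 128 samples, carrying its AAMI label, representation mode,
#' subject of origin and provenance flags.
#'
#' @param samples numeric vector of exactly 128 samples (mV).
#' @param mode `"single"` (one beat centered on its R peak) or `"trio"`
#'   (previous + center + next beat resampled together).
#' @param label AAMI class symbol of the (center) beat.
#' @param subject_id subject identifier string.
#' @param is_synthetic `TRUE` when the beat was synthesized by a degradation
#'   filter rather than cut from a real record.
#' @param beat_index integer index of the source beat within its record
#'   (1-based annotation row), `NA` for synthetic beats.
#' @return An object of class `beat_vector`.
#' @export
beat_vector <- function(samples, mode = c("single", "trio"), label,
                        subject_id = "", is_synthetic = FALSE,
                        beat_index = NA_integer_) {
  mode <- match.arg(mode)
  samples <- as.numeric(samples)
  if (length(samples) != beat_length())
    stop("beat_vector requires exactly ", beat_length(), " samples, got ",
         length(samples), call. = FALSE)
  if (anyNA(samples)) stop("beat_vector samples contain NA", call. = FALSE)
  assert_aami(label)
  structure(
    list(samples = samples, mode = mode, label = label,
         subject_id = as.character(subject_id),
         is_synthetic = isTRUE(is_synthetic),
         beat_index = as.integer(beat_index)),
    class = "beat_vector"
  )
}

#' @export
print.beat_vector <- function(x, ...) {
  cat(sprintf("<beat_vector> %s-mode %s beat, subject '%s'%s\n",
              x$mode, x$label, x$subject_id,
              if (x$is_synthetic) " (synthetic)" else ""))
  invisible(x)
}

#' Construct an annotated single-lead ECG record
#'
#' @param subject_id subject identifier string.
#' @param signal numeric vector of samples (mV).
#' @param fs sampling rate in Hz (default 360, the MIT-BIH rate).
#' @param annotations data frame with columns `r_sample` (0-based sample
#'   index of each R peak, strictly increasing) and `label` (AAMI symbol).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(subject_id, signal, fs = 360, annotations) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  signal <- as.numeric(signal)
  if (is.null(annotations))
    annotations <- data.frame(r_sample = integer(), label = character())
  stopifnot(is.data.frame(annotations),
            all(c("r_sample", "label") %in% names(annotations)))
  ann <- data.frame(r_sample = as.integer(annotations$r_sample),
                    label = as.character(annotations$label),
                    stringsAsFactors = FALSE)
  if (nrow(ann)) {
    if (any(ann$r_sample < 0L)) stop("r_sample must be >= 0", call. = FALSE)
    if (any(ann$r_sample >= length(signal)))
      stop("annotation r_sample beyond end of signal", call. = FALSE)
    if (is.unsorted(ann$r_sample, strictly = TRUE))
      stop("annotations must be strictly increasing in r_sample", call. = FALSE)
    bad <- setdiff(unique(ann$label), aami_classes())
    if (length(bad))
      stop("unknown AAMI labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), signal = signal,
                 fs = fs, annotations = ann),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  tab <- table(factor(x$annotations$label, levels = aami_classes()))
  cat(sprintf("<ecg_record> subject '%s': %.1f s at %g Hz, %d beats (%s)\n",
              x$subject_id, length(x$signal) / x$fs, x$fs,
              nrow(x$annotations),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " ")))
  invisible(x)
}

#' Duration of a record in seconds
#' @param record an [ecg_record()].
#' @return Numeric scalar, `length(signal) / fs`.
#' @export
record_duration <- function(record) length(record$signal) / record$fs
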