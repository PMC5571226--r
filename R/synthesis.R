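# Abnormal beat synthesis and personalized training-set assembly: the
# (subject-excluded) filter library applied to a person's ANB yields their
# potential abnormal beats; together with the person's real normal beats
# from the first five minutes these form the training set — no real
# abnormal beat ever enters it.

#' Synthesize a potential abnormal beat
#'
#' Applies one degradation filter to the matching-mode representation of a
#' person's average normal beat: the output is the centered, same-length
#' convolution of the ANB with the filter kernel, labelled with the
#' filter's source class and flagged synthetic.
#'
#' @param anb an [select_anb()] result (or a single [beat_vector()] whose
#'   mode matches the filter).
#' @param f an `abs_filter`.
#' @return A synthetic [beat_vector()] owned by the ANB's subject.
#' @export
synthesize_beat <- function(anb, f) {
  stopifnot(inherits(f, "abs_filter"))
  a <- if (inherits(anb, "average_normal_beat")) {
    if (f$mode == "trio") anb$trio else anb$single
  } else anb
  stopifnot(inherits(a, "beat_vector"))
  if (a$mode != f$mode)
    stop("mode mismatch: ANB is ", a$mode, ", filter is ", f$mode,
         call. = FALSE)
  beat_vector(apply_kernel(a$samples, f$h), mode = f$mode,
              label = f$source_class, subject_id = a$subject_id,
              is_synthetic = TRUE)
}

new_training_set <- function(items, subject_id, flagged_single_class = FALSE) {
  for (it in items) {
    stopifnot(inherits(it$single, "beat_vector"),
              inherits(it$trio, "beat_vector"))
    if (it$label == "N" && (it$single$is_synthetic || it$trio$is_synthetic))
      stop("training set invariant violated: synthetic N beat", call. = FALSE)
    if (it$label != "N" && !(it$single$is_synthetic && it$trio$is_synthetic))
      stop("training set invariant violated: real abnormal beat", call. = FALSE)
  }
  labels <- vapply(items, `[[`, "", "label")
  structure(
    list(items = items, subject_id = subject_id,
         n_real_normal = sum(labels == "N"),
         n_synthetic_by_class = table(factor(labels[labels != "N"],
                                             levels = abnormal_classes())),
         flagged_single_class = flagged_single_class),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  syn <- x$n_synthetic_by_class
  cat(sprintf("<training_set> subject '%s': %d real N + %d synthetic (%s)%s\n",
              x$subject_id, x$n_real_normal, sum(syn),
              paste(sprintf("%s=%d", names(syn), as.integer(syn)),
                    collapse = " "),
              if (x$flagged_single_class) " [single-class]" else ""))
  invisible(x)
}

#' @export
length.training_set <- function(x) length(x$items)

#' Assemble the personalized training set for one subject
#'
#' Real part: every N beat in the first `duration_s` seconds of the
#' subject's record, in both representations (first/last beats of the
#' record have no trio and are skipped). Synthetic part: the filter
#' library — with the subject's own filters excluded by default — applied
#' to the subject's ANB.
#'
#' Filters come per representation mode, and a synthesized training item
#' needs both channels. Filters present in both mode libraries under the
#' same id (same source abnormal beat) are paired; a filter surviving
#' curation in only one mode contributes the subject's own ANB as the
#' missing channel. That default is deliberate: a timing-only S degradation
#' exists only in the trio representation precisely because the single-beat
#' morphology *is* normal.
#'
#' Common training data — real N beats from donor records — can be merged
#' in via `common_records`. Donor records carry arrhythmias, so their N
#' beats include windows a healthy monitored subject cannot supply (e.g.
#' an N beat whose trio contains a neighboring ectopic and its
#' compensatory pause); without them the classifier has never seen such
#' contexts labelled N. `common_per_donor` N beats are taken per donor,
#' preferring ectopic-adjacent ones (two thirds of the budget, evenly
#' spaced) topped up with evenly spaced plain N beats — a deterministic
#' selection; the monitored subject is never its own donor.
#'
#' @param subject an [ecg_record()] with >= 1 N beat in the window.
#' @param libraries a single `filter_library`, or a list with elements
#'   `single` and/or `trio`.
#' @param exclude exclude the subject's own filters (default `TRUE`,
#'   mirroring leave-subject-out evaluation).
#' @param duration_s real-normal window in seconds (default 300).
#' @param half_window,method segmentation parameters.
#' @param common_records optional list of donor [ecg_record()]s supplying
#'   common training data (default `NULL`: none).
#' @param common_per_donor real N beats taken per donor record (default 30).
#' @return A `training_set`. If the (possibly excluded) library is empty
#'   the set contains only the N class and is flagged; CNN training refuses
#'   such sets.
#' @export
build_training_set <- function(subject, libraries, exclude = TRUE,
                               duration_s = 300, half_window = NULL,
                               method = "linear", common_records = NULL,
                               common_per_donor = 30L) {
  if (inherits(libraries, "filter_library"))
    libraries <- stats::setNames(list(libraries),
                                 libraries$design_config$mode)
  stopifnot(all(names(libraries) %in% c("single", "trio")))
  hw_supplied <- !is.null(half_window)
  if (!hw_supplied) half_window <- default_half_window(subject$fs)
  if (exclude)
    libraries <- lapply(libraries, exclude_subject, subject$subject_id)
  anb <- select_anb(subject, duration_s, half_window, method)

  ann <- subject$annotations
  in_win <- beats_in_window(subject, duration_s)
  n_idx <- in_win[ann$label[in_win] == "N"]
  n_idx <- n_idx[n_idx > 1L & n_idx < nrow(ann)]  # need a trio
  items <- lapply(n_idx, function(i) list(
    single = segment_single_beat(subject, i, half_window, method),
    trio = segment_trio(subject, i, half_window, method),
    label = "N"))

  for (donor in common_records) {
    if (donor$subject_id == subject$subject_id || common_per_donor < 1L)
      next
    dann <- donor$annotations
    cand <- which(dann$label == "N")
    cand <- cand[cand > 1L & cand < nrow(dann)]
    if (!length(cand)) next
    # prefer N beats adjacent to an ectopic: their trios carry a
    # neighbor's abnormal morphology and the compensatory pause, the one
    # kind of normal window a healthy monitored subject cannot supply
    ab <- which(dann$label != "N")
    adjacent <- cand[(cand - 1L) %in% ab | (cand + 1L) %in% ab]
    plain <- setdiff(cand, adjacent)
    spaced <- function(v, n) {
      if (n < 1L || !length(v)) return(integer())
      v[unique(round(seq(1L, length(v), length.out = min(n, length(v)))))]
    }
    pick <- spaced(adjacent, ceiling(2 * common_per_donor / 3))
    pick <- sort(c(pick, spaced(plain, common_per_donor - length(pick))))
    dhw <- if (hw_supplied) half_window else default_half_window(donor$fs)
    for (i in pick)
      items[[length(items) + 1L]] <- list(
        single = segment_single_beat(donor, i, dhw, method),
        trio = segment_trio(donor, i, dhw, method),
        label = "N")
  }

  get_filters <- function(mode) {
    lib <- libraries[[mode]]
    if (is.null(lib)) list() else lib$filters
  }
  fs_single <- get_filters("single")
  fs_trio <- get_filters("trio")
  ids_single <- vapply(fs_single, `[[`, "", "id")
  ids_trio <- vapply(fs_trio, `[[`, "", "id")
  all_ids <- sort(unique(c(ids_single, ids_trio)))
  for (id in all_ids) {
    f_s <- if (id %in% ids_single) fs_single[[match(id, ids_single)]] else NULL
    f_t <- if (id %in% ids_trio) fs_trio[[match(id, ids_trio)]] else NULL
    cls <- if (!is.null(f_s)) f_s$source_class else f_t$source_class
    bs <- if (!is.null(f_s)) synthesize_beat(anb, f_s) else
      beat_vector(anb$single$samples, "single", cls, subject$subject_id,
                  is_synthetic = TRUE)
    bt <- if (!is.null(f_t)) synthesize_beat(anb, f_t) else
      beat_vector(anb$trio$samples, "trio", cls, subject$subject_id,
                  is_synthetic = TRUE)
    items[[length(items) + 1L]] <- list(single = bs, trio = bt, label = cls)
  }
  flagged <- length(all_ids) == 0L
  if (flagged)
    warning("empty filter library for subject '", subject$subject_id,
            "': training set has only the N class", call. = FALSE)
  new_training_set(items, subject$subject_id, flagged)
}

#' Find the most similar synthetic beat to a real abnormal beat
#'
#' Exhaustive Euclidean nearest-neighbor scan; used to audit visually (and
#' numerically) how well the library covers a subject's real abnormal
#' morphologies.
#'
#' @param real_abnormal a [beat_vector()].
#' @param synthetic non-empty list of [beat_vector()]s of the same mode.
#' @return List with elements `beat` (the nearest synthetic beat),
#'   `distance` and `index`.
#' @export
nearest_synthetic <- function(real_abnormal, synthetic) {
  stopifnot(inherits(real_abnormal, "beat_vector"))
  if (!length(synthetic)) stop("empty synthetic list", call. = FALSE)
  d <- vapply(synthetic, function(s) {
    if (s$mode != real_abnormal$mode) stop("mode mismatch", call. = FALSE)
    sqrt(sum((s$samples - real_abnormal$samples)^2))
  }, 1)
  i <- which.min(d)
  list(beat = synthetic[[i]], distance = d[i], index = i)
}

# --- training-set serialization: paired full-precision CSVs

#' Write a training set to paired CSVs
#'
#' `<path>.beats.csv` holds one row per item: `item, label, is_synthetic`
#' followed by 128 single-channel columns `s1..s128` and 128 trio-channel
#' columns `t1..t128`, all printed with 17 significant digits so the
#' round-trip is bit-exact and byte-deterministic.
#'
#' @param ts a `training_set`.
#' @param path path prefix.
#' @return Invisibly, the path written.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  file <- paste0(path, ".beats.csv")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("item", "label", "is_synthetic",
                     paste0("s", 1:128), paste0("t", 1:128)),
                   collapse = ","), con)
  for (i in seq_along(ts$items)) {
    it <- ts$items[[i]]
    writeLines(paste(c(i, it$label, as.integer(it$single$is_synthetic),
                       sprintf("%.17g", it$single$samples),
                       sprintf("%.17g", it$trio$samples)),
                     collapse = ","), con)
  }
  invisible(file)
}

#' Read a training set written by [write_training_set()]
#' @param path path prefix.
#' @param subject_id subject id to stamp on the result.
#' @return A `training_set`.
#' @export
read_training_set <- function(path, subject_id = basename(path)) {
  tab <- utils::read.csv(paste0(path, ".beats.csv"),
                         colClasses = c(label = "character"))
  items <- lapply(seq_len(nrow(tab)), function(i) {
    lab <- tab$label[i]
    syn <- tab$is_synthetic[i] == 1L
    list(single = beat_vector(as.numeric(tab[i, paste0("s", 1:128)]),
                              "single", lab, subject_id,
                              is_synthetic = syn),
         trio = beat_vector(as.numeric(tab[i, paste0("t", 1:128)]),
                            "trio", lab, subject_id, is_synthetic = syn),
         label = lab)
  })
  new_training_set(items, subject_id,
                   flagged_single_class = all(tab$label == "N"))
}
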