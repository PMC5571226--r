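# Abnormal-beat-synthesis (ABS) filters: each normal-to-abnormal beat
# degradation is modeled as an M-tap FIR kernel h fitted by ridge-regularized
# least squares so that (ANB * h) reproduces the target abnormal beat.

#' Filter design configuration
#'
#' @param M filter length in taps (default 32 — a quarter of the beat
#'   length: long enough to reshape QRS/T morphology, short enough that the
#'   128-equation system stays well over-determined).
#' @param lam ridge regularization weight \eqn{\lambda \ge 0} (default 1e-3).
#' @param mode beat representation the filters act on, `"single"` or `"trio"`.
#' @return An object of class `filter_design_config`.
#' @export
filter_design_config <- function(M = 32L, lam = 1e-3,
                                 mode = c("single", "trio")) {
  mode <- match.arg(mode)
  M <- as.integer(M)
  if (is.na(M) || M < 1L || M > beat_length())
    stop("M must be in 1..", beat_length(), call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("lam must be a non-negative scalar", call. = FALSE)
  structure(list(M = M, lam = lam, mode = mode),
            class = "filter_design_config")
}

#' Convolution matrix of a beat
#'
#' Builds the 128 x M matrix `A` whose columns are shifted copies of the
#' beat `a`, such that `A %*% h` equals the same-length, center-tap-aligned
#' convolution of `a` with an M-tap kernel `h` (output index `t` is
#' `sum_k h[k] * a[t - k + floor(M/2)]` in 0-based indexing, zero-padded at
#' the borders). This makes filter application a linear map directly
#' comparable to a 128-sample target beat.
#'
#' @param a numeric vector of 128 samples (or a [beat_vector()]).
#' @param M number of taps, >= 1.
#' @return A 128 x M numeric matrix.
#' @export
convolution_matrix <- function(a, M) {
  if (inherits(a, "beat_vector")) a <- a$samples
  a <- as.numeric(a)
  if (length(a) != beat_length())
    stop("a must have ", beat_length(), " samples", call. = FALSE)
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be >= 1", call. = FALSE)
  n <- beat_length()
  center <- M %/% 2L
  A <- matrix(0, n, M)
  for (k in 0:(M - 1L)) {
    shift <- k - center               # column k holds a delayed by shift
    t0 <- 0:(n - 1L)
    src <- t0 - shift
    ok <- src >= 0L & src < n
    A[t0[ok] + 1L, k + 1L] <- a[src[ok] + 1L]
  }
  A
}

## internal: apply an M-tap kernel to 128 samples with the same alignment
## as convolution_matrix (used by synthesis; avoids materializing A)
apply_kernel <- function(a, h) {
  as.numeric(convolution_matrix(a, length(h)) %*% h)
}

#' Design one degradation filter by ridge-regularized least squares
#'
#' Solves `h = argmin ||b - A h||^2 + lambda ||h||^2` in closed form via the
#' regularized normal equations, where `A` is the convolution matrix of the
#' subject's average normal beat and `b` is the target abnormal beat. With
#' `lam = 0` and a singular system the minimum-norm pseudoinverse solution
#' is returned and flagged.
#'
#' @param anb single- or trio-mode [beat_vector()] of the average normal beat.
#' @param abnormal target [beat_vector()] with a non-N label, same mode.
#' @param cfg a [filter_design_config()] with matching mode.
#' @return An object of class `abs_filter` with elements `h` (M
#'   coefficients), `source_subject`, `source_class`, `source_beat_index`,
#'   `mode`, `coeff_variance` (variance of `h`), `fit_residual` (RMSE of the
#'   synthesized beat against the target), `singular` flag and `id`.
#' @export
design_filter <- function(anb, abnormal, cfg) {
  stopifnot(inherits(anb, "beat_vector"), inherits(abnormal, "beat_vector"),
            inherits(cfg, "filter_design_config"))
  if (anb$mode != cfg$mode || abnormal$mode != cfg$mode)
    stop("mode mismatch: anb=", anb$mode, ", abnormal=", abnormal$mode,
         ", cfg=", cfg$mode, call. = FALSE)
  if (abnormal$label == "N")
    stop("target beat must be abnormal (label != N)", call. = FALSE)
  A <- convolution_matrix(anb$samples, cfg$M)
  b <- abnormal$samples
  G <- crossprod(A) + cfg$lam * diag(cfg$M)
  rhs <- crossprod(A, b)
  singular <- FALSE
  h <- tryCatch(as.numeric(solve(G, rhs)),
                error = function(e) {
                  singular <<- TRUE
                  as.numeric(MASS::ginv(G) %*% rhs)
                })
  resid <- sqrt(mean((A %*% h - b)^2))
  new_abs_filter(h, abnormal$subject_id, abnormal$label, abnormal$beat_index,
                 cfg$mode, resid, singular)
}

new_abs_filter <- function(h, source_subject, source_class,
                           source_beat_index, mode, fit_residual,
                           singular = FALSE) {
  structure(
    list(h = as.numeric(h),
         source_subject = as.character(source_subject),
         source_class = source_class,
         source_beat_index = as.integer(source_beat_index),
         mode = mode,
         coeff_variance = if (length(h) > 1L) stats::var(as.numeric(h)) else 0,
         fit_residual = fit_residual,
         singular = isTRUE(singular),
         id = paste0(source_subject, ":", source_beat_index)),
    class = "abs_filter"
  )
}

#' @export
print.abs_filter <- function(x, ...) {
  cat(sprintf("<abs_filter> %d taps, %s-mode %s degradation from '%s' (RMSE %.4g)\n",
              length(x$h), x$mode, x$source_class, x$source_subject,
              x$fit_residual))
  invisible(x)
}

#' Test whether a degradation is effectively all-pass
#'
#' An abnormal beat whose shape is nearly identical to the ANB would yield a
#' filter that merely reproduces normal beats; such filters are excluded
#' from the library. The test is a similarity check on the beats themselves
#' (normalized distance `||b - a|| / ||a||` below `threshold`), independent
#' of the filter length. Timing-only anomalies (typical S beats) are
#' all-pass in the single representation but not in the trio representation.
#'
#' @param anb,abnormal [beat_vector()]s of the same mode.
#' @param threshold normalized-distance threshold (default 0.15).
#' @return Logical flag.
#' @export
is_all_pass <- function(anb, abnormal, threshold = 0.15) {
  stopifnot(inherits(anb, "beat_vector"), inherits(abnormal, "beat_vector"))
  if (anb$mode != abnormal$mode) stop("mode mismatch", call. = FALSE)
  na <- sqrt(sum(anb$samples^2))
  if (na == 0) stop("ANB has zero norm", call. = FALSE)
  sqrt(sum((abnormal$samples - anb$samples)^2)) / na < threshold
}

## internal: similarity of two coefficient vectors — Pearson correlation,
## with degenerate (constant) vectors compared by relative distance
coef_similarity <- function(h1, h2) {
  s1 <- stats::sd(h1); s2 <- stats::sd(h2)
  if (s1 == 0 || s2 == 0) {
    d <- sqrt(sum((h1 - h2)^2))
    return(if (d <= 1e-12 * max(1, sqrt(sum(h1^2)))) 1 else 0)
  }
  stats::cor(h1, h2)
}

#' Drop near-duplicate filters, keeping the best fit of each cluster
#'
#' When several abnormal beats of one subject are similar to each other,
#' one or a few representative filters suffice. Filters are processed in
#' `(fit_residual, source_subject, id)` order and greedily retained unless
#' their coefficient vector correlates above `sim_threshold` with an
#' already-retained filter — so each similarity cluster keeps its
#' lowest-residual member and the result is independent of input order.
#'
#' @param filters list of [design_filter()] results, same mode and M.
#' @param sim_threshold Pearson-correlation threshold (default 0.95).
#' @return Filtered list of `abs_filter`s.
#' @export
dedup_similar <- function(filters, sim_threshold = 0.95) {
  if (!length(filters)) return(filters)
  modes <- unique(vapply(filters, `[[`, "", "mode"))
  lens <- unique(vapply(filters, function(f) length(f$h), 1L))
  if (length(modes) != 1L || length(lens) != 1L)
    stop("filters must share one mode and one M", call. = FALSE)
  ord <- order(vapply(filters, `[[`, 1, "fit_residual"),
               vapply(filters, `[[`, "", "source_subject"),
               vapply(filters, `[[`, "", "id"))
  kept <- list()
  for (f in filters[ord]) {
    dup <- any(vapply(kept, function(g)
      coef_similarity(f$h, g$h) > sim_threshold, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- f
  }
  kept
}

#' Keep the k most distinct filters by coefficient variance
#'
#' The most distinct degradations — those with the highest variance among
#' the filter coefficients — are selected into the library. Ties are broken
#' by source subject, then id.
#'
#' @param filters list of `abs_filter`s.
#' @param k number to keep (default `Inf`: keep all, sorted).
#' @return List of at most `k` filters, sorted by descending variance.
#' @export
select_distinct <- function(filters, k = Inf) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!length(filters)) return(filters)
  ord <- order(-vapply(filters, `[[`, 1, "coeff_variance"),
               vapply(filters, `[[`, "", "source_subject"),
               vapply(filters, `[[`, "", "id"))
  utils::head(filters[ord], min(k, length(filters)))
}

#' Curation thresholds for library building
#'
#' @param all_pass_threshold normalized beat-distance below which the
#'   degradation is deemed all-pass and skipped (default 0.15).
#' @param sim_threshold coefficient-correlation threshold for per-subject
#'   deduplication (default 0.95).
#' @param k library size cap applied after pooling (default `Inf`).
#' @return A list of thresholds.
#' @export
curation_thresholds <- function(all_pass_threshold = 0.15,
                                sim_threshold = 0.95, k = Inf) {
  list(all_pass_threshold = all_pass_threshold,
       sim_threshold = sim_threshold, k = k)
}

new_filter_library <- function(filters, design_config, attrition = NULL) {
  provenance <- split(vapply(filters, `[[`, "", "id"),
                      vapply(filters, `[[`, "", "source_subject"))
  structure(list(filters = filters, design_config = design_config,
                 provenance = provenance, attrition = attrition),
            class = "filter_library")
}

#' @export
print.filter_library <- function(x, ...) {
  cls <- table(factor(vapply(x$filters, `[[`, "", "source_class"),
                      levels = abnormal_classes()))
  cat(sprintf("<filter_library> %s-mode, M=%d: %d filters (%s) from %d subjects\n",
              x$design_config$mode, x$design_config$M, length(x$filters),
              paste(sprintf("%s=%d", names(cls), as.integer(cls)),
                    collapse = " "),
              length(x$provenance)))
  invisible(x)
}

#' @export
length.filter_library <- function(x) length(x$filters)

#' Build the ABS filter library from a training cohort
#'
#' For each record: select the ANB from the first `anb_duration_s` seconds,
#' design one filter per abnormal beat that is not flagged all-pass, then
#' deduplicate similar filters within the subject. The per-subject
#' survivors are pooled and the most distinct `k` kept. Per-subject
#' attrition (designed / all-pass-skipped / dedup-removed / selected) is
#' recorded in the result. The whole procedure is deterministic.
#'
#' @param records list of [ecg_record()]s with at least one N beat in the
#'   first `anb_duration_s` seconds each.
#' @param cfg a [filter_design_config()].
#' @param curation a [curation_thresholds()] list.
#' @param anb_duration_s ANB selection window (default 300 s).
#' @param half_window,method segmentation parameters, see
#'   [segment_single_beat()].
#' @return A `filter_library`.
#' @export
build_library <- function(records, cfg, curation = curation_thresholds(),
                          anb_duration_s = 300, half_window = NULL,
                          method = "linear") {
  stopifnot(inherits(cfg, "filter_design_config"))
  trio <- cfg$mode == "trio"
  all_filters <- list()
  attrition <- list()
  for (rec in records) {
    hw <- if (is.null(half_window)) default_half_window(rec$fs)
          else half_window
    anb <- select_anb(rec, anb_duration_s, hw, method)
    a <- if (trio) anb$trio else anb$single
    ann <- rec$annotations
    ab_idx <- which(ann$label != "N")
    if (trio) ab_idx <- setdiff(ab_idx, c(1L, nrow(ann)))
    designed <- 0L; skipped <- 0L
    subj_filters <- list()
    for (i in ab_idx) {
      b <- if (trio) segment_trio(rec, i, hw, method)
           else segment_single_beat(rec, i, hw, method)
      if (is_all_pass(a, b, curation$all_pass_threshold)) {
        skipped <- skipped + 1L
        next
      }
      designed <- designed + 1L
      subj_filters[[length(subj_filters) + 1L]] <- design_filter(a, b, cfg)
    }
    deduped <- dedup_similar(subj_filters, curation$sim_threshold)
    attrition[[rec$subject_id]] <- c(
      abnormal_beats = length(ab_idx), all_pass_skipped = skipped,
      designed = designed, dedup_removed = designed - length(deduped),
      retained = length(deduped))
    all_filters <- c(all_filters, deduped)
  }
  selected <- select_distinct(all_filters, curation$k)
  new_filter_library(selected, cfg,
                     attrition = do.call(rbind, attrition))
}

#' Leave-subject-out view of a library
#'
#' Removes every filter designed from `subject_id`'s real abnormal beats,
#' so that a monitored person's classifier never sees degradations learned
#' from their own arrhythmias. The original library is untouched.
#'
#' @param library a `filter_library`.
#' @param subject_id subject to exclude.
#' @return A new `filter_library` without that subject's filters.
#' @export
exclude_subject <- function(library, subject_id) {
  stopifnot(inherits(library, "filter_library"))
  keep <- vapply(library$filters, function(f)
    f$source_subject != subject_id, TRUE)
  new_filter_library(library$filters[keep], library$design_config,
                     attrition = library$attrition)
}

# --- library serialization: JSON manifest + full-precision coefficient CSV

#' Write a filter library to disk
#'
#' Writes `<path>.json` (design config, provenance, per-filter metadata)
#' and `<path>.coef.csv` (one row per filter: id plus M coefficient columns
#' printed with 17 significant digits, so the round-trip through
#' [read_library()] is bit-exact).
#'
#' @param library a `filter_library`.
#' @param path path prefix.
#' @param config_hash optional provenance hash echoed into the manifest.
#' @return Invisibly, the paths written.
#' @export
write_library <- function(library, path, config_hash = NULL) {
  stopifnot(inherits(library, "filter_library"))
  meta <- lapply(library$filters, function(f)
    list(id = f$id, source_subject = f$source_subject,
         source_class = f$source_class,
         source_beat_index = f$source_beat_index, mode = f$mode,
         coeff_variance = f$coeff_variance, fit_residual = f$fit_residual,
         singular = f$singular))
  manifest <- list(format = "abswarn-filter-library", version = 1L,
                   config_hash = config_hash,
                   design_config = unclass(library$design_config),
                   filters = meta,
                   attrition = if (is.null(library$attrition)) NULL else
                     as.data.frame(library$attrition))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  M <- library$design_config$M
  con <- file(paste0(path, ".coef.csv"), "w")
  on.exit(close(con))
  writeLines(paste(c("id", paste0("h", seq_len(M))), collapse = ","), con)
  for (f in library$filters)
    writeLines(paste(c(f$id, sprintf("%.17g", f$h)), collapse = ","), con)
  invisible(paste0(path, c(".json", ".coef.csv")))
}

#' Read a filter library written by [write_library()]
#' @param path path prefix.
#' @return A `filter_library`.
#' @export
read_library <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(manifest$format, "abswarn-filter-library"))
    stop("not a filter library manifest: ", path, ".json", call. = FALSE)
  cfg <- filter_design_config(manifest$design_config$M,
                              manifest$design_config$lam,
                              manifest$design_config$mode)
  coef <- utils::read.csv(paste0(path, ".coef.csv"),
                          colClasses = c(id = "character"))
  filters <- lapply(manifest$filters, function(m) {
    row <- which(coef$id == m$id)[1]
    f <- new_abs_filter(as.numeric(coef[row, -1]), m$source_subject,
                        m$source_class, m$source_beat_index, m$mode,
                        m$fit_residual, m$singular)
    f
  })
  lib <- new_filter_library(filters, cfg)
  lib$config_hash <- manifest$config_hash
  lib
}
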