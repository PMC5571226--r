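# Orchestration of the five workflow steps: simulate (or supply) records,
# build the degradation-filter library, synthesize each person's training
# set and train their CNN ensemble, then monitor the beat stream and
# report detection metrics.  Every artifact on disk embeds the hash of the
# configuration that produced it; downstream steps refuse mixed-hash
# inputs unless forced.

#' Pipeline configuration
#'
#' Bundles every tunable of the workflow with the defaults used throughout
#' the package. The cohort arguments are forwarded to [gen_cohort()]; the
#' filter/curation/CNN arguments to their respective constructors.
#'
#' @param out_dir artifact directory.
#' @param seed master seed for cohort simulation and CNN initialization.
#' @param cohort named list of [gen_cohort()] arguments.
#' @param filter_M,filter_lam filter length and ridge weight.
#' @param curation a [curation_thresholds()] list.
#' @param cnn a [cnn_config()].
#' @param n_runs CNN ensemble size per subject (default 10).
#' @param anb_duration_s patient-specific window in seconds (default 300).
#' @param common_per_donor real N beats per training-partition donor merged
#'   into each personalized training set as common training data
#'   (default 30; 0 disables).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = file.path(tempdir(), "abswarn"),
                            seed = 1L, cohort = list(),
                            filter_M = 32L, filter_lam = 1e-3,
                            curation = curation_thresholds(),
                            cnn = cnn_config(seed = seed),
                            n_runs = 10L, anb_duration_s = 300,
                            common_per_donor = 30L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              filter_M = as.integer(filter_M), filter_lam = filter_lam,
              curation = curation, cnn = cnn, n_runs = as.integer(n_runs),
              anb_duration_s = anb_duration_s,
              common_per_donor = as.integer(common_per_donor))
  class(cfg) <- "pipeline_config"
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Hash a configuration for artifact provenance
#'
#' MD5 of the canonical JSON rendering of the configuration (excluding the
#' output directory and the hash field itself, so relocating artifacts
#' does not invalidate them).
#'
#' @param config a [pipeline_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  core <- strip_classes(unclass(config))
  core$out_dir <- NULL
  core$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## internal: stop when an artifact was produced under a different config
check_hash <- function(found, config, what, force = FALSE) {
  if (is.null(found) || identical(found, config$hash)) return(invisible())
  msg <- paste0(what, " was produced under config hash ", found,
                " but the current config hashes to ", config$hash)
  if (force) warning(msg, " (continuing: force = TRUE)", call. = FALSE)
  else stop(msg, " (pass force = TRUE to override)", call. = FALSE)
}

#' Step 1 — simulate and write the synthetic cohort
#'
#' Generates the cohort and writes each record in the CSV dialect under
#' `<out_dir>/records/`, plus `cohort_manifest.json` listing subjects,
#' partitions, seeds and beat counts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the cohort (list with `train`, `test`).
#' @export
pipeline_simulate <- function(config) {
  cohort <- do.call(gen_cohort, c(list(seed = config$seed), config$cohort))
  rec_dir <- file.path(config$out_dir, "records")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  describe <- function(rec, partition) {
    write_record(rec, file.path(rec_dir, rec$subject_id), "csv")
    list(subject_id = rec$subject_id, partition = partition,
         n_beats = nrow(rec$annotations),
         n_abnormal = sum(rec$annotations$label != "N"),
         fs = rec$fs, n_samples = length(rec$signal))
  }
  manifest <- list(
    format = "abswarn-cohort", version = 1L, config_hash = config$hash,
    seed = config$seed,
    subjects = c(lapply(cohort$train, describe, "train"),
                 lapply(cohort$test, describe, "test")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

## internal: load the cohort manifest and the records of one partition
load_partition <- function(config, partition, force = FALSE) {
  man_path <- file.path(config$out_dir, "cohort_manifest.json")
  if (!file.exists(man_path))
    stop("no cohort manifest at ", man_path, "; run pipeline_simulate first",
         call. = FALSE)
  manifest <- jsonlite::read_json(man_path)
  check_hash(manifest$config_hash, config, "cohort", force)
  ids <- vapply(manifest$subjects, function(s)
    if (s$partition == partition) s$subject_id else NA_character_, "")
  ids <- ids[!is.na(ids)]
  stats::setNames(lapply(ids, function(id)
    read_record(file.path(config$out_dir, "records", id), "csv",
                subject_id = id)), ids)
}

#' Step 2 — build and write the filter library
#'
#' Builds the single-mode and trio-mode degradation-filter libraries over
#' the training partition and writes them (JSON manifest + coefficient
#' CSV) to `<out_dir>/library_single` and `<out_dir>/library_trio`,
#' logging per-subject curation attrition.
#'
#' @param config a [pipeline_config()].
#' @param force proceed despite a config-hash mismatch.
#' @return Invisibly, list with `single` and `trio` libraries.
#' @export
pipeline_build_library <- function(config, force = FALSE) {
  records <- load_partition(config, "train", force)
  libs <- lapply(c(single = "single", trio = "trio"), function(mode) {
    lib <- build_library(
      records,
      filter_design_config(config$filter_M, config$filter_lam, mode),
      curation = config$curation, anb_duration_s = config$anb_duration_s)
    write_library(lib, file.path(config$out_dir, paste0("library_", mode)),
                  config_hash = config$hash)
    message(sprintf("%s-mode library: %d filters from %d subjects",
                    mode, length(lib), length(lib$provenance)))
    if (!is.null(lib$attrition))
      for (s in rownames(lib$attrition))
        message(sprintf(
          "  subject %s: %d abnormal beats, %d all-pass skipped, %d designed, %d dedup-removed, %d retained",
          s, lib$attrition[s, "abnormal_beats"],
          lib$attrition[s, "all_pass_skipped"],
          lib$attrition[s, "designed"], lib$attrition[s, "dedup_removed"],
          lib$attrition[s, "retained"]))
    lib
  })
  invisible(libs)
}

## internal: read both mode libraries, verifying provenance
load_libraries <- function(config, force = FALSE) {
  lapply(c(single = "single", trio = "trio"), function(mode) {
    path <- file.path(config$out_dir, paste0("library_", mode))
    if (!file.exists(paste0(path, ".json")))
      stop("no ", mode, "-mode library at ", path,
           "; run pipeline_build_library first", call. = FALSE)
    lib <- read_library(path)
    check_hash(lib$config_hash, config, paste0(mode, "-mode library"), force)
    lib
  })
}

#' Step 3+4 — synthesize a person's training set and train their ensemble
#'
#' Excludes the subject's own filters from the library (leave-subject-out;
#' disable with `exclude = FALSE` for the deployment scenario where the
#' monitored person contributed none), builds the personalized training
#' set, trains `n_runs` CNNs from consecutive seeds and writes the
#' training set, per-run models and training histories under
#' `<out_dir>/models/<subject_id>/`.
#'
#' @param config a [pipeline_config()].
#' @param subject_id test-partition subject to train for.
#' @param exclude apply leave-subject-out filter exclusion (default TRUE).
#' @param force proceed despite config-hash mismatches.
#' @return Invisibly, the list of [train_cnn()] results.
#' @export
pipeline_train_person <- function(config, subject_id, exclude = TRUE,
                                  force = FALSE) {
  subject <- read_record(file.path(config$out_dir, "records", subject_id),
                         "csv", subject_id = subject_id)
  libs <- load_libraries(config, force)
  donors <- if (config$common_per_donor > 0L)
    load_partition(config, "train", force) else NULL
  ts <- build_training_set(subject, libs, exclude = exclude,
                           duration_s = config$anb_duration_s,
                           common_records = donors,
                           common_per_donor = config$common_per_donor)
  if (ts$flagged_single_class)
    stop("cannot train for subject '", subject_id,
         "': training set has a single class", call. = FALSE)
  runs <- run_ensemble(ts, config$cnn, n_runs = config$n_runs,
                       seed = config$seed)
  subj_dir <- file.path(config$out_dir, "models", subject_id)
  dir.create(subj_dir, recursive = TRUE, showWarnings = FALSE)
  write_training_set(ts, file.path(subj_dir, "training_set"))
  for (k in seq_along(runs)) {
    write_cnn(runs[[k]]$model, file.path(subj_dir, sprintf("run%02d.json", k)),
              config_hash = config$hash)
    utils::write.csv(cbind(run = k, runs[[k]]$history,
                           stop_reason = runs[[k]]$stop_reason),
                     file.path(subj_dir, sprintf("history%02d.csv", k)),
                     row.names = FALSE)
  }
  message(sprintf("subject %s: %d real N + %d synthetic beats, %d runs trained",
                  subject_id, ts$n_real_normal,
                  sum(ts$n_synthetic_by_class), length(runs)))
  invisible(runs)
}

#' Extract the monitored beat stream of a record
#'
#' All beats annotated after `after_s` seconds (the patient-specific
#' window is reserved for training), in both representations; the last
#' beat of the record has no trio and is dropped.
#'
#' @param record an [ecg_record()].
#' @param after_s stream start in seconds (default 300).
#' @param half_window,method segmentation parameters.
#' @return List with `X` (`B x 2 x 128`), `labels` and `beat_index`.
#' @export
stream_beats <- function(record, after_s = 300,
                         half_window = default_half_window(record$fs),
                         method = "linear") {
  ann <- record$annotations
  idx <- which(ann$r_sample >= after_s * record$fs)
  idx <- idx[idx > 1L & idx < nrow(ann)]
  X <- array(0, c(length(idx), 2L, beat_length()))
  for (j in seq_along(idx)) {
    X[j, 1, ] <- segment_single_beat(record, idx[j], half_window,
                                     method)$samples
    X[j, 2, ] <- segment_trio(record, idx[j], half_window, method)$samples
  }
  list(X = X, labels = ann$label[idx], beat_index = idx)
}

#' Monitor a subject's beat stream with a trained ensemble
#'
#' Streams every post-window beat through each model, cumulates the
#' 5-class confusion matrix over models, collapses it and computes
#' detection metrics, plus the first-alarm latency of each model: the
#' position, among the true abnormal beats in stream order, of the first
#' one flagged abnormal (1 = the very first abnormal beat was caught).
#'
#' @param record the monitored [ecg_record()].
#' @param models list of `cnn_model`s or [train_cnn()] results.
#' @param after_s stream start (default 300 s).
#' @param half_window,method segmentation parameters.
#' @return List with `cm5`, `cm2`, `metrics`, `first_alarm_latency`
#'   (integer per model, NA if that model never alarmed), `n_streamed`,
#'   `n_abnormal` and `decisions` (model x beat label matrix).
#' @export
monitor_subject <- function(record, models, after_s = 300,
                            half_window = default_half_window(record$fs),
                            method = "linear") {
  if (!length(models)) stop("no models supplied", call. = FALSE)
  models <- lapply(models, function(m)
    if (inherits(m, "cnn_model")) m else m$model)
  stream <- stream_beats(record, after_s, half_window, method)
  n <- length(stream$labels)
  decisions <- matrix(NA_character_, length(models), n)
  for (k in seq_along(models))
    decisions[k, ] <- cnn_predict_batch(models[[k]], stream$X)
  cm5 <- as_confusion_matrix5(Reduce(`+`, lapply(seq_along(models),
    function(k) unclass(confusion_matrix5(stream$labels, decisions[k, ])))))
  cm2 <- collapse_cm(cm5)
  ab_pos <- which(stream$labels != "N")
  latency <- vapply(seq_along(models), function(k) {
    if (!length(ab_pos)) return(NA_integer_)
    hit <- which(decisions[k, ab_pos] != "N")
    if (length(hit)) hit[1] else NA_integer_
  }, 1L)
  list(cm5 = cm5, cm2 = cm2,
       metrics = detection_metrics(cm2),
       first_alarm_latency = latency,
       n_streamed = n, n_abnormal = length(ab_pos),
       decisions = decisions, labels = stream$labels)
}

#' Step 5 — monitor a subject and write the detection report
#'
#' @param config a [pipeline_config()].
#' @param subject_id subject to monitor (models must exist).
#' @param force proceed despite config-hash mismatches.
#' @return Invisibly, the [monitor_subject()] result.
#' @export
pipeline_monitor <- function(config, subject_id, force = FALSE) {
  subj_dir <- file.path(config$out_dir, "models", subject_id)
  model_files <- sort(list.files(subj_dir, pattern = "^run[0-9]+\\.json$",
                                 full.names = TRUE))
  if (!length(model_files))
    stop("no trained models for subject '", subject_id, "' under ",
         subj_dir, "; run pipeline_train_person first", call. = FALSE)
  models <- lapply(model_files, read_cnn)
  for (m in models)
    check_hash(m$config_hash, config, "model", force)
  record <- read_record(file.path(config$out_dir, "records", subject_id),
                        "csv", subject_id = subject_id)
  res <- monitor_subject(record, models, after_s = config$anb_duration_s)
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    format = "abswarn-report", version = 1L, config_hash = config$hash,
    subject_id = subject_id, n_models = length(models),
    n_streamed = res$n_streamed, n_abnormal = res$n_abnormal,
    cm5 = unclass(res$cm5), cm2 = unclass(res$cm2),
    metrics = unclass(res$metrics),
    first_alarm_latency = res$first_alarm_latency)
  jsonlite::write_json(report,
                       file.path(rep_dir, paste0(subject_id, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Run the full pipeline end to end
#'
#' simulate -> build library -> for each test subject: train the ensemble
#' and monitor the stream; finishes with a pooled per-subject report.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return List with `libraries`, per-subject `monitor` results, `report`
#'   (the [per_subject_report()] data frame) and `pooled_metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  run <- if (quiet) suppressMessages else identity
  run(pipeline_simulate(config))
  libs <- run(pipeline_build_library(config))
  manifest <- jsonlite::read_json(
    file.path(config$out_dir, "cohort_manifest.json"))
  test_ids <- unlist(lapply(manifest$subjects, function(s)
    if (s$partition == "test") s$subject_id))
  monitors <- list()
  for (id in test_ids) {
    run(pipeline_train_person(config, id))
    monitors[[id]] <- run(pipeline_monitor(config, id))
  }
  report <- per_subject_report(lapply(monitors, `[[`, "cm2"))
  list(libraries = libs, monitors = monitors, report = report,
       pooled_metrics = detection_metrics(
         confusion_matrix2(tn = report$tn[nrow(report)],
                           fn = report$fn[nrow(report)],
                           fp = report$fp[nrow(report)],
                           tp = report$tp[nrow(report)])))
}
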