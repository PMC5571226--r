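# Detection performance: 5-class confusion matrices cumulated over ensemble
# runs, collapsed to Normal-vs-Abnormal, with the standard metric set
# (Acc/Sen/Spe/Ppr/FAR) and the miss-probability / advance-warning figures.

#' Build a 5x5 confusion matrix from truth/prediction vectors
#'
#' Rows are ground truth, columns predictions, both in the order
#' N, S, V, F, Q.
#'
#' @param truth,predicted character vectors of AAMI symbols, same length.
#' @return An object of class `confusion_matrix5` (an integer matrix).
#' @export
confusion_matrix5 <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  lv <- aami_classes()
  m <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  structure(matrix(as.integer(m), 5, 5, dimnames = list(truth = lv, predicted = lv)),
            class = c("confusion_matrix5", "matrix"))
}

#' Construct a confusion matrix from counts
#' @param counts 5x5 non-negative integer matrix (rows truth, columns
#'   predicted, order N,S,V,F,Q).
#' @return A `confusion_matrix5`.
#' @export
as_confusion_matrix5 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(5L, 5L)), all(counts >= 0))
  lv <- aami_classes()
  structure(matrix(as.integer(round(counts)), 5, 5,
                   dimnames = list(truth = lv, predicted = lv)),
            class = c("confusion_matrix5", "matrix"))
}

#' Cumulate confusion matrices of an ensemble over a labelled beat stream
#'
#' Each beat is classified once per model and all per-model confusion
#' matrices are summed, matching the cumulated-over-10-runs reporting
#' convention.
#'
#' @param models list of `cnn_model`s (or [train_cnn()] results).
#' @param X `B x 2 x 128` input array.
#' @param truth character vector of true AAMI labels, length `B`.
#' @return A `confusion_matrix5` with total `B * length(models)`.
#' @export
accumulate_cm <- function(models, X, truth) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  total <- matrix(0L, 5, 5)
  for (m in models) {
    if (!inherits(m, "cnn_model")) m <- m$model
    total <- total + unclass(confusion_matrix5(truth, cnn_predict_batch(m, X)))
  }
  as_confusion_matrix5(total)
}

#' Collapse a 5-class confusion matrix to Normal-vs-Abnormal
#'
#' N is the negative class; S, V, F, Q together form the positive
#' (abnormal) class. A true abnormal beat predicted as any abnormal class
#' counts as a true positive even if the class label is wrong — the task
#' is detection, not typing.
#'
#' @param cm5 a `confusion_matrix5`.
#' @return An object of class `confusion_matrix2`: list with `tn`, `fn`,
#'   `fp`, `tp`.
#' @export
collapse_cm <- function(cm5) {
  m <- unclass(as_confusion_matrix5(cm5))
  confusion_matrix2(tn = m[1, 1],
                    fp = sum(m[1, -1]),
                    fn = sum(m[-1, 1]),
                    tp = sum(m[-1, -1]))
}

#' 2x2 Normal-vs-Abnormal confusion matrix
#' @param tn,fn,fp,tp non-negative counts (N negative, abnormal positive).
#' @return An object of class `confusion_matrix2`.
#' @export
confusion_matrix2 <- function(tn, fn, fp, tp) {
  v <- c(tn = tn, fn = fn, fp = fp, tp = tp)
  if (any(v < 0)) stop("confusion-matrix counts must be >= 0", call. = FALSE)
  structure(as.list(v), class = "confusion_matrix2")
}

#' @export
print.confusion_matrix2 <- function(x, ...) {
  cat("<confusion_matrix2>  (rows truth, cols predicted)\n")
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("N", "A"), c("N", "A")))
  print(m)
  invisible(x)
}

#' Detection metrics from a 2x2 confusion matrix
#'
#' Standard definitions: Sen = tp/(tp+fn), Spe = tn/(tn+fp),
#' Ppr = tp/(tp+fp), Acc = (tp+tn)/total, FAR = fp/(tn+fp) = 100 - Spe,
#' reported as percentages. The advance-warning figures model consecutive
#' abnormal-beat detections as independent: `p_miss1 = fn/(tp+fn)` is the
#' probability of missing the first abnormal beat, `p_miss3 = p_miss1^3`
#' of missing three in a row, and `p_detect_within3 = 1 - p_miss3` of
#' catching at least one of the first three occurrences. `p_miss1_trunc3`
#' is the 3-decimal truncation of `p_miss1` (a common printed rendering).
#' A metric whose denominator is zero is `NA` (not 0).
#'
#' @param cm2 a [confusion_matrix2()] (or a `confusion_matrix5`, collapsed
#'   first).
#' @return An object of class `detection_metrics`: list of percentages
#'   `acc, sen, spe, ppr, far` and probabilities `p_miss1, p_miss1_trunc3,
#'   p_miss3, p_detect_within3`.
#' @export
detection_metrics <- function(cm2) {
  if (inherits(cm2, "confusion_matrix5")) cm2 <- collapse_cm(cm2)
  stopifnot(inherits(cm2, "confusion_matrix2"))
  tn <- cm2$tn; fn <- cm2$fn; fp <- cm2$fp; tp <- cm2$tp
  total <- tn + fn + fp + tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- ratio(tp, tp + fn)
  spe <- ratio(tn, tn + fp)
  p_miss1 <- ratio(fn, tp + fn)
  structure(list(
    acc = 100 * (tp + tn) / total,
    sen = 100 * sen,
    spe = 100 * spe,
    ppr = 100 * ratio(tp, tp + fp),
    far = 100 * ratio(fp, tn + fp),
    p_miss1 = p_miss1,
    p_miss1_trunc3 = if (is.na(p_miss1)) NA_real_ else
      trunc(p_miss1 * 1000) / 1000,
    p_miss3 = p_miss1^3,
    p_detect_within3 = 1 - p_miss1^3
  ), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Sen %.2f%%  Spe %.2f%%  Ppr %.2f%%  FAR %.2f%%\n",
              x$acc, x$sen, x$spe, x$ppr, x$far))
  cat(sprintf("P(miss 1st abnormal) %.4f   P(miss 3 consecutive) %.4f   P(detect within 3) %.4f\n",
              x$p_miss1, x$p_miss3, x$p_detect_within3))
  invisible(x)
}

#' Per-subject detection report with a pooled row
#'
#' Pooling sums the 2x2 matrices before computing metrics (it is *not* the
#' mean of per-subject metrics). Subjects with no abnormal beats have
#' undefined Sen/Ppr/miss probabilities (reported `NA`) but a well-defined
#' FAR — they are the cleanest probes of the real false-alarm rate.
#'
#' @param cms named list of [confusion_matrix2()]s, one per subject.
#' @return Data frame with one row per subject plus a `"pooled"` row;
#'   columns `subject, tn, fn, fp, tp, acc, sen, spe, ppr, far, p_miss1,
#'   p_miss3, p_detect_within3`.
#' @export
per_subject_report <- function(cms) {
  stopifnot(length(cms) > 0)
  ids <- names(cms)
  if (is.null(ids)) ids <- as.character(seq_along(cms))
  row_of <- function(id, cm) {
    met <- detection_metrics(cm)
    data.frame(subject = id, tn = cm$tn, fn = cm$fn, fp = cm$fp, tp = cm$tp,
               acc = met$acc, sen = met$sen, spe = met$spe, ppr = met$ppr,
               far = met$far, p_miss1 = met$p_miss1, p_miss3 = met$p_miss3,
               p_detect_within3 = met$p_detect_within3)
  }
  rows <- Map(row_of, ids, cms)
  pooled <- confusion_matrix2(
    tn = sum(vapply(cms, `[[`, 1, "tn")),
    fn = sum(vapply(cms, `[[`, 1, "fn")),
    fp = sum(vapply(cms, `[[`, 1, "fp")),
    tp = sum(vapply(cms, `[[`, 1, "tp")))
  out <- do.call(rbind, c(rows, list(row_of("pooled", pooled))))
  rownames(out) <- NULL
  out
}
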