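# Labeled scalogram-image datasets with subject-level splits, and
# confusion-matrix evaluation of a trained classifier.

#' Build a labeled scalogram-image dataset with subject-level splits
#'
#' Converts each recording's Korotkoff window (annotation preferred) to a
#' CWT scalogram RGB image, then assigns SUBJECTS (never individual
#' recordings) to train/validation/test splits, stratified by class, so no
#' subject leaks across splits. Deterministic under `seed`.
#'
#' @param recordings list of [koro_recording()]s.
#' @param labels binary label per recording (0/1 or logical).
#' @param split fractions `c(train, val, test)` summing to 1.
#' @param seed integer seed for the split shuffle.
#' @param size image side in pixels.
#' @param f_min,f_max,n_scales CWT band and scale count.
#' @param whole_record if `TRUE`, transform the full record instead of the
#'   detected Korotkoff window.
#' @param config [feature_config()] used for window detection.
#' @return list of class `koro_imageset`: `images` (list of
#'   `size x size x 3` arrays), `labels`, `subject_ids`, `split`
#'   (train/val/test per image).
#' @export
build_dataset <- function(recordings, labels, split = c(0.7, 0.15, 0.15),
                          seed = 1L, size = 32L, f_min = 5, f_max = 100,
                          n_scales = 32L, whole_record = FALSE,
                          config = feature_config()) {
  labels <- as.integer(labels)
  if (length(labels) != length(recordings))
    stop("one label per recording required")
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (min(table(labels)) < 10L) stop("need >= 10 recordings per class")
  images <- lapply(recordings, function(rec) {
    x <- if (whole_record) rec$sound else {
      w <- detect_window(rec, config)
      rec$sound[(w$start + 1L):w$end]
    }
    scalogram_to_rgb(cwt_scalogram(x, rec$fs, f_min, f_max, n_scales),
                     height = size, width = size)
  })
  ids <- vapply(recordings, `[[`, "", "subject_id")
  subj_label <- tapply(labels, ids, function(l) l[1])
  split_of <- setNames(character(length(subj_label)), names(subj_label))
  for (cl in unique(subj_label)) {
    members <- names(subj_label)[subj_label == cl]
    members <- .with_seed(.derive_seed(seed, 1000L + cl),
                          sample(members))
    n <- length(members)
    n_te <- round(split[3] * n); n_va <- round(split[2] * n)
    tags <- rep("train", n)
    if (n_te > 0) tags[seq_len(n_te)] <- "test"
    if (n_va > 0) tags[n_te + seq_len(n_va)] <- "val"
    split_of[members] <- tags
  }
  structure(list(images = images, labels = labels, subject_ids = ids,
                 split = unname(split_of[ids])),
            class = "koro_imageset")
}

#' Subset an image set to one split
#' @param ds a [build_dataset()] result.
#' @param which `"train"`, `"val"` or `"test"`.
#' @return list with `images`, `labels`, `subject_ids`.
#' @export
dataset_split <- function(ds, which) {
  sel <- ds$split == which
  list(images = ds$images[sel], labels = ds$labels[sel],
       subject_ids = ds$subject_ids[sel])
}

#' Confusion-matrix metrics from counts
#'
#' @param tp,fn,fp,tn counts (positive class = label 1).
#' @return list of class `koro_confusion`: the counts, sensitivity
#'   (recall of class 1), specificity (recall of class 0), per-class
#'   precision, and overall accuracy.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty test set")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = safe(tp, tp + fn),
                 specificity = safe(tn, tn + fp),
                 precision_pos = safe(tp, tp + fp),
                 precision_neg = safe(tn, tn + fn),
                 accuracy = (tp + tn) / total),
            class = "koro_confusion")
}

#' @export
print.koro_confusion <- function(x, ...) {
  cat(sprintf(paste0("<koro_confusion> tp=%d fn=%d fp=%d tn=%d\n",
                     "  sensitivity=%.3f specificity=%.3f accuracy=%.3f\n"),
              x$tp, x$fn, x$fp, x$tn, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}

#' Evaluate a classifier on a held-out image set
#'
#' Argmax decisions of the model on each test image, summarized as
#' confusion counts and the derived per-class recalls/precisions and
#' overall accuracy.
#'
#' @param model a [train_compact_cnn()] model.
#' @param test list with `images` and `labels` (e.g. from
#'   [dataset_split()]).
#' @return a [confusion_metrics()] object.
#' @export
evaluate_classifier <- function(model, test) {
  if (!length(test$images)) stop("empty test set")
  probs <- predict_cnn(model, test$images)
  pred <- max.col(probs) - 1L
  y <- as.integer(test$labels)
  confusion_metrics(tp = sum(pred == 1 & y == 1),
                    fn = sum(pred == 0 & y == 1),
                    fp = sum(pred == 1 & y == 0),
                    tn = sum(pred == 0 & y == 0))
}
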