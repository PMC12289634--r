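#' Segmentation metrics
#'
#' Per-class Dice similarity, IoU, F1, precision and recall on
#' class-indexed masks, plus inference timing. Dice is the primary metric:
#' DSC = 2|T intersect P| / (|T| + |P|) for target pixels T and predicted
#' pixels P of one class. When a class is absent from both masks the
#' metrics are defined as 1 (perfect agreement on absence); absent from
#' only one, 0.
#'
#' @name eval-metrics
NULL

check_same_shape <- function(pred, target) {
  if (!all(dim(pred) == dim(target)))
    stopf("pred and target shapes differ: %s vs %s",
          paste(dim(pred), collapse = "x"), paste(dim(target), collapse = "x"))
}

#' Dice similarity coefficient for one class
#'
#' @param pred,target H x W integer class masks of equal shape.
#' @param cls class label.
#' @return Dice in [0, 1].
#' @export
dice_score <- function(pred, target, cls) {
  check_same_shape(pred, target)
  p <- pred == cls; t <- target == cls
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Per-class confusion counts
#'
#' @inheritParams dice_score
#' @return list with integer TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, target, cls) {
  check_same_shape(pred, target)
  p <- pred == cls; t <- target == cls
  tp <- sum(p & t)
  list(TP = tp, FP = sum(p) - tp, FN = sum(t) - tp,
       TN = length(p) - sum(p | t) + 0L)
}

#' Derived metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN); precision = TP/(TP+FP); recall = TP/(TP+FN);
#' F1 = 2 pr / (p + r). An undefined ratio is 1 when the class is absent
#' from both masks (TP+FP+FN = 0) and 0 otherwise.
#'
#' @param counts output of [confusion_counts()].
#' @return named list iou, precision, recall, f1.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  both_absent <- (tp + fp + fn) == 0
  rat <- function(num, den) if (den == 0) { if (both_absent) 1 else 0 } else num / den
  p <- rat(tp, tp + fp); r <- rat(tp, tp + fn)
  f1 <- if (p + r == 0) { if (both_absent) 1 else 0 } else 2 * p * r / (p + r)
  list(iou = rat(tp, tp + fp + fn), precision = p, recall = r, f1 = f1)
}

per_class_metrics <- function(pred, target, cls) {
  m <- metrics_from_counts(confusion_counts(pred, target, cls))
  c(dice = dice_score(pred, target, cls), iou = m$iou, f1 = m$f1,
    precision = m$precision, recall = m$recall)
}

# resolve a predictor: either a fitted model or a function(image) -> mask
as_predictor <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "larynx_model")) return(function(img) predict(model, img))
  stopf("model must be a larynx_model or a function(image) -> mask")
}

#' Evaluate a predictor on a sample set
#'
#' Computes per-class metrics for every sample and macro-averages them
#' over images (mean of per-image values, not pooled pixel counts).
#'
#' @param model a fitted `larynx_model`, or a function mapping an
#'   H x W x 3 image to an H x W class mask (useful for oracles in tests).
#' @param samples list of `larynx_sample` objects with ground-truth masks.
#' @param postprocess_on apply [postprocess_mask()] to predictions first?
#' @param classes class labels to report (default trachea 1, supraglottis 2).
#' @param config [post_config()] used when `postprocess_on`.
#' @return a `metrics_report`: data frame (class, dice, iou, f1, precision,
#'   recall) with attributes `aggregation = "macro"` and `n_images`.
#' @export
evaluate_model <- function(model, samples, postprocess_on = FALSE,
                           classes = c(1L, 2L), config = post_config()) {
  if (length(samples) == 0) stopf("samples must be non-empty")
  fn <- as_predictor(model)
  per_image <- lapply(samples, function(s) {
    pr <- fn(s$image)
    if (postprocess_on) pr <- postprocess_mask(pr, config)
    vapply(classes, function(cl) per_class_metrics(pr, s$mask, cl), numeric(5))
  })
  # per_image[[i]] is 5 x nclass; average over images
  avg <- Reduce(`+`, per_image) / length(per_image)
  rep <- data.frame(class = classes, t(avg))
  attr(rep, "aggregation") <- "macro"
  attr(rep, "n_images") <- length(samples)
  class(rep) <- c("metrics_report", "data.frame")
  rep
}

#' Time single-image inference
#'
#' Wall-clock per-image forward pass at batch size 1, after warm-up.
#'
#' @param model predictor as in [evaluate_model()].
#' @param images list of H x W x 3 arrays.
#' @param n_warmup untimed warm-up passes.
#' @param n_timed timed passes (cycling over `images`).
#' @return list with `duration_ms` (mean per image), `fps` = 1000 /
#'   duration_ms, `n_warmup`, `n_timed`.
#' @export
time_inference <- function(model, images, n_warmup = 5, n_timed = 20) {
  if (n_timed < 1) stopf("n_timed must be >= 1")
  fn <- as_predictor(model)
  pick <- function(k) images[[((k - 1) %% length(images)) + 1]]
  for (k in seq_len(n_warmup)) fn(pick(k))
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(n_timed)) fn(pick(k))
  el <- proc.time()[["elapsed"]] - t0
  dur <- 1000 * el / n_timed
  list(duration_ms = dur, fps = if (dur > 0) 1000 / dur else Inf,
       n_warmup = n_warmup, n_timed = n_timed)
}
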