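# Training objective (equally weighted BCE + Dice) and confusion-matrix
# evaluation metrics (precision, recall, F1, IoU, overall and expected
# accuracy, Cohen's kappa).

.check_pair <- function(pred, target) {
  if (!all(dim(pred) == dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1-y) log(1-p)]`; predictions are clamped
#' to `[clamp, 1-clamp]` before the logarithms.
#'
#' @param pred probability map (values in [0,1]).
#' @param target binary map of the same shape.
#' @param clamp clamping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(pred, target, clamp = 1e-7) {
  .check_pair(pred, target)
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2 sum(p*y) + s) / (sum(p) + sum(y) + s)` with smooth term `s`.
#'
#' @inheritParams bce_loss
#' @param smooth smoothing constant `s` (guards empty masks).
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1.0) {
  .check_pair(pred, target)
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Combined segmentation loss
#'
#' Equally weighted sum: `0.5 * BCE + 0.5 * Dice`.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, smooth = 1.0, clamp = 1e-7) {
  0.5 * bce_loss(pred, target, clamp) + 0.5 * dice_loss(pred, target, smooth)
}

# Gradient of the combined loss w.r.t. the probability map.
combined_loss_grad <- function(pred, target, smooth = 1.0, clamp = 1e-7) {
  n <- length(pred)
  p <- pmin(pmax(pred, clamp), 1 - clamp)
  g_bce <- (p - target) / (p * (1 - p)) / n
  den <- sum(pred) + sum(target) + smooth
  num <- 2 * sum(pred * target) + smooth
  g_dice <- -(2 * target * den - num) / den^2
  0.5 * g_bce + 0.5 * g_dice
}

#' Confusion counts between binary masks
#'
#' @param pred_mask,true_mask binary (0/1) arrays of identical shape.
#' @return list of class `confusion_counts` with fields TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  .check_pair(pred_mask, true_mask)
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  # doubles, not integers: EA's products overflow 32-bit counts on large sets
  tp <- as.numeric(sum(pred_mask == 1 & true_mask == 1))
  fp <- as.numeric(sum(pred_mask == 1 & true_mask == 0))
  fn <- as.numeric(sum(pred_mask == 0 & true_mask == 1))
  tn <- as.numeric(sum(pred_mask == 0 & true_mask == 0))
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

# Pool counts over an evaluation set (micro-averaging).
add_counts <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 FN = a$FN + b$FN, TN = a$TN + b$TN),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2 Pr Rec / (Pr + Rec)`, `IoU = TP/(TP+FP+FN)`, overall accuracy
#' `OA = (TP+TN)/total`, expected (chance) accuracy
#' `EA = [(TP+FN)(TP+FP) + (TN+FN)(TN+FP)] / total^2`, and Cohen's kappa
#' `(OA - EA)/(1 - EA)`. Degenerate denominators (`TP+FP = 0`, `TP+FN = 0`,
#' `EA = 1`) define the affected quantity as 0 and set the `degenerate` flag.
#'
#' @param cc a [confusion_counts()] object (or list with TP/FP/FN/TN).
#' @return list of class `metrics_report`: Pr, Rec, F1, IoU, OA, EA, Kappa,
#'   degenerate flag.
#' @export
compute_metrics <- function(cc) {
  tp <- as.numeric(cc$TP); fp <- as.numeric(cc$FP)
  fn <- as.numeric(cc$FN); tn <- as.numeric(cc$TN)
  total <- tp + fp + fn + tn
  if (total <= 0) stop("confusion counts are all zero")
  degenerate <- FALSE
  pr <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (pr + rec > 0) 2 * pr * rec / (pr + rec) else 0
  iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else { degenerate <- TRUE; 0 }
  oa <- (tp + tn) / total
  ea <- ((tp + fn) * (tp + fp) + (tn + fn) * (tn + fp)) / total^2
  kappa <- if (ea < 1) (oa - ea) / (1 - ea) else { degenerate <- TRUE; 0 }
  structure(list(Pr = pr, Rec = rec, F1 = f1, IoU = iou, OA = oa, EA = ea,
                 Kappa = kappa, degenerate = degenerate),
            class = "metrics_report")
}

#' Write a metrics report as a flat key-value text record
#'
#' One `metric value` pair per line; optionally appends the report as a row
#' to a CSV log.
#'
#' @param report a `metrics_report`.
#' @param path output text file.
#' @param csv_log optional CSV file to append a row to (created with a header
#'   if missing).
#' @export
write_metrics_report <- function(report, path, csv_log = NULL) {
  keys <- c("Pr", "Rec", "F1", "IoU", "OA", "EA", "Kappa")
  writeLines(sprintf("%s %.6f", keys, unlist(report[keys])), path)
  if (!is.null(csv_log)) {
    row <- as.data.frame(report[keys])
    utils::write.table(row, csv_log, sep = ",", append = file.exists(csv_log),
                       col.names = !file.exists(csv_log), row.names = FALSE)
  }
  invisible(path)
}
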