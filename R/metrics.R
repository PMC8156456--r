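# Segmentation evaluation from pixel confusion counts, with lesion as the
# positive class.  The six measures: sensitivity, specificity, accuracy,
# Jaccard, Dice and Matthews correlation coefficient.
#
# Degenerate conventions (empty classes): SEN with TP+FN = 0 -> 1;
# JAC/DIC with an empty union -> 1; SPE with FP+TN = 0 -> 1;
# MCC with any zero factor under the root -> 0.

#' Pixel confusion counts
#'
#' @param pred_mask,gt_mask binary masks (0/1 or logical) of equal shape.
#' @return list of class `confusion_counts` with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("pred and gt masks must have the same shape")
  p <- as.numeric(pred_mask); g <- as.numeric(gt_mask)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("masks must be binary 0/1")
  # doubles, not integers: metric products (MCC root) overflow 32-bit
  structure(list(TP = as.numeric(sum(p == 1 & g == 1)),
                 FP = as.numeric(sum(p == 1 & g == 0)),
                 TN = as.numeric(sum(p == 0 & g == 0)),
                 FN = as.numeric(sum(p == 0 & g == 1))),
            class = "confusion_counts")
}

#' The six confusion-matrix metrics
#'
#' SEN = TP/(TP+FN), SPE = TN/(FP+TN), ACC = (TP+TN)/total,
#' JAC = TP/(TP+FN+FP), DIC = 2TP/(2TP+FP+FN),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' @param c a `confusion_counts` object (or a list with TP/FP/TN/FN).
#' @return list of class `metrics_report` with SEN, SPE, ACC, JAC, DIC, MCC
#'   as fractions in [0,1] (MCC in [-1,1]).
#' @export
compute_metrics <- function(c) {
  TP <- as.numeric(c$TP); FP <- as.numeric(c$FP)
  TN <- as.numeric(c$TN); FN <- as.numeric(c$FN)
  total <- TP + FP + TN + FN
  if (total <= 0) stop("empty confusion counts")
  sen <- if (TP + FN == 0) 1 else TP / (TP + FN)
  spe <- if (FP + TN == 0) 1 else TN / (FP + TN)
  acc <- (TP + TN) / total
  jac <- if (TP + FN + FP == 0) 1 else TP / (TP + FN + FP)
  dic <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  root <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (root == 0) 0 else (TP * TN - FP * FN) / sqrt(root)
  structure(list(SEN = sen, SPE = spe, ACC = acc, JAC = jac, DIC = dic,
                 MCC = mcc),
            class = "metrics_report")
}

#' Per-image evaluation with mean row
#'
#' Computes each metric per image and appends the unweighted mean across
#' images (the per-image averaging protocol used for test-set tables; note
#' this differs from pooling pixels across images).
#'
#' @param pred_masks,gt_masks aligned lists of binary masks.
#' @param percent report metrics in percent (default TRUE).
#' @param pooled also append a `pooled` row computed from the summed
#'   confusion counts of all images (differs from the per-image mean in
#'   general; the tables use the per-image mean).
#' @return data.frame with one row per image plus a final `mean` row (and
#'   optionally a `pooled` row).
#' @export
evaluate_per_image <- function(pred_masks, gt_masks, percent = TRUE,
                               pooled = FALSE) {
  if (length(pred_masks) != length(gt_masks))
    stop("pred and gt lists must have equal length")
  if (length(pred_masks) == 0) stop("no masks given")
  confs <- lapply(seq_along(pred_masks), function(i)
    confusion(pred_masks[[i]], gt_masks[[i]]))
  rows <- lapply(seq_along(confs), function(i) {
    mt <- compute_metrics(confs[[i]])
    data.frame(image = i, SEN = mt$SEN, SPE = mt$SPE, ACC = mt$ACC,
               JAC = mt$JAC, DIC = mt$DIC, MCC = mt$MCC)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(image = NA_integer_, t(colMeans(df[, -1])))
  names(mean_row) <- names(df)
  df <- rbind(df, mean_row)
  labels <- c(seq_along(pred_masks), "mean")
  if (pooled) {
    tot <- list(TP = sum(vapply(confs, `[[`, 0, "TP")),
                FP = sum(vapply(confs, `[[`, 0, "FP")),
                TN = sum(vapply(confs, `[[`, 0, "TN")),
                FN = sum(vapply(confs, `[[`, 0, "FN")))
    mp <- compute_metrics(tot)
    df <- rbind(df, data.frame(image = NA_integer_, SEN = mp$SEN,
                               SPE = mp$SPE, ACC = mp$ACC, JAC = mp$JAC,
                               DIC = mp$DIC, MCC = mp$MCC))
    labels <- c(labels, "pooled")
  }
  rownames(df) <- labels
  if (percent) df[, -1] <- df[, -1] * 100
  df
}

dice_of_masks <- function(pred, gt) {
  compute_metrics(confusion(pred, gt))$DIC
}
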