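#' Evaluate a fitted model on a patch dataset
#'
#' Runs inference on every patch, binarizes the probability masks at 0.5,
#' and assembles the full evaluation report: per-patch IOU/IOP/IOA against
#' the annotation, confused-pixel counts, per-lesion-kind aggregates, AP of
#' mask detections at IOU thresholds 0.3/0.5/0.7, patch-level
#' classification metrics, and — when the dataset carries true lesion masks
#' (synthetic phantoms) — a recovery block comparing predictions and
#' annotations to the hidden true lesion.
#'
#' @param fit A `latentcadx` fit (or a bare `seg_model`).
#' @param dataset A `patch_dataset` or list of `tissue_patch` objects.
#' @param threshold Binarization threshold for the probability mask.
#' @param epsilon Confused-pixel band half-width.
#' @return An object of class `eval_report` with elements `per_patch`
#'   (data frame), `aggregate`, `ap_at_iou`, `classification`, `recovery`
#'   (or `NULL`) and `conventions`.
#' @export
evaluate <- function(fit, dataset, threshold = 0.5, epsilon = 0.2) {
  if (length(dataset) == 0) stop("empty dataset")
  pred <- predict(fit, dataset)
  n <- length(dataset)
  masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- dataset[[i]]
    M <- pred$M[, , i]
    P <- binarize(M, threshold)
    masks[[i]] <- P
    m <- iop_ioa_iou(P, p$annotation)
    rows[[i]] <- data.frame(patch_id = p$patch_id,
                            lesion_kind = p$lesion_kind,
                            label = p$label,
                            y = pred$y[i],
                            iou = m[["iou"]], iop = m[["iop"]],
                            ioa = m[["ioa"]],
                            confused_pixels = confused_pixels(M, epsilon),
                            pred_pixels = sum(P > 0),
                            egress_pixels = sum(P > 0 & p$annotation == 0),
                            stringsAsFactors = FALSE)
  }
  per_patch <- do.call(rbind, rows)
  agg_over <- function(df) {
    data.frame(n = nrow(df), iou = mean(df$iou), iop = mean(df$iop),
               ioa = mean(df$ioa),
               confused_pixels = mean(df$confused_pixels))
  }
  pos <- per_patch[per_patch$label == 1, ]
  aggregate <- cbind(subset = "all_positive", agg_over(pos))
  for (kind in setdiff(unique(pos$lesion_kind), "none")) {
    aggregate <- rbind(aggregate,
                       cbind(subset = kind,
                             agg_over(pos[pos$lesion_kind == kind, ])))
  }
  anns <- lapply(dataset, `[[`, "annotation")
  ap <- vapply(c(0.3, 0.5, 0.7), function(th) {
    ap_at_iou(masks, per_patch$y, anns, threshold = th,
              patch_ids = per_patch$patch_id)
  }, 0)
  names(ap) <- c("0.3", "0.5", "0.7")
  cls <- if (length(unique(per_patch$label)) == 2) {
    classification_metrics(per_patch$y, per_patch$label)
  } else NULL
  has_true <- vapply(dataset, function(p) !is.null(p$true_mask), TRUE)
  recovery <- NULL
  if (any(has_true)) {
    idx <- which(has_true)
    iou_pred_true <- vapply(idx, function(i) {
      iop_ioa_iou(masks[[i]], dataset[[i]]$true_mask)[["iou"]]
    }, 0)
    iou_ann_true <- vapply(idx, function(i) {
      iop_ioa_iou(dataset[[i]]$annotation, dataset[[i]]$true_mask)[["iou"]]
    }, 0)
    recovery <- list(n = length(idx),
                     mean_iou_prediction_true = mean(iou_pred_true),
                     mean_iou_annotation_true = mean(iou_ann_true))
  }
  structure(list(per_patch = per_patch, aggregate = aggregate,
                 ap_at_iou = ap, classification = cls,
                 recovery = recovery, threshold = threshold,
                 epsilon = epsilon,
                 conventions = paste(
                   "empty prediction: IOP = 1 if annotation also empty",
                   "else 0 (IOA symmetric); IOU of two empty masks = 1;",
                   "binarization uses >= threshold; AP uses all-points",
                   "interpolation")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("Evaluation report (", nrow(x$per_patch), " patches, threshold ",
      x$threshold, ", epsilon ", x$epsilon, ")\n", sep = "")
  cat("\nAggregate over positive patches:\n")
  print(format(x$aggregate, digits = digits), row.names = FALSE)
  cat("\nAP at IOU thresholds:\n")
  print(round(x$ap_at_iou, digits))
  if (!is.null(x$classification)) {
    cat("\nClassification:\n")
    print(round(x$classification, digits))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf(paste0(
      "\nLatent-lesion recovery (n = %d):\n",
      "  mean IOU(prediction, true lesion)  %.3f\n",
      "  mean IOU(annotation, true lesion)  %.3f\n"),
      x$recovery$n, x$recovery$mean_iou_prediction_true,
      x$recovery$mean_iou_annotation_true))
  }
  invisible(x)
}
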