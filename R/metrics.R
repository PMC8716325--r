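#' Threshold a probability mask to a binary mask
#'
#' Pixels with probability greater than or equal to the threshold become 1
#' (ties go to positive).
#'
#' @param M Probability mask in `[0, 1]`.
#' @param threshold Probability cut, default 0.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(M, threshold = 0.5) {
  out <- M
  out[] <- as.integer(M >= threshold)
  out
}

#' Intersection over prediction, annotation, and union
#'
#' For binary prediction P and annotation A with intersection I:
#' `iop = |I| / |P|` (pixel-level specificity with respect to the
#' annotation), `ioa = |I| / |A|` (pixel-level sensitivity) and
#' `iou = |I| / |P or A|`. When annotations merely circumscribe the lesion,
#' high IOP combined with low IOA is the signature of a prediction tighter
#' than its annotation. Empty-set conventions: an empty prediction scores
#' IOP 1 against an empty annotation (a perfect negative) and 0 otherwise;
#' IOA symmetrically; the IOU of two empty masks is 1.
#'
#' @param P Binary prediction mask.
#' @param A Binary annotation mask of the same shape.
#' @return Named numeric vector `c(iop, ioa, iou)`.
#' @examples
#' A <- matrix(0, 4, 4); A[1:2, 1:2] <- 1
#' P <- matrix(0, 4, 4); P[1:2, 1] <- 1
#' iop_ioa_iou(P, A)   # iop 1, ioa 0.5, iou 0.5
#' @export
iop_ioa_iou <- function(P, A) {
  if (!identical(dim(P), dim(A))) stop("mask shapes differ")
  p <- P > 0
  a <- A > 0
  i <- sum(p & a)
  np <- sum(p)
  na <- sum(a)
  nu <- sum(p | a)
  c(iop = if (np == 0) as.numeric(na == 0) else i / np,
    ioa = if (na == 0) as.numeric(np == 0) else i / na,
    iou = if (nu == 0) 1 else i / nu)
}

#' Count confused pixels in a probability mask
#'
#' Pixels whose predicted probability lies in the inclusive band
#' `[0.5 - epsilon, 0.5 + epsilon]` are "confused": the model cannot commit
#' them to lesion or healthy tissue. The band width quantifies boundary
#' uncertainty; a binary mask has none.
#'
#' @param M Probability mask.
#' @param epsilon Band half-width in `(0, 0.5)`, default 0.2 (band
#'   0.3-0.7).
#' @return Integer count.
#' @export
confused_pixels <- function(M, epsilon = 0.2) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  sum(M >= 0.5 - epsilon & M <= 0.5 + epsilon)
}

# Non-interpolated average precision (classification convention):
# precision-weighted recall increments over every distinct score cut-point,
# so tied scores enter as one group.
ap_from_scores <- function(scores, labels) {
  n_positive <- sum(labels == 1)
  if (n_positive == 0) return(NA_real_)
  ord <- order(-scores)
  scores <- scores[ord]
  labels <- labels[ord]
  tp <- cumsum(labels == 1)
  fp <- cumsum(labels == 0)
  # group boundary = last index of each distinct score
  last <- which(c(scores[-1] != scores[-length(scores)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n_positive
  sum(diff(c(0, rec)) * prec)
}

# All-points (VOC 2010+/COCO) interpolated AP for detection: precision is
# replaced by its running maximum over decreasing recall.
ap_interpolated <- function(is_tp, n_positive) {
  if (n_positive == 0) return(NA_real_)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  prec <- tp / (tp + fp)
  rec <- tp / n_positive
  prec <- rev(cummax(rev(prec)))
  dr <- diff(c(0, rec))
  sum(prec * dr)
}

#' Average precision of mask detections at a fixed IOU threshold
#'
#' Each patch carries one predicted mask with a confidence score. On a
#' positive patch (nonempty annotation) the prediction is a true positive
#' when its IOU with the annotation reaches `threshold`, otherwise a false
#' positive; any nonempty prediction on a negative patch is a false
#' positive; an empty prediction is no detection (a missed positive lowers
#' recall). Detections are ranked by confidence (ties broken by patch id
#' for determinism) and AP is computed with all-points interpolation.
#'
#' @param predictions List of binary prediction masks.
#' @param confidences Numeric vector of per-patch confidence scores.
#' @param annotations List of binary annotation masks (empty mask = negative
#'   patch).
#' @param threshold IOU threshold (the reported operating points are 0.3,
#'   0.5 and 0.7).
#' @param patch_ids Optional ids used for deterministic tie-breaking.
#' @return AP in `[0, 1]`.
#' @export
ap_at_iou <- function(predictions, confidences, annotations,
                      threshold = 0.5,
                      patch_ids = as.character(seq_along(predictions))) {
  stopifnot(length(predictions) == length(annotations),
            length(predictions) == length(confidences))
  pos <- vapply(annotations, function(a) sum(a > 0) > 0, TRUE)
  if (!any(pos)) stop("AP undefined: no positive annotations")
  nonempty <- vapply(predictions, function(p) sum(p > 0) > 0, TRUE)
  det <- which(nonempty)
  if (length(det) == 0) return(0)
  is_tp <- vapply(det, function(i) {
    pos[i] && iop_ioa_iou(predictions[[i]], annotations[[i]])["iou"] >=
      threshold
  }, TRUE)
  ord <- order(-confidences[det], patch_ids[det])
  ap_interpolated(is_tp[ord], sum(pos))
}

#' Patch-level classification metrics
#'
#' F1, precision and recall at the 0.5 score threshold, average precision
#' (area under the precision-recall curve, non-interpolated) and ROC-AUC
#' (trapezoid over all cut-points, equivalent to the rank statistic).
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels; both classes must be present.
#' @return Named numeric vector `c(f1, precision, recall, ap, roc_auc)`.
#' @export
classification_metrics <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  if (length(unique(labels)) < 2) {
    stop("classification metrics need both classes")
  }
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  ap <- ap_from_scores(scores, labels)
  # Mann-Whitney form handles ties exactly
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(f1 = f1, precision = precision, recall = recall, ap = ap,
    roc_auc = auc)
}
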