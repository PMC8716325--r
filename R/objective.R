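#' Loss weights for the joint objective
#'
#' The total training objective combines a patch-level classification
#' cross-entropy with a segmentation loss decomposed over the annotation
#' mask: an in-bounds term (mean squared shortfall inside the annotation)
#' and an out-of-bounds term (mean squared egress outside it), weighted by
#' `alpha`, `beta` and `gamma` respectively. Defaults are the full-stage
#' configuration alpha = 2, beta = 1, gamma = 0.5; the decoder warm-up stage
#' uses [warmup_weights()] with beta = gamma = 1 and no classification term.
#'
#' @param alpha Weight of the classification cross-entropy term.
#' @param beta Weight of the in-bounds segmentation term.
#' @param gamma Weight of the out-of-bounds segmentation term.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 2, beta = 1, gamma = 0.5) {
  if (any(c(alpha, beta, gamma) < 0)) stop("loss weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' @rdname loss_weights
#' @export
warmup_weights <- function() loss_weights(alpha = 0, beta = 1, gamma = 1)

# Clamp predicted probabilities away from 0/1 before taking logs.
PROB_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Binary cross-entropy between predicted probability and label
#'
#' `-(label * log(y) + (1 - label) * log(1 - y))`, with `y` clamped to
#' `[1e-7, 1 - 1e-7]` so hard labels stay finite. Vectorized over patches.
#'
#' @param y Predicted probability (or vector of probabilities) in `[0, 1]`.
#' @param label Binary label(s).
#' @return Nonnegative cross-entropy value(s).
#' @examples
#' cross_entropy(0.5, 1)    # log(2)
#' cross_entropy(0.9, 1)    # -log(0.9)
#' @export
cross_entropy <- function(y, label) {
  y <- clamp_prob(y)
  -(label * log(y) + (1 - label) * log(1 - y))
}

#' Out-of-bounds segmentation loss
#'
#' Mean squared predicted probability over the pixels outside the
#' annotation: with complement mask `M' = 1 - annotation`, the loss is
#' `(1 / N_oob) * sum(M' * M^2)` where `N_oob = sum(M')`. It penalizes
#' probability mass that egresses beyond the circumscribing annotation
#' boundary. Returns 0 when the annotation covers the whole patch
#' (`N_oob = 0`).
#'
#' @param M Probability mask in `[0, 1]`.
#' @param annotation Binary mask of the same shape.
#' @return List with `value` (the loss) and `n` (`N_oob`).
#' @export
loss_oob <- function(M, annotation) {
  check_same_dim(M, annotation)
  comp <- 1 - (annotation > 0)
  n <- sum(comp)
  value <- if (n == 0) 0 else sum(comp * M^2) / n
  list(value = value, n = n)
}

#' In-bounds segmentation loss
#'
#' Mean squared shortfall of the predicted probability inside the
#' annotation: `(1 / N_inb) * sum(A * (A - M)^2)`, i.e. the mean of
#' `(1 - M)^2` over annotated pixels, `N_inb = sum(A)`. Returns 0 for an
#' empty annotation (negative patches contribute only classification and
#' out-of-bounds terms).
#'
#' @inheritParams loss_oob
#' @return List with `value` (the loss) and `n` (`N_inb`).
#' @export
loss_inb <- function(M, annotation) {
  check_same_dim(M, annotation)
  a <- annotation > 0
  n <- sum(a)
  value <- if (n == 0) 0 else sum(a * (1 - M)^2) / n
  list(value = value, n = n)
}

check_same_dim <- function(M, annotation) {
  if (!identical(dim(M), dim(annotation))) {
    stop("probability mask and annotation shapes differ")
  }
  invisible(TRUE)
}

#' Weighted joint classification-segmentation loss for one patch
#'
#' Combines the three objective terms for a single patch:
#' `total = alpha * cross_entropy(y, label) + beta * l_inb + gamma * l_oob`.
#' Batch losses are reduced as the mean of per-patch totals.
#'
#' @param y Predicted patch-level lesion probability.
#' @param label Binary patch label.
#' @param M Probability mask.
#' @param annotation Binary annotation mask, same shape as `M`.
#' @param w A [loss_weights()] object.
#' @return A `loss_breakdown` list with components `cross_ent`, `l_inb`,
#'   `l_oob`, `total`, `n_inb`, `n_oob`.
#' @examples
#' ann <- matrix(c(1, 0, 0, 0), 2, 2)
#' M <- matrix(c(0.5, 0, 0.5, 0), 2, 2)
#' total_loss(0.9, 1, M, ann, loss_weights(2, 1, 0.5))$total  # ~0.50239
#' @export
total_loss <- function(y, label, M, annotation, w = loss_weights()) {
  ce <- cross_entropy(y, label)
  inb <- loss_inb(M, annotation)
  oob <- loss_oob(M, annotation)
  structure(list(cross_ent = ce,
                 l_inb = inb$value,
                 l_oob = oob$value,
                 total = w$alpha * ce + w$beta * inb$value +
                   w$gamma * oob$value,
                 n_inb = inb$n,
                 n_oob = oob$n),
            class = "loss_breakdown")
}

# Batched loss over model outputs, plus gradients w.r.t. the pre-sigmoid
# outputs (logits), reduced as the mean over the batch. `annotations` is an
# (H, W, 1, N) array, `labels` a length-N 0/1 vector. Setting `plain_mse`
# replaces the inb/oob decomposition with an undivided full-image MSE
# against the annotation (comparison baseline).
batch_objective <- function(out, labels, annotations, w,
                            plain_mse = FALSE, with_grads = TRUE) {
  n <- length(labels)
  grads <- list()
  ce <- 0
  if (w$alpha > 0 && !is.null(out$y)) {
    ce <- mean(cross_entropy(out$y, labels))
    if (with_grads) grads$gylogit <- w$alpha * (out$y - labels) / n
  }
  l_inb <- 0
  l_oob <- 0
  mse <- 0
  if (!is.null(out$M)) {
    M <- out$M
    A <- annotations
    if (plain_mse) {
      npx <- prod(dim(M)[1:3])
      diff <- M - A
      mse <- sum(diff^2) / (npx * n)
      if (with_grads) {
        grads$gMlogit <- (2 * diff / (npx * n)) * M * (1 - M)
      }
    } else {
      gM <- zero_arr(M)
      for (i in seq_len(n)) {
        Ai <- A[, , 1, i]
        Mi <- M[, , 1, i]
        inb <- loss_inb(Mi, Ai)
        oob <- loss_oob(Mi, Ai)
        l_inb <- l_inb + inb$value / n
        l_oob <- l_oob + oob$value / n
        gMi <- 0 * Mi
        if (inb$n > 0) gMi <- gMi + w$beta * (Ai > 0) * 2 * (Mi - 1) / inb$n
        if (oob$n > 0) gMi <- gMi + w$gamma * (Ai <= 0) * 2 * Mi / oob$n
        gM[, , 1, i] <- gMi / n
      }
      if (with_grads) grads$gMlogit <- gM * M * (1 - M)
    }
  }
  seg <- if (plain_mse) mse else w$beta * l_inb + w$gamma * l_oob
  list(cross_ent = ce, l_inb = l_inb, l_oob = l_oob, mse = mse,
       total = w$alpha * ce + seg, grads = grads)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss breakdown: total %.5f (CE %.5f, inb %.5f over %d px, oob %.5f over %d px)\n",
    x$total, x$cross_ent, x$l_inb, x$n_inb, x$l_oob, x$n_oob))
  invisible(x)
}
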