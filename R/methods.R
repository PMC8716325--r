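# S3 methods for fitted models.

#' Predict lesion probabilities and segmentation masks
#'
#' @param object A `latentcadx` fit or bare `seg_model`.
#' @param newdata A `patch_dataset`, list of `tissue_patch` objects, a
#'   single `tissue_patch`, or an `(H, W, 1, N)` array of images.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return List with `y` (patch-level lesion probabilities) and `M`
#'   (`H x W x N` array of per-pixel lesion probabilities).
#' @export
predict.latentcadx <- function(object, newdata, batch_size = 32, ...) {
  predict_model(object$model, newdata, batch_size)
}

#' @export
predict.seg_model <- function(object, newdata, batch_size = 32, ...) {
  predict_model(object, newdata, batch_size)
}

predict_model <- function(model, newdata, batch_size = 32) {
  if (inherits(newdata, "tissue_patch")) newdata <- list(newdata)
  x <- if (is.array(newdata) && length(dim(newdata)) == 4) {
    newdata
  } else {
    n <- length(newdata)
    sz <- nrow(newdata[[1]]$image)
    a <- array(0, c(sz, sz, 1, n))
    for (i in seq_len(n)) a[, , 1, i] <- newdata[[i]]$image
    a
  }
  n <- dim(x)[4]
  heads <- intersect(model$cfg$heads, c("classify", "segment"))
  y <- numeric(n)
  M <- array(0, c(dim(x)[1], dim(x)[2], n))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- forward_pass(model, x[, , , b, drop = FALSE], heads = heads)
    if (!is.null(fw$y)) y[b] <- fw$y
    if (!is.null(fw$M)) M[, , b] <- fw$M[, , 1, ]
  }
  list(y = y, M = M)
}

#' @export
print.latentcadx <- function(x, ...) {
  cat("latentcadx fit (mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  %d patches, input %d px, %d encoder stages, %d decoder blocks\n",
              x$n_patches, x$model_cfg$input_size,
              length(x$model_cfg$encoder_stages),
              x$model_cfg$decoder_blocks))
  tl <- x$logs$train
  if (!is.null(tl)) {
    cat(sprintf("  %d epochs trained; final train loss %.5f, val loss %.5f\n",
                nrow(tl), tl$train_total[nrow(tl)], tl$val_total[nrow(tl)]))
  }
  invisible(x)
}

#' @export
summary.latentcadx <- function(object, ...) {
  np <- length(unlist(object$model$params, use.names = FALSE))
  cat("Weakly-supervised joint classification-segmentation fit\n")
  print(object)
  cat(sprintf("  %d parameters; elapsed %.1f s\n", np, object$elapsed))
  if (!is.null(object$transfer_report)) {
    cat("  weight transfer:\n")
    print(object$transfer_report, row.names = FALSE)
  }
  if (!is.null(object$logs$train)) {
    cat("  last epochs:\n")
    print(utils::tail(object$logs$train[, c("epoch", "phase", "lr",
                                            "train_total", "val_total")], 5),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.latentcadx <- function(object, ...) object$model$params

#' Overlay a predicted mask on a patch
#'
#' Renders the patch in grayscale with the annotation boundary region in
#' red, the predicted mask in green, and their overlap in yellow.
#'
#' @param x A `latentcadx` fit.
#' @param patch A `tissue_patch`.
#' @param threshold Binarization threshold.
#' @param ... Passed to [graphics::rasterImage()].
#' @export
plot.latentcadx <- function(x, patch, threshold = 0.5, ...) {
  pred <- predict(x, patch)
  P <- binarize(pred$M[, , 1], threshold)
  img <- patch$image
  r <- img; g <- img; b <- img
  ann <- patch$annotation > 0
  pr <- P > 0
  r[ann & !pr] <- 1; g[ann & !pr] <- g[ann & !pr] * 0.3
  g[pr & !ann] <- 1; r[pr & !ann] <- r[pr & !ann] * 0.3
  r[ann & pr] <- 1; g[ann & pr] <- 1; b[ann & pr] <- b[ann & pr] * 0.3
  rgb_arr <- array(c(r, g, b), c(dim(img), 3))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(rgb_arr, 0, 0, 1, 1, ...)
  graphics::title(main = sprintf("%s  y = %.2f", patch$patch_id,
                                 pred$y[1]))
  invisible(x)
}

#' @export
print.seg_model <- function(x, ...) {
  np <- length(unlist(x$params, use.names = FALSE))
  cat(sprintf("seg_model: input %d px, deepest %dx%dx%d, heads [%s], %d parameters\n",
              x$cfg$input_size, x$cfg$deepest_grid, x$cfg$deepest_grid,
              x$cfg$deepest_channels, paste(x$cfg$heads, collapse = ", "),
              np))
  invisible(x)
}
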