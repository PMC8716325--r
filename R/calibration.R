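#' Calibration pipeline configuration for raw scans
#'
#' Raw scanner intensities are mapped to optical density (OD), clipped,
#' normalized to `[0, 1]`, zero-padded to a common canvas and downsampled.
#' Scanner-specific OD curves are pluggable through `od_map`; the default is
#' the linear map `raw / 65535 * 3` taking the full 16-bit range onto OD
#' 0-3. OD values below `od_clip_low` are clipped to 0 and values above
#' `od_clip_high` to `od_clip_high`, before dividing by `od_clip_high`.
#'
#' @param od_map Monotone function from raw intensity to optical density.
#' @param od_clip_low,od_clip_high OD clipping bounds (defaults 0.05 and 3).
#' @param pad_to Canvas size `c(rows, cols)` that raw scans are zero-padded
#'   to before downsampling (default 4000 x 6000).
#' @param downsample_factor Linear scale factor in `(0, 1]` (default 0.25;
#'   block-mean area averaging when `1 / factor` is an integer).
#' @param patch_size Side of the tissue patches sampled downstream.
#' @param rotation_deg,crop,noise_sigma Augmentation settings: maximum
#'   rotation in degrees, whether to random-crop (and resize back), and the
#'   additive image noise scale.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(od_map = function(raw) raw / 65535 * 3,
                               od_clip_low = 0.05,
                               od_clip_high = 3.0,
                               pad_to = c(4000, 6000),
                               downsample_factor = 0.25,
                               patch_size = 256,
                               rotation_deg = 15,
                               crop = TRUE,
                               noise_sigma = 0.02) {
  stopifnot(is.function(od_map),
            od_clip_low >= 0, od_clip_low < od_clip_high,
            downsample_factor > 0, downsample_factor <= 1,
            length(pad_to) == 2)
  if (patch_size > min(pad_to) * downsample_factor) {
    stop("patch_size exceeds the downsampled canvas")
  }
  structure(list(od_map = od_map, od_clip_low = od_clip_low,
                 od_clip_high = od_clip_high, pad_to = as.integer(pad_to),
                 downsample_factor = downsample_factor,
                 patch_size = as.integer(patch_size),
                 rotation_deg = rotation_deg, crop = isTRUE(crop),
                 noise_sigma = noise_sigma),
            class = "calibration_config")
}

# Block-mean area downsampling for integer reciprocal factors.
block_mean <- function(x, k) {
  h <- nrow(x) %/% k
  w <- ncol(x) %/% k
  x <- x[seq_len(h * k), seq_len(w * k), drop = FALSE]
  colMeans(matrix(aperm(array(x, c(k, h, k, w)), c(1, 3, 2, 4)),
                  k * k, h * w)) |>
    matrix(h, w)
}

#' Calibrate a raw 16-bit scan to the normalized `[0, 1]` scale
#'
#' Applies the full preprocessing pipeline: OD mapping, clipping (below
#' `od_clip_low` to 0, above `od_clip_high` to `od_clip_high`),
#' normalization by `od_clip_high`, zero-padding to `pad_to` and
#' downsampling by `downsample_factor`. The pipeline is monotone pixelwise
#' and never crops: a scan larger than the canvas is an error.
#'
#' @param raw Numeric matrix of raw scanner intensities.
#' @param cfg A [calibration_config()].
#' @return Matrix with values in `[0, 1]` of size
#'   `round(pad_to * downsample_factor)`.
#' @examples
#' cfg <- calibration_config(od_map = identity, pad_to = c(8, 8),
#'                           downsample_factor = 1, patch_size = 8)
#' calibrate_scan(matrix(c(0.04, 0.05, 1.5, 3.2), 2), cfg)
#' @export
calibrate_scan <- function(raw, cfg = calibration_config()) {
  raw <- as.matrix(raw)
  if (length(raw) == 0) stop("empty scan")
  if (nrow(raw) > cfg$pad_to[1] || ncol(raw) > cfg$pad_to[2]) {
    stop("scan exceeds the padding canvas; refusing to crop silently")
  }
  od <- cfg$od_map(raw)
  od[od < cfg$od_clip_low] <- 0
  od[od > cfg$od_clip_high] <- cfg$od_clip_high
  norm <- od / cfg$od_clip_high
  canvas <- matrix(0, cfg$pad_to[1], cfg$pad_to[2])
  canvas[seq_len(nrow(norm)), seq_len(ncol(norm))] <- norm
  f <- cfg$downsample_factor
  if (f == 1) return(canvas)
  k <- 1 / f
  if (abs(k - round(k)) < 1e-9) {
    block_mean(canvas, as.integer(round(k)))
  } else {
    as.matrix(EBImage::resize(canvas, w = round(nrow(canvas) * f),
                              h = round(ncol(canvas) * f)))
  }
}

# Clamp a window start so [start, start + size) fits in [1, n].
clamp_window <- function(start, size, n) {
  if (size > n) stop("patch larger than scan")
  min(max(start, 1L), n - size + 1L)
}

#' Extract the positive patch centered on a region of interest
#'
#' The patch window is centered on the ROI center of mass (rounded to the
#' nearest pixel) and shifted inward when it would exceed the scan; the
#' annotation is the ROI mask cropped to the same window.
#'
#' @param scan Calibrated scan matrix in `[0, 1]`.
#' @param roi_mask Binary matrix of the same shape, nonempty.
#' @param patch_size Patch side in pixels.
#' @param lesion_kind Lesion category recorded on the patch.
#' @return A `tissue_patch` with `label = 1` and no `true_mask`.
#' @export
sample_positive_patch <- function(scan, roi_mask, patch_size = 256,
                                  lesion_kind = "mass") {
  stopifnot(identical(dim(scan), dim(roi_mask)))
  pos <- which(roi_mask > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("empty ROI mask")
  com <- round(colMeans(pos))
  half <- patch_size %/% 2
  r0 <- clamp_window(com[1] - half, patch_size, nrow(scan))
  c0 <- clamp_window(com[2] - half, patch_size, ncol(scan))
  rows <- r0 + seq_len(patch_size) - 1L
  cols <- c0 + seq_len(patch_size) - 1L
  structure(list(image = scan[rows, cols],
                 label = 1L,
                 annotation = matrix(as.integer(roi_mask[rows, cols] > 0),
                                     patch_size, patch_size),
                 true_mask = NULL,
                 lesion_kind = lesion_kind,
                 patch_id = sprintf("pos_r%d_c%d", r0, c0),
                 seed = NA_integer_),
            class = "tissue_patch")
}

#' Extract negative patches with a sliding window
#'
#' Raster-order windows (row-major) over the scan; windows whose fraction
#' of tissue pixels (intensity above `intensity_threshold`) falls below
#' `tissue_min` are discarded. All returned patches have label 0 and an
#' all-zero annotation.
#'
#' @param scan Calibrated scan matrix.
#' @param patch_size Window side in pixels.
#' @param stride Window step in pixels (`>= 1`).
#' @param tissue_min Minimum tissue fraction to keep a window.
#' @param intensity_threshold Intensity above which a pixel counts as
#'   tissue.
#' @return List of `tissue_patch` objects (possibly empty).
#' @export
sample_negative_patches <- function(scan, patch_size = 256, stride = 256,
                                    tissue_min = 0.25,
                                    intensity_threshold = 0.05) {
  stopifnot(stride >= 1)
  starts_r <- seq(1L, nrow(scan) - patch_size + 1L, by = stride)
  starts_c <- seq(1L, ncol(scan) - patch_size + 1L, by = stride)
  out <- list()
  zero_ann <- matrix(0L, patch_size, patch_size)
  for (r0 in starts_r) {
    for (c0 in starts_c) {
      win <- scan[r0 + seq_len(patch_size) - 1L,
                  c0 + seq_len(patch_size) - 1L]
      if (mean(win > intensity_threshold) < tissue_min) next
      out[[length(out) + 1L]] <- structure(
        list(image = win, label = 0L, annotation = zero_ann,
             true_mask = NULL, lesion_kind = "none",
             patch_id = sprintf("neg_r%d_c%d", r0, c0),
             seed = NA_integer_),
        class = "tissue_patch")
    }
  }
  out
}

# Resample `mat` at real-valued source coordinates (sy, sx); "bilinear" for
# intensities, "nearest" for masks; out-of-bounds samples are 0.
sample_grid <- function(mat, sy, sx, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  n <- nrow(mat); m <- ncol(mat)
  if (filter == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= n & ix >= 1 & ix <= m
    out <- numeric(length(sy))
    out[ok] <- mat[cbind(iy[ok], ix[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    out <- numeric(length(sy))
    for (dy in 0:1) {
      for (dx in 0:1) {
        yy <- y0 + dy; xx <- x0 + dx
        wgt <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
        ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= m & wgt > 0
        out[ok] <- out[ok] + wgt[ok] * mat[cbind(yy[ok], xx[ok])]
      }
    }
  }
  matrix(out, n)
}

warp_rotate <- function(mat, angle_deg, filter) {
  n <- nrow(mat)
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  gy <- matrix(rep(seq_len(n), n), n) - ctr
  gx <- matrix(rep(seq_len(n), each = n), n) - ctr
  sy <- ctr + cos(th) * gy - sin(th) * gx
  sx <- ctr + sin(th) * gy + cos(th) * gx
  sample_grid(mat, sy, sx, filter)
}

warp_crop_resize <- function(mat, r0, c0, side, filter) {
  n <- nrow(mat)
  u <- (seq_len(n) - 1) / (n - 1)
  sy <- matrix(rep(r0 + u * (side - 1), n), n)
  sx <- matrix(rep(c0 + u * (side - 1), each = n), n)
  sample_grid(mat, sy, sx, filter)
}

#' Randomly augment a tissue patch
#'
#' Applies, in order: a random rotation uniform in
#' `[-rotation_deg, rotation_deg]` about the patch center (bilinear for the
#' image, nearest-neighbor for the masks, so masks stay binary and the
#' circumscription of the true mask by the annotation is preserved); an
#' optional random crop (side fraction in `[0.85, 1]`) resized back to the
#' original resolution; and additive Gaussian noise on the image only,
#' re-clipped to `[0, 1]`. Deterministic under `seed`.
#'
#' @param patch A `tissue_patch`.
#' @param cfg A [calibration_config()] carrying the augmentation settings.
#' @param seed Integer seed.
#' @return The augmented `tissue_patch`.
#' @export
augment_patch <- function(patch, cfg = calibration_config(), seed = 1L) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  img <- patch$image
  ann <- patch$annotation
  tm <- patch$true_mask
  angle <- stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg)
  if (angle != 0) {
    img <- warp_rotate(img, angle, "bilinear")
    ann <- warp_rotate(ann, angle, "nearest")
    if (!is.null(tm)) tm <- warp_rotate(tm, angle, "nearest")
  }
  if (cfg$crop) {
    n <- nrow(img)
    frac <- stats::runif(1, 0.85, 1)
    side <- max(2, round(frac * n))
    r0 <- sample.int(n - side + 1L, 1)
    c0 <- sample.int(n - side + 1L, 1)
    img <- warp_crop_resize(img, r0, c0, side, "bilinear")
    ann <- warp_crop_resize(ann, r0, c0, side, "nearest")
    if (!is.null(tm)) tm <- warp_crop_resize(tm, r0, c0, side, "nearest")
  }
  if (cfg$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = cfg$noise_sigma),
                        nrow(img))
  }
  patch$image <- pmin(pmax(img, 0), 1)
  patch$annotation <- matrix(as.integer(ann > 0.5), nrow(ann))
  if (!is.null(tm)) patch$true_mask <- matrix(as.integer(tm > 0.5), nrow(tm))
  patch$label <- as.integer(any(patch$annotation > 0))
  patch
}
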