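#' Specification of a synthetic tissue phantom patch
#'
#' Describes one family of seedable phantom patches: a textured background,
#' optionally a bright blob-like "mass" lesion or a cluster of small bright
#' "calcification" specks, the true lesion support, and a coarse hand-drawn
#' style annotation that strictly circumscribes the lesion. The annotation
#' is the morphological dilation of the convex hull of the true mask by a
#' margin drawn uniformly from `annotation_margin_range` — emulating
#' clinical annotations that enclose the lesion plus a band of healthy
#' tissue, with calcification clusters receiving a single coarse loop
#' around all specks.
#'
#' @param patch_size Square patch side in pixels (64 for desk-scale work,
#'   256 for scan-scale patches).
#' @param lesion_kind `"mass"`, `"calcification"` or `"none"`.
#' @param mass_radius_range Base radius range of a mass lesion, pixels.
#' @param mass_boundary_irregularity Amplitude of the radial boundary
#'   perturbation `r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k))`,
#'   harmonics k = 2..5; 0 gives a disc.
#' @param calc_speck_count_range Range of speck counts per cluster.
#' @param calc_speck_radius_range Speck radius range, pixels.
#' @param annotation_margin_range Dilation margin range, pixels; the lower
#'   bound must be at least 1 so annotations strictly circumscribe.
#' @param contrast Lesion-over-background intensity lift in `[0, 1]`.
#' @param noise_sigma Standard deviation of per-pixel Gaussian noise.
#' @param seed Default seed used by [generate_patch()] when none is given.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(patch_size = 64,
                           lesion_kind = c("mass", "calcification", "none"),
                           mass_radius_range = c(10, 18),
                           mass_boundary_irregularity = 0.25,
                           calc_speck_count_range = c(5, 12),
                           calc_speck_radius_range = c(1, 2),
                           annotation_margin_range = c(4, 10),
                           contrast = 0.5,
                           noise_sigma = 0.08,
                           seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  check_range <- function(r, nm, lo_min = 0) {
    if (length(r) != 2 || any(r < lo_min) || r[1] > r[2]) {
      stop(nm, " must be c(low, high) with ", lo_min, " <= low <= high")
    }
  }
  check_range(mass_radius_range, "mass_radius_range")
  check_range(calc_speck_count_range, "calc_speck_count_range", 1)
  check_range(calc_speck_radius_range, "calc_speck_radius_range")
  check_range(annotation_margin_range, "annotation_margin_range", 1)
  stopifnot(patch_size >= 16, contrast >= 0, contrast <= 1, noise_sigma >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 lesion_kind = lesion_kind,
                 mass_radius_range = mass_radius_range,
                 mass_boundary_irregularity = mass_boundary_irregularity,
                 calc_speck_count_range = as.integer(calc_speck_count_range),
                 calc_speck_radius_range = calc_speck_radius_range,
                 annotation_margin_range = annotation_margin_range,
                 contrast = contrast,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Binary raster of the filled convex hull of the positive pixels of `mask`.
# Falls back to the mask itself for degenerate (< 3 point, collinear) sets.
convex_hull_mask <- function(mask) {
  pos <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pos) < 3) return(mask > 0)
  hull_idx <- grDevices::chull(pos[, 2], pos[, 1])
  if (length(hull_idx) < 3) return(mask > 0)
  vx <- pos[hull_idx, 2]   # column coordinate
  vy <- pos[hull_idx, 1]   # row coordinate
  n <- nrow(mask)
  px <- matrix(rep(seq_len(ncol(mask)), each = n), n)
  py <- matrix(rep(seq_len(n), ncol(mask)), n)
  inside <- matrix(TRUE, n, ncol(mask))
  k <- length(vx)
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    cross <- (vx[e2] - vx[e]) * (py - vy[e]) - (vy[e2] - vy[e]) * (px - vx[e])
    inside <- inside & (cross <= 1e-9)   # chull returns clockwise order
  }
  inside | (mask > 0)
}

# Dilate a binary mask by a disc of the given integer radius.
dilate_mask <- function(mask, radius) {
  radius <- as.integer(round(radius))
  if (radius < 1 || !any(mask)) return(mask > 0)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::dilate(matrix(as.numeric(mask > 0), nrow(mask)), brush) > 0
}

# Smoothly textured background in roughly [0.1, 0.4].
textured_background <- function(n, smooth_sigma) {
  g <- matrix(stats::rnorm(n * n), n, n)
  sm <- EBImage::gblur(g, sigma = smooth_sigma)
  rng <- range(sm)
  b <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else sm * 0
  0.1 + 0.3 * b
}

disc_mask <- function(n, center, radius) {
  r <- matrix(rep(seq_len(n), n), n)
  c_ <- matrix(rep(seq_len(n), each = n), n)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

# Irregular star-convex mass: radius modulated by low-order harmonics.
mass_mask <- function(n, center, r0, irregularity) {
  ks <- 2:5
  amp <- irregularity * stats::runif(length(ks), -1, 1) / length(ks)
  phi <- stats::runif(length(ks), 0, 2 * pi)
  r <- matrix(rep(seq_len(n), n), n)
  c_ <- matrix(rep(seq_len(n), each = n), n)
  dy <- r - center[1]
  dx <- c_ - center[2]
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(ks), function(i) {
    amp[i] * sin(ks[i] * theta + phi[i])
  })))
  rad <- pmax(rad, 1)
  sqrt(dy^2 + dx^2) <= rad
}

#' Generate one synthetic tissue patch
#'
#' Deterministically renders a phantom patch from its specification: the
#' same `(spec, seed)` pair always yields a bit-identical patch. Positive
#' patches carry the true lesion support in `true_mask` and a strictly
#' circumscribing coarse `annotation`; for `lesion_kind = "none"` both masks
#' are empty and the label is 0. If the drawn margin pushes the annotation
#' against the patch border, the annotation is clipped to the patch and a
#' warning is raised.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return An object of class `tissue_patch`: a list with `image` (matrix in
#'   `[0, 1]`), `label` (0/1), `annotation` and `true_mask` (binary
#'   matrices), `lesion_kind`, `patch_id` and `seed`.
#' @examples
#' p <- generate_patch(synthetic_spec(lesion_kind = "mass"), seed = 1)
#' sum(p$true_mask) < sum(p$annotation)   # strictly circumscribed
#' @export
generate_patch <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  n <- spec$patch_size
  img <- textured_background(n, smooth_sigma = n / 8)
  true_mask <- matrix(FALSE, n, n)
  if (spec$lesion_kind == "mass") {
    # patches are lesion-centered (sampled at the ROI center of mass), so
    # the lesion sits near the middle and occupies a substantial fraction
    center <- stats::runif(2, 0.45 * n, 0.55 * n)
    r0 <- stats::runif(1, spec$mass_radius_range[1], spec$mass_radius_range[2])
    true_mask <- mass_mask(n, center, r0, spec$mass_boundary_irregularity)
  } else if (spec$lesion_kind == "calcification") {
    center <- stats::runif(2, 0.45 * n, 0.55 * n)
    k <- spec$calc_speck_count_range[1] +
      sample.int(diff(spec$calc_speck_count_range) + 1L, 1) - 1L
    for (i in seq_len(k)) {
      sc <- pmin(pmax(center + stats::rnorm(2, sd = n / 10), 2), n - 1)
      sr <- stats::runif(1, spec$calc_speck_radius_range[1],
                         spec$calc_speck_radius_range[2])
      true_mask <- true_mask | disc_mask(n, sc, sr)
    }
  }
  annotation <- matrix(FALSE, n, n)
  if (any(true_mask)) {
    mr <- as.integer(spec$annotation_margin_range)
    margin <- mr[1] + sample.int(mr[2] - mr[1] + 1L, 1) - 1L
    annotation <- dilate_mask(convex_hull_mask(true_mask), margin)
    if (any(annotation[1, ]) || any(annotation[n, ]) ||
        any(annotation[, 1]) || any(annotation[, n])) {
      warning("annotation reached the patch border and was clipped")
    }
    img <- img + spec$contrast * true_mask
  }
  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img,
                 label = as.integer(any(annotation)),
                 annotation = matrix(as.integer(annotation), n, n),
                 true_mask = if (spec$lesion_kind == "none") NULL
                             else matrix(as.integer(true_mask), n, n),
                 lesion_kind = spec$lesion_kind,
                 patch_id = sprintf("%s_%010d", spec$lesion_kind,
                                    as.integer(seed)),
                 seed = as.integer(seed)),
            class = "tissue_patch")
}

#' Generate a reproducible dataset of synthetic patches
#'
#' Draws per-patch seeds from the master seed, renders every patch, and
#' builds a manifest. With `dir` given, patches are written as grayscale
#' PNGs (masks as 0/255 PNGs) plus `manifest.csv`; identical calls produce
#' byte-identical manifests and images.
#'
#' @param spec_table List of `list(spec = synthetic_spec, count = n)` rows.
#' @param seed Master integer seed.
#' @param dir Optional output directory.
#' @return An object of class `patch_dataset`: a list of `tissue_patch`
#'   objects with the manifest data frame in `attr(, "manifest")`.
#' @export
generate_dataset <- function(spec_table, seed = 1L, dir = NULL) {
  counts <- vapply(spec_table, function(r) as.integer(r$count), 0L)
  if (any(counts <= 0)) stop("counts must be positive")
  total <- sum(counts)
  if (total == 0) stop("no patches requested")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  patch_seeds <- sample.int(.Machine$integer.max - 1L, total)
  patches <- vector("list", total)
  rows <- vector("list", total)
  idx <- 0L
  for (r in spec_table) {
    for (i in seq_len(r$count)) {
      idx <- idx + 1L
      p <- generate_patch(r$spec, seed = patch_seeds[idx])
      p$patch_id <- sprintf("p%05d_%s", idx, r$spec$lesion_kind)
      patches[[idx]] <- p
      rows[[idx]] <- data.frame(patch_id = p$patch_id,
                                image_path = NA_character_,
                                annotation_path = NA_character_,
                                true_mask_path = NA_character_,
                                label = p$label,
                                lesion_kind = p$lesion_kind,
                                seed = p$seed,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(total)) {
      p <- patches[[i]]
      ip <- file.path(dir, paste0(p$patch_id, ".png"))
      ap <- file.path(dir, paste0(p$patch_id, "_annotation.png"))
      png::writePNG(p$image, ip)
      png::writePNG(p$annotation + 0, ap)
      manifest$image_path[i] <- ip
      manifest$annotation_path[i] <- ap
      if (!is.null(p$true_mask)) {
        tp <- file.path(dir, paste0(p$patch_id, "_true.png"))
        png::writePNG(p$true_mask + 0, tp)
        manifest$true_mask_path[i] <- tp
      }
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(patches, manifest = manifest, class = "patch_dataset")
}

#' Convenience cohort builder with a configurable class imbalance
#'
#' Builds a mixed dataset of negative, mass and calcification patches at a
#' chosen negative:positive ratio (screening data is heavily imbalanced;
#' the desk-scale default keeps 3 negatives per positive, while scan-scale
#' cohorts run near 12.7:1).
#'
#' @param n_positive Number of positive patches (split evenly between mass
#'   and calcification; an odd remainder goes to mass).
#' @param neg_ratio Negatives per positive.
#' @param seed Master seed.
#' @param ... Passed on to [synthetic_spec()] (e.g. `patch_size`,
#'   `annotation_margin_range`).
#' @return A `patch_dataset`.
#' @export
synthetic_cohort <- function(n_positive, neg_ratio = 3, seed = 1L, ...) {
  n_mass <- ceiling(n_positive / 2)
  n_calc <- n_positive - n_mass
  n_neg <- round(neg_ratio * n_positive)
  tab <- list(list(spec = synthetic_spec(lesion_kind = "none", ...),
                   count = n_neg),
              list(spec = synthetic_spec(lesion_kind = "mass", ...),
                   count = n_mass))
  if (n_calc > 0) {
    tab <- c(tab, list(list(
      spec = synthetic_spec(lesion_kind = "calcification", ...),
      count = n_calc)))
  }
  generate_dataset(tab, seed = seed)
}

#' @export
print.tissue_patch <- function(x, ...) {
  cat(sprintf("tissue_patch %s: %dx%d px, label %d, %d annotated px%s\n",
              x$patch_id, nrow(x$image), ncol(x$image), x$label,
              sum(x$annotation),
              if (!is.null(x$true_mask)) {
                sprintf(", %d true lesion px", sum(x$true_mask))
              } else ""))
  invisible(x)
}

#' @export
print.patch_dataset <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("patch_dataset: %d patches (%d positive)\n",
              length(x), sum(m$label)))
  invisible(x)
}
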