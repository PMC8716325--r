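test_that("negative patches are empty and labeled 0", {
  p <- generate_patch(synthetic_spec(lesion_kind = "none"), seed = 7)
  expect_equal(p$label, 0L)
  expect_true(all(p$annotation == 0))
  expect_null(p$true_mask)
  expect_true(all(p$image >= 0 & p$image <= 1))
})

test_that("annotations strictly circumscribe the true lesion", {
  for (kind in c("mass", "calcification")) {
    for (seed in 1:5) {
      p <- suppressWarnings(
        generate_patch(synthetic_spec(lesion_kind = kind,
                                      annotation_margin_range = c(4, 4)),
                       seed = seed))
      expect_equal(p$label, 1L)
      # every true pixel is annotated, and the annotation is strictly larger
      expect_true(all(p$true_mask <= p$annotation))
      expect_gt(sum(p$annotation), sum(p$true_mask))
      # and some annotated pixels are healthy tissue
      expect_gt(sum(p$annotation == 1 & p$true_mask == 0), 0)
    }
  }
})

test_that("a regular mass matches the brute-force point-in-disc raster", {
  spec <- synthetic_spec(lesion_kind = "mass",
                         mass_radius_range = c(8, 8),
                         mass_boundary_irregularity = 0,
                         annotation_margin_range = c(4, 4))
  p <- generate_patch(spec, seed = 3)
  expect_gte(sum(p$true_mask), pi * 7.5^2)
  expect_lte(sum(p$true_mask), pi * 8.5^2)
  # recover the center from the mask and compare against the loop oracle
  pos <- which(p$true_mask == 1, arr.ind = TRUE)
  center <- colMeans(pos)
  expect_equal(sum(p$true_mask),
               oracle_disc_count(spec$patch_size, center, 8),
               tolerance = 0.02)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- synthetic_spec(lesion_kind = "mass")
  a <- generate_patch(spec, seed = 1)
  b <- generate_patch(spec, seed = 1)
  expect_identical(a, b)
  imgs <- lapply(1:10, function(s) generate_patch(spec, seed = s)$image)
  hashes <- vapply(imgs, function(m) paste(c(range(m), sum(m)), collapse = ","), "")
  expect_gt(length(unique(hashes)), 1)
})

test_that("lesions are brighter than background by about the contrast", {
  spec <- synthetic_spec(lesion_kind = "mass", contrast = 0.5,
                         noise_sigma = 0.1)   # sigma below contrast / 4
  diffs <- vapply(1:8, function(s) {
    p <- generate_patch(spec, seed = s)
    mean(p$image[p$true_mask == 1]) - mean(p$image[p$true_mask == 0])
  }, 0)
  expect_true(all(diffs >= 0.25))
})

test_that("datasets have the requested composition and are reproducible", {
  tab <- list(list(spec = synthetic_spec(lesion_kind = "none"), count = 30),
              list(spec = synthetic_spec(lesion_kind = "mass"), count = 10))
  ds1 <- suppressWarnings(generate_dataset(tab, seed = 5))
  ds2 <- suppressWarnings(generate_dataset(tab, seed = 5))
  m1 <- attr(ds1, "manifest")
  expect_length(ds1, 40)
  expect_equal(sum(m1$label), 10)
  expect_identical(m1, attr(ds2, "manifest"))
  expect_identical(ds1[[35]]$image, ds2[[35]]$image)
  expect_error(generate_dataset(list(), seed = 1))
  expect_error(generate_dataset(
    list(list(spec = synthetic_spec(), count = 0)), seed = 1))
})

test_that("mean annotation / true-mask area ratio exceeds one", {
  tab <- list(list(spec = synthetic_spec(lesion_kind = "mass",
                                         annotation_margin_range = c(6, 12)),
                   count = 20))
  ds <- suppressWarnings(generate_dataset(tab, seed = 9))
  ratios <- vapply(ds, function(p) sum(p$annotation) / sum(p$true_mask), 0)
  expect_gt(mean(ratios), 1)
})

test_that("dataset round-trips through PNG files and a CSV manifest", {
  dir <- withr::local_tempdir()
  tab <- list(list(spec = synthetic_spec(lesion_kind = "mass"), count = 2),
              list(spec = synthetic_spec(lesion_kind = "none"), count = 2))
  ds <- suppressWarnings(generate_dataset(tab, seed = 11, dir = dir))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$image_path)))
  img <- png::readPNG(man$image_path[3])
  expect_equal(dim(img), dim(ds[[3]]$image))
  expect_lt(max(abs(img - ds[[3]]$image)), 1 / 255)
  ann <- png::readPNG(man$annotation_path[3])
  expect_identical(ann > 0.5, ds[[3]]$annotation == 1)
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_spec(annotation_margin_range = c(0, 4)))
  expect_error(synthetic_spec(mass_radius_range = c(8, 4)))
  expect_error(synthetic_spec(contrast = 1.5))
})

test_that("an oversized margin clips the annotation with a warning", {
  spec <- synthetic_spec(lesion_kind = "mass",
                         mass_radius_range = c(18, 18),
                         annotation_margin_range = c(20, 20))
  expect_warning(p <- generate_patch(spec, seed = 2), "clipped")
  expect_equal(dim(p$annotation), c(64L, 64L))
})
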