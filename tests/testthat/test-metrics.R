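test_that("binarization thresholds with ties going positive", {
  expect_equal(as.numeric(binarize(c(0.49, 0.5, 0.51))), c(0, 1, 1))
  expect_equal(binarize(matrix(0, 2, 2)), matrix(0L, 2, 2))
  expect_equal(binarize(matrix(0.2, 2, 2), threshold = 0),
               matrix(1L, 2, 2))
})

test_that("IOP/IOA/IOU reproduce hand counts and empty-set conventions", {
  A <- matrix(0, 4, 4); A[1:2, 1:2] <- 1
  P <- matrix(0, 4, 4); P[1:2, 1] <- 1
  expect_equal(iop_ioa_iou(P, A),
               c(iop = 1, ioa = 0.5, iou = 0.5))
  expect_equal(iop_ioa_iou(A, A), c(iop = 1, ioa = 1, iou = 1))
  D <- matrix(0, 4, 4); D[4, 4] <- 1
  expect_equal(iop_ioa_iou(D, A), c(iop = 0, ioa = 0, iou = 0))
  z <- matrix(0, 4, 4)
  expect_equal(iop_ioa_iou(z, z), c(iop = 1, ioa = 1, iou = 1))
  expect_equal(iop_ioa_iou(z, A), c(iop = 0, ioa = 0, iou = 0))
  expect_equal(iop_ioa_iou(A, z), c(iop = 0, ioa = 0, iou = 0))
  expect_error(iop_ioa_iou(matrix(0, 2, 2), z), "shape")
})

test_that("intersection metrics satisfy their structural identities", {
  set.seed(21)
  for (i in 1:100) {
    P <- random_mask(8, runif(1, 0.1, 0.9))
    A <- random_mask(8, runif(1, 0.1, 0.9))
    m <- iop_ioa_iou(P, A)
    o <- oracle_iou3(P, A)
    expect_equal(m, o, tolerance = 1e-9)
    expect_lte(m[["iou"]], min(m[["iop"]], m[["ioa"]]) + 1e-12)
    # subset implications
    if (all(P <= A)) expect_equal(m[["iop"]], if (sum(P)) 1 else m[["iop"]])
    if (all(A <= P)) expect_equal(m[["ioa"]], if (sum(A)) 1 else m[["ioa"]])
    # harmonic identity whenever the intersection is nonempty
    if (sum(P & A) > 0) {
      expect_equal(m[["iou"]],
                   1 / (1 / m[["iop"]] + 1 / m[["ioa"]] - 1),
                   tolerance = 1e-9)
    }
  }
})

test_that("confused pixels count the inclusive probability band", {
  expect_equal(confused_pixels(c(0.1, 0.31, 0.5, 0.69, 0.71), 0.2), 3)
  expect_equal(confused_pixels(c(0.3, 0.7), 0.2), 2)   # inclusive ends
  expect_equal(confused_pixels(matrix(c(0, 1, 1, 0), 2, 2)), 0)
  expect_equal(confused_pixels(matrix(0.5, 3, 3)), 9)
  set.seed(22)
  for (i in 1:50) {
    M <- random_prob(8)
    expect_equal(confused_pixels(M, 0.2), oracle_confused(M, 0.2))
    # monotone non-increasing as the band shrinks
    expect_lte(confused_pixels(M, 0.1), confused_pixels(M, 0.2))
  }
  expect_error(confused_pixels(matrix(0.5, 2, 2), 0.6))
})

test_that("detection AP reproduces single-case PR curves", {
  A <- matrix(0, 8, 8); A[2:5, 2:5] <- 1
  # exact predictions with full confidence give AP 1 at every threshold
  anns <- list(A, matrix(0, 8, 8), A)
  preds <- list(A, matrix(0, 8, 8), A)
  for (th in c(0.3, 0.5, 0.7)) {
    expect_equal(ap_at_iou(preds, c(1, 1, 1), anns, th), 1)
  }
  # one positive patch with IOU 0.4 against its annotation
  P <- matrix(0, 8, 8); P[2:5, 1:3] <- 1   # intersection 8, union 20
  expect_equal(iop_ioa_iou(P, A)[["iou"]], 0.4)
  expect_equal(ap_at_iou(list(P), 0.9, list(A), 0.3), 1)
  expect_equal(ap_at_iou(list(P), 0.9, list(A), 0.5), 0)
  expect_error(ap_at_iou(list(P), 0.9, list(matrix(0, 8, 8)), 0.5),
               "positive")
})

test_that("detection AP matches the exhaustive cut-point oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 12
    anns <- lapply(1:n, function(i) {
      if (i <= 8) random_mask(8, 0.4) else matrix(0, 8, 8)
    })
    preds <- lapply(1:n, function(i) random_mask(8, runif(1, 0, 0.6)))
    conf <- runif(n)
    th <- sample(c(0.1, 0.3, 0.5), 1)
    pos <- vapply(anns, function(a) sum(a) > 0, TRUE)
    det <- which(vapply(preds, function(p) sum(p) > 0, TRUE))
    got <- ap_at_iou(preds, conf, anns, th)
    if (length(det) == 0) {
      expect_equal(got, 0)
    } else {
      is_tp <- vapply(det, function(i) {
        pos[i] && oracle_iou3(preds[[i]], anns[[i]])[["iou"]] >= th
      }, TRUE)
      expect_equal(got,
                   oracle_det_ap(conf[det], is_tp, sum(pos), det),
                   tolerance = 1e-9)
    }
  }
})

test_that("classification metrics match oracles and a reference package", {
  # perfectly separated scores
  perfect <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(perfect), rep(1, 5))
  expect_error(classification_metrics(c(0.1, 0.9), c(1, 1)), "classes")
  set.seed(24)
  for (i in 1:20) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- runif(n) * 0.5 + labels * runif(n, 0, 0.5)
    m <- classification_metrics(scores, labels)
    expect_equal(m[["roc_auc"]], oracle_auc(scores, labels),
                 tolerance = 1e-9)
    expect_equal(m[["ap"]], oracle_ap(scores, labels), tolerance = 1e-9)
  }
  # randomly shuffled labels give chance-level AUC
  set.seed(25)
  labels <- rep(c(0, 1), 500)
  scores <- runif(1000)
  expect_lt(abs(classification_metrics(scores, labels)[["roc_auc"]] - 0.5),
            0.05)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(26)
    labels <- rbinom(60, 1, 0.5)
    scores <- runif(60) + labels * 0.3
    auc_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<")))
    expect_equal(classification_metrics(scores, labels)[["roc_auc"]],
                 auc_ref, tolerance = 1e-9)
  }
})
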