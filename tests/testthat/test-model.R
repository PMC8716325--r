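tiny_cfg <- function(...) {
  seg_model_config(input_size = 32, stem_channels = 4,
                   encoder_stages = list(c(1, 6), c(1, 8), c(1, 12)), ...)
}

test_that("configuration arithmetic is validated at build time", {
  cfg <- seg_model_config(input_size = 64)
  expect_equal(cfg$deepest_grid, 4L)
  expect_equal(cfg$decoder_blocks, 4L)
  # scan-scale shape law: 256 px and an 8x8 deepest grid force 5 blocks
  big <- seg_model_config(input_size = 256, stem_channels = 8,
                          encoder_stages = list(c(1, 8), c(1, 8), c(1, 8),
                                                c(1, 8), c(1, 8)),
                          deepest_grid = 8, decoder_blocks = 5)
  expect_equal(big$decoder_blocks, 5L)
  expect_error(seg_model_config(input_size = 256, deepest_grid = 8,
                                encoder_stages = list(c(1, 8), c(1, 8),
                                                      c(1, 8), c(1, 8),
                                                      c(1, 8)),
                                decoder_blocks = 4),
               "configuration error")
  expect_error(seg_model_config(input_size = 100), "configuration error")
})

test_that("the segmentation output matches the input resolution", {
  for (sz in c(32, 64)) {
    cfg <- if (sz == 32) tiny_cfg() else seg_model_config()
    model <- build_model(cfg, seed = 1)
    x <- array(runif(sz * sz * 2), c(sz, sz, 1, 2))
    out <- latentcadx:::forward_pass(model, x)
    expect_equal(dim(out$M), c(sz, sz, 1, 2))
    expect_true(all(out$M > 0 & out$M < 1))
    expect_true(all(out$y > 0 & out$y < 1))
    expect_equal(dim(out$rpn),
                 c(cfg$deepest_grid, cfg$deepest_grid, 2, 2))
    # per-cell softmax pairs sum to one
    expect_equal(out$rpn[, , 1, ] + out$rpn[, , 2, ],
                 array(1, c(cfg$deepest_grid, cfg$deepest_grid, 2)))
  }
})

test_that("heads are independent: detaching the RPN changes nothing else", {
  model <- build_model(tiny_cfg(), seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  full <- latentcadx:::forward_pass(model, x)
  no_rpn <- latentcadx:::forward_pass(model, x,
                                      heads = c("classify", "segment"))
  expect_identical(full$y, no_rpn$y)
  expect_identical(full$M, no_rpn$M)
  expect_null(no_rpn$rpn)
})

test_that("the skip-free ablation architecture builds and runs", {
  cfg <- tiny_cfg(skip_connections = FALSE)
  model <- build_model(cfg, seed = 3)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  out <- latentcadx:::forward_pass(model, x)
  expect_equal(dim(out$M), c(32, 32, 1, 1))
})

test_that("model builds are seed-reproducible", {
  a <- build_model(tiny_cfg(), seed = 9)
  b <- build_model(tiny_cfg(), seed = 9)
  expect_identical(a$params, b$params)
})

test_that("weight transfer copies the encoder and leaves the decoder fresh", {
  cfg <- tiny_cfg()
  pre_cfg <- tiny_cfg(heads = c("classify", "rpn"))
  source <- build_model(pre_cfg, seed = 4)
  target <- build_model(cfg, seed = 5)
  fresh_decoder <- target$params$decoder
  target2 <- transfer_weights(source, target)
  expect_identical(target2$params$encoder, source$params$encoder)
  expect_identical(target2$params$decoder, fresh_decoder)
  rep <- attr(target2, "transfer_report")
  expect_equal(rep$status[rep$group == "encoder"], "copied")
  expect_equal(rep$status[rep$group == "decoder"], "fresh")
  # identical input -> identical classification output after transfer
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  ys <- latentcadx:::forward_pass(source, x, heads = "classify",
                                  train_groups = "encoder")$y
  yt <- latentcadx:::forward_pass(target2, x, heads = "classify",
                                  train_groups = "encoder")$y
  expect_equal(ys, yt, tolerance = 1e-12)
  # mismatched widths are refused with the offending group named
  other <- build_model(seg_model_config(
    input_size = 32, stem_channels = 5,
    encoder_stages = list(c(1, 6), c(1, 8), c(1, 12))), seed = 6)
  expect_error(transfer_weights(other, target), "encoder")
})

test_that("RPN targets equal the brute-force per-cell fraction count", {
  expect_equal(rpn_targets(matrix(0, 64, 64), 4), matrix(0L, 4, 4))
  one_cell <- matrix(0, 64, 64)
  one_cell[17:32, 33:48] <- 1
  expect_equal(sum(rpn_targets(one_cell, 4)), 1)
  expect_equal(rpn_targets(one_cell, 4)[2, 3], 1L)
  set.seed(101)
  for (i in 1:20) {
    ann <- random_mask(64, p = runif(1, 0.02, 0.5))
    expect_identical(rpn_targets(ann, 4), oracle_rpn_targets(ann, 4))
    expect_identical(rpn_targets(ann, 8, 0.25),
                     oracle_rpn_targets(ann, 8, 0.25))
  }
  expect_error(rpn_targets(matrix(0, 63, 63), 4), "divisible")
})

test_that("backpropagation matches finite differences through the graph", {
  ns <- asNamespace("latentcadx")
  cfg <- seg_model_config(input_size = 16, stem_channels = 3,
                          encoder_stages = list(c(1, 4), c(1, 6)))
  model <- build_model(cfg, seed = 1)
  set.seed(7)
  n <- 2
  x <- array(runif(16 * 16 * n), c(16, 16, 1, n))
  ann <- array(0, c(16, 16, 1, n)); ann[4:9, 4:9, 1, 1] <- 1
  labels <- c(1, 0)
  w <- loss_weights(2, 1, 0.5)
  lossfun <- function(m) {
    fw <- ns$forward_pass(m, x, want_cache = TRUE,
                          train_groups = c("encoder", "decoder"))
    obj <- ns$batch_objective(fw, labels, ann, w)
    list(total = obj$total, grads = obj$grads, fw = fw)
  }
  res <- lossfun(model)
  grads <- ns$backward_pass(model, res$fw, res$grads)
  eps <- 1e-5
  paths <- list(c("encoder", "stem", "W"),
                c("encoder", "stage1", "block1", "conv1", "gamma"),
                c("encoder", "stage2", "down", "W"),
                c("classify_head", "W"),
                c("decoder", "block1", "up", "W"),
                c("decoder", "block2", "conv", "beta"),
                c("decoder", "final", "b"))
  for (lp in paths) {
    arr <- model$params[[lp]]
    i <- 1L
    m1 <- model; m1$params[[lp]][i] <- arr[i] + eps
    m2 <- model; m2$params[[lp]][i] <- arr[i] - eps
    fd <- (lossfun(m1)$total - lossfun(m2)$total) / (2 * eps)
    expect_equal(unname(grads[[lp]][i]), fd, tolerance = 1e-4)
  }
})
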