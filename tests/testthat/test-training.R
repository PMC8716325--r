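tiny_data <- function(n_pos = 6, seed = 5) {
  suppressWarnings(synthetic_cohort(n_pos, neg_ratio = 1, seed = seed,
                                    patch_size = 32,
                                    mass_radius_range = c(5, 9),
                                    annotation_margin_range = c(2, 4)))
}

tiny_model_cfg <- function(...) {
  seg_model_config(input_size = 32, stem_channels = 4,
                   encoder_stages = list(c(1, 6), c(1, 8), c(1, 12)), ...)
}

tiny_sched <- function(...) {
  args <- utils::modifyList(list(batch_size = 8, lr_initial = 0.05,
                                 val_fraction = 0.25, seed = 3),
                            list(...))
  do.call(schedule_config, args)
}

test_that("the learning rate halves on schedule", {
  expect_equal(lr_at_epoch(1:10, 0.001, 10), rep(0.001, 10))
  expect_equal(lr_at_epoch(11, 0.001, 10), 0.0005)
  expect_equal(lr_at_epoch(21, 0.001, 10), 0.00025)
  expect_equal(lr_at_epoch(20, 0.001, 10), 0.0005)
})

test_that("pretraining logs the schedule and is seed-deterministic", {
  ds <- tiny_data()
  sched <- tiny_sched(pretrain_epochs = 2)
  out <- pretrain_rpn(ds, tiny_model_cfg(), sched)
  expect_equal(nrow(out$log), 2)
  expect_equal(out$log$lr, rep(0.05, 2))   # halving period not reached
  expect_true(all(is.finite(out$log$val_total)))
  out2 <- pretrain_rpn(ds, tiny_model_cfg(), sched)
  expect_equal(out$log$train_total, out2$log$train_total,
               tolerance = 1e-6)
  expect_identical(out$model$params, out2$model$params)
  neg_only <- Filter(function(p) p$label == 0, ds)
  expect_error(pretrain_rpn(neg_only, tiny_model_cfg(), sched),
               "positive")
})

test_that("warm-up locks every transferred weight bit-for-bit", {
  ds <- tiny_data()
  sched <- tiny_sched(pretrain_epochs = 2, warmup_epochs = 3,
                      max_epochs = 3, mode = "latentcadx")
  pre <- pretrain_rpn(ds, tiny_model_cfg(), sched)
  fit <- latentcadx(ds, tiny_model_cfg(), sched, pretrained = pre)
  dig <- latentcadx:::params_digest
  expect_identical(dig(fit$model$params$encoder),
                   dig(pre$model$params$encoder))
  expect_identical(dig(fit$model$params$classify_head),
                   dig(pre$model$params$classify_head))
  # batch-norm running statistics of the frozen encoder are untouched too
  pre_bn <- latentcadx:::bn_snapshot(pre$model)
  fit_bn <- latentcadx:::bn_snapshot(fit$model)
  enc_keys <- grep("^enc/", names(pre_bn), value = TRUE)
  expect_identical(fit_bn[enc_keys], pre_bn[enc_keys])
  # but the decoder did train
  expect_false(identical(dig(fit$model$params$decoder),
                         dig(latentcadx:::build_model(tiny_model_cfg(),
                                                      seed = sched$seed + 7L)$params$decoder)))
  expect_true(all(fit$logs$train$phase == "warmup"))
  expect_equal(fit$logs$train$cross_ent, rep(0, 3))  # no classification term
})

test_that("joint fine-tuning switches weights and unfreezes the encoder", {
  ds <- tiny_data()
  sched <- tiny_sched(pretrain_epochs = 1, warmup_epochs = 1,
                      max_epochs = 3, mode = "latentcadx")
  fit <- latentcadx(ds, tiny_model_cfg(), sched)
  tl <- fit$logs$train
  expect_equal(tl$phase, c("warmup", "joint", "joint"))
  expect_equal(tl$cross_ent[1], 0)
  expect_gt(tl$cross_ent[2], 0)   # classification active under alpha = 2
  expect_equal(fit$sched$full_weights,
               loss_weights(alpha = 2, beta = 1, gamma = 0.5))
  expect_equal(fit$sched$warmup_weights$beta, 1)
  expect_equal(fit$sched$warmup_weights$gamma, 1)
})

test_that("a plateaued validation loss terminates the run early", {
  # a vanishing learning rate on a constant dataset drives consecutive
  # validation losses together until the stop fires at the tolerance
  p <- suppressWarnings(generate_patch(
    synthetic_spec(patch_size = 32, mass_radius_range = c(5, 9),
                   annotation_margin_range = c(2, 4)), seed = 3))
  ds <- rep(list(p), 12)
  sched <- tiny_sched(pretrain_epochs = 1, warmup_epochs = 0,
                      max_epochs = 80, batch_size = 4,
                      lr_initial = 1e-9, early_stop_tol = 1e-6,
                      mode = "latentcadx")
  fit <- latentcadx(ds, tiny_model_cfg(), sched)
  tl <- fit$logs$train
  expect_lt(nrow(tl), 80)
  expect_lt(abs(diff(utils::tail(tl$val_total, 2))), 1e-6)
})

test_that("the ablation trains from scratch without transfer or freezing", {
  ds <- tiny_data()
  sched <- tiny_sched(pretrain_epochs = 1, warmup_epochs = 0,
                      max_epochs = 2, mode = "from_scratch_alpha")
  fit <- latentcadx(ds, tiny_model_cfg(), sched)
  expect_null(fit$transfer_report)
  expect_null(fit$logs$pretrain)
  expect_equal(unique(fit$logs$train$phase), "from_scratch_alpha")
  sched_b <- tiny_sched(pretrain_epochs = 1, warmup_epochs = 0,
                        max_epochs = 2, mode = "plain_mse_baseline")
  fit_b <- latentcadx(ds, tiny_model_cfg(), sched_b)
  # the baseline's segmentation term is undivided MSE: inb/oob not logged
  expect_equal(fit_b$logs$train$l_inb, rep(0, 2))
  expect_gt(fit_b$logs$train$train_total[1], 0)
  # reproducibility
  fit_b2 <- latentcadx(ds, tiny_model_cfg(), sched_b)
  expect_equal(fit_b$logs$train$train_total,
               fit_b2$logs$train$train_total, tolerance = 1e-6)
})

test_that("training reduces the training loss on the shipped fixture", {
  ds <- tiny_data(n_pos = 8, seed = 12)
  sched <- tiny_sched(pretrain_epochs = 3, warmup_epochs = 1,
                      max_epochs = 6, lr_initial = 0.1,
                      mode = "latentcadx")
  fit <- latentcadx(ds, tiny_model_cfg(), sched)
  tl <- fit$logs$train
  joint <- tl[tl$phase == "joint", ]
  expect_lt(joint$train_total[nrow(joint)], joint$train_total[1])
})

test_that("predict and the S3 surface work on a fitted model", {
  ds <- tiny_data()
  sched <- tiny_sched(pretrain_epochs = 1, warmup_epochs = 1,
                      max_epochs = 2, mode = "latentcadx")
  fit <- latentcadx(ds, tiny_model_cfg(), sched)
  pr <- predict(fit, ds[1:3])
  expect_length(pr$y, 3)
  expect_equal(dim(pr$M), c(32, 32, 3))
  expect_true(all(pr$M >= 0 & pr$M <= 1))
  expect_output(print(fit), "latentcadx fit")
  expect_output(summary(fit), "weight transfer")
  expect_type(coef(fit), "list")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, ds[[which(vapply(ds, `[[`, 0L, "label") == 1)[1]]]))
})
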