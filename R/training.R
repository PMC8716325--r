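#' Training schedule configuration
#'
#' Captures the procedural training recipe: region-proposal pretraining of
#' the encoder, weight transfer, a frozen-encoder decoder warm-up, then
#' joint fine-tuning under the weighted objective. Defaults are the
#' scan-scale values (50 pretraining epochs, 15 warm-up epochs, 100 max
#' epochs, SGD at 0.001 halved every 10 epochs, batch 32, early stop when
#' the validation loss changes by less than 1e-6); desk-scale runs pass
#' smaller values.
#'
#' @param pretrain_epochs Epochs of RPN/classification pretraining.
#' @param warmup_epochs Epochs with the transferred weights locked and only
#'   the decoder training.
#' @param max_epochs Total epoch budget for the staged run.
#' @param lr_initial Initial SGD learning rate.
#' @param lr_halving_period Epochs between halvings of the learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Images per batch.
#' @param early_stop_tol Validation-loss plateau tolerance.
#' @param patience Consecutive plateau epochs required to stop.
#' @param warmup_weights [loss_weights()] for the warm-up phase (in/out of
#'   bounds both 1, no classification term).
#' @param full_weights [loss_weights()] for joint fine-tuning.
#' @param mode `"latentcadx"` (staged, transferred), `"from_scratch_alpha"`
#'   (identical architecture, random init, unweighted objective) or
#'   `"plain_mse_baseline"` (undivided full-image MSE against the
#'   annotation plus classification).
#' @param val_fraction Fraction held out for validation, stratified by
#'   label.
#' @param seed Integer seed controlling splits, shuffling and
#'   initialization.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(pretrain_epochs = 50,
                            warmup_epochs = 15,
                            max_epochs = 100,
                            lr_initial = 0.001,
                            lr_halving_period = 10,
                            momentum = 0.9,
                            batch_size = 32,
                            early_stop_tol = 1e-6,
                            patience = 1,
                            warmup_weights = latentcadx::warmup_weights(),
                            full_weights = loss_weights(),
                            mode = c("latentcadx", "from_scratch_alpha",
                                     "plain_mse_baseline"),
                            val_fraction = 0.2,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(warmup_epochs <= max_epochs, lr_initial > 0, batch_size >= 1,
            pretrain_epochs >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 max_epochs = as.integer(max_epochs),
                 lr_initial = lr_initial,
                 lr_halving_period = as.integer(lr_halving_period),
                 momentum = momentum,
                 batch_size = as.integer(batch_size),
                 early_stop_tol = early_stop_tol,
                 patience = as.integer(patience),
                 warmup_weights = warmup_weights,
                 full_weights = full_weights,
                 mode = mode,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "schedule_config")
}

#' Learning rate at a given epoch
#'
#' Step-wise halving: `lr_initial * 0.5 ^ floor((epoch - 1) / period)`.
#'
#' @param epoch 1-based epoch index.
#' @param lr_initial Initial rate.
#' @param period Halving period in epochs.
#' @export
lr_at_epoch <- function(epoch, lr_initial = 0.001, period = 10) {
  lr_initial * 0.5^((epoch - 1) %/% period)
}

# Stack a list of tissue patches into training tensors.
stack_patches <- function(patches) {
  n <- length(patches)
  sz <- nrow(patches[[1]]$image)
  x <- array(0, c(sz, sz, 1, n))
  ann <- array(0, c(sz, sz, 1, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    x[, , 1, i] <- patches[[i]]$image
    ann[, , 1, i] <- patches[[i]]$annotation
    labels[i] <- patches[[i]]$label
  }
  list(x = x, ann = ann, labels = labels, n = n, size = sz)
}

slice_batch <- function(tensors, idx) {
  list(x = tensors$x[, , , idx, drop = FALSE],
       ann = tensors$ann[, , , idx, drop = FALSE],
       labels = tensors$labels[idx],
       n = length(idx))
}

# Stratified validation split; returns list(train_idx, val_idx).
stratified_split <- function(labels, fraction, seed) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  val <- integer(0)
  for (lab in unique(labels)) {
    grp <- which(labels == lab)
    k <- max(1L, round(fraction * length(grp)))
    val <- c(val, sample(grp, k))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), val = val)
}

# RPN objective over a batch: per-cell 2-way softmax cross-entropy against
# rpn_targets, averaged over cells and batch. Returns loss and logit grads.
rpn_objective <- function(out, targets) {
  probs <- out$rpn
  g <- dim(probs)[1]
  n <- dim(probs)[4]
  p2 <- probs[, , 2, , drop = FALSE]
  p2 <- pmin(pmax(p2, PROB_EPS), 1 - PROB_EPS)
  t_ <- targets
  loss <- -mean(t_ * log(p2) + (1 - t_) * log(1 - p2))
  grl <- zero_arr(probs)
  denom <- g * g * n
  grl[, , 2, ] <- (probs[, , 2, , drop = FALSE] - t_) / denom
  grl[, , 1, ] <- -grl[, , 2, , drop = FALSE]
  list(loss = loss, grpn_logits = grl)
}

# One optimization epoch. Returns the model, velocity and mean losses.
run_epoch <- function(model, velocity, tensors, idx, sched, w, heads,
                      groups, frozen, lr, plain_mse = FALSE,
                      rpn_targets_arr = NULL, epoch_rng_seed = 0L) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(epoch_rng_seed)
  idx <- idx[sample.int(length(idx))]
  batches <- split(idx, ceiling(seq_along(idx) / sched$batch_size))
  acc <- c(cross_ent = 0, l_inb = 0, l_oob = 0, total = 0)
  for (b in batches) {
    bt <- slice_batch(tensors, b)
    fw <- forward_pass(model, bt$x, heads = heads, want_cache = TRUE,
                       train_groups = intersect(groups,
                                                c("encoder", "decoder")))
    obj <- batch_objective(fw, bt$labels, bt$ann, w, plain_mse = plain_mse)
    g <- obj$grads
    total <- obj$total
    if (!is.null(rpn_targets_arr) && "rpn" %in% heads) {
      ro <- rpn_objective(fw, rpn_targets_arr[, , , b, drop = FALSE])
      g$grpn_logits <- ro$grpn_logits
      total <- total + ro$loss
    }
    grads <- backward_pass(model, fw, g, groups = groups)
    step <- sgd_step(model$params, grads, velocity, lr,
                     momentum = sched$momentum, frozen = frozen)
    model$params <- step$params
    velocity <- step$velocity
    wgt <- length(b) / length(idx)
    acc <- acc + wgt * c(obj$cross_ent, obj$l_inb, obj$l_oob, total)
  }
  list(model = model, velocity = velocity, losses = acc)
}

# Mean losses over a held-out set (no gradients).
eval_loss <- function(model, tensors, idx, sched, w, heads,
                      plain_mse = FALSE, rpn_targets_arr = NULL) {
  batches <- split(idx, ceiling(seq_along(idx) / sched$batch_size))
  total <- 0
  ys <- numeric(0)
  for (b in batches) {
    bt <- slice_batch(tensors, b)
    fw <- forward_pass(model, bt$x, heads = heads, want_cache = FALSE)
    obj <- batch_objective(fw, bt$labels, bt$ann, w, plain_mse = plain_mse,
                           with_grads = FALSE)
    tot <- obj$total
    if (!is.null(rpn_targets_arr) && "rpn" %in% heads) {
      tot <- tot + rpn_objective(fw, rpn_targets_arr[, , , b,
                                                     drop = FALSE])$loss
    }
    total <- total + tot * length(b) / length(idx)
    if (!is.null(fw$y)) ys <- c(ys, fw$y)
  }
  list(total = total, y = ys)
}

#' Pretrain the encoder under classification and region-proposal objectives
#'
#' Trains a classification + RPN model (no decoder) whose encoder is later
#' transferred into the full model. The objective is the patch
#' cross-entropy plus the per-cell RPN cross-entropy against
#' [rpn_targets()]. Logs per-epoch learning rate, train/validation loss and
#' validation classification AP / ROC-AUC.
#'
#' @param dataset A `patch_dataset` (or list of `tissue_patch`) with at
#'   least one positive patch.
#' @param model_cfg A [seg_model_config()].
#' @param sched A [schedule_config()].
#' @return A list with `model` (the pretrained `seg_model`) and `log`
#'   (per-epoch data frame).
#' @export
pretrain_rpn <- function(dataset, model_cfg, sched = schedule_config()) {
  tensors <- stack_patches(dataset)
  if (sum(tensors$labels) == 0) {
    stop("pretraining needs positive patches (AP undefined without them)")
  }
  cfg <- model_cfg
  cfg$heads <- c("classify", "rpn")
  model <- build_model(cfg, seed = sched$seed)
  g <- cfg$deepest_grid
  rpn_t <- array(0, c(g, g, 1, tensors$n))
  for (i in seq_len(tensors$n)) {
    rpn_t[, , 1, i] <- rpn_targets(tensors$ann[, , 1, i], g,
                                   cfg$rpn_positive_fraction)
  }
  split <- stratified_split(tensors$labels, sched$val_fraction,
                            sched$seed + 1L)
  velocity <- zero_like(model$params)
  w <- loss_weights(alpha = 1, beta = 0, gamma = 0)
  heads <- c("classify", "rpn")
  log <- NULL
  prev_val <- NA
  plateau <- 0L
  for (epoch in seq_len(sched$pretrain_epochs)) {
    lr <- lr_at_epoch(epoch, sched$lr_initial, sched$lr_halving_period)
    res <- run_epoch(model, velocity, tensors, split$train, sched, w,
                     heads, groups = names(model$params),
                     frozen = character(), lr = lr,
                     rpn_targets_arr = rpn_t,
                     epoch_rng_seed = sched$seed + 1000L + epoch)
    model <- res$model
    velocity <- res$velocity
    val <- eval_loss(model, tensors, split$val, sched, w, heads,
                     rpn_targets_arr = rpn_t)
    vl <- tensors$labels[split$val]
    cm <- if (length(unique(vl)) == 2 && !anyNA(val$y)) {
      classification_metrics(val$y, vl)
    } else c(ap = NA_real_, roc_auc = NA_real_)
    log <- rbind(log, data.frame(epoch = epoch, phase = "pretrain",
                                 lr = lr,
                                 train_total = res$losses["total"],
                                 val_total = val$total,
                                 val_ap = unname(cm["ap"]),
                                 val_roc_auc = unname(cm["roc_auc"]),
                                 row.names = NULL))
    if (!is.na(prev_val) &&
        abs(val$total - prev_val) < sched$early_stop_tol) {
      plateau <- plateau + 1L
      if (plateau >= sched$patience) break
    } else {
      plateau <- 0L
    }
    prev_val <- val$total
  }
  list(model = model, log = log)
}

# Staged training of the full model from a pretrained encoder.
train_staged <- function(dataset, pretrained, model_cfg, sched) {
  if (is.null(pretrained)) {
    stop("mode 'latentcadx' requires a pretrained model for weight transfer")
  }
  tensors <- stack_patches(dataset)
  model <- build_model(model_cfg, seed = sched$seed + 7L)
  model <- transfer_weights(pretrained$model, model)
  transfer_report <- attr(model, "transfer_report")
  split <- stratified_split(tensors$labels, sched$val_fraction,
                            sched$seed + 1L)
  velocity <- zero_like(model$params)
  log <- NULL
  prev_val <- NA
  plateau <- 0L
  best <- list(val = Inf, params = model$params, bn = bn_snapshot(model))
  phase_boundary_params <- NULL
  for (epoch in seq_len(sched$max_epochs)) {
    warm <- epoch <= sched$warmup_epochs
    phase <- if (warm) "warmup" else "joint"
    w <- if (warm) sched$warmup_weights else sched$full_weights
    heads <- if (warm) "segment" else c("classify", "segment")
    groups <- if (warm) "decoder" else
      setdiff(names(model$params), "rpn_head")
    frozen <- if (warm) setdiff(names(model$params), "decoder") else
      "rpn_head"
    lr <- lr_at_epoch(epoch, sched$lr_initial, sched$lr_halving_period)
    res <- run_epoch(model, velocity, tensors, split$train, sched, w,
                     heads, groups = groups, frozen = frozen, lr = lr,
                     epoch_rng_seed = sched$seed + 2000L + epoch)
    model <- res$model
    velocity <- res$velocity
    val <- eval_loss(model, tensors, split$val, sched, w, heads)
    log <- rbind(log, data.frame(epoch = epoch, phase = phase, lr = lr,
                                 cross_ent = res$losses["cross_ent"],
                                 l_inb = res$losses["l_inb"],
                                 l_oob = res$losses["l_oob"],
                                 train_total = res$losses["total"],
                                 val_total = val$total,
                                 row.names = NULL))
    if (epoch == sched$warmup_epochs) {
      phase_boundary_params <- model$params
    }
    if (!warm) {
      if (val$total < best$val) {
        best <- list(val = val$total, params = model$params,
                     bn = bn_snapshot(model))
      }
      if (!is.na(prev_val) &&
          abs(val$total - prev_val) < sched$early_stop_tol) {
        plateau <- plateau + 1L
        if (plateau >= sched$patience) break
      } else {
        plateau <- 0L
      }
      prev_val <- val$total
    }
  }
  if (is.finite(best$val)) {
    model$params <- best$params
    model <- bn_restore(model, best$bn)
  }
  list(model = model, log = log, transfer_report = transfer_report,
       split = split, phase_boundary_params = phase_boundary_params)
}

#' Train the from-scratch ablation or plain-MSE baseline
#'
#' `from_scratch_alpha`: the identical architecture trained from random
#' initialization under the unweighted objective (alpha = beta = gamma = 1),
#' with no weight transfer and no freezing. `plain_mse_baseline`: same, but
#' the segmentation term is the undivided full-image mean squared error
#' against the annotation (no in/out-of-bounds decomposition).
#'
#' @inheritParams pretrain_rpn
#' @return A list with `model`, `log` and `split`.
#' @export
train_ablation <- function(dataset, model_cfg, sched) {
  stopifnot(sched$mode %in% c("from_scratch_alpha", "plain_mse_baseline"))
  plain <- sched$mode == "plain_mse_baseline"
  tensors <- stack_patches(dataset)
  cfg <- model_cfg
  cfg$heads <- c("classify", "segment")
  model <- build_model(cfg, seed = sched$seed + 7L)
  split <- stratified_split(tensors$labels, sched$val_fraction,
                            sched$seed + 1L)
  velocity <- zero_like(model$params)
  w <- loss_weights(alpha = 1, beta = 1, gamma = 1)
  heads <- c("classify", "segment")
  log <- NULL
  prev_val <- NA
  plateau <- 0L
  best <- list(val = Inf, params = model$params, bn = bn_snapshot(model))
  for (epoch in seq_len(sched$max_epochs)) {
    lr <- lr_at_epoch(epoch, sched$lr_initial, sched$lr_halving_period)
    res <- run_epoch(model, velocity, tensors, split$train, sched, w,
                     heads, groups = names(model$params),
                     frozen = character(), lr = lr, plain_mse = plain,
                     epoch_rng_seed = sched$seed + 2000L + epoch)
    model <- res$model
    velocity <- res$velocity
    val <- eval_loss(model, tensors, split$val, sched, w, heads,
                     plain_mse = plain)
    log <- rbind(log, data.frame(epoch = epoch, phase = sched$mode,
                                 lr = lr,
                                 cross_ent = res$losses["cross_ent"],
                                 l_inb = res$losses["l_inb"],
                                 l_oob = res$losses["l_oob"],
                                 train_total = res$losses["total"],
                                 val_total = val$total,
                                 row.names = NULL))
    if (val$total < best$val) {
      best <- list(val = val$total, params = model$params,
                   bn = bn_snapshot(model))
    }
    if (!is.na(prev_val) &&
        abs(val$total - prev_val) < sched$early_stop_tol) {
      plateau <- plateau + 1L
      if (plateau >= sched$patience) break
    } else {
      plateau <- 0L
    }
    prev_val <- val$total
  }
  model$params <- best$params
  model <- bn_restore(model, best$bn)
  list(model = model, log = log, split = split)
}

#' Fit the weakly-supervised joint classification-segmentation model
#'
#' The single front-end for model fitting. In the default `"latentcadx"`
#' mode it runs the full procedural recipe: (1) pretrain a classification +
#' region-proposal model, (2) transfer its encoder into the full
#' architecture, (3) train only the decoder for `warmup_epochs` with the
#' transferred weights locked and the unweighted in/out-of-bounds objective,
#' (4) unfreeze and fine-tune jointly under the weighted objective
#' (classification 2, in-bounds 1, out-of-bounds 0.5), discarding the RPN
#' output. Ablation modes skip pretraining and staging (see
#' [train_ablation()]).
#'
#' @param data A `patch_dataset` (see [generate_dataset()]) or list of
#'   `tissue_patch` objects.
#' @param model_cfg A [seg_model_config()].
#' @param sched A [schedule_config()]; its `mode` selects the recipe.
#' @param pretrained Optional result of [pretrain_rpn()] to reuse; when
#'   `NULL` in `"latentcadx"` mode, pretraining is run first.
#' @return An object of class `latentcadx` with the fitted `seg_model`,
#'   per-epoch logs, the transfer report and the validation split.
#' @examples
#' \donttest{
#' ds <- synthetic_cohort(8, neg_ratio = 1, seed = 1, patch_size = 32)
#' cfg <- seg_model_config(input_size = 32,
#'                         encoder_stages = list(c(1, 8), c(1, 12), c(1, 16)))
#' sched <- schedule_config(pretrain_epochs = 1, warmup_epochs = 1,
#'                          max_epochs = 2, batch_size = 8)
#' fit <- latentcadx(ds, cfg, sched)
#' }
#' @export
latentcadx <- function(data, model_cfg = seg_model_config(),
                       sched = schedule_config(), pretrained = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (sched$mode == "latentcadx") {
    if (is.null(pretrained)) {
      pretrained <- pretrain_rpn(data, model_cfg, sched)
    }
    res <- train_staged(data, pretrained, model_cfg, sched)
    logs <- list(pretrain = pretrained$log, train = res$log)
  } else {
    res <- train_ablation(data, model_cfg, sched)
    logs <- list(pretrain = NULL, train = res$log)
  }
  structure(list(model = res$model,
                 model_cfg = model_cfg,
                 sched = sched,
                 mode = sched$mode,
                 logs = logs,
                 transfer_report = res$transfer_report,
                 split = res$split,
                 phase_boundary_params = res$phase_boundary_params,
                 elapsed = proc.time()[["elapsed"]] - t0,
                 n_patches = length(data)),
            class = "latentcadx")
}
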