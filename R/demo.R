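#' One-command end-to-end demonstration on synthetic phantoms
#'
#' Generates a synthetic cohort with circumscribing annotations, trains both
#' the staged weakly-supervised model and the plain-MSE baseline on it, and
#' evaluates both on a held-out test cohort. The `"smoke"` budget finishes
#' in minutes on one CPU; `"full_desk"` is the desk-scale experiment
#' (300 train / 100 test patches, margins 4-10 px, at most 30 total
#' epochs).
#'
#' @param seed Integer seed driving data generation and both fits.
#' @param budget `"smoke"` or `"full_desk"`.
#' @param out_dir Optional directory for logs and the report (JSON when
#'   jsonlite is installed, CSV otherwise).
#' @param n_train,n_test,pretrain_epochs,warmup_epochs,max_epochs Optional
#'   overrides of the budget's scale (used to shrink further for quick
#'   checks).
#' @return List with elements `latentcadx` and `plain_mse_baseline`, each
#'   holding `fit` and `report`, plus `test_data` and `settings`.
#' @export
latentcadx_demo <- function(seed = 0L,
                            budget = c("smoke", "full_desk"),
                            out_dir = NULL,
                            n_train = NULL, n_test = NULL,
                            pretrain_epochs = NULL, warmup_epochs = NULL,
                            max_epochs = NULL) {
  budget <- match.arg(budget)
  s <- if (budget == "smoke") {
    list(n_train = 80, n_test = 40, pretrain = 3, warmup = 1, max = 5)
  } else {
    list(n_train = 300, n_test = 100, pretrain = 10, warmup = 3, max = 20)
  }
  if (!is.null(n_train)) s$n_train <- n_train
  if (!is.null(n_test)) s$n_test <- n_test
  if (!is.null(pretrain_epochs)) s$pretrain <- pretrain_epochs
  if (!is.null(warmup_epochs)) s$warmup <- warmup_epochs
  if (!is.null(max_epochs)) s$max <- max_epochs
  neg_ratio <- 3
  n_pos_train <- round(s$n_train / (1 + neg_ratio))
  n_pos_test <- round(s$n_test / (1 + neg_ratio))
  train <- synthetic_cohort(n_pos_train, neg_ratio = neg_ratio,
                            seed = seed + 1L)
  test <- synthetic_cohort(n_pos_test, neg_ratio = neg_ratio,
                           seed = seed + 2L)
  cfg <- seg_model_config()
  # desk-scale schedule: every stage length of the scan-scale recipe
  # (50 pretrain / 15 warm-up / 100 max, halving every 10) divided by 5,
  # and a learning rate of 0.1 -- the miniature normalized network has a
  # few hundred SGD steps to train in, against tens of thousands at scan
  # scale
  halving <- max(1L, round(s$max / 10))
  sched_l <- schedule_config(pretrain_epochs = s$pretrain,
                             warmup_epochs = s$warmup,
                             max_epochs = s$max,
                             batch_size = 32, lr_initial = 0.1,
                             lr_halving_period = halving,
                             mode = "latentcadx", seed = seed + 3L)
  sched_b <- schedule_config(pretrain_epochs = 1,
                             warmup_epochs = 0,
                             max_epochs = s$max,
                             batch_size = 32, lr_initial = 0.1,
                             lr_halving_period = halving,
                             mode = "plain_mse_baseline", seed = seed + 3L)
  fit_l <- latentcadx(train, cfg, sched_l)
  fit_b <- latentcadx(train, cfg, sched_b)
  rep_l <- evaluate(fit_l, test)
  rep_b <- evaluate(fit_b, test)
  out <- list(latentcadx = list(fit = fit_l, report = rep_l),
              plain_mse_baseline = list(fit = fit_b, report = rep_b),
              test_data = test,
              settings = c(s, seed = seed, neg_ratio = neg_ratio))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit_l$logs$train,
                     file.path(out_dir, "latentcadx_train_log.csv"),
                     row.names = FALSE)
    utils::write.csv(fit_b$logs$train,
                     file.path(out_dir, "baseline_train_log.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_l$per_patch,
                     file.path(out_dir, "latentcadx_per_patch.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_b$per_patch,
                     file.path(out_dir, "baseline_per_patch.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(report_summary(out),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

# Flat numeric summary of a demo run, used by the demo JSON report.
report_summary <- function(demo) {
  f <- function(rep, prefix) {
    pos <- rep$aggregate[rep$aggregate$subset == "all_positive", ]
    out <- list(mean_iou = pos$iou, mean_iop = pos$iop, mean_ioa = pos$ioa,
                mean_confused_pixels = pos$confused_pixels,
                ap_iou_0.5 = unname(rep$ap_at_iou[["0.5"]]))
    if (!is.null(rep$classification)) {
      out$roc_auc <- unname(rep$classification[["roc_auc"]])
      out$classification_ap <- unname(rep$classification[["ap"]])
    }
    if (!is.null(rep$recovery)) {
      out$mean_iou_prediction_true <- rep$recovery$mean_iou_prediction_true
      out$mean_iou_annotation_true <- rep$recovery$mean_iou_annotation_true
    }
    stats::setNames(out, paste0(prefix, "_", names(out)))
  }
  c(f(demo$latentcadx$report, "latentcadx"),
    f(demo$plain_mse_baseline$report, "plain_mse_baseline"))
}
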