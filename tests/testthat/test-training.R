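# Small 32 px datasets keep the training unit tests in the seconds range;
# the full 64 px study-scale runs live in the acceptance suite.
make_tiny_ds <- function(n_labeled = 60, n_unlabeled = 0, holdout = 20,
                         seed = 77) {
  generate_dataset(synthetic_config(image_size = 32, n_labeled = n_labeled,
                                    n_unlabeled = n_unlabeled,
                                    holdout_size = holdout, seed = seed))
}

test_that("five-fold assignments partition and stratify the ids", {
  ids <- sprintf("im%04d", 1:900)
  labels <- rep(c(0, 1), each = 450)
  folds <- five_fold_cv(ids, labels, seed = 3)
  expect_length(folds, 5)
  val_sizes <- vapply(folds, function(f) length(f$val_ids), numeric(1))
  expect_true(all(val_sizes == 180))
  all_val <- unlist(lapply(folds, `[[`, "val_ids"))
  expect_setequal(all_val, ids)           # union is the full set
  expect_equal(anyDuplicated(all_val), 0L) # pairwise disjoint
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    n_pos <- sum(f$val_ids %in% ids[labels == 1])
    expect_lte(abs(n_pos - 90), 1)         # stratified within +/- 1
  }
  expect_error(five_fold_cv(letters[1:4]), "5 folds")
})

test_that("the plateau rule halves the rate after patience+1 flat epochs", {
  cfg <- train_config(lr_patience = 7, lr_threshold = 0.01, lr_factor = 0.5)
  st <- list(lr = 0.03, best = Inf, bad = 0L)
  lrs <- numeric(20)
  for (e in 1:20) {
    st <- dermrank:::plateau_step(st, 1.0, cfg)   # never improves
    lrs[e] <- st$lr
  }
  # epoch 1 sets the incumbent best; halvings then land every 8 epochs
  expect_equal(lrs[8], 0.03)
  expect_equal(lrs[9], 0.015)
  expect_equal(lrs[16], 0.015)
  expect_equal(lrs[17], 0.0075)
  # an improving epoch resets the counter
  st2 <- list(lr = 0.03, best = 1.0, bad = 6L)
  st2 <- dermrank:::plateau_step(st2, 0.5, cfg)
  expect_equal(st2$bad, 0L)
  expect_equal(st2$lr, 0.03)
})

test_that("training histories are bit-reproducible for a fixed seed", {
  ds <- make_tiny_ds()
  cfg <- train_config(seed = 11, max_epochs = 3, early_stop_patience = 3,
                      batch_size = 16L, augment = FALSE,
                      loss_weights = loss_weights(1, 1, 1, 0))
  f1 <- train_supervised(ds, cfg)
  f2 <- train_supervised(ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("semisupervised training degenerates to the supervised loop", {
  ds <- make_tiny_ds(n_unlabeled = 20)
  cfg <- train_config(seed = 12, max_epochs = 3, early_stop_patience = 3,
                      batch_size = 16L, labeled_fraction_per_batch = 1,
                      augment = FALSE,
                      loss_weights = loss_weights(1, 1, 0, 0))
  sup <- train_supervised(ds, cfg)
  expect_warning(semi <- train_semisupervised(ds, cfg), NA)
  expect_identical(sup$history, semi$history)
})

test_that("a zero consistency weight with no unlabeled pool warns", {
  ds <- make_tiny_ds(n_unlabeled = 0)
  cfg <- train_config(seed = 13, max_epochs = 2, early_stop_patience = 2,
                      batch_size = 16L, augment = FALSE,
                      loss_weights = loss_weights(1, 0, 0, 1))
  expect_warning(train_semisupervised(ds, cfg, unlabeled_idx = integer(0)),
                 "no unlabeled")
})

test_that("feature losses demand feature labels; disease-only does not", {
  ds <- make_tiny_ds()
  idx <- which(ds$truth$split == "train")
  ds$truth[idx, c("asymmetry", "network", "bluewhite")] <- NA
  cfg_fsl <- train_config(seed = 14, max_epochs = 2, early_stop_patience = 2,
                          batch_size = 16L, augment = FALSE,
                          loss_weights = loss_weights(1, 1, 0, 0))
  expect_error(train_supervised(ds, cfg_fsl), "feature labels")
  cfg_dsl <- train_config(seed = 14, max_epochs = 2, early_stop_patience = 2,
                          batch_size = 16L, augment = FALSE,
                          loss_weights = loss_weights(1, 0, 0, 0))
  expect_no_error(train_supervised(ds, cfg_dsl))
})

test_that("a disease-supervised run overfits its own training split", {
  ds <- make_tiny_ds(n_labeled = 120, holdout = 0, seed = 21)
  cfg <- train_config(seed = 21, max_epochs = 25, early_stop_patience = 25,
                      batch_size = 16L, augment = FALSE,
                      learning_rate = 0.05, restore_best = FALSE,
                      loss_weights = loss_weights(1, 0, 0, 0))
  fit <- train_supervised(ds, cfg)
  idx <- which(ds$truth$split == "train")
  pred <- model_predict(fit$model, dermrank:::dataset_batch(ds, idx))
  expect_gt(accuracy(as.integer(pred$disease_prob > 0.5),
                     ds$truth$disease[idx]), 0.9)
})

test_that("the ablation runner reproduces a direct train+evaluate call", {
  ds <- make_tiny_ds(seed = 31)
  cfg <- train_config(seed = 31, max_epochs = 2, early_stop_patience = 2,
                      batch_size = 16L, augment = FALSE)
  presets <- list(DSL = loss_weights(1, 0, 0, 0),
                  "DSL+FSL" = loss_weights(1, 1, 0, 0))
  rep <- run_ablation(presets, ds, cfg)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$preset, c("DSL", "DSL+FSL"))
  metric_cells <- c("disease_acc", "disease_auc", "asymmetry_acc",
                    "asymmetry_auc", "network_acc", "network_auc",
                    "bluewhite_acc", "bluewhite_auc")
  expect_true(all(metric_cells %in% names(rep)))
  expect_false(anyNA(rep[metric_cells]))
  expect_true(all(nzchar(rep$config_hash)))
  # single-preset consistency with the direct path
  cfg_direct <- cfg
  cfg_direct$loss_weights <- presets$DSL
  fit <- train_supervised(ds, cfg_direct)
  direct <- evaluate_model(fit$model, ds, split = "holdout")
  expect_equal(rep$disease_acc[1], direct$disease_acc)
  expect_equal(rep$bluewhite_auc[1], direct$bluewhite_auc)
  expect_error(run_ablation(list(A = presets[[1]], A = presets[[2]]),
                            ds, cfg), "uniquely")
})

test_that("the teacher tracks the student through a training run", {
  ds <- make_tiny_ds(seed = 41)
  cfg <- train_config(seed = 41, max_epochs = 3, early_stop_patience = 3,
                      batch_size = 16L, augment = FALSE, ema_decay = 0.95,
                      loss_weights = loss_weights(1, 0, 0, 0))
  fit <- train_supervised(ds, cfg)
  d <- sqrt(sum(mapply(function(t, s) sum((t - s)^2),
                       fit$model$teacher, fit$model$params)))
  expect_gt(d, 0)          # teacher lags the student...
  expect_lt(d, 5)          # ...but stays in its neighborhood
})

test_that("cross-validation rotates five stratified folds", {
  ds <- make_tiny_ds(n_labeled = 50, holdout = 0, seed = 51)
  cfg <- train_config(seed = 51, max_epochs = 2, early_stop_patience = 2,
                      batch_size = 16L, augment = FALSE,
                      loss_weights = loss_weights(1, 0, 0, 0))
  cv <- cross_validate(ds, cfg)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(sum(cv$per_fold$n_val), 50)
  expect_true(all(cv$per_fold$disease_acc >= 0 &
                  cv$per_fold$disease_acc <= 1))
  expect_gte(cv$aggregate$disease_acc$sd, 0)
})

test_that("unlabeled samples can join the ranking loss via teacher scores", {
  ds <- make_tiny_ds(n_labeled = 30, n_unlabeled = 20, holdout = 0,
                     seed = 61)
  cfg <- train_config(seed = 61, max_epochs = 2, early_stop_patience = 2,
                      batch_size = 16L, augment = FALSE,
                      ranking_source = "teacher",
                      loss_weights = loss_weights(1, 1, 1, 1))
  fit <- train_semisupervised(ds, cfg)
  expect_true(all(is.finite(fit$history$rl)))
  expect_true(all(fit$history$rl > 0))
})
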