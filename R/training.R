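#' Training configuration
#'
#' @param batch_size Images per optimization step (desk-scale default 64).
#' @param labeled_fraction_per_batch Fraction of each mixed batch drawn
#'   from the labeled pool during semisupervised training.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param lr_factor,lr_threshold,lr_patience Plateau schedule: the learning
#'   rate is multiplied by `lr_factor` after `lr_patience + 1` consecutive
#'   epochs whose monitored validation loss fails to improve on the best by
#'   more than `lr_threshold` (mode "min", absolute threshold).
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement; the best-epoch parameters are restored.
#' @param seed Seed controlling shuffling, augmentation and initialization.
#' @param loss_weights A [loss_weights()] object selecting the objective.
#' @param ema_decay Teacher EMA decay.
#' @param backbone Backbone passed to [build_model()].
#' @param augment Random flip/rotation augmentation of the student view
#'   (the teacher view is always perturbed independently when the
#'   consistency loss is active).
#' @param cl_ramp_frac Fraction of total steps over which the consistency
#'   weight ramps linearly from 0 to `lambda_cl`.
#' @param consistency_mode `"both"` heads or `"disease_only"`.
#' @param ranking_source `"labeled"` restricts ranking pairs to annotated
#'   scores; `"teacher"` additionally scores unlabeled batch members with
#'   the teacher's feature predictions thresholded at 0.5.
#' @param restore_best Restore the parameters of the epoch with the best
#'   monitored validation loss at the end of training (set `FALSE` to keep
#'   the final-epoch parameters, e.g. for overfitting probes).
#' @param use_unlabeled_disease Apply the disease supervised loss to
#'   unlabeled batch members too when they carry a disease tag.
#' @return A `dermrank_train_config` object.
#' @export
train_config <- function(batch_size = 64L, labeled_fraction_per_batch = 0.5,
                         learning_rate = 0.03, momentum = 0.9,
                         lr_factor = 0.5, lr_threshold = 0.01,
                         lr_patience = 7L, max_epochs = 40L,
                         early_stop_patience = 15L, seed = 1L,
                         loss_weights = dermrank::loss_weights(),
                         ema_decay = 0.99, backbone = "tiny_cnn",
                         augment = TRUE, cl_ramp_frac = 0.2,
                         consistency_mode = "both",
                         ranking_source = "labeled",
                         use_unlabeled_disease = TRUE,
                         restore_best = TRUE) {
  stopifnot(batch_size >= 2, labeled_fraction_per_batch > 0,
            labeled_fraction_per_batch <= 1, learning_rate > 0,
            lr_factor > 0, lr_factor < 1, lr_patience >= 0,
            max_epochs >= 1, inherits(loss_weights, "dermrank_loss_weights"),
            ranking_source %in% c("labeled", "teacher"))
  structure(list(batch_size = as.integer(batch_size),
                 labeled_fraction_per_batch = labeled_fraction_per_batch,
                 optimizer = "sgd", learning_rate = learning_rate,
                 momentum = momentum, lr_factor = lr_factor,
                 lr_threshold = lr_threshold,
                 lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), loss_weights = loss_weights,
                 ema_decay = ema_decay, backbone = backbone,
                 augment = augment, cl_ramp_frac = cl_ramp_frac,
                 consistency_mode = consistency_mode,
                 ranking_source = ranking_source,
                 use_unlabeled_disease = use_unlabeled_disease,
                 restore_best = restore_best),
            class = "dermrank_train_config")
}

#' Stratified 5-fold cross-validation assignment
#'
#' Shuffles once with the seed, deals ids of each disease class round-robin
#' into 5 near-equal subsets, and rotates each subset as the validation
#' fold, so each id validates exactly once and every fold is an 80/20
#' split stratified by disease.
#'
#' @param ids Vector of sample ids (>= 5).
#' @param labels Optional disease labels for stratification.
#' @param seed Shuffle seed.
#' @return List of 5 assignments, each with `fold_index`, `train_ids`,
#'   `val_ids`.
#' @export
five_fold_cv <- function(ids, labels = NULL, seed = 1L) {
  n <- length(ids)
  if (n < 5) stop("need at least 5 ids for 5 folds")
  set_seed(derive_seed(seed, 3))
  if (is.null(labels)) labels <- rep(0L, n)
  fold_of <- integer(n)
  for (cls in unique(labels)) {
    pos <- which(labels == cls)
    pos <- pos[sample.int(length(pos))]
    fold_of[pos] <- rep_len(1:5, length(pos))
  }
  lapply(1:5, function(k) list(fold_index = k - 1L,
                               train_ids = ids[fold_of != k],
                               val_ids = ids[fold_of == k]))
}

# Plateau learning-rate rule (mode "min", absolute threshold): after
# lr_patience + 1 consecutive non-improving epochs the rate is scaled by
# lr_factor and the counter resets.
plateau_step <- function(state, val_loss, config) {
  if (val_loss < state$best - config$lr_threshold) {
    state$best <- val_loss
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad > config$lr_patience) {
      state$lr <- state$lr * config$lr_factor
      state$bad <- 0L
    }
  }
  state
}

# Supervised validation loss: the enabled supervised terms (DSL/FSL/RL)
# evaluated on the validation split -- the scalar the plateau schedule and
# early stopping monitor.
validation_loss <- function(model, dataset, idx, w) {
  x <- dataset_batch(dataset, idx)
  out <- model_forward(model, x)
  tr <- dataset$truth[idx, ]
  parts <- list(dsl = NA, fsl = NA, rl = NA, cl = NA)
  if (w$lambda_dsl > 0)
    parts$dsl <- disease_supervised_loss(out$disease_logits, tr$disease)
  if (w$lambda_fsl > 0)
    parts$fsl <- feature_supervised_loss(
      out$feature_logits, t(as.matrix(tr[c("asymmetry", "network",
                                           "bluewhite")])),
      w$feature_weights)
  if (w$lambda_rl > 0)
    parts$rl <- ranking_loss(out$disease_logits[1, ],
                             checklist_score(as.matrix(
                               tr[c("asymmetry", "network", "bluewhite")])))
  wsup <- loss_weights(w$lambda_dsl, w$lambda_fsl, w$lambda_rl,
                       lambda_cl = 0, feature_weights = w$feature_weights)
  combined_loss(parts, wsup)
}

# One SGD-with-momentum update over the flat parameter list.
sgd_update <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    velocity[[nm]] <- momentum * velocity[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

# Shared training loop behind train_supervised() and
# train_semisupervised().  When `unlabeled_idx` is empty and lambda_cl is
# 0 the two entry points perform identical RNG draws, so the supervised
# loop is exactly the semisupervised loop degenerated.
train_loop <- function(dataset, config, train_idx, val_idx,
                       unlabeled_idx = integer(0)) {
  w <- config$loss_weights
  tr <- dataset$truth
  need_feats <- w$lambda_fsl > 0 || w$lambda_rl > 0
  if (need_feats &&
      anyNA(tr[train_idx, c("asymmetry", "network", "bluewhite")]))
    stop("FSL/RL enabled but some training samples lack feature labels")
  if (w$lambda_dsl > 0 && anyNA(tr$disease[c(train_idx, unlabeled_idx)]))
    stop("DSL enabled but some samples lack a disease label")

  semisup <- w$lambda_cl > 0 && length(unlabeled_idx) > 0
  if (w$lambda_cl > 0 && length(unlabeled_idx) == 0 &&
      !is.null(attr(train_idx, "wants_unlabeled")))
    warning("consistency weight > 0 with no unlabeled data; ",
            "degenerating to supervised training")

  model <- build_model(config$backbone, ema_decay = config$ema_decay,
                       seed = config$seed)
  velocity <- lapply(model$params, function(p) p * 0)
  set_seed(derive_seed(config$seed, 11))

  n_lab_batch <- if (semisup)
    max(2L, round(config$batch_size * config$labeled_fraction_per_batch))
  else config$batch_size
  n_unlab_batch <- if (semisup) config$batch_size - n_lab_batch else 0L
  steps_per_epoch <- max(1L, ceiling(length(train_idx) / n_lab_batch))
  total_steps <- steps_per_epoch * config$max_epochs
  ramp_steps <- max(1, ceiling(config$cl_ramp_frac * total_steps))

  sched <- list(lr = config$learning_rate, best = Inf, bad = 0L)
  best_val <- Inf; best_state <- NULL; since_best <- 0L
  history <- NULL
  unlab_queue <- integer(0)
  step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    order_lab <- train_idx[sample.int(length(train_idx))]
    epoch_parts <- c(dsl = 0, fsl = 0, rl = 0, cl = 0)
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      take <- order_lab[((s - 1L) * n_lab_batch + 1L):
                          min(s * n_lab_batch, length(order_lab))]
      if (length(take) < 2) take <- c(take, order_lab[1L])
      if (semisup) {
        while (length(unlab_queue) < n_unlab_batch)
          unlab_queue <- c(unlab_queue,
                           unlabeled_idx[sample.int(length(unlabeled_idx))])
        u_take <- unlab_queue[seq_len(n_unlab_batch)]
        unlab_queue <- unlab_queue[-seq_len(n_unlab_batch)]
      } else u_take <- integer(0)
      batch_idx <- c(take, u_take)
      is_lab <- c(rep(TRUE, length(take)), rep(FALSE, length(u_take)))
      nb <- length(batch_idx)

      x <- dataset_batch(dataset, batch_idx)
      xs <- if (config$augment) augment_batch(x) else x
      fwd <- model_forward(model, xs, keep_cache = TRUE)

      d_dis <- matrix(0, model$n_diseases, nb)
      d_fea <- matrix(0, model$n_features, nb)
      parts <- list(dsl = NA, fsl = NA, rl = NA, cl = NA)

      if (w$lambda_dsl > 0) {
        dsl_mask <- if (config$use_unlabeled_disease) rep(TRUE, nb) else is_lab
        r <- disease_supervised_loss(
          fwd$disease_logits[, dsl_mask, drop = FALSE],
          tr$disease[batch_idx[dsl_mask]], grad = TRUE)
        parts$dsl <- r$loss
        d_dis[, dsl_mask] <- d_dis[, dsl_mask] + w$lambda_dsl * r$grad
      }
      if (w$lambda_fsl > 0) {
        y <- t(as.matrix(tr[batch_idx[is_lab],
                            c("asymmetry", "network", "bluewhite")]))
        r <- feature_supervised_loss(
          fwd$feature_logits[, is_lab, drop = FALSE], y,
          w$feature_weights, grad = TRUE)
        parts$fsl <- r$loss
        d_fea[, is_lab] <- d_fea[, is_lab] + w$lambda_fsl * r$grad
      }
      if (w$lambda_rl > 0) {
        rl_mask <- is_lab
        scores <- checklist_score(as.matrix(
          tr[batch_idx[is_lab], c("asymmetry", "network", "bluewhite")]))
        if (config$ranking_source == "teacher" && any(!is_lab)) {
          t_out <- model_forward(model, xs[, , , !is_lab, drop = FALSE],
                                 params = model$teacher)
          pseudo <- checklist_score(t(plogis(t_out$feature_logits) > 0.5) * 1)
          scores <- c(scores, pseudo)
          rl_mask <- rep(TRUE, nb)
        }
        r <- ranking_loss(fwd$disease_logits[1, rl_mask], scores,
                          grad = TRUE)
        parts$rl <- r$loss
        d_dis[1, rl_mask] <- d_dis[1, rl_mask] + w$lambda_rl * r$grad
      }
      if (w$lambda_cl > 0 && semisup) {
        xt <- if (config$augment) augment_batch(x) else x
        t_out <- model_forward(model, xt, params = model$teacher)
        r <- consistency_loss(fwd, t_out, mode = config$consistency_mode,
                              grad = TRUE)
        ramp <- min(1, step / ramp_steps)
        parts$cl <- r$loss
        d_dis <- d_dis + w$lambda_cl * ramp * r$grad_disease
        d_fea <- d_fea + w$lambda_cl * ramp * r$grad_feature
      }

      grads <- model_backward(model, xs, fwd, d_dis, d_fea)
      upd <- sgd_update(model$params, grads, velocity, sched$lr,
                        config$momentum)
      model$params <- upd$params
      velocity <- upd$velocity
      model$step <- step
      model <- ema_update(model)

      for (k in names(epoch_parts))
        if (!is.na(parts[[k]]))
          epoch_parts[k] <- epoch_parts[k] + parts[[k]] / steps_per_epoch
    }

    vloss <- validation_loss(model, dataset, val_idx, w)
    vpred <- model_predict(model, dataset_batch(dataset, val_idx))
    vacc <- accuracy(as.integer(vpred$disease_prob > 0.5),
                     tr$disease[val_idx])
    lr_now <- sched$lr
    sched <- plateau_step(sched, vloss, config)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr_now, dsl = epoch_parts["dsl"],
      fsl = epoch_parts["fsl"], rl = epoch_parts["rl"],
      cl = epoch_parts["cl"], val_loss = vloss, val_acc = vacc,
      row.names = NULL))

    if (vloss < best_val - 1e-12) {
      best_val <- vloss
      best_state <- list(params = model$params, teacher = model$teacher,
                         step = model$step)
      since_best <- 0L
    } else since_best <- since_best + 1L
    if (since_best >= config$early_stop_patience) break
  }

  if (config$restore_best && !is.null(best_state)) {
    model$params <- best_state$params
    model$teacher <- best_state$teacher
  }
  list(model = model, history = history,
       config_hash = config_hash(unclass(config)))
}

#' Train the two-headed classifier on labeled data
#'
#' Minimizes the enabled supervised terms (disease cross-entropy, feature
#' BCE, pairwise ranking loss) with SGD + momentum under the plateau
#' learning-rate rule; the EMA teacher is maintained throughout.
#'
#' @param dataset A `dermrank_dataset`.
#' @param config A [train_config()].
#' @param train_idx,val_idx Row indices into `dataset$truth`; default to
#'   the labeled manifest's train/val split.
#' @return List with the trained `model`, the per-epoch `history` (all
#'   loss components, learning rate, validation loss/accuracy) and the
#'   config hash.
#' @export
train_supervised <- function(dataset, config = train_config(),
                             train_idx = NULL, val_idx = NULL) {
  tr <- dataset$truth
  if (is.null(train_idx))
    train_idx <- which(tr$split == "train" & tr$labeled)
  if (is.null(val_idx)) val_idx <- which(tr$split == "val")
  train_loop(dataset, config, train_idx, val_idx)
}

#' Train with the mean-teacher semisupervised objective
#'
#' Each step draws a mixed batch (`labeled_fraction_per_batch` labeled);
#' the student receives the supervised terms on the labeled portion (and,
#' by default, the disease term on any unlabeled member carrying a disease
#' tag) plus the consistency loss against the teacher's independently
#' perturbed forward pass over the whole batch; the teacher is updated by
#' EMA after every optimizer step.
#'
#' @param dataset A `dermrank_dataset`.
#' @param config A [train_config()] with `lambda_cl > 0`.
#' @param train_idx,val_idx,unlabeled_idx Row indices; default to the
#'   manifest's labeled train/val split and the whole unlabeled pool.
#' @return As [train_supervised()].
#' @export
train_semisupervised <- function(dataset, config = train_config(),
                                 train_idx = NULL, val_idx = NULL,
                                 unlabeled_idx = NULL) {
  tr <- dataset$truth
  if (is.null(train_idx))
    train_idx <- which(tr$split == "train" & tr$labeled)
  if (is.null(val_idx)) val_idx <- which(tr$split == "val")
  if (is.null(unlabeled_idx)) unlabeled_idx <- which(!tr$labeled)
  if (config$loss_weights$lambda_cl > 0 && length(unlabeled_idx) == 0)
    warning("consistency weight > 0 with no unlabeled data; ",
            "degenerating to supervised training")
  train_loop(dataset, config, train_idx, val_idx, unlabeled_idx)
}

#' Named loss-weight presets for the ablation grid
#'
#' The eight rows of the loss-ablation study: each combination of disease
#' supervised loss, feature supervised loss and consistency loss, plus the
#' asymmetry-emphasis variant (feature weight 2 on asymmetry).
#'
#' @param asymmetry_weight Emphasis weight for the asymmetry feature in
#'   the weighted variant.
#' @return Named list of [loss_weights()] objects.
#' @export
ablation_presets <- function(asymmetry_weight = 2) {
  list(
    "CL"          = loss_weights(0, 0, 0, 1),
    "DSL"         = loss_weights(1, 0, 0, 0),
    "FSL"         = loss_weights(0, 1, 0, 0),
    "FSL+CL"      = loss_weights(0, 1, 0, 1),
    "DSL+FSL"     = loss_weights(1, 1, 0, 0),
    "DSL+CL"      = loss_weights(1, 0, 0, 1),
    "DSL+FSL+CL"  = loss_weights(1, 1, 0, 1),
    "DSL+FSL(asym)+CL" = loss_weights(1, 1, 0, 1,
      feature_weights = c(asymmetry_weight, 1, 1)))
}

#' Run the loss-ablation grid
#'
#' Trains one model per preset with a shared seed and split assignment
#' (semisupervised whenever the preset enables the consistency loss) and
#' scores each on the holdout split, producing a report shaped like the
#' ablation table: one row per preset, accuracy and AUC per head.
#'
#' @param presets Named list of [loss_weights()] (e.g.
#'   [ablation_presets()]).  Duplicate names are rejected.
#' @param dataset A `dermrank_dataset`.
#' @param config Base [train_config()]; its `loss_weights` are replaced by
#'   each preset in turn.
#' @param eval_split Split to score (default `"holdout"`).
#' @return Data frame: one row per preset with the 8 metric cells and the
#'   config hash that produced it.
#' @export
run_ablation <- function(presets, dataset, config = train_config(),
                         eval_split = "holdout") {
  if (is.null(names(presets)) || anyDuplicated(names(presets)))
    stop("presets must be uniquely named")
  rows <- lapply(names(presets), function(nm) {
    cfg <- config
    cfg$loss_weights <- presets[[nm]]
    fit <- if (presets[[nm]]$lambda_cl > 0)
      train_semisupervised(dataset, cfg)
    else train_supervised(dataset, cfg)
    rep <- evaluate_model(fit$model, dataset, split = eval_split)
    rep$preset <- nm
    rep$config_hash <- fit$config_hash
    rep
  })
  out <- do.call(rbind, rows)
  out[c("preset", setdiff(names(out), "preset"))]
}

#' Cross-validate a configuration over the stratified 5-fold rotation
#'
#' Rotates each fold of [five_fold_cv()] as the validation share, trains
#' one model per fold with a shared configuration, and aggregates the
#' per-fold validation metrics (mean and sample SD).
#'
#' @param dataset A `dermrank_dataset`.
#' @param config A [train_config()].
#' @param use_unlabeled Include the unlabeled pool (semisupervised) when
#'   the consistency weight is positive.
#' @return List with `per_fold` (one evaluation row per fold) and
#'   `aggregate` (mean/SD of disease accuracy and AUC across folds).
#' @export
cross_validate <- function(dataset, config = train_config(),
                           use_unlabeled = TRUE) {
  tr <- dataset$truth
  lab <- which(tr$labeled & tr$split != "holdout")
  folds <- five_fold_cv(tr$image_id[lab], tr$disease[lab],
                        seed = config$seed)
  unlab <- if (use_unlabeled) which(!tr$labeled) else integer(0)
  rows <- lapply(folds, function(f) {
    tr_idx <- match(f$train_ids, tr$image_id)
    va_idx <- match(f$val_ids, tr$image_id)
    fit <- if (config$loss_weights$lambda_cl > 0 && length(unlab) > 0)
      train_loop(dataset, config, tr_idx, va_idx, unlab)
    else train_loop(dataset, config, tr_idx, va_idx)
    pred <- model_predict(fit$model, dataset_batch(dataset, va_idx))
    data.frame(fold = f$fold_index,
               disease_acc = accuracy(as.integer(pred$disease_prob > 0.5),
                                      tr$disease[va_idx]),
               disease_auc = auc(pred$disease_prob, tr$disease[va_idx]),
               n_val = length(va_idx))
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       aggregate = list(disease_acc = fold_aggregate(per_fold$disease_acc),
                        disease_auc = fold_aggregate(per_fold$disease_auc)))
}
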