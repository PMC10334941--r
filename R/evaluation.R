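#' Classification accuracy
#'
#' @param predictions,truth Aligned binary label vectors.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) == 0)
    stop("predictions and truth must be aligned and nonempty")
  mean(predictions == truth)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted half.  Undefined when only one class is present; returns `NA`
#' with a warning in that case.
#'
#' @param scores Real-valued scores (higher = more positive).
#' @param truth Binary labels aligned with `scores`.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate a per-fold metric
#'
#' @param per_fold Numeric vector of per-fold values (>= 2 folds).
#' @return List with `mean` and `sd` (sample SD, divisor n - 1).
#' @export
fold_aggregate <- function(per_fold) {
  if (length(per_fold) < 2) stop("need at least 2 folds")
  list(mean = mean(per_fold), sd = stats::sd(per_fold))
}

extract_flags <- function(x, feature) {
  feats <- c("asymmetry", "network", "bluewhite")
  if (is.data.frame(x)) {
    if (feature == "overall") as.vector(as.matrix(x[feats]))
    else x[[feature]]
  } else as.vector(x)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' annotators' marginal frequencies.  For annotation tables (data frames
#' with columns `asymmetry`, `network`, `bluewhite`), `feature = "overall"`
#' pools the per-feature decisions; a single feature name restricts to that
#' flag.  Degenerate marginals (`p_e = 1`) make kappa undefined (`NA`).
#'
#' @param a,b Aligned binary vectors, or annotation data frames.
#' @param feature `"overall"` or one of `"asymmetry"`, `"network"`,
#'   `"bluewhite"`.
#' @return Kappa in `[-1, 1]`, or `NA`.
#' @export
cohen_kappa <- function(a, b, feature = "overall") {
  va <- extract_flags(a, feature); vb <- extract_flags(b, feature)
  if (length(va) != length(vb) || length(va) == 0)
    stop("annotation sets must be aligned and nonempty")
  lev <- sort(unique(c(va, vb)))
  p_o <- mean(va == vb)
  p_e <- sum(vapply(lev, function(l) mean(va == l) * mean(vb == l),
                    numeric(1)))
  if (abs(1 - p_e) < 1e-12) {
    warning("kappa undefined: degenerate marginals (p_e = 1)")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Majority-vote adjudication of three annotators
#'
#' Consensus protocol: when the first two annotators agree, their value is
#' the consensus and the third is ignored; otherwise the third annotator
#' breaks the tie.  Missing values leave the image unresolved (`NA`).
#'
#' @param a,b,c Aligned binary vectors (per-image flags).
#' @return Consensus vector; `NA` marks unresolved images.
#' @export
majority_vote <- function(a, b, c) {
  n <- length(a)
  if (length(b) != n || length(c) != n) stop("annotators must be aligned")
  out <- ifelse(!is.na(a) & !is.na(b) & a == b, a,
                ifelse(is.na(a) | is.na(b) | is.na(c), NA, c))
  as.integer(out)
}

#' Predict disease and feature probabilities
#'
#' @param model A `dermrank_model`.
#' @param x Batch array (C, H, W, N).
#' @param use `"student"` or `"teacher"` parameters.
#' @param batch_size Forward-pass chunk size.
#' @return List with `disease_prob` (melanoma probability, length N) and
#'   `feature_prob` (3 x N).
#' @export
model_predict <- function(model, x, use = c("student", "teacher"),
                          batch_size = 256L) {
  use <- match.arg(use)
  params <- if (use == "teacher") model$teacher else model$params
  n <- dim(x)[4]
  dp <- numeric(n); fp <- matrix(0, model$n_features, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- model_forward(model, x[, , , idx, drop = FALSE], params = params)
    dp[idx] <- softmax_cols(out$disease_logits)[1, ]
    fp[, idx] <- plogis(out$feature_logits)
  }
  list(disease_prob = dp, feature_prob = fp)
}

#' Evaluate a model on one split of a dataset
#'
#' Scores the disease head and each feature head with accuracy (features
#' thresholded at probability 0.5) and AUC (raw probabilities) against the
#' internally retained ground truth.
#'
#' @param model A `dermrank_model`.
#' @param dataset A `dermrank_dataset` (preprocessed or raw).
#' @param split Which split to score (`"holdout"`, `"val"`, `"train"`).
#' @param use `"student"` or `"teacher"` parameters.
#' @return A one-row data frame with the 8 metric cells (4 heads x
#'   accuracy/AUC), the sample count and the model's provenance hash.
#' @export
evaluate_model <- function(model, dataset, split = "holdout",
                           use = "student") {
  idx <- which(dataset$truth$split == split)
  if (length(idx) == 0) stop("no samples in split '", split, "'")
  x <- dataset_batch(dataset, idx)
  pred <- model_predict(model, x, use = use)
  tr <- dataset$truth[idx, ]
  feats <- c("asymmetry", "network", "bluewhite")
  out <- data.frame(
    disease_acc = accuracy(as.integer(pred$disease_prob > 0.5), tr$disease),
    disease_auc = auc(pred$disease_prob, tr$disease))
  for (k in 1:3) {
    out[[paste0(feats[k], "_acc")]] <-
      accuracy(as.integer(pred$feature_prob[k, ] > 0.5), tr[[feats[k]]])
    out[[paste0(feats[k], "_auc")]] <- auc(pred$feature_prob[k, ],
                                           tr[[feats[k]]])
  }
  out$n <- length(idx)
  out$split <- split
  out$config_hash <- config_hash(list(backbone = model$backbone,
                                      seed = model$seed, step = model$step))
  out
}
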