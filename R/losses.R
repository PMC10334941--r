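# The four training-loss terms and their analytic gradients.
#
# The ranking loss encodes the 3-point-checklist triage rule: for a pair of
# images (i, j) with checklist scores s_i, s_j, the melanoma-logit
# difference o_ij = f(x_i) - f(x_j) is pushed, through a sigmoid posterior
# P_ij = 1 / (1 + exp(-o_ij)), toward the target Pbar_ij that is 1 when
# s_i > s_j, 0 when s_i < s_j, and 1/2 on ties.  The pair cross-entropy
#   C_ij = -Pbar_ij log P_ij - (1 - Pbar_ij) log(1 - P_ij)
# is evaluated in the numerically stable rewritten form
#   C_ij = -Pbar_ij o_ij + log(1 + exp(o_ij)).

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

log1pexp <- function(o) pmax(o, 0) + log1p(exp(-abs(o)))

#' Checklist score of an annotation
#'
#' One point per feature present (asymmetry, atypical network, blue-white
#' structure), so the score ranges over 0..3.
#'
#' @param features Length-3 binary vector, or an n x 3 binary matrix.
#' @return Integer score(s) in 0..3.
#' @export
checklist_score <- function(features) {
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(m) != 3 || any(!m %in% c(0, 1)))
    stop("annotation must consist of three binary flags")
  s <- as.integer(rowSums(m))
  if (!is.matrix(features)) s[1] else s
}

#' Pairwise ranking target from two checklist scores
#'
#' @param s_i,s_j Integer scores in 0..3 (vectorized).
#' @return 1 when `s_i > s_j`, 0 when `s_i < s_j`, 0.5 on ties.
#' @export
ranking_target <- function(s_i, s_j) {
  if (any(!c(s_i, s_j) %in% 0:3)) stop("scores must be in 0..3")
  (sign(s_i - s_j) + 1) / 2
}

#' Pairwise ranking loss on melanoma logits
#'
#' Mean over all unordered pairs in the batch of the pair cross-entropy
#' between the sigmoid posterior of the logit difference and the
#' score-derived target.  Ties are kept with target 0.5.  A batch with
#' fewer than two samples has no pairs; the loss is defined as 0 with a
#' warning.
#'
#' @param melanoma_logits Numeric vector f over the batch.
#' @param scores Integer checklist scores in 0..3, same length.
#' @param grad Also return the gradient with respect to the logits.
#' @return The scalar loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
ranking_loss <- function(melanoma_logits, scores, grad = FALSE) {
  n <- length(melanoma_logits)
  if (length(scores) != n) stop("logit and score vectors differ in length")
  if (n < 2) {
    warning("ranking loss needs at least 2 samples; returning 0")
    return(if (grad) list(loss = 0, grad = numeric(n)) else 0)
  }
  O <- outer(melanoma_logits, melanoma_logits, "-")
  Pbar <- (sign(outer(scores, scores, "-")) + 1) / 2
  C <- -Pbar * O + log1pexp(O)
  upper <- upper.tri(C)
  npairs <- n * (n - 1) / 2
  loss <- sum(C[upper]) / npairs
  if (!grad) return(loss)
  M <- (plogis(O) - Pbar) * upper
  g <- (rowSums(M) - colSums(M)) / npairs
  list(loss = loss, grad = g)
}

#' Disease supervised loss (softmax cross-entropy)
#'
#' Row 1 of the logits is the melanoma class, row 2 the nevus class;
#' labels use 1 = melanoma, 0 = nevus.
#'
#' @param disease_logits 2 x N matrix of logits.
#' @param labels Binary vector of length N.
#' @param grad Also return the gradient with respect to the logits.
#' @return Mean cross-entropy, or `list(loss, grad)`.
#' @export
disease_supervised_loss <- function(disease_logits, labels, grad = FALSE) {
  if (any(!labels %in% c(0, 1))) stop("disease labels must be 0/1")
  n <- ncol(disease_logits)
  if (length(labels) != n) stop("label/logit length mismatch")
  p <- softmax_cols(disease_logits)
  onehot <- rbind(labels, 1 - labels)
  loss <- -mean(log(colSums(p * onehot)))
  if (!grad) return(loss)
  list(loss = loss, grad = (p - onehot) / n)
}

#' Feature supervised loss (weighted sigmoid binary cross-entropy)
#'
#' Weighted mean over the three features of the per-feature mean BCE.  The
#' weights are normalized to sum to 3 so `c(1, 1, 1)` reproduces the plain
#' mean; raising one weight (e.g. asymmetry emphasis, `c(2, 1, 1)`)
#' emphasizes that feature's errors.
#'
#' @param feature_logits 3 x N matrix of logits.
#' @param feature_labels 3 x N binary matrix.
#' @param feature_weights Length-3 nonnegative weights.
#' @param grad Also return the gradient with respect to the logits.
#' @return Scalar loss, or `list(loss, grad)`.
#' @export
feature_supervised_loss <- function(feature_logits, feature_labels,
                                    feature_weights = c(1, 1, 1),
                                    grad = FALSE) {
  if (any(feature_weights < 0) || sum(feature_weights) == 0)
    stop("feature weights must be nonnegative with a positive sum")
  if (any(!feature_labels %in% c(0, 1))) stop("feature labels must be 0/1")
  if (!all(dim(feature_logits) == dim(feature_labels)))
    stop("logit/label shape mismatch")
  n <- ncol(feature_logits)
  w <- 3 * feature_weights / sum(feature_weights)
  z <- feature_logits; y <- feature_labels
  bce <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  loss <- sum(w * rowMeans(bce)) / 3
  if (!grad) return(loss)
  list(loss = loss, grad = (plogis(z) - y) * w / (3 * n))
}

#' Mean-teacher consistency loss
#'
#' Mean squared difference between the student's and the teacher's
#' predicted distributions: the softmax over the disease logits and the
#' sigmoids over the feature logits, concatenated (`mode = "both"`), or
#' the disease softmax alone (`mode = "disease_only"`).  Teacher outputs
#' are treated as constants: no gradient flows to the teacher.
#'
#' @param student,teacher Lists with `disease_logits` (2 x N) and
#'   `feature_logits` (3 x N), e.g. from [model_forward()].
#' @param mode `"both"` (default) or `"disease_only"`.
#' @param grad Also return gradients with respect to the student logits.
#' @return Scalar loss, or `list(loss, grad_disease, grad_feature)`.
#' @export
consistency_loss <- function(student, teacher, mode = c("both",
                             "disease_only"), grad = FALSE) {
  mode <- match.arg(mode)
  if (!all(dim(student$disease_logits) == dim(teacher$disease_logits)) ||
      !all(dim(student$feature_logits) == dim(teacher$feature_logits)))
    stop("student/teacher output shapes differ")
  n <- ncol(student$disease_logits)
  ps_d <- softmax_cols(student$disease_logits)
  pt_d <- softmax_cols(teacher$disease_logits)
  ps_f <- plogis(student$feature_logits)
  pt_f <- plogis(teacher$feature_logits)
  if (mode == "both") {
    nelem <- 5 * n
    loss <- (sum((ps_d - pt_d)^2) + sum((ps_f - pt_f)^2)) / nelem
  } else {
    nelem <- 2 * n
    loss <- sum((ps_d - pt_d)^2) / nelem
  }
  if (!grad) return(loss)
  dP_d <- 2 * (ps_d - pt_d) / nelem
  gd <- ps_d * sweep(dP_d, 2, colSums(dP_d * ps_d))
  if (mode == "both") {
    dP_f <- 2 * (ps_f - pt_f) / nelem
    gf <- dP_f * ps_f * (1 - ps_f)
  } else {
    gf <- matrix(0, nrow(ps_f), n)
  }
  list(loss = loss, grad_disease = gd, grad_feature = gf)
}

#' Loss-balancing coefficients
#'
#' The lambda coefficients weight the four terms of the combined objective
#' (disease supervised, feature supervised, ranking, consistency); the
#' per-feature weights implement the asymmetry-emphasis ablation axis.
#'
#' @param lambda_dsl,lambda_fsl,lambda_rl,lambda_cl Nonnegative weights.
#' @param feature_weights Length-3 nonnegative per-feature weights.
#' @return A `dermrank_loss_weights` object.
#' @export
loss_weights <- function(lambda_dsl = 1, lambda_fsl = 1, lambda_rl = 1,
                         lambda_cl = 1, feature_weights = c(1, 1, 1)) {
  lam <- c(lambda_dsl, lambda_fsl, lambda_rl, lambda_cl)
  stopifnot(all(lam >= 0), any(lam > 0), length(feature_weights) == 3,
            all(feature_weights >= 0))
  structure(list(lambda_dsl = lambda_dsl, lambda_fsl = lambda_fsl,
                 lambda_rl = lambda_rl, lambda_cl = lambda_cl,
                 feature_weights = feature_weights),
            class = "dermrank_loss_weights")
}

#' Combine the four loss terms
#'
#' Weighted sum `lambda_dsl*DSL + lambda_fsl*FSL + lambda_rl*RL +
#' lambda_cl*CL`.  Terms with weight 0 may be passed as `NA`: disabled
#' losses are skipped entirely and never require their labels.
#'
#' @param parts Named list/vector with entries `dsl`, `fsl`, `rl`, `cl`
#'   (each a scalar or `NA` when disabled).
#' @param weights A [loss_weights()] object.
#' @return The combined scalar loss.
#' @export
combined_loss <- function(parts, weights = loss_weights()) {
  stopifnot(inherits(weights, "dermrank_loss_weights"))
  lam <- c(dsl = weights$lambda_dsl, fsl = weights$lambda_fsl,
           rl = weights$lambda_rl, cl = weights$lambda_cl)
  total <- 0
  for (k in names(lam)) {
    if (lam[[k]] == 0) next
    v <- parts[[k]]
    if (is.null(v) || is.na(v))
      stop("loss term '", k, "' is enabled but missing")
    if (!is.finite(v)) stop("loss term '", k, "' is not finite")
    total <- total + lam[[k]] * v
  }
  total
}
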