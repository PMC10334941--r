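# Four convolution blocks; the stem convolution uses stride 2 so the bulk
# of the arithmetic happens at quarter resolution, which keeps one CPU
# training epoch in the seconds range at 64x64 input.
backbone_tiny_cnn <- function() {
  list(net = list(
         layer_conv("conv1", 3L, 8L, stride = 2L), layer_relu(), layer_pool(),
         layer_conv("conv2", 8L, 16L), layer_relu(), layer_pool(),
         layer_conv("conv3", 16L, 32L), layer_relu(), layer_pool(),
         layer_conv("conv4", 32L, 32L), layer_relu(), layer_pool(),
         layer_gap()),
       n_trunk = 32L)
}

# Residual backbone in the spirit of the 18-layer reference architecture,
# with widths scaled to CPU training: a stem convolution, three stages of
# basic residual blocks separated by max pooling, global average pooling.
backbone_resnet18_style <- function() {
  list(net = list(
         layer_conv("stem", 3L, 16L), layer_relu(), layer_pool(),
         layer_resblock("res1a", 16L, 16L),
         layer_resblock("res1b", 16L, 16L), layer_pool(),
         layer_resblock("res2a", 16L, 32L),
         layer_resblock("res2b", 32L, 32L), layer_pool(),
         layer_resblock("res3a", 32L, 64L),
         layer_resblock("res3b", 64L, 64L), layer_pool(),
         layer_gap()),
       n_trunk = 64L)
}

# A deliberately small two-layer probe (one convolution + heads) used by
# the finite-difference gradient checks.
backbone_probe <- function() {
  list(net = list(layer_conv("conv1", 3L, 4L), layer_relu(), layer_gap()),
       n_trunk = 4L)
}

supported_backbones <- function()
  c("tiny_cnn", "resnet18_style", "probe")

#' Build the two-headed classifier with its EMA teacher
#'
#' One shared convolutional trunk feeds two output heads: a 2-way disease
#' head (melanoma, nevus; trained with softmax cross-entropy) and a 3-way
#' feature head (asymmetry, atypical network, blue-white; independent
#' sigmoids).  The teacher starts as an exact copy of the student and is
#' only ever updated by an exponential moving average of the student
#' parameters, never by gradients.
#'
#' @param backbone One of `"tiny_cnn"` (4 conv blocks, the desk-scale
#'   default), `"resnet18_style"` (residual blocks), or `"probe"` (one
#'   convolution, for gradient checks).
#' @param n_diseases Number of disease classes (2).
#' @param n_features Number of checklist features (3).
#' @param ema_decay EMA decay alpha of the teacher.
#' @param seed Integer seed for parameter initialization.
#' @return A `dermrank_model` with `$params` (student), `$teacher`,
#'   `$ema_decay` and `$step`.
#' @export
build_model <- function(backbone = "tiny_cnn", n_diseases = 2L,
                        n_features = 3L, ema_decay = 0.99, seed = 1L) {
  if (!backbone %in% supported_backbones())
    stop("unknown backbone '", backbone, "'; supported: ",
         paste(supported_backbones(), collapse = ", "))
  bb <- switch(backbone, tiny_cnn = backbone_tiny_cnn(),
               resnet18_style = backbone_resnet18_style(),
               probe = backbone_probe())
  set_seed(derive_seed(seed, 7))
  params <- init_net(bb$net)
  nt <- bb$n_trunk
  params$head_d.W <- matrix(rnorm(n_diseases * nt, sd = sqrt(1 / nt)),
                            n_diseases, nt)
  params$head_d.b <- numeric(n_diseases)
  params$head_f.W <- matrix(rnorm(n_features * nt, sd = sqrt(1 / nt)),
                            n_features, nt)
  params$head_f.b <- numeric(n_features)
  structure(list(backbone = backbone, net = bb$net, n_trunk = nt,
                 n_diseases = as.integer(n_diseases),
                 n_features = as.integer(n_features),
                 params = params, teacher = params,
                 ema_decay = ema_decay, step = 0L, seed = as.integer(seed)),
            class = "dermrank_model")
}

#' @export
print.dermrank_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dermrank_model %s: %d parameters, step %d, ema_decay %g>\n",
              x$backbone, np, x$step, x$ema_decay))
  invisible(x)
}

#' Forward pass of the two-headed model
#'
#' @param model A `dermrank_model`.
#' @param x Batch array in (C, H, W, N) layout, channels first.
#' @param params Parameter list to use: the student (`model$params`,
#'   default) or the teacher (`model$teacher`).
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `disease_logits` (2 x N; row 1 is the melanoma logit
#'   f), `feature_logits` (3 x N), `trunk` (features x N) and, if
#'   requested, `caches`.
#' @export
model_forward <- function(model, x, params = model$params,
                          keep_cache = FALSE) {
  # inputs are intensities in [0, 1]; center them so the first layer sees
  # a roughly zero-mean signal (keeps plain SGD well behaved without
  # normalization layers)
  r <- net_forward(model$net, params, x - 0.5, keep_cache = keep_cache)
  feats <- r$out
  list(disease_logits = params$head_d.W %*% feats + params$head_d.b,
       feature_logits = params$head_f.W %*% feats + params$head_f.b,
       trunk = feats,
       caches = if (keep_cache) r$caches)
}

# Backward pass: head-logit gradients in, parameter gradients out.
model_backward <- function(model, x, fwd, d_disease, d_feature,
                           params = model$params) {
  feats <- fwd$trunk
  grads <- list(
    head_d.W = d_disease %*% t(feats), head_d.b = rowSums(d_disease),
    head_f.W = d_feature %*% t(feats), head_f.b = rowSums(d_feature))
  dfeats <- crossprod(params$head_d.W, d_disease) +
            crossprod(params$head_f.W, d_feature)
  r <- net_backward(model$net, params, fwd$caches, dfeats)
  c(grads, r$grads)
}

#' Update the teacher by exponential moving average
#'
#' Applies `teacher <- alpha * teacher + (1 - alpha) * student` to every
#' parameter.  `alpha = 1` leaves the teacher untouched; `alpha = 0` copies
#' the student.
#'
#' @param model A `dermrank_model`.
#' @param alpha Decay in `[0, 1]`; defaults to the model's `ema_decay`.
#' @return The model with an updated teacher.
#' @export
ema_update <- function(model, alpha = model$ema_decay) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(lapply(model$teacher, dim), lapply(model$params, dim)))
    stop("teacher/student parameter shapes diverged")
  model$teacher <- mapply(function(t, s) alpha * t + (1 - alpha) * s,
                          model$teacher, model$params, SIMPLIFY = FALSE)
  model
}

# Random horizontal/vertical flips, drawn independently per image from the
# current RNG stream.  This is the label-preserving input perturbation that
# makes the student and teacher views differ in the mean-teacher scheme.
augment_batch <- function(x) {
  d <- dim(x)
  n <- d[4]
  hflip <- runif(n) < 0.5
  vflip <- runif(n) < 0.5
  for (i in seq_len(n)) {
    if (!hflip[i] && !vflip[i]) next
    img <- x[, , , i, drop = FALSE]
    dim(img) <- d[1:3]
    if (hflip[i]) img <- img[, , rev(seq_len(d[3])), drop = FALSE]
    if (vflip[i]) img <- img[, rev(seq_len(d[2])), , drop = FALSE]
    x[, , , i] <- img
  }
  x
}

#' Save / load a training checkpoint
#'
#' Self-describing checkpoint holding student and teacher parameters, the
#' step counter, the backbone name and a format version.
#'
#' @param model A `dermrank_model`.
#' @param path Destination file.
#' @return `path` (for `save_checkpoint`), or the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "dermrank-checkpoint-v1", backbone = model$backbone,
               model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dermrank-checkpoint-v1"))
    stop("not a dermrank checkpoint: ", path)
  obj$model
}
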