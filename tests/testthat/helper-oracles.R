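# Independent brute-force oracles.  These deliberately follow the
# unsimplified textbook formulas (explicit pair/element loops, naive
# probability arithmetic) and share no code with the package internals.

oracle_ranking_loss <- function(f, s) {
  n <- length(f)
  total <- 0
  npairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    o <- f[i] - f[j]
    P <- 1 / (1 + exp(-o))
    Pbar <- if (s[i] > s[j]) 1 else if (s[i] < s[j]) 0 else 0.5
    total <- total - Pbar * log(P) - (1 - Pbar) * log(1 - P)
    npairs <- npairs + 1
  }
  total / npairs
}

oracle_disease_ce <- function(logits, labels) {
  n <- ncol(logits)
  total <- 0
  for (i in 1:n) {
    z <- logits[, i]
    p <- exp(z) / sum(exp(z))
    cls <- if (labels[i] == 1) 1 else 2   # row 1 = melanoma
    total <- total - log(p[cls])
  }
  total / n
}

oracle_feature_bce <- function(logits, labels, w = c(1, 1, 1)) {
  wn <- 3 * w / sum(w)
  per_feat <- numeric(3)
  for (k in 1:3) {
    tot <- 0
    for (i in seq_len(ncol(logits))) {
      p <- 1 / (1 + exp(-logits[k, i]))
      tot <- tot - labels[k, i] * log(p) - (1 - labels[k, i]) * log(1 - p)
    }
    per_feat[k] <- tot / ncol(logits)
  }
  sum(wn * per_feat) / 3
}

oracle_consistency_mse <- function(st, te) {
  n <- ncol(st$disease_logits)
  tot <- 0
  for (i in 1:n) {
    ps <- exp(st$disease_logits[, i]); ps <- ps / sum(ps)
    pt <- exp(te$disease_logits[, i]); pt <- pt / sum(pt)
    qs <- 1 / (1 + exp(-st$feature_logits[, i]))
    qt <- 1 / (1 + exp(-te$feature_logits[, i]))
    tot <- tot + sum((ps - pt)^2) + sum((qs - qt)^2)
  }
  tot / (5 * n)
}

oracle_auc <- function(scores, truth) {
  pos <- which(truth == 1); neg <- which(truth == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

oracle_gray_world <- function(px) {
  e <- c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]))
  d <- e / sqrt(sum(e^2))
  1 / (sqrt(3) * d)
}

oracle_max_rgb <- function(px) {
  e <- c(max(px[, , 1]), max(px[, , 2]), max(px[, , 3]))
  d <- e / sqrt(sum(e^2))
  1 / (sqrt(3) * d)
}

# Radial asymmetry statistic: mean absolute difference between the maximal
# lesion radius at opposite angles, relative to the mean radius.  Zero for
# any centrally symmetric lesion shape.
radial_asym_stat <- function(px, nbins = 16) {
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  # lesion mask: darker than the midpoint of the (robust) luminance range
  thr <- 0.5 * (quantile(lum, 0.02) + quantile(lum, 0.98))
  mask <- lum < thr
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)
  rad <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  bin <- floor((ang + pi) / (2 * pi) * nbins) %% nbins
  rmax <- vapply(0:(nbins - 1), function(b) {
    v <- rad[bin == b]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  opp <- ((0:(nbins - 1)) + nbins / 2) %% nbins + 1
  mean(abs(rmax - rmax[opp]), na.rm = TRUE) / mean(rmax, na.rm = TRUE)
}

# 4x4 mean-pool each channel of a 64x64x3 image into a length-768 vector.
downsample_pixels <- function(px) {
  out <- numeric(16 * 16 * 3)
  k <- 1
  for (ch in 1:3) {
    m <- px[, , ch]
    dim(m) <- c(4, 16, 64)
    m2 <- t(apply(m, c(2, 3), mean))
    dim(m2) <- c(4, 16, 16)
    out[k:(k + 255)] <- as.vector(apply(m2, c(2, 3), mean))
    k <- k + 256
  }
  out
}

# Random model-output pair for loss oracle tests.
random_outputs <- function(n, scale = 2) {
  list(disease_logits = matrix(rnorm(2 * n, sd = scale), 2, n),
       feature_logits = matrix(rnorm(3 * n, sd = scale), 3, n))
}
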