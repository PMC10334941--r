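#' Configuration for the synthetic lesion generator
#'
#' The generator emulates the structure of a dermoscopic study set: a small
#' pool with checklist-feature annotations plus disease labels, a larger
#' pool carrying disease labels only, and a separately annotated holdout
#' partition.  Defaults mirror that design at desk scale: 900 annotated
#' images balanced 450/450 between melanoma and nevus, a 2000-image
#' unannotated pool, and a 400-image holdout.
#'
#' Disease is tied to the three checklist features through a logistic link
#' on the checklist score s in 0..3: P(melanoma) = plogis(beta0 + beta1*s),
#' so the triage rule "higher score, higher risk" is true by construction.
#' An optional melanoma-specific darkening cue (independent of the three
#' features) lets disease accuracy exceed the checklist ceiling, so the
#' disease head is not redundant with the feature heads.
#'
#' @param image_size Pixels per side (square images), at least 32.
#' @param n_labeled Number of feature-annotated images.
#' @param n_unlabeled Number of images carrying only a disease label.
#' @param holdout_size Number of fully annotated holdout images.
#' @param class_balance Fraction of melanoma in the labeled set.
#' @param feature_prevalence Length-3 vector of marginal probabilities for
#'   asymmetry, atypical network and blue-white structure (independent).
#' @param score_logit_intercept,score_logit_slope Logistic-link parameters
#'   beta0 and beta1 for P(melanoma | score).
#' @param direct_cue_strength Strength in `[0, 1]` of the melanoma-specific
#'   lesion darkening that is independent of the checklist features.
#' @param illumination_cast_range Maximum per-channel multiplicative tint:
#'   channel gains are drawn uniformly from `[1 - range, 1]`, so casts dim
#'   and tint but never clip highlights.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   dataset.
#' @return A validated config object of class `dermrank_synthetic_config`.
#' @export
synthetic_config <- function(image_size = 64, n_labeled = 900,
                             n_unlabeled = 2000, holdout_size = 400,
                             class_balance = 0.5,
                             feature_prevalence = c(0.5, 0.5, 0.5),
                             score_logit_intercept = -2.2,
                             score_logit_slope = 1.5,
                             direct_cue_strength = 0.6,
                             illumination_cast_range = 0.25,
                             seed = 1L) {
  stopifnot(image_size >= 32, n_labeled >= 0, n_unlabeled >= 0,
            holdout_size >= 0, class_balance >= 0, class_balance <= 1,
            length(feature_prevalence) == 3,
            all(feature_prevalence >= 0 & feature_prevalence <= 1),
            direct_cue_strength >= 0, direct_cue_strength <= 1,
            illumination_cast_range >= 0, illumination_cast_range < 1)
  structure(list(image_size = as.integer(image_size),
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 holdout_size = as.integer(holdout_size),
                 class_balance = class_balance,
                 feature_prevalence = feature_prevalence,
                 score_logit_intercept = score_logit_intercept,
                 score_logit_slope = score_logit_slope,
                 direct_cue_strength = direct_cue_strength,
                 illumination_cast_range = illumination_cast_range,
                 seed = as.integer(seed)),
            class = "dermrank_synthetic_config")
}

#' Construct a lesion image object
#'
#' @param pixels H x W x 3 array of intensities in `[0, 1]`.
#' @param image_id Identifier string.
#' @return An object of class `lesion_image`.
#' @export
lesion_image <- function(pixels, image_id = "img") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(is.finite(pixels)), min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, image_id = image_id, color_space = "RGB"),
            class = "lesion_image")
}

#' @export
print.lesion_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<lesion_image %s: %dx%d RGB, range [%.3f, %.3f]>\n",
              x$image_id, d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Soft edge used for every rendered boundary so masks are antialiased and
# the half-area asymmetry statistic is stable under resampling.
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Render one synthetic lesion image
#'
#' Draws a skin-tone background with one elliptical lesion and embeds the
#' requested checklist cues: asymmetry enlarges the boundary radius on one
#' half of the lesion, an atypical network overlays a darker reticular mesh
#' on part of the lesion, and a blue-white structure places a blue-gray
#' blob inside it.  A per-image multiplicative color cast is applied last,
#' so the color-constancy stage has real work to do.  All randomness comes
#' from the current R RNG state.
#'
#' @param features Length-3 binary vector (asymmetry, network, blue-white).
#' @param image_size Pixels per side, at least 32.
#' @param melanoma_cue Darkening in `[0, 1]` applied to the lesion body
#'   (the disease-specific cue, usually `direct_cue_strength * disease`).
#' @param cast_range Maximum fractional dimming of the per-channel cast.
#' @param image_id Identifier stored in the result.
#' @return A `lesion_image` whose attributes `cast_gains` (length-3 gains
#'   `<= 1`) allow exact recovery of the cast-free image (gains never clip).
#' @export
render_lesion <- function(features, image_size = 64, melanoma_cue = 0,
                          cast_range = 0.25, image_id = "img") {
  features <- as.integer(features)
  if (length(features) != 3 || any(!features %in% c(0L, 1L)))
    stop("`features` must be three binary flags")
  if (image_size < 32)
    stop("image_size must be >= 32 to render all checklist cues")
  S <- as.integer(image_size)

  # Fixed draw order, all draws unconditional, so a seed pins the geometry
  # regardless of which cues are switched on.
  cx   <- runif(1, -0.08, 0.08)
  cy   <- runif(1, -0.08, 0.08)
  r0   <- runif(1, 0.42, 0.55)
  arat <- runif(1, 0.78, 0.98)
  phi  <- runif(1, 0, 2 * pi)
  psi  <- runif(1, 0, 2 * pi)    # asymmetry axis
  mesh_phase <- runif(2, 0, 2 * pi)
  mesh_freq  <- runif(2, 6.0, 8.0)
  blob_ang <- runif(1, 0, 2 * pi)
  blob_rad <- runif(1, 0.20, 0.42)
  blob_sz  <- runif(1, 0.34, 0.46)
  gains <- runif(3, 1 - cast_range, 1)
  noise <- rnorm(S * S * 3, sd = 0.02)

  ax <- seq(-1, 1, length.out = S)
  X <- matrix(rep(ax, each = S), S, S)   # column coordinate (width)
  Y <- matrix(rep(ax, times = S), S, S)  # row coordinate (height)
  dx <- X - cx; dy <- Y - cy
  u <-  dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  rho <- sqrt(u^2 + (v / arat)^2)
  theta <- atan2(dy, dx)

  delta <- if (features[1] == 1) 0.5 else 0
  redge <- r0 * (1 + delta * plogis(8 * sin(theta - psi)))
  alpha <- smoothstep((redge - rho) / 0.05)

  skin <- c(0.85, 0.66, 0.55)
  body <- c(0.46, 0.31, 0.23) * (1 - 0.30 * melanoma_cue)

  px <- array(0, c(S, S, 3))
  for (ch in 1:3) px[, , ch] <- skin[ch] * (1 - alpha) + body[ch] * alpha

  if (features[2] == 1) {
    mesh <- sin(mesh_freq[1] * pi * u + mesh_phase[1]) *
            sin(mesh_freq[2] * pi * v + mesh_phase[2])
    lines_mask <- smoothstep((abs(mesh) - 0.32) / 0.15) *
      smoothstep((0.95 * redge - rho) / 0.05)
    dark <- 1 - 0.5 * lines_mask * alpha
    for (ch in 1:3) px[, , ch] <- px[, , ch] * dark
  }

  if (features[3] == 1) {
    bx <- cx + blob_rad * r0 * cos(blob_ang)
    by <- cy + blob_rad * r0 * sin(blob_ang)
    bd <- sqrt((X - bx)^2 + (Y - by)^2)
    balpha <- smoothstep((blob_sz * r0 - bd) / 0.05) * alpha
    blue <- c(0.42, 0.52, 0.75)
    for (ch in 1:3)
      px[, , ch] <- px[, , ch] * (1 - 0.9 * balpha) + blue[ch] * 0.9 * balpha
  }

  px <- px + array(noise, c(S, S, 3))
  px <- pmin(pmax(px, 0), 1)
  # White-balance the pre-cast render to equal Minkowski-6 channel means:
  # the cast-free reference then has "calibrated camera" semantics, and
  # Shades of Gray correction of the tinted image can recover it (the
  # correction would otherwise neutralize the intrinsic skin tone together
  # with the cast).
  e <- vapply(1:3, function(ch) mean(px[, , ch]^6)^(1 / 6), numeric(1))
  wb <- exp(mean(log(e))) / e
  for (ch in 1:3) px[, , ch] <- px[, , ch] * wb[ch]
  cast_free <- pmin(pmax(px, 0), 1)
  tinted <- cast_free
  for (ch in 1:3) tinted[, , ch] <- tinted[, , ch] * gains[ch]

  img <- lesion_image(tinted, image_id)
  attr(img, "cast_gains") <- gains
  img
}

#' Recover the cast-free image from a rendered lesion
#'
#' The cast gains are at most 1, so the tint never clips and dividing by
#' the stored gains restores the pre-cast render exactly.
#'
#' @param img A `lesion_image` produced by [render_lesion()].
#' @return A `lesion_image` without the illumination cast.
#' @export
cast_free_reference <- function(img) {
  g <- attr(img, "cast_gains")
  if (is.null(g)) stop("image carries no cast_gains attribute")
  px <- img$pixels
  for (ch in 1:3) px[, , ch] <- px[, , ch] / g[ch]
  lesion_image(pmin(px, 1), paste0(img$image_id, "_castfree"))
}

#' Draw a disease label from a checklist score
#'
#' Melanoma is drawn with probability `plogis(beta0 + beta1 * score)`; the
#' probability is strictly increasing in the score whenever `beta1 > 0`,
#' encoding the triage rule that a higher checklist score means a higher
#' melanoma risk.
#'
#' @param score Integer checklist score(s) in 0..3 (vectorized).
#' @param config A [synthetic_config()] holding beta0 and beta1.
#' @return Binary label(s): 1 = melanoma, 0 = melanocytic nevus.
#' @export
sample_disease <- function(score, config = synthetic_config()) {
  if (any(!score %in% 0:3)) stop("score must be in 0..3")
  p <- plogis(config$score_logit_intercept +
              config$score_logit_slope * score)
  rbinom(length(score), 1, p)
}

draw_sample_labels <- function(config) {
  f <- as.integer(runif(3) < config$feature_prevalence)
  s <- sum(f)
  list(features = f, score = s,
       disease = sample_disease(s, config))
}

#' Generate a complete synthetic study set
#'
#' Emits `n_labeled` feature-annotated samples (split 80/20 into train and
#' validation, stratified by disease), `n_unlabeled` samples whose feature
#' annotations are withheld from the manifest (ground truth is retained
#' internally for evaluation), and a fully annotated holdout partition.
#' Class balance in the labeled set is enforced by quota sampling; if a
#' quota cannot be filled the manifest summary carries a warning and the
#' balance is best-effort.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `dermrank_dataset`: list with `images`
#'   (H x W x 3 x N array in `[0, 1]`), `manifest` (data frame with feature
#'   columns `NA` for unlabeled rows), `truth` (full ground truth incl.
#'   withheld features), `cast_gains` (3 x N), `config`, `config_hash`, and
#'   `summary` (counts and warnings).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "dermrank_synthetic_config"))
  set_seed(derive_seed(config$seed, 1))

  n_mel <- round(config$n_labeled * config$class_balance)
  n_nev <- config$n_labeled - n_mel
  warnings <- character()

  labeled <- vector("list", config$n_labeled)
  got_mel <- 0L; got_nev <- 0L; filled <- 0L
  attempts <- 0L; max_attempts <- 200L * max(config$n_labeled, 1L)
  while (filled < config$n_labeled && attempts < max_attempts) {
    attempts <- attempts + 1L
    d <- draw_sample_labels(config)
    if (d$disease == 1 && got_mel < n_mel) {
      got_mel <- got_mel + 1L
    } else if (d$disease == 0 && got_nev < n_nev) {
      got_nev <- got_nev + 1L
    } else next
    filled <- filled + 1L
    labeled[[filled]] <- d
  }
  if (filled < config$n_labeled) {
    warnings <- c(warnings, sprintf(
      "class_balance %.2f unreachable: filled %d/%d labeled samples",
      config$class_balance, filled, config$n_labeled))
    while (filled < config$n_labeled) {  # best effort: unconstrained draws
      filled <- filled + 1L
      labeled[[filled]] <- draw_sample_labels(config)
    }
  }

  unlabeled <- replicate(config$n_unlabeled, draw_sample_labels(config),
                         simplify = FALSE)
  holdout <- replicate(config$holdout_size, draw_sample_labels(config),
                       simplify = FALSE)

  all_draws <- c(labeled, unlabeled, holdout)
  n_total <- length(all_draws)
  pool <- c(rep("labeled", config$n_labeled),
            rep("unlabeled", config$n_unlabeled),
            rep("holdout", config$holdout_size))

  # 80/20 train/val inside the labeled pool, stratified by disease.
  split <- character(n_total)
  split[pool == "unlabeled"] <- "train"
  split[pool == "holdout"] <- "holdout"
  lab_idx <- which(pool == "labeled")
  lab_dis <- vapply(all_draws[lab_idx], `[[`, integer(1), "disease")
  for (cls in unique(lab_dis)) {
    ids <- lab_idx[lab_dis == cls]
    ids <- ids[sample.int(length(ids))]
    n_val <- round(length(ids) * 0.2)
    split[ids[seq_len(n_val)]] <- "val"
    split[setdiff(ids, ids[seq_len(n_val)])] <- "train"
  }

  S <- config$image_size
  images <- array(0, c(S, S, 3, n_total))
  cast_gains <- matrix(0, 3, n_total)
  ids <- sprintf("syn%05d", seq_len(n_total))
  for (i in seq_len(n_total)) {
    set_seed(derive_seed(config$seed, 1000 + i))
    img <- render_lesion(all_draws[[i]]$features, S,
                         melanoma_cue = config$direct_cue_strength *
                           all_draws[[i]]$disease,
                         cast_range = config$illumination_cast_range,
                         image_id = ids[i])
    images[, , , i] <- img$pixels
    cast_gains[, i] <- attr(img, "cast_gains")
  }

  feat <- t(vapply(all_draws, `[[`, integer(3), "features"))
  truth <- data.frame(
    image_id = ids,
    split = split,
    labeled = pool != "unlabeled",
    disease = vapply(all_draws, `[[`, integer(1), "disease"),
    asymmetry = feat[, 1], network = feat[, 2], bluewhite = feat[, 3],
    score = vapply(all_draws, `[[`, integer(1), "score"),
    stringsAsFactors = FALSE)

  manifest <- truth[c("image_id", "split", "labeled", "disease",
                      "asymmetry", "network", "bluewhite")]
  manifest$path <- paste0(manifest$image_id, ".png")
  manifest[!manifest$labeled, c("asymmetry", "network", "bluewhite")] <- NA
  manifest <- manifest[c("image_id", "path", "split", "labeled", "disease",
                         "asymmetry", "network", "bluewhite")]

  structure(list(images = images, manifest = manifest, truth = truth,
                 cast_gains = cast_gains, config = config,
                 config_hash = config_hash(unclass(config)),
                 summary = list(
                   n_total = n_total,
                   n_labeled = config$n_labeled,
                   n_unlabeled = config$n_unlabeled,
                   n_holdout = config$holdout_size,
                   n_melanoma_labeled = sum(truth$disease[pool == "labeled"]),
                   warnings = warnings)),
            class = "dermrank_dataset")
}

#' @export
print.dermrank_dataset <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<dermrank_dataset: %d images (%d labeled / %d ",
                     "unlabeled / %d holdout), %dpx, hash %s>\n"),
              s$n_total, s$n_labeled, s$n_unlabeled, s$n_holdout,
              x$config$image_size, substr(x$config_hash, 1, 8)))
  if (length(s$warnings)) cat("  warning:", s$warnings, "\n")
  invisible(x)
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Feature cells are written empty for unlabeled rows, mirroring a study
#' manifest whose unannotated pool carries only the disease label.
#'
#' @param dataset A `dermrank_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dermrank_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(dataset$images)[4]
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[, , , i],
                  file.path(dir, dataset$manifest$path[i]))
  }
  write_manifest(dataset$manifest, file.path(dir, "manifest.csv"))
  summ <- c(sprintf("config_hash: %s", dataset$config_hash),
            dataset$summary$warnings)
  writeLines(summ, file.path(dir, "summary.txt"))
  invisible(file.path(dir, "manifest.csv"))
}

# Extract images for a set of manifest row indices as a (C, H, W, N) batch,
# the layout the network kernels expect.
dataset_batch <- function(dataset, idx) {
  x <- dataset$images[, , , idx, drop = FALSE]
  aperm(x, c(3, 1, 2, 4))
}
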