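#' Preprocessing configuration
#'
#' The chain runs, in order: center crop + resize, Shades of Gray color
#' constancy, then CLAHE on the lightness channel.  Stages can be disabled
#' or reordered for ablation.  All stages operate in floating point; images
#' are quantized once, on write.
#'
#' @param target_size Output side length in pixels.
#' @param minkowski_p Minkowski exponent of the Shades of Gray illuminant
#'   estimate; `p = 1` is Gray World, large `p` approaches max-RGB.  The
#'   default 6 is the canonical setting in the dermoscopy color-constancy
#'   literature.
#' @param clahe_clip_limit Histogram clip limit as a multiple of the mean
#'   bin count (> 0).
#' @param clahe_tile_grid Integer pair: tiles along rows and columns.
#' @param enabled_stages Ordered character subset of
#'   `c("crop_resize", "color_constancy", "clahe")`.
#' @return A `dermrank_preprocess_config` object.
#' @export
preprocess_config <- function(target_size = 64, minkowski_p = 6,
                              clahe_clip_limit = 2,
                              clahe_tile_grid = c(8L, 8L),
                              enabled_stages = c("crop_resize",
                                                 "color_constancy",
                                                 "clahe")) {
  stopifnot(target_size > 0, minkowski_p >= 1, clahe_clip_limit > 0,
            length(clahe_tile_grid) == 2, all(clahe_tile_grid >= 1),
            all(enabled_stages %in% c("crop_resize", "color_constancy",
                                      "clahe")))
  structure(list(target_size = as.integer(target_size),
                 minkowski_p = minkowski_p,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 enabled_stages = enabled_stages),
            class = "dermrank_preprocess_config")
}

as_pixels <- function(image) {
  if (inherits(image, "lesion_image")) image$pixels
  else if (is.array(image) && length(dim(image)) == 3) image
  else stop("expected a lesion_image or an H x W x 3 array")
}

rewrap <- function(image, pixels) {
  if (inherits(image, "lesion_image")) {
    image$pixels <- pixels
    image
  } else pixels
}

#' Center crop and resize to a square
#'
#' Takes the largest centered square crop (preserving the lesion-bearing
#' central region under the usual dermoscopic framing) and resamples it to
#' `target_size` with a bilinear kernel.  A square input already at the
#' target size is returned unchanged.
#'
#' @param image A `lesion_image` or H x W x 3 array.
#' @param target_size Output side length in pixels.
#' @return Same type as the input, `target_size` x `target_size` x 3.
#' @export
crop_resize <- function(image, target_size) {
  px <- as_pixels(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < 2 || w < 2) stop("image smaller than 2 px in a dimension")
  side <- min(h, w)
  r0 <- floor((h - side) / 2)
  c0 <- floor((w - side) / 2)
  px <- px[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  if (side != target_size) {
    px <- EBImage::resize(px, w = target_size, h = target_size,
                          filter = "bilinear")
    px <- pmin(pmax(px, 0), 1)
  }
  rewrap(image, px)
}

#' Shades of Gray illuminant estimate
#'
#' Estimates the scene illuminant as the per-channel Minkowski mean
#' `e_c = (mean(I_c^p))^(1/p)`, normalizes it to unit L2 norm, and returns
#' the per-channel gains that map the estimated illuminant to neutral gray
#' (a uniformly gray image yields gains of exactly 1).
#'
#' @param image A `lesion_image` or H x W x 3 array.
#' @param p Minkowski exponent, at least 1.
#' @return Length-3 vector of channel gains (R, G, B).
#' @export
estimate_illuminant <- function(image, p = 6) {
  if (p < 1) stop("Minkowski exponent p must be >= 1")
  px <- as_pixels(image)
  e <- numeric(3)
  for (ch in 1:3) {
    v <- px[, , ch]
    m <- max(v)
    if (m <= 0) stop("channel ", ch, " is all zero; illuminant undefined")
    # factor out the max so large p cannot overflow
    e[ch] <- m * mean((v / m)^p)^(1 / p)
  }
  d <- e / sqrt(sum(e^2))
  1 / (sqrt(3) * d)
}

#' Apply illuminant correction gains
#'
#' Multiplies each channel by its gain.  With `clip = TRUE` (default) the
#' result is clipped to `[0, 1]`; pre-clipping values can be requested for
#' diagnostics (the corrected image then has exactly equal per-channel
#' Minkowski means).
#'
#' @param image A `lesion_image` or H x W x 3 array.
#' @param gains Length-3 positive gains from [estimate_illuminant()].
#' @param clip Clip the result to the valid range.
#' @return Corrected image, same type as the input.
#' @export
apply_illuminant <- function(image, gains, clip = TRUE) {
  if (length(gains) != 3 || any(gains <= 0)) stop("gains must be 3 positive values")
  px <- as_pixels(image)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * gains[ch]
  if (clip) px <- pmin(pmax(px, 0), 1)
  rewrap(image, px)
}

# sRGB <-> CIE Lab via grDevices, on an n x 3 matrix in [0,1].
srgb_to_lab <- function(m) grDevices::convertColor(m, from = "sRGB", to = "Lab")
lab_to_srgb <- function(m) grDevices::convertColor(m, from = "Lab", to = "sRGB")

# Clipped-histogram equalization mapping for one tile: 256-bin histogram,
# clipped at clip_limit times the mean count, excess redistributed evenly,
# then the CDF rescaled to 0..255.  Nondecreasing by construction.
clahe_tile_map <- function(bins, npix, clip_limit) {
  h <- tabulate(bins + 1L, nbins = 256L)
  clip <- clip_limit * npix / 256
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / 256
  cdf <- cumsum(h)
  255 * cdf / npix
}

#' Contrast-limited adaptive histogram equalization on lightness
#'
#' Converts to CIE Lab, equalizes the L channel with per-tile clipped
#' histograms and bilinear interpolation between tile mappings, and
#' converts back; chroma is preserved up to the conversion round trip.
#'
#' @param image A `lesion_image` or H x W x 3 array.
#' @param clip_limit Clip limit as a multiple of the mean bin count.
#' @param tile_grid Integer pair: number of tiles along rows and columns.
#' @return Equalized image, same type as the input.
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8L, 8L)) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  px <- as_pixels(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  gh <- as.integer(tile_grid[1]); gw <- as.integer(tile_grid[2])
  if (gh > h || gw > w) stop("tile grid larger than the image")

  lab <- srgb_to_lab(matrix(px, ncol = 3))
  L <- matrix(lab[, 1], h, w)
  bins <- matrix(pmin(255L, pmax(0L, as.integer(floor(L / 100 * 256)))), h, w)

  rb <- round(seq(0, h, length.out = gh + 1))
  cb <- round(seq(0, w, length.out = gw + 1))
  maps <- array(0, c(256, gh, gw))
  for (ti in seq_len(gh)) for (tj in seq_len(gw)) {
    rows <- (rb[ti] + 1):rb[ti + 1]
    cols <- (cb[tj] + 1):cb[tj + 1]
    tb <- bins[rows, cols]
    maps[, ti, tj] <- clahe_tile_map(as.vector(tb), length(tb), clip_limit)
  }

  # Bilinear interpolation between the four surrounding tile mappings.
  interp_index <- function(pos, bounds, g) {
    centers <- (bounds[-1] + bounds[-(g + 1)] + 1) / 2  # 1-based centers
    lo <- findInterval(pos, centers)
    i1 <- pmax(lo, 1L); i2 <- pmin(lo + 1L, g)
    wgt <- ifelse(lo < 1, 0, ifelse(lo >= g, 1,
      (pos - centers[i1]) / pmax(centers[i2] - centers[i1], 1e-12)))
    # wgt is the weight of tile i2 (0 when clamped below, 1 above)
    wgt[lo < 1] <- 0
    list(i1 = i1, i2 = i2, w = wgt)
  }
  ri <- interp_index(seq_len(h), rb, gh)
  ci <- interp_index(seq_len(w), cb, gw)

  B <- as.vector(bins) + 1L
  R1 <- rep(ri$i1, times = w); R2 <- rep(ri$i2, times = w)
  WR <- rep(ri$w, times = w)
  C1 <- rep(ci$i1, each = h); C2 <- rep(ci$i2, each = h)
  WC <- rep(ci$w, each = h)
  newL <- (1 - WR) * (1 - WC) * maps[cbind(B, R1, C1)] +
          (1 - WR) * WC       * maps[cbind(B, R1, C2)] +
          WR       * (1 - WC) * maps[cbind(B, R2, C1)] +
          WR       * WC       * maps[cbind(B, R2, C2)]

  lab[, 1] <- newL / 255 * 100
  out <- lab_to_srgb(lab)
  out <- pmin(pmax(out, 0), 1)
  rewrap(image, array(out, dim(px)))
}

#' Run the configured preprocessing chain on one image
#'
#' @param image A `lesion_image` or H x W x 3 array.
#' @param config A [preprocess_config()].
#' @return The processed image; the estimated illuminant gains are attached
#'   as attribute `illuminant_gains` when the color-constancy stage ran.
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "dermrank_preprocess_config"))
  gains <- NULL
  for (stage in config$enabled_stages) {
    image <- switch(stage,
      crop_resize = crop_resize(image, config$target_size),
      color_constancy = {
        gains <- estimate_illuminant(image, config$minkowski_p)
        apply_illuminant(image, gains)
      },
      clahe = clahe(image, config$clahe_clip_limit, config$clahe_tile_grid))
  }
  if (!is.null(gains)) attr(image, "illuminant_gains") <- gains
  image
}

#' Preprocess every image of a synthetic dataset in memory
#'
#' @param dataset A `dermrank_dataset`.
#' @param config A [preprocess_config()].
#' @return The dataset with processed images; the per-image illuminant
#'   gains (when estimated) are stored in `$illuminant_log`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "dermrank_dataset"))
  n <- dim(dataset$images)[4]
  log <- matrix(NA_real_, 3, n)
  out <- NULL
  for (i in seq_len(n)) {
    img <- preprocess_image(dataset$images[, , , i], config)
    if (is.null(out)) out <- array(0, c(dim(img)[1:3], n))
    out[, , , i] <- img
    g <- attr(img, "illuminant_gains")
    if (!is.null(g)) log[, i] <- g
  }
  dataset$images <- out
  dataset$illuminant_log <- log
  dataset$preprocess_config <- config
  dataset
}
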