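# Stochastic augmentation chain for contrastive view generation.
#
# Stages fire independently, each with its own probability, in a fixed
# order: (1) channel jitter, (2) rotation, (3) horizontal flip, (4) vertical
# flip, (5) translation, (6) Gaussian blur, (7) random crop-and-resize.
# Geometric stages transform all 5 channels coherently (contiguous affine
# stages are composed into a single resampling pass; the mask channel is
# sampled nearest-neighbour and re-binarized). Photometric stages touch only
# the 4 IF channels; the mask encodes identity, not signal, and is never
# jittered or blurred.

#' Augmentation configuration
#'
#' Defaults follow the view-generation recipe used for training the
#' encoder: channel jitter (brightness 0.4, contrast 0.4, saturation 0.4,
#' hue 0.2), rotation uniform in \[-180, 180\] degrees, horizontal/vertical
#' flips, translation up to 15 px per axis, Gaussian blur with a 3-pixel
#' kernel and sigma uniform in \[0.5, 3\], and random crop to 50-100% of the
#' side length resized back to 75 x 75 — every stage with probability 0.5.
#'
#' Hue/saturation are defined on RGB images; on a 4-channel IF stack this
#' package implements "saturation" as a blend toward the per-pixel
#' cross-channel mean and "hue" as a small random invertible mixing among
#' the three non-DAPI channels (set `hue = 0` to disable the spectral
#' mixing).
#'
#' @param jitter_p,rotate_p,hflip_p,vflip_p,translate_p,blur_p,crop_p
#'   Per-stage apply probabilities in `[0, 1]`.
#' @param brightness,contrast,saturation,hue Jitter magnitudes.
#' @param translate_max Maximum |translation| per axis, pixels.
#' @param blur_sigma Range of the blur sigma.
#' @param crop_frac Range of the crop side fraction.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(jitter_p = 0.5, brightness = 0.4,
                                contrast = 0.4, saturation = 0.4, hue = 0.2,
                                rotate_p = 0.5, hflip_p = 0.5, vflip_p = 0.5,
                                translate_p = 0.5, translate_max = 15,
                                blur_p = 0.5, blur_sigma = c(0.5, 3),
                                crop_p = 0.5, crop_frac = c(0.5, 1)) {
  p <- c(jitter_p, rotate_p, hflip_p, vflip_p, translate_p, blur_p, crop_p)
  if (any(p < 0 | p > 1)) stop("stage probabilities must lie in [0, 1]")
  if (length(blur_sigma) != 2 || any(blur_sigma <= 0) || diff(blur_sigma) < 0)
    stop("blur_sigma must be an increasing positive range")
  if (length(crop_frac) != 2 || any(crop_frac <= 0 | crop_frac > 1) ||
      diff(crop_frac) < 0)
    stop("crop_frac must be an increasing range in (0, 1]")
  structure(list(jitter_p = jitter_p, brightness = brightness,
                 contrast = contrast, saturation = saturation, hue = hue,
                 rotate_p = rotate_p, hflip_p = hflip_p, vflip_p = vflip_p,
                 translate_p = translate_p, translate_max = translate_max,
                 blur_p = blur_p, blur_sigma = blur_sigma, crop_p = crop_p,
                 crop_frac = crop_frac), class = "augmentation_config")
}

#' Identity augmentation configuration (all stage probabilities zero)
#' @export
no_augmentation <- function() {
  augmentation_config(jitter_p = 0, rotate_p = 0, hflip_p = 0, vflip_p = 0,
                      translate_p = 0, blur_p = 0, crop_p = 0)
}

.warp <- function(x, A, t) {
  Ainv <- solve(A)
  cpp_warp_affine(x, Ainv, t, c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

#' Apply the stochastic augmentation chain to a crop
#'
#' Uses the current R random stream; seed with `set.seed()` for
#' reproducible views.
#'
#' @param crop A [cell_crop()].
#' @param config An [augmentation_config()].
#' @return The augmented [cell_crop()] (75 x 75 x 5, binary mask channel).
#' @export
augment <- function(crop, config = augmentation_config()) {
  if (!inherits(config, "augmentation_config")) stop("malformed config")
  x <- unclass(crop)
  storage.mode(x) <- "double"

  # (1) channel jitter: photometric, IF channels only
  if (stats::runif(1) < config$jitter_p) {
    for (k in 1:4) {
      fb <- stats::runif(1, 1 - config$brightness, 1 + config$brightness)
      x[, , k] <- x[, , k] * fb
    }
    for (k in 1:4) {
      fc <- stats::runif(1, 1 - config$contrast, 1 + config$contrast)
      mu <- mean(x[, , k])
      x[, , k] <- mu + fc * (x[, , k] - mu)
    }
    fs <- stats::runif(1, 1 - config$saturation, 1 + config$saturation)
    m <- (x[, , 1] + x[, , 2] + x[, , 3] + x[, , 4]) / 4
    for (k in 1:4) x[, , k] <- m + fs * (x[, , k] - m)
    if (config$hue > 0) {
      s <- stats::runif(3, -config$hue, config$hue)
      S <- matrix(c(0, s[1], s[2], -s[1], 0, s[3], -s[2], -s[3], 0), 3, 3)
      M <- diag(3) + S
      v <- cbind(as.vector(x[, , 2]), as.vector(x[, , 3]), as.vector(x[, , 4]))
      v <- v %*% t(M)
      for (k in 1:3) x[, , k + 1] <- matrix(v[, k], 75, 75)
    }
    x[, , 1:4] <- pmin(pmax(x[, , 1:4], 0), 65535)
  }

  # (2)-(5): compose contiguous affine stages into one resampling pass
  A <- diag(2); tt <- c(0, 0); fired <- FALSE
  bump <- function(A2, t2) {
    A <<- A2 %*% A
    tt <<- as.vector(A2 %*% tt) + t2
    fired <<- TRUE
  }
  if (stats::runif(1) < config$rotate_p) {
    th <- stats::runif(1, -pi, pi)
    bump(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2), c(0, 0))
  }
  if (stats::runif(1) < config$hflip_p) bump(diag(c(1, -1)), c(0, 0))
  if (stats::runif(1) < config$vflip_p) bump(diag(c(-1, 1)), c(0, 0))
  if (stats::runif(1) < config$translate_p)
    bump(diag(2), stats::runif(2, -config$translate_max, config$translate_max))
  if (fired) x <- .warp(x, A, tt)

  # (6) Gaussian blur, 3-px kernel, IF channels only
  if (stats::runif(1) < config$blur_p) {
    sg <- stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
    for (k in 1:4) x[, , k] <- cpp_gauss_blur(x[, , k], sg, 1L)
  }

  # (7) random crop to 50-100% of the side, resized back to 75 x 75
  if (stats::runif(1) < config$crop_p) {
    f <- stats::runif(1, config$crop_frac[1], config$crop_frac[2])
    s <- f * 75
    maxoff <- (75 - s) / 2
    ctr_off <- stats::runif(2, -maxoff, maxoff)
    sc <- 75 / s
    x <- .warp(x, diag(c(sc, sc)), -sc * ctr_off)
  }

  x[, , 5] <- (x[, , 5] >= 0.5) * 1
  x[, , 1:4] <- pmin(pmax(x[, , 1:4], 0), 65535)
  cell_crop(x, cell_id = attr(crop, "cell_id"), frame = attr(crop, "frame"))
}

#' Two independent augmented views of the same crop
#'
#' @inheritParams augment
#' @return List of two [cell_crop()]s sharing the source cell id.
#' @export
make_view_pair <- function(crop, config = augmentation_config()) {
  list(augment(crop, config), augment(crop, config))
}
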