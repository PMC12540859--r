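# Engineered 368-dimension feature baseline: morphometry, intensity
# statistics and Haralick texture, computed on the masked pixels of a
# 75x75x5 crop. The exact layout is frozen in the manifest returned by
# feature_manifest() (also shipped as inst/extdata/engineered_manifest.csv).

.stat_names <- c("mean", "median", "sd", "mad", "min", "max",
                 "q05", "q25", "q75", "q95", "skew", "kurt")
.har_names <- c("asm", "contrast", "correlation", "variance", "idm",
                "sum_avg", "sum_var", "sum_entropy", "entropy",
                "diff_var", "diff_entropy", "imc1", "imc2")

.image_names <- function() {
  ch <- cyto_channels()
  pairs <- utils::combn(ch, 2, paste, collapse = "x")
  c(ch, pairs)
}

#' Manifest of the 368 engineered features
#'
#' The feature families follow the engineered baseline used throughout the
#' benchmarks: cell shape (area, eccentricity and companions), per-channel
#' and channel-pair-product intensity statistics (mean, median, sd and a
#' fixed quantile set), direction-averaged Haralick texture (13 statistics,
#' 64 fixed grey levels, offsets 1 and 2 px) and gradient-magnitude
#' statistics. The exact 368-item layout is this package's frozen
#' convention; byte-parity with any external feature package is a non-goal.
#'
#' @return data.frame with columns `index`, `name`, `family`, `image`.
#' @export
feature_manifest <- function() {
  imgs <- .image_names()
  ch <- cyto_channels()
  rows <- list(
    data.frame(family = "shape", image = "mask",
               name = c("area", "perimeter", "eccentricity", "major_axis",
                        "minor_axis", "solidity", "extent", "equiv_diameter")),
    data.frame(family = "mask_global", image = "mask",
               name = c("boundary_roughness", "center_offset")),
    data.frame(family = "wcentroid", image = rep(ch, each = 2),
               name = paste0(rep(ch, each = 2), "_wc_", c("dr", "dc"))),
    data.frame(family = "intensity", image = rep(imgs, each = 12),
               name = paste0(rep(imgs, each = 12), "_", .stat_names)),
    data.frame(family = "haralick",
               image = c(rep(ch, each = 26), rep(imgs[5:10], each = 13)),
               name = c(paste0(rep(ch, each = 26), "_har_",
                               rep(c(paste0(.har_names, "_s1"),
                                     paste0(.har_names, "_s2")), 4)),
                        paste0(rep(imgs[5:10], each = 13), "_har_",
                               .har_names, "_s1"))),
    data.frame(family = "gradient", image = rep(ch, each = 12),
               name = paste0(rep(ch, each = 12), "_grad_", .stat_names))
  )
  out <- do.call(rbind, rows)
  out <- data.frame(index = seq_len(nrow(out)), name = out$name,
                    family = out$family, image = out$image,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 368L, !anyDuplicated(out$name))
  out
}

#' Engineered 368-dimension feature vector of a crop
#'
#' Deterministic per crop: shape features depend only on the mask channel,
#' intensity/texture features only on the IF channels inside the mask
#' (intensities pre-scaled to `[0, 1]` by 1/65535). All 368 features are
#' invariant under horizontal and vertical flips.
#'
#' @param crop A [cell_crop()] (or any 75x75x5 array with a nonempty binary
#'   mask in channel 5).
#' @return Named numeric vector of length 368.
#' @export
engineered_features <- function(crop) {
  x <- unclass(crop)
  if (sum(x[, , 5]) == 0) stop("degenerate cell: empty mask")
  v <- cpp_engineered_features(x)
  names(v) <- feature_manifest()$name
  v
}

#' Engineered feature matrix for a set of crops
#'
#' @param crops List of [cell_crop()]s.
#' @return n x 368 matrix tagged with feature space `"engineered-368"`.
#' @export
engineered_feature_matrix <- function(crops) {
  m <- t(vapply(crops, function(cr) cpp_engineered_features(unclass(cr)),
                numeric(368)))
  colnames(m) <- feature_manifest()$name
  feature_matrix(m, "engineered-368")
}
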