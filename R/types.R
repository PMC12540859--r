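#' Core containers
#'
#' Light S3 wrappers over base arrays. An `if_frame` holds the four
#' co-registered 16-bit intensity planes of one scanner frame as an
#' H x W x 4 array (third dimension named by [cyto_channels()]); an
#' `instance_mask` is an integer matrix of per-pixel cell labels (0 =
#' background); a `cell_crop` is a 75 x 75 x 5 array (4 IF channels plus the
#' binary mask of the center cell).
#'
#' @param x Numeric array/matrix with the dimensions described above.
#' @param pixel_size Relative pixel scale tag (dimensionless, default 1).
#' @return The classed object.
#' @export
if_frame <- function(x, pixel_size = 1) {
  if (length(dim(x)) != 3L || dim(x)[3] != 4L)
    stop("an if_frame needs an H x W x 4 array")
  if (min(x) < 0 || max(x) > 65535)
    stop("intensities must lie in [0, 65535]")
  dimnames(x) <- list(NULL, NULL, cyto_channels())
  structure(x, pixel_size = pixel_size, class = "if_frame")
}

#' @rdname if_frame
#' @export
instance_mask <- function(x) {
  if (!is.matrix(x)) stop("an instance_mask is a matrix")
  if (any(x < 0) || any(x != round(x))) stop("labels must be non-negative integers")
  storage.mode(x) <- "integer"
  structure(x, class = "instance_mask")
}

#' @rdname if_frame
#' @param cell_id,frame Provenance tags for a crop.
#' @export
cell_crop <- function(x, cell_id = NA_integer_, frame = NA_integer_) {
  d <- dim(x)
  if (length(d) != 3L || d[1] != 75L || d[2] != 75L || d[3] != 5L)
    stop("a cell_crop is a 75 x 75 x 5 array")
  m <- x[, , 5]
  if (!all(m %in% c(0, 1))) stop("channel 5 must be a binary mask")
  dimnames(x) <- list(NULL, NULL, c(cyto_channels(), "mask"))
  structure(x, cell_id = cell_id, frame = frame, class = "cell_crop")
}

#' @export
print.if_frame <- function(x, ...) {
  d <- dim(x)
  cat("<if_frame> ", d[1], " x ", d[2], ", channels: ",
      paste(cyto_channels(), collapse = ", "),
      ", pixel_size = ", attr(x, "pixel_size"), "\n", sep = "")
  invisible(x)
}

#' @export
print.instance_mask <- function(x, ...) {
  cat("<instance_mask> ", nrow(x), " x ", ncol(x), ", ",
      length(setdiff(unique(as.vector(x)), 0L)), " objects\n", sep = "")
  invisible(x)
}

#' @export
print.cell_crop <- function(x, ...) {
  cat("<cell_crop> 75 x 75 x 5, cell_id = ", attr(x, "cell_id"),
      ", mask area = ", sum(x[, , 5]), " px\n", sep = "")
  invisible(x)
}

# Tag a feature matrix (cells x dims) with its space.
feature_matrix <- function(m, space = c("learned-128", "engineered-368")) {
  space <- match.arg(space)
  dim_expected <- if (space == "learned-128") 128L else 368L
  if (ncol(m) != dim_expected)
    stop(space, " feature matrices must have ", dim_expected, " columns")
  if (!all(is.finite(m))) stop("feature values must be finite")
  attr(m, "space") <- space
  m
}

#' Feature-space tag of a feature matrix
#' @param m A feature matrix produced by [encode()] or
#'   [engineered_features()].
#' @return `"learned-128"` or `"engineered-368"`.
#' @export
feature_space <- function(m) attr(m, "space")
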