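# Format adapters: 16-bit per-channel TIFF frames (one file per channel per
# frame, channel name in the filename), integer-label mask TIFFs, truth and
# feature tables. Integer artifacts round-trip bit-exactly; masks are stored
# as 32-bit float TIFF holding integer labels (exact below 2^24).

.frame_file <- function(frame, channel) sprintf("%04d_%s.tif", frame, channel)

#' Write a synthetic slide to a directory
#'
#' Frames are written per channel as 16-bit grayscale TIFF
#' (`{frame:04d}_{DAPI|CK|VIM|CD45CD31}.tif`), masks as
#' `{frame:04d}_mask.tif`, and the truth table as `truth.csv` with header
#' `cell_id,frame,row,col,phenotype,area`.
#'
#' @param slide A list from [generate_slide()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(slide$frames)) {
    fr <- slide$frames[[f]]
    for (k in seq_along(cyto_channels())) {
      tiff::writeTIFF(unclass(fr)[, , k] / 65535,
                      file.path(dir, .frame_file(f, cyto_channels()[k])),
                      bits.per.sample = 16)
    }
    write_mask(slide$masks[[f]], file.path(dir, sprintf("%04d_mask.tif", f)))
  }
  write.csv(slide$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_slide
#' @param mask An [instance_mask()].
#' @param path Output file.
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask)
  storage.mode(m) <- "double"
  if (max(m) >= 2^24) stop("labels above 2^24 cannot be stored exactly")
  tiff::writeTIFF(m / 2^24, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  instance_mask(matrix(as.integer(round(m * 2^24)), nrow(m), ncol(m)))
}

#' Read slide frames written by [write_slide()]
#'
#' @param dir Directory containing per-channel frame TIFFs.
#' @return List with `frames`, `masks` (if present), and `truth` (if
#'   present).
#' @export
read_slide <- function(dir) {
  files <- list.files(dir, pattern = "^[0-9]{4}_.*\\.tif$")
  if (!length(files)) stop("no frame TIFFs found in ", dir)
  fids <- sort(unique(as.integer(substr(files, 1, 4))))
  frames <- list(); masks <- list()
  for (f in fids) {
    planes <- lapply(cyto_channels(), function(ch) {
      p <- file.path(dir, .frame_file(f, ch))
      if (!file.exists(p)) stop("missing channel file ", basename(p),
                                " (channel-count mismatch)")
      round(tiff::readTIFF(p) * 65535)
    })
    shp <- unique(vapply(planes, function(p) paste(dim(p), collapse = "x"), ""))
    if (length(shp) != 1) stop("channel planes differ in shape for frame ", f)
    frames[[length(frames) + 1L]] <-
      if_frame(array(unlist(planes), c(dim(planes[[1]]), 4L)))
    mp <- file.path(dir, sprintf("%04d_mask.tif", f))
    if (file.exists(mp)) masks[[length(masks) + 1L]] <- read_mask(mp)
  }
  tp <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tp)) read_truth(tp) else NULL
  list(frames = frames, masks = if (length(masks)) masks else NULL,
       truth = truth)
}

#' Read a cell truth table
#'
#' @param path CSV with header `cell_id,frame,row,col,phenotype,area`.
#' @return data.frame; duplicate cell ids are rejected.
#' @export
read_truth <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "row", "col", "phenotype", "area")
  if (!all(need %in% names(tr)))
    stop("truth table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tr$cell_id)) stop("duplicate cell ids in truth table")
  tr
}

#' Write / read a feature table
#'
#' Features are stored as a columnar table (`crop_id` plus one named column
#' per feature). CSV output keeps full double precision
#' (`read(write(x)) == x` within 1e-7, and is typically bit-exact).
#'
#' @param features Feature matrix ([encode()] / [engineered_feature_matrix()]).
#' @param path Output `.csv` path.
#' @param crop_id Optional crop identifiers (default row sequence).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, crop_id = seq_len(nrow(features))) {
  df <- data.frame(crop_id = crop_id, as.data.frame(as.matrix(features)),
                   check.names = FALSE)
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "crop_id") stop("feature table must start with crop_id")
  if (anyDuplicated(df$crop_id)) stop("duplicate crop ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$crop_id
  space <- if (ncol(m) == 128) "learned-128" else if (ncol(m) == 368)
    "engineered-368" else NULL
  if (!is.null(space)) m <- feature_matrix(m, space)
  m
}

#' Write / read crops as 5-page multi-page TIFF plus a CSV index
#'
#' @param crops List of [cell_crop()]s.
#' @param dir Output directory.
#' @param labels Optional labels recorded in the index
#'   (`crop_id,slide,frame,cell_id,label`).
#' @param slide Slide tag for the index.
#' @return `dir`, invisibly.
#' @export
write_crops <- function(crops, dir, labels = NA, slide = "slide") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- rep_len(labels, length(crops))
  idx <- data.frame(
    crop_id = seq_along(crops), slide = slide,
    frame = vapply(crops, function(cr) as.integer(attr(cr, "frame") %||% NA_integer_), 1L),
    cell_id = vapply(crops, function(cr) as.integer(attr(cr, "cell_id") %||% NA_integer_), 1L),
    label = labels)
  for (i in seq_along(crops)) {
    x <- unclass(crops[[i]])
    pages <- lapply(1:5, function(k)
      if (k == 5) x[, , 5] else x[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, sprintf("crop_%06d.tif", i)),
                    bits.per.sample = 16)
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_crops
#' @export
read_crops <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  crops <- lapply(idx$crop_id, function(i) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("crop_%06d.tif", i)),
                            all = TRUE)
    x <- array(0, c(75L, 75L, 5L))
    for (k in 1:4) x[, , k] <- round(pages[[k]] * 65535)
    x[, , 5] <- round(pages[[5]])
    cell_crop(x, cell_id = idx$cell_id[i], frame = idx$frame[i])
  })
  list(crops = crops, index = idx)
}
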