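# Segmentation interface, object-level F1 at IoU evaluation, and centered
# 75x75x5 crop extraction.

#' Reference nuclear segmenter
#'
#' A classical DAPI-driven segmenter standing behind the pluggable
#' `segmenter` interface: background subtraction, Otsu threshold, hole
#' filling, distance-transform watershed to split touching nuclei, and a
#' minimum-area filter. A learned instance-segmentation model can be plugged
#' in anywhere an `instance_mask` is accepted; this reference implementation
#' keeps the evaluation stack self-contained.
#'
#' @param frame An [if_frame()].
#' @param min_area Minimum object area in pixels.
#' @param watershed_tolerance Minimum object-height separation passed to the
#'   watershed split.
#' @return An [instance_mask()]. A blank DAPI plane yields an empty mask.
#' @export
reference_segment <- function(frame, min_area = 40, watershed_tolerance = 1) {
  stopifnot(inherits(frame, "if_frame"))
  dapi <- frame[, , 1] / 65535
  bg <- stats::median(dapi)
  x <- pmax(dapi - bg, 0)
  if (max(x) <= 0) return(instance_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  x <- x / max(x)
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  bw <- x > thr
  if (!any(bw)) return(instance_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  bw <- EBImage::fillHull(EBImage::Image(bw))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  m <- EBImage::imageData(lab)
  storage.mode(m) <- "integer"
  areas <- tabulate(m[m > 0])
  drop <- which(areas > 0 & areas < min_area)
  if (length(drop)) m[m %in% drop] <- 0L
  instance_mask(m)
}

# all overlapping (gt, pred) label pairs with pixel counts and IoU
.iou_pairs <- function(gt, pred) {
  idx <- which(gt > 0L & pred > 0L)
  a_gt <- tabulate(gt[gt > 0L])
  a_pr <- tabulate(pred[pred > 0L])
  if (length(idx) == 0) {
    return(list(pairs = data.frame(gt = integer(0), pred = integer(0),
                                   iou = numeric(0)),
                n_gt = sum(a_gt > 0), n_pred = sum(a_pr > 0)))
  }
  g <- as.numeric(gt[idx]); p <- as.numeric(pred[idx])
  key <- g * (max(p) + 1) + p
  u <- sort(unique(key))
  inter <- tabulate(match(key, u), nbins = length(u))
  gu <- floor(u / (max(p) + 1)); pu <- u - gu * (max(p) + 1)
  iou <- inter / (a_gt[gu] + a_pr[pu] - inter)
  list(pairs = data.frame(gt = as.integer(gu), pred = as.integer(pu),
                          iou = iou),
       n_gt = sum(a_gt > 0), n_pred = sum(a_pr > 0))
}

# greedy one-to-one matching: descend on IoU, ties broken by
# (lower gt id, lower pred id)
.greedy_match <- function(pairs, n_gt, n_pred, iou_threshold) {
  cand <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$gt, cand$pred), , drop = FALSE]
  used_g <- integer(0); used_p <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$gt[i] %in% used_g) && !(cand$pred[i] %in% used_p)) {
      keep[i] <- TRUE
      used_g <- c(used_g, cand$gt[i])
      used_p <- c(used_p, cand$pred[i])
    }
  }
  matched <- cand[keep, , drop = FALSE]
  tp <- nrow(matched)
  structure(list(iou_threshold = iou_threshold, TP = tp,
                 FP = n_pred - tp, FN = n_gt - tp, matches = matched),
            class = "match_result")
}

#' Match predicted to ground-truth instances at an IoU threshold
#'
#' One-to-one matching between ground-truth and predicted objects: a pair is
#' matchable iff its pixel IoU (intersection over union) reaches the
#' threshold; each ground-truth object is matched to at most one prediction.
#' Matching is greedy on descending IoU with deterministic tie-breaks.
#' Unmatched predictions count as false positives, unmatched ground-truth
#' objects as false negatives.
#'
#' @param gt,pred [instance_mask()]s of identical shape.
#' @param iou_threshold IoU threshold in (0, 1).
#' @return A `match_result`: `iou_threshold`, counts `TP`, `FP`, `FN`, and
#'   the matched pair table (`gt`, `pred`, `iou`).
#' @export
match_instances <- function(gt, pred, iou_threshold) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred masks differ in shape")
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)")
  ip <- .iou_pairs(gt, pred)
  .greedy_match(ip$pairs, ip$n_gt, ip$n_pred, iou_threshold)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> IoU >= ", x$iou_threshold, ": TP = ", x$TP,
      ", FP = ", x$FP, ", FN = ", x$FN, "\n", sep = "")
  invisible(x)
}

#' Object-level F1 score of a match result
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. An empty scene (TP = FP = FN = 0) is
#' defined as perfect agreement, F1 = 1.
#'
#' @param match A `match_result` from [match_instances()].
#' @return F1 in `[0, 1]`.
#' @export
f1_at_iou <- function(match) {
  with(match, if (TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN))
}

#' Object-level F1 across IoU thresholds
#'
#' @param gt,pred [instance_mask()]s of identical shape.
#' @param thresholds Strictly increasing IoU thresholds in (0, 1).
#' @return data.frame with columns `threshold`, `F1` (non-increasing in
#'   threshold).
#' @export
f1_curve <- function(gt, pred, thresholds = seq(0.5, 0.9, by = 0.1)) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must lie in (0, 1)")
  if (!all(dim(gt) == dim(pred))) stop("gt and pred masks differ in shape")
  ip <- .iou_pairs(gt, pred)
  f1 <- vapply(thresholds, function(th)
    f1_at_iou(.greedy_match(ip$pairs, ip$n_gt, ip$n_pred, th)), 0)
  data.frame(threshold = thresholds, F1 = f1)
}

#' Extract a centered 75x75x5 crop of one cell
#'
#' The window is centered on the cell's mask centroid (rounded half-up);
#' regions extending past the frame are zero-padded (padding cannot
#' fabricate marker signal). Channel 5 is the binary indicator of this cell
#' only: other cells' mask pixels are zeroed while their intensities are
#' left untouched.
#'
#' @param frame An [if_frame()].
#' @param mask An [instance_mask()] aligned to the frame.
#' @param cell_id Label present in `mask`.
#' @return A [cell_crop()].
#' @export
extract_crop <- function(frame, mask, cell_id) {
  pix <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("cell_id ", cell_id, " not present in mask")
  cr <- floor(mean(pix[, 1]) + 0.5)
  cc <- floor(mean(pix[, 2]) + 0.5)
  half <- 37L
  rows <- (cr - half):(cr + half)
  cols <- (cc - half):(cc + half)
  out <- array(0, c(75L, 75L, 5L))
  vr <- rows >= 1 & rows <= nrow(mask)
  vc <- cols >= 1 & cols <= ncol(mask)
  fr <- rows[vr]; fc <- cols[vc]
  for (k in 1:4) out[which(vr), which(vc), k] <- frame[fr, fc, k]
  out[which(vr), which(vc), 5] <- (mask[fr, fc] == cell_id) * 1
  cell_crop(out, cell_id = cell_id)
}
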