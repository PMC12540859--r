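# WBC depletion: a binary convolutional classifier (WBC vs non-WBC) used to
# remove the leukocyte supermajority when assembling representation-learning
# datasets. Trunk: four batch-normalized 3x3 convolutions with ReLU, each
# followed by 2x2 max-pooling; adaptive average pooling then a two-layer
# dense head to 2 logits. Trained with cross-entropy and Adam.

#' Depletion model configuration
#'
#' @param widths Convolution widths (default 16/32/64/128).
#' @param hidden Hidden width of the dense head (head is hidden -> 2 logits).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 25).
#' @param batch_size Mini-batch size.
#' @param val_split Fraction held out (stratified) for the validation trace.
#' @param use_mask Feed the binary mask channel to the network (all 5 crop
#'   channels by default; set `FALSE` to use only the 4 IF channels).
#' @return A `depletion_config` list.
#' @export
depletion_config <- function(widths = c(16L, 32L, 64L, 128L), hidden = 64L,
                             lr = 1e-4, epochs = 25L, batch_size = 64L,
                             val_split = 0.2, use_mask = TRUE) {
  structure(list(widths = as.integer(widths), hidden = as.integer(hidden),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_split = val_split,
                 use_mask = isTRUE(use_mask)), class = "depletion_config")
}

#' Train the WBC depletion classifier
#'
#' @param crops List of [cell_crop()]s.
#' @param is_wbc Logical vector: `TRUE` for WBC crops.
#' @param config A [depletion_config()].
#' @param seed Integer seed (fixes split, shuffling and initialization).
#' @return A `wbc_model` with weights, normalization constants, and `trace`
#'   (per-epoch train/validation cross-entropy).
#' @export
train_depletion <- function(crops, is_wbc, config = depletion_config(),
                            seed = 1L) {
  crops <- check_crops(crops)
  is_wbc <- as.logical(is_wbc)
  if (length(is_wbc) != length(crops)) stop("labels must match crops")
  if (length(unique(is_wbc)) < 2) stop("both classes must be present")
  ncfg <- net_config(config$widths, head_dims = c(config$hidden, 2L),
                     in_ch = if (config$use_mask) 5L else 4L, pool_each = TRUE)
  norm <- norm_constants(crops)
  y <- as.integer(is_wbc)          # 0 = non-WBC, 1 = WBC
  # stratified validation split
  set.seed(derive_seed(seed, 3))
  val <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1L, round(config$val_split * length(ix))))))
  tr <- setdiff(seq_along(y), val)
  weights <- init_net(ncfg, derive_seed(seed, 1))
  ad <- adam_init(weights)
  step <- 0L
  trace <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                      val_loss = NA_real_)
  tobatch <- function(ix) {
    X <- crops_to_batch(crops[ix], norm)
    if (!config$use_mask) X <- X[seq_len(75 * 75 * 4), , drop = FALSE]
    X
  }
  Xval <- tobatch(val)
  set.seed(derive_seed(seed, 2))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    losses <- c()
    i <- 1L
    while (i <= length(ord)) {
      take <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      step <- step + 1L
      res <- cpp_step_supervised(tobatch(take), y[take], weights, ad$m, ad$v,
                                 ncfg, step, config$lr, 0)
      weights <- res$weights
      ad$m <- res$m; ad$v <- res$v
      losses <- c(losses, res$loss)
    }
    trace$train_loss[ep] <- mean(losses)
    trace$val_loss[ep] <- cpp_eval_ce(Xval, y[val], weights, ncfg)
  }
  structure(list(weights = weights, net_cfg = ncfg, norm = norm,
                 config = config, trace = trace, seed = seed),
            class = "wbc_model")
}

#' @export
print.wbc_model <- function(x, ...) {
  cat("<wbc_model> ", x$config$epochs, " epochs, final train loss ",
      sprintf("%.4f", rev(x$trace$train_loss)[1]), "\n", sep = "")
  invisible(x)
}

#' Probability that a crop is a WBC
#'
#' Softmax of the two-logit head; `p(WBC) + p(non-WBC) = 1`.
#'
#' @param model A `wbc_model`.
#' @param crops A [cell_crop()] or list of them.
#' @return Numeric vector of WBC probabilities in `[0, 1]`.
#' @export
wbc_probability <- function(model, crops) {
  stopifnot(inherits(model, "wbc_model"))
  crops <- check_crops(crops)
  X <- crops_to_batch(crops, model$norm)
  if (!model$config$use_mask) X <- X[seq_len(75 * 75 * 4), , drop = FALSE]
  lg <- cpp_forward_head(X, model$weights, model$net_cfg)
  e <- exp(sweep(lg, 2, apply(lg, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  p[2, ]
}

#' Deplete WBCs from a crop set
#'
#' Keeps crops with `p(WBC) < keep_threshold`; kept and removed sets
#' partition the input, so counts are always conserved, and raising the
#' threshold never shrinks the kept set.
#'
#' @param crops List of [cell_crop()]s.
#' @param model A `wbc_model`.
#' @param keep_threshold Probability threshold in (0, 1).
#' @return List with `kept`, `removed` (crop lists), `kept_idx`, and
#'   `p_wbc`.
#' @export
deplete <- function(crops, model, keep_threshold = 0.5) {
  if (keep_threshold <= 0 || keep_threshold >= 1)
    stop("keep_threshold must lie in (0, 1)")
  crops <- check_crops(crops)
  p <- wbc_probability(model, crops)
  keep <- p < keep_threshold
  list(kept = crops[keep], removed = crops[!keep],
       kept_idx = which(keep), p_wbc = p)
}
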