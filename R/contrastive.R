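# Contrastive representation learning: encoder configuration, NT-Xent loss,
# training loop, and feature extraction. The encoder is a four-block
# convolutional trunk (conv 3x3 -> batch norm -> ReLU, max-pooled) followed
# by 1x1 adaptive average pooling to the 128-dim representation h and a
# two-layer projection head to the 64-dim z used only inside the loss.
# Downstream features always come from h, never z.

#' Encoder configuration
#'
#' Two profiles are provided. `"full"` carries the full-scale
#' hyperparameters (batch 1024, 50 epochs, warm-up 10, trunk widths
#' 32/64/128/128 with a single max-pool after the last convolution).
#' `"desk"` is the CPU-scale profile used throughout the tests: batch 128,
#' 12 epochs, warm-up 4, narrower trunk (8/16/32/128) with a 2x2 max-pool
#' after every convolution so training fits in CPU minutes. Both share:
#' representation dim 128, projection dim 64, temperature 0.13, weight decay
#' 1e-4, and a linear learning-rate warm-up from 1e-3 to 1e-2.
#'
#' @param profile `"desk"` or `"full"`.
#' @param widths,pool_each,batch_size,epochs Optional overrides.
#' @param tau Softmax temperature (> 0).
#' @param weight_decay L2 weight decay on weight matrices.
#' @param lr_start,lr_max,warmup_epochs Learning-rate schedule.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(profile = c("desk", "full"), widths = NULL,
                           pool_each = NULL, batch_size = NULL, epochs = NULL,
                           tau = 0.13, weight_decay = 1e-4, lr_start = 1e-3,
                           lr_max = 1e-2, warmup_epochs = 10) {
  profile <- match.arg(profile)
  def <- if (profile == "desk") {
    list(widths = c(8L, 16L, 32L, 128L), pool_each = TRUE,
         batch_size = 128L, epochs = 12L, warmup = 4)
  } else {
    list(widths = c(32L, 64L, 128L, 128L), pool_each = FALSE,
         batch_size = 1024L, epochs = 50L, warmup = 10)
  }
  if (tau <= 0) stop("temperature must be positive")
  if (missing(warmup_epochs)) warmup_epochs <- def$warmup
  cfg <- list(profile = profile,
              widths = as.integer(widths %||% def$widths),
              pool_each = pool_each %||% def$pool_each,
              batch_size = as.integer(batch_size %||% def$batch_size),
              epochs = as.integer(epochs %||% def$epochs),
              tau = tau, weight_decay = weight_decay, lr_start = lr_start,
              lr_max = lr_max, warmup_epochs = warmup_epochs,
              repr_dim = 128L, proj_dim = 64L)
  if (cfg$widths[4] != cfg$repr_dim)
    stop("last trunk width must equal the representation dimension (128)")
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.enc_net_cfg <- function(cfg) {
  net_config(cfg$widths, head_dims = c(cfg$repr_dim, cfg$proj_dim),
             in_ch = 5L, pool_each = cfg$pool_each)
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' For a batch of N positive pairs, each of the 2N projection vectors is an
#' anchor; its positive is the other view of the same source crop, and every
#' remaining vector in the batch is a negative. With cosine similarity
#' `sim`, the anchor term is
#' `-log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`,
#' and the loss is the mean over all 2N anchors (averaging makes the loss
#' batch-size comparable). With N = 1 the only non-anchor term is the
#' positive itself, so the loss is exactly 0.
#'
#' @param z1,z2 N x P matrices of paired projection vectors (row i of `z1`
#'   and row i of `z2` are the two views of the same source).
#' @param temperature Positive temperature tau.
#' @return Non-negative scalar loss.
#' @export
nt_xent_loss <- function(z1, z2, temperature = 0.13) {
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  if (!all(dim(z1) == dim(z2))) stop("z1 and z2 must have identical shape")
  if (temperature <= 0) stop("temperature must be positive")
  Z <- rbind(z1, z2)                       # 2N x P, pair (i, i+N)
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm < 1e-12)) stop("zero-norm projection vector: cosine undefined")
  Zn <- Z / nrm
  n2 <- nrow(Zn)
  S <- tcrossprod(Zn) / temperature
  diag(S) <- -Inf
  N <- n2 / 2
  pos <- c((N + 1):n2, 1:N)
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  lse[!is.finite(mx)] <- -Inf              # defensive; cannot happen for N >= 1
  mean(lse - S[cbind(seq_len(n2), pos)])
}

#' Train the contrastive encoder
#'
#' Each epoch shuffles the crops, draws two augmented views per crop, and
#' minimizes the NT-Xent loss over in-batch positives/negatives with Adam
#' (L2 weight decay, linear learning-rate warm-up). Intensities are
#' normalized by 1/65535 and per-channel standardization constants computed
#' from the training crops and frozen into the model.
#'
#' @param crops List of [cell_crop()]s.
#' @param config An [encoder_config()].
#' @param aug An [augmentation_config()].
#' @param seed Integer seed; with a fixed thread count the loss trace is
#'   reproducible.
#' @param verbose Print the per-epoch loss?
#' @return A `cyto_encoder`: weights, net config, normalization constants,
#'   the training config, and `loss_trace` (mean NT-Xent loss per epoch).
#' @export
train_encoder <- function(crops, config = encoder_config(),
                          aug = augmentation_config(), seed = 1L,
                          verbose = FALSE) {
  crops <- check_crops(crops)
  if (config$batch_size < 2) stop("batch size must be at least 2")
  n <- length(crops)
  norm <- norm_constants(crops)
  ncfg <- .enc_net_cfg(config)
  weights <- init_net(ncfg, derive_seed(seed, 1))
  ad <- adam_init(weights)
  step <- 0L
  trace <- numeric(config$epochs)
  set.seed(derive_seed(seed, 2))
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr_start + (config$lr_max - config$lr_start) *
      min(1, (ep - 1) / config$warmup_epochs)
    ord <- sample.int(n)
    losses <- c()
    i <- 1L
    while (i <= n) {
      take <- ord[i:min(i + config$batch_size - 1L, n)]
      i <- i + config$batch_size
      if (length(take) < 2) next
      v1 <- vector("list", length(take))
      v2 <- vector("list", length(take))
      for (j in seq_along(take)) {
        pair <- make_view_pair(crops[[take[j]]], aug)
        v1[[j]] <- pair[[1]]; v2[[j]] <- pair[[2]]
      }
      X <- cbind(crops_to_batch(v1, norm), crops_to_batch(v2, norm))
      step <- step + 1L
      res <- cpp_step_contrastive(X, weights, ad$m, ad$v, ncfg, step, lr,
                                  config$weight_decay, config$tau)
      weights <- res$weights
      ad$m <- res$m; ad$v <- res$v
      losses <- c(losses, res$loss)
    }
    trace[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f (lr %.4g)", ep, trace[ep], lr))
  }
  structure(list(weights = weights, net_cfg = ncfg, norm = norm,
                 config = config, loss_trace = trace, seed = seed),
            class = "cyto_encoder")
}

#' Randomly initialized (untrained) encoder
#'
#' Baseline for representation-quality comparisons: same architecture and
#' normalization plumbing, untrained weights.
#'
#' @inheritParams train_encoder
#' @export
random_encoder <- function(crops, config = encoder_config(), seed = 1L) {
  crops <- check_crops(crops)
  ncfg <- .enc_net_cfg(config)
  structure(list(weights = init_net(ncfg, derive_seed(seed, 1)),
                 net_cfg = ncfg, norm = norm_constants(crops),
                 config = config, loss_trace = numeric(0), seed = seed),
            class = "cyto_encoder")
}

#' @export
print.cyto_encoder <- function(x, ...) {
  cat("<cyto_encoder> profile ", x$config$profile, ", widths ",
      paste(x$config$widths, collapse = "/"),
      if (length(x$loss_trace)) sprintf(", final loss %.4f", rev(x$loss_trace)[1])
      else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Encode crops to 128-dim learned representations
#'
#' Inference mode: batch normalization uses running statistics, so the
#' output is deterministic and independent of how crops are batched.
#'
#' @param model A `cyto_encoder`.
#' @param crops List of [cell_crop()]s.
#' @param batch Internal batch size (no effect on values).
#' @return n x 128 matrix tagged with feature space `"learned-128"`.
#' @export
encode <- function(model, crops, batch = 256L) {
  stopifnot(inherits(model, "cyto_encoder"))
  crops <- check_crops(crops)
  out <- matrix(0, length(crops), model$config$repr_dim)
  i <- 1L
  while (i <= length(crops)) {
    take <- i:min(i + batch - 1L, length(crops))
    X <- crops_to_batch(crops[take], model$norm)
    out[take, ] <- t(cpp_forward_h(X, model$weights, model$net_cfg))
    i <- i + batch
  }
  colnames(out) <- sprintf("f%03d", seq_len(ncol(out)) - 1L)
  feature_matrix(out, "learned-128")
}

#' Project representations through the encoder's head
#'
#' Maps 128-dim representations h to the 64-dim projections z used only
#' inside the contrastive loss; z is never a downstream feature space.
#'
#' @param model A `cyto_encoder`.
#' @param h n x 128 matrix of representations.
#' @return n x 64 matrix of projections.
#' @export
project <- function(model, h) {
  stopifnot(inherits(model, "cyto_encoder"))
  h <- as.matrix(h)
  if (ncol(h) != model$config$repr_dim)
    stop("h must have ", model$config$repr_dim, " columns")
  t(cpp_head_only(t(h), model$weights, model$net_cfg))
}
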