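# Shared plumbing for the compiled CNN engine: configuration, weight
# initialization, Adam state, and crop <-> matrix conversion with the
# frozen normalization scheme (x/65535, then per-channel standardization
# with constants computed on the training set; the mask channel is never
# normalized).

net_config <- function(widths, head_dims, in_ch = 5L, pool_each = TRUE) {
  stopifnot(length(widths) == 4L, all(widths > 0), length(head_dims) >= 1)
  list(widths = as.integer(widths), in_ch = as.integer(in_ch),
       pool_each = isTRUE(pool_each), head_dims = as.integer(head_dims))
}

init_net <- function(cfg, seed) {
  set.seed(seed)
  cin <- cfg$in_ch
  W <- b <- g <- be <- rm <- rv <- vector("list", 4L)
  for (l in 1:4) {
    k <- cfg$widths[l]
    fan <- 9L * cin
    W[[l]] <- matrix(rnorm(k * fan, 0, sqrt(2 / fan)), k, fan)
    b[[l]] <- numeric(k)
    g[[l]] <- rep(1, k)
    be[[l]] <- numeric(k)
    rm[[l]] <- numeric(k)
    rv[[l]] <- rep(1, k)
    cin <- k
  }
  din <- cfg$widths[4]
  Wh <- bh <- vector("list", length(cfg$head_dims))
  for (l in seq_along(cfg$head_dims)) {
    dout <- cfg$head_dims[l]
    Wh[[l]] <- matrix(rnorm(dout * din, 0, sqrt(2 / din)), dout, din)
    bh[[l]] <- numeric(dout)
    din <- dout
  }
  list(Wconv = W, bconv = b, gamma = g, beta = be, rmean = rm, rvar = rv,
       Whead = Wh, bhead = bh)
}

# Adam state mirrors the trainable parameter order used by the C++ side:
# Wconv(4), bconv(4), gamma(4), beta(4), Whead..., bhead...
adam_init <- function(weights) {
  zeros <- function(x) {
    m <- as.matrix(x)
    matrix(0, nrow(m), ncol(m))
  }
  params <- c(weights$Wconv, weights$bconv, weights$gamma, weights$beta,
              weights$Whead, weights$bhead)
  list(m = lapply(params, zeros), v = lapply(params, zeros))
}

# crops (list of 75x75x5 arrays, 16-bit counts) -> D x B matrix under the
# model's normalization constants (norm$mean, norm$sd per IF channel)
crops_to_batch <- function(crops, norm) {
  X <- vapply(crops, function(cr) as.vector(unclass(cr)),
              numeric(75 * 75 * 5))
  hw <- 75 * 75
  for (k in 1:4) {
    rows <- ((k - 1) * hw + 1):(k * hw)
    X[rows, ] <- (X[rows, ] / 65535 - norm$mean[k]) / norm$sd[k]
  }
  X
}

# per-channel normalization constants from a training crop set
norm_constants <- function(crops) {
  s <- numeric(4); ss <- numeric(4); n <- 0
  for (cr in crops) {
    a <- unclass(cr)
    for (k in 1:4) {
      v <- a[, , k] / 65535
      s[k] <- s[k] + sum(v)
      ss[k] <- ss[k] + sum(v * v)
    }
    n <- n + 75 * 75
  }
  mu <- s / n
  sdv <- sqrt(pmax(ss / n - mu^2, 1e-8))
  list(mean = mu, sd = sdv)
}

check_crops <- function(crops) {
  if (inherits(crops, "cell_crop")) crops <- list(crops)
  ok <- vapply(crops, function(x) {
    d <- dim(x)
    length(d) == 3 && all(d == c(75L, 75L, 5L))
  }, TRUE)
  if (!all(ok)) stop("all crops must be 75 x 75 x 5 arrays")
  crops
}
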