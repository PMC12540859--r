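# Rare-event outlier detection on feature matrices: COPOD and ECOD
# (empirical-distribution tail probabilities with skewness correction) and
# isolation forest (100 trees, subsample 256). Scores are higher = more
# outlying; the contamination parameter only thresholds the binary labels
# and never affects the ranking.

.ecdf_tails <- function(X, denom_plus_one = FALSE) {
  n <- nrow(X)
  den <- if (denom_plus_one) n + 1 else n
  U <- apply(X, 2, function(v) rank(v, ties.method = "max") / den)        # P(<= x)
  V <- apply(X, 2, function(v) rank(-v, ties.method = "max") / den)       # P(>= x)
  skew <- apply(X, 2, function(v) {
    m <- mean(v); s <- mean((v - m)^2)
    if (s < 1e-24) 0 else mean((v - m)^3) / s^1.5
  })
  list(U = pmin(pmax(U, 1e-12), 1), V = pmin(pmax(V, 1e-12), 1), skew = skew)
}

.tail_score <- function(X, denom_plus_one) {
  t <- .ecdf_tails(X, denom_plus_one)
  o_left <- -rowSums(log(t$U))
  o_right <- -rowSums(log(t$V))
  W <- t$U
  W[, t$skew >= 0] <- t$V[, t$skew >= 0, drop = FALSE]
  o_skew <- -rowSums(log(W))
  pmax(o_left, o_right, o_skew)
}

# isolation forest: trees stored as flat arrays, scored level-wise so large
# cohorts traverse in vectorized passes
.iforest_build <- function(X, n_trees = 100L, psi = 256L) {
  n <- nrow(X)
  psi <- min(psi, n)
  hlim <- ceiling(log2(max(psi, 2)))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    samp <- sample.int(n, psi)
    feat <- integer(0); split <- numeric(0)
    left <- integer(0); right <- integer(0); size <- integer(0)
    new_node <- function() {
      k <- length(feat) + 1L
      feat[k] <<- -1L; split[k] <<- NA_real_
      left[k] <<- 0L; right[k] <<- 0L; size[k] <<- 0L
      k
    }
    grow <- function(idx, depth) {
      k <- new_node()
      rngs <- apply(X[idx, , drop = FALSE], 2, range)
      spread <- rngs[2, ] - rngs[1, ]
      if (length(idx) <= 1L || depth >= hlim || all(spread <= 0)) {
        size[k] <<- length(idx)
        return(k)
      }
      w <- which(spread > 0)
      j <- w[sample.int(length(w), 1L)]
      sv <- runif(1, rngs[1, j], rngs[2, j])
      go <- X[idx, j] < sv
      if (all(go) || !any(go)) {
        size[k] <<- length(idx)
        return(k)
      }
      feat[k] <<- j; split[k] <<- sv
      left[k] <<- grow(idx[go], depth + 1L)
      right[k] <<- grow(idx[!go], depth + 1L)
      k
    }
    grow(samp, 0L)
    trees[[t]] <- list(feat = feat, split = split, left = left,
                       right = right, size = size)
  }
  list(trees = trees, psi = psi)
}

.harmonic <- function(k) ifelse(k > 0, log(k) + 0.5772156649, 0)
.cfactor <- function(k) ifelse(k > 1, 2 * .harmonic(k - 1) - 2 * (k - 1) / k, 0)

.iforest_score <- function(forest, X) {
  n <- nrow(X)
  depth_sum <- numeric(n)
  for (tr in forest$trees) {
    node <- rep(1L, n)
    depth <- numeric(n)
    repeat {
      active <- which(tr$feat[node] > 0)
      if (!length(active)) break
      j <- tr$feat[node[active]]
      go_left <- X[cbind(active, j)] < tr$split[node[active]]
      node[active] <- ifelse(go_left, tr$left[node[active]],
                             tr$right[node[active]])
      depth[active] <- depth[active] + 1
    }
    depth_sum <- depth_sum + depth + .cfactor(tr$size[node])
  }
  e_depth <- depth_sum / length(forest$trees)
  2^(-e_depth / max(.cfactor(forest$psi), 1e-12))
}

# per-feature robust scaling (median/MAD, sd fallback for constant-MAD
# features); degenerate features are left centred
.robust_scale <- function(X) {
  ctr <- apply(X, 2, median)
  sc <- apply(X, 2, mad)
  alt <- apply(X, 2, sd)
  sc[sc < 1e-12] <- alt[sc < 1e-12]
  sc[sc < 1e-12] <- 1
  sweep(sweep(X, 2, ctr), 2, sc, "/")
}

#' Rank cells by outlierness
#'
#' Supported methods: `"copod"` and `"ecod"` (deterministic
#' empirical-distribution tail scores; duplicated points receive equal
#' scores) and `"iforest"` (isolation forest, 100 trees, subsample 256,
#' seeded). The contamination level only sets the binary `labels` cutoff;
#' the ranking is contamination-free.
#'
#' @param features n x d feature matrix (n >= 10).
#' @param method One of `"copod"`, `"ecod"`, `"iforest"`.
#' @param contamination Expected outlier fraction (default 0.001).
#' @param seed Seed for the isolation forest.
#' @param scale Apply per-feature robust scaling first (default TRUE).
#' @return An `outlier_ranking`: `score` (higher = more outlying), `rank`
#'   (permutation ordering cells by descending score), `labels`, `method`,
#'   `contamination`.
#' @export
detect_outliers <- function(features, method = c("copod", "ecod", "iforest"),
                            contamination = 0.001, seed = 1L, scale = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(features)
  if (nrow(X) < 10) stop("need at least 10 cells")
  if (scale) X <- .robust_scale(X)
  score <- switch(method,
    copod = .tail_score(X, denom_plus_one = TRUE),
    ecod = .tail_score(X, denom_plus_one = FALSE),
    iforest = {
      set.seed(seed)
      f <- .iforest_build(X)
      .iforest_score(f, X)
    })
  rk <- order(-score)
  cutoff <- quantile(score, 1 - contamination, type = 7)
  structure(list(score = score, rank = rk, labels = score > cutoff,
                 method = method, contamination = contamination),
            class = "outlier_ranking")
}

#' @export
print.outlier_ranking <- function(x, ...) {
  cat("<outlier_ranking> ", x$method, ", n = ", length(x$score),
      ", flagged = ", sum(x$labels), "\n", sep = "")
  invisible(x)
}
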