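# Downstream benchmark suite comparing the learned (128-dim) and engineered
# (368-dim) feature spaces: linear probing, perturbation robustness,
# imbalance-swept clustering, and rare-phenotype enumeration. Feature-space
# comparisons always run both spaces through identical splits, seeds and
# subsamples.

# stratified train/test split indices
.strat_split <- function(labels, test_frac, seed) {
  set.seed(seed)
  test <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    if (length(ix) < 2) stop("every class needs at least 2 members")
    sample(ix, max(1L, round(test_frac * length(ix))))
  }))
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Linear probe of a feature space
#'
#' Trains a multinomial logistic classifier (L2-regularized, up to 10,000
#' iterations) on a stratified 80% split of the features and evaluates on
#' the held-out 20%: the resulting accuracy measures how linearly separable
#' the phenotypes are in the representation.
#'
#' @param features n x d feature matrix.
#' @param labels Factor (or coercible) of phenotype labels.
#' @param split_seed Seed for the stratified split.
#' @param max_iter Optimizer iteration cap.
#' @param decay L2 penalty passed to the optimizer.
#' @return List: `accuracy`, `per_class` (precision/recall/F1),
#'   `confusion`, `macro_roc_auc`, `micro_roc_auc`, `macro_pr_auc`,
#'   `micro_pr_auc`, and the split indices.
#' @export
linear_probe <- function(features, labels, split_seed = 1L, max_iter = 10000L,
                         decay = 1e-4) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("features must be finite")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  sp <- .strat_split(y, 0.2, split_seed)
  mu <- colMeans(X[sp$train, , drop = FALSE])
  sdv <- apply(X[sp$train, , drop = FALSE], 2, sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  df <- data.frame(y = y, Z)
  fit <- nnet::multinom(y ~ ., data = df[sp$train, ], maxit = max_iter,
                        decay = decay, MaxNWts = 100000, trace = FALSE)
  prob <- predict(fit, newdata = df[sp$test, ], type = "probs")
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob)   # 2-class case
  colnames(prob) <- fit$lev
  pred <- factor(fit$lev[max.col(prob)], levels = levels(y))
  truth <- y[sp$test]
  confusion <- table(truth = truth, pred = pred)
  acc <- mean(pred == truth)
  per_class <- t(vapply(levels(y), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prf_counts(tp, sum(pred == cl) - tp, sum(truth == cl) - tp)
  }, numeric(3)))
  aucs <- lapply(levels(y), function(cl) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) return(c(roc = NA_real_, pr = NA_real_))
    c(roc = roc_auc(prob[, cl], pos), pr = pr_auc(prob[, cl], pos))
  })
  aucm <- do.call(rbind, aucs)
  flat_truth <- as.vector(vapply(levels(y), function(cl) truth == cl,
                                 logical(length(truth))))
  flat_prob <- as.vector(prob[, levels(y)])
  list(accuracy = acc, per_class = per_class, confusion = confusion,
       macro_roc_auc = mean(aucm[, "roc"], na.rm = TRUE),
       micro_roc_auc = roc_auc(flat_prob, flat_truth),
       macro_pr_auc = mean(aucm[, "pr"], na.rm = TRUE),
       micro_pr_auc = pr_auc(flat_prob, flat_truth),
       split = sp)
}

#' Perturbation specification
#'
#' @param kind `"gaussian_blur"` (sigma in px), `"intensity_scale"` (factor
#'   in `[0.8, 1.2]`, i.e. up to +/-20%), or `"resize"` (isotropic factor in
#'   `[0.9, 1.1]`, restored to 75 x 75 by center crop/pad).
#' @param magnitude Perturbation magnitude (see `kind`).
#' @param channel For `intensity_scale`: channel index 1-4 or `NULL` for all
#'   IF channels.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("gaussian_blur", "intensity_scale",
                                       "resize"),
                              magnitude, channel = NULL) {
  kind <- match.arg(kind)
  ok <- switch(kind,
    gaussian_blur = magnitude >= 0 && magnitude <= 5,
    intensity_scale = magnitude >= 0.8 && magnitude <= 1.2,
    resize = magnitude >= 0.9 && magnitude <= 1.1)
  if (!ok) stop("magnitude ", magnitude, " outside the stated range for ", kind)
  structure(list(kind = kind, magnitude = magnitude, channel = channel),
            class = "perturbation_spec")
}

#' Apply a single controlled corruption to a crop
#'
#' Blur and intensity scaling never touch the mask channel; resizing
#' transforms all five channels coherently (nearest-neighbour for the mask)
#' and restores 75 x 75 by center crop/pad. Intensities are clipped to the
#' 16-bit range.
#'
#' @param crop A [cell_crop()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed [cell_crop()].
#' @export
perturb <- function(crop, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  x <- unclass(crop)
  storage.mode(x) <- "double"
  if (spec$kind == "gaussian_blur") {
    if (spec$magnitude > 0)
      for (k in 1:4) x[, , k] <- cpp_gauss_blur(x[, , k], spec$magnitude, 0L)
  } else if (spec$kind == "intensity_scale") {
    ch <- spec$channel %||% 1:4
    for (k in ch) x[, , k] <- x[, , k] * spec$magnitude
  } else {
    f <- spec$magnitude
    if (f != 1) x <- .warp(x, diag(c(f, f)), c(0, 0))
    x[, , 5] <- (x[, , 5] >= 0.5) * 1
  }
  x[, , 1:4] <- pmin(pmax(x[, , 1:4], 0), 65535)
  cell_crop(x, cell_id = attr(crop, "cell_id"), frame = attr(crop, "frame"))
}

#' Cosine drift between paired feature vectors
#'
#' `1 - cosine similarity`; 0 for identical (or proportional) vectors, 1
#' for orthogonal ones.
#'
#' @param f_original,f_perturbed Equal-length numeric vectors from the same
#'   feature space.
#' @return Drift in `[0, 2]`.
#' @export
cosine_drift <- function(f_original, f_perturbed) {
  if (length(f_original) != length(f_perturbed))
    stop("feature vectors differ in length")
  n1 <- sqrt(sum(f_original^2)); n2 <- sqrt(sum(f_perturbed^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero vector: cosine undefined")
  1 - sum(f_original * f_perturbed) / (n1 * n2)
}

# row-wise cosine drift between two matrices
.drift_rows <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) cosine_drift(A[i, ], B[i, ]), 0)
}

#' Feature drift under controlled perturbations
#'
#' For each perturbation and each feature extractor, computes the per-cell
#' cosine distance between features of the original and perturbed crops and
#' aggregates mean/sd. All extractors see identical perturbed crops.
#'
#' @param crops List of [cell_crop()]s.
#' @param extractors Named list of functions mapping a crop list to a
#'   feature matrix (e.g. learned and engineered extractors).
#' @param specs List of [perturbation_spec()]s.
#' @return data.frame: `space`, `kind`, `magnitude`, `mean_drift`,
#'   `sd_drift`, `n`.
#' @export
robustness_report <- function(crops, extractors, specs) {
  if (length(extractors) < 2)
    warning("robustness comparisons usually need at least 2 extractors")
  base <- lapply(extractors, function(f) as.matrix(f(crops)))
  rows <- list()
  for (sp in specs) {
    pert <- lapply(crops, perturb, spec = sp)
    for (nm in names(extractors)) {
      pf <- tryCatch(as.matrix(extractors[[nm]](pert)), error = function(e)
        stop("extractor '", nm, "' failed under ", sp$kind, ": ",
             conditionMessage(e)))
      d <- .drift_rows(base[[nm]], pf)
      rows[[length(rows) + 1L]] <- data.frame(
        space = nm, kind = sp$kind, magnitude = sp$magnitude,
        mean_drift = mean(d), sd_drift = sd(d), n = length(d))
    }
  }
  do.call(rbind, rows)
}

#' Subsample to a target immune/rare imbalance ratio
#'
#' Retains every rare cell and samples immune cells without replacement to
#' `ratio` times the rare count.
#'
#' @param features Feature matrix.
#' @param labels Label vector.
#' @param rare_classes Labels counted as rare; everything else is immune.
#' @param ratio Immune/rare ratio in `[0.5, 10]`.
#' @param seed Sampling seed.
#' @return List: `features`, `labels`, `idx` (row indices kept).
#' @export
subsample_imbalance <- function(features, labels, rare_classes, ratio,
                                seed = 1L) {
  if (ratio < 0.5 || ratio > 10) stop("ratio must lie in [0.5, 10]")
  rare <- which(labels %in% rare_classes)
  imm <- which(!labels %in% rare_classes)
  if (!length(rare)) stop("no rare cells present")
  need <- round(ratio * length(rare))
  if (need > length(imm))
    stop("insufficient immune cells; maximum feasible ratio is ",
         round(length(imm) / length(rare), 2))
  set.seed(seed)
  keep <- sort(c(rare, sample(imm, need)))
  list(features = features[keep, , drop = FALSE], labels = labels[keep],
       idx = keep)
}

#' Cluster cells in feature space
#'
#' `"kmeans"`: k centers (default 10), seeded. `"leiden"`: symmetrized
#' cosine k-nearest-neighbour graph (default neighborhood 15), Leiden
#' community detection under the modularity objective, seeded.
#'
#' @param features n x d feature matrix.
#' @param method `"kmeans"` or `"leiden"`.
#' @param k Number of k-means clusters.
#' @param knn Neighborhood size for the Leiden graph.
#' @param seed Seed.
#' @param scale Robust-scale features first (default TRUE).
#' @return Integer cluster labels of length n.
#' @export
cluster_cells <- function(features, method = c("kmeans", "leiden"), k = 10L,
                          knn = 15L, seed = 1L, scale = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(features)
  if (scale) X <- .robust_scale(X)
  n <- nrow(X)
  if (method == "kmeans") {
    if (n <= k) stop("need more points than clusters")
    set.seed(seed)
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)$cluster
  } else {
    if (n <= knn) stop("need more points than the neighborhood size")
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm < 1e-12] <- 1
    Z <- X / nrm
    # cosine kNN in row blocks
    edges <- vector("list", ceiling(n / 1024))
    bi <- 1L; i <- 1L
    while (i <= n) {
      take <- i:min(i + 1023L, n)
      S <- Z[take, , drop = FALSE] %*% t(Z)
      S[cbind(seq_along(take), take)] <- -Inf
      nb <- t(apply(S, 1, function(s) order(-s)[seq_len(knn)]))
      edges[[bi]] <- cbind(rep(take, each = knn), as.vector(t(nb)))
      bi <- bi + 1L; i <- i + 1024L
    }
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(e, directed = TRUE)
    g <- igraph::as_undirected(g, mode = "collapse")   # symmetrize (union)
    set.seed(seed)
    igraph::cluster_leiden(g, objective_function = "modularity",
                           n_iterations = 3)$membership
  }
}

#' Imbalance-swept clustering comparison
#'
#' For each imbalance ratio, subsamples immune cells (the rare-cell set is
#' fixed; only the immune subsample varies), clusters every feature space on
#' the identical subset, and scores against the true phenotypes.
#'
#' @param feature_sets Named list of feature matrices over the same cells.
#' @param labels Phenotype labels.
#' @param rare_classes Labels counted as rare.
#' @param ratios Imbalance ratios to sweep.
#' @param methods Clustering methods to run.
#' @param k,knn,seed Passed to [cluster_cells()].
#' @return data.frame with one row per space x method x ratio and the four
#'   agreement metrics.
#' @export
imbalance_sweep <- function(feature_sets, labels, rare_classes,
                            ratios = c(0.5, 2, 5, 10),
                            methods = c("kmeans", "leiden"), k = 10L,
                            knn = 15L, seed = 1L) {
  rows <- list()
  for (ratio in ratios) {
    sub <- subsample_imbalance(feature_sets[[1]], labels, rare_classes,
                               ratio, seed = derive_seed(seed, round(100 * ratio)))
    for (m in methods) {
      for (nm in names(feature_sets)) {
        X <- feature_sets[[nm]][sub$idx, , drop = FALSE]
        cl <- cluster_cells(X, method = m, k = k, knn = knn, seed = seed)
        met <- clustering_metrics(cl, labels[sub$idx])
        rows[[length(rows) + 1L]] <- data.frame(
          space = nm, method = m, ratio = ratio, ari = met$ari,
          nmi = met$nmi, homogeneity = met$homogeneity,
          completeness = met$completeness, n = length(sub$idx))
      }
    }
  }
  do.call(rbind, rows)
}

# ---- rare-phenotype enumeration -------------------------------------------

# minimal dense MLP trained with Adam + softmax cross-entropy (pure R);
# used for the enumeration heads on 128-dim representations
.mlp_train <- function(X, y, hidden, epochs, lr, wd, batch, seed) {
  set.seed(seed)
  dims <- c(ncol(X), hidden, nlevels(y))
  L <- length(dims) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(dims[l + 1] * dims[l], 0, sqrt(2 / dims[l])),
           dims[l + 1], dims[l]))
  b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  n <- nrow(X); t0 <- 0
  yi <- as.integer(y)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      take <- ord[i:min(i + batch - 1L, n)]
      i <- i + batch
      A <- list(t(X[take, , drop = FALSE]))
      for (l in seq_len(L)) {
        Zl <- W[[l]] %*% A[[l]] + b[[l]]
        A[[l + 1]] <- if (l < L) pmax(Zl, 0) else Zl
      }
      P <- A[[L + 1]]
      P <- exp(sweep(P, 2, apply(P, 2, max)))
      P <- sweep(P, 2, colSums(P), "/")
      D <- P
      D[cbind(yi[take], seq_along(take))] <-
        D[cbind(yi[take], seq_along(take))] - 1
      D <- D / length(take)
      t0 <- t0 + 1
      for (l in rev(seq_len(L))) {
        gW <- D %*% t(A[[l]]) + wd * W[[l]]
        gb <- rowSums(D)
        if (l > 1) {
          D <- t(W[[l]]) %*% D
          D[A[[l]] <= 0] <- 0
        }
        mW[[l]] <- 0.9 * mW[[l]] + 0.1 * gW
        vW[[l]] <- 0.999 * vW[[l]] + 0.001 * gW^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - 0.9^t0)) /
          (sqrt(vW[[l]] / (1 - 0.999^t0)) + 1e-8)
        mb[[l]] <- 0.9 * mb[[l]] + 0.1 * gb
        vb[[l]] <- 0.999 * vb[[l]] + 0.001 * gb^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - 0.9^t0)) /
          (sqrt(vb[[l]] / (1 - 0.999^t0)) + 1e-8)
      }
    }
  }
  list(W = W, b = b)
}

.mlp_prob <- function(net, X) {
  A <- t(X)
  L <- length(net$W)
  for (l in seq_len(L)) {
    A <- net$W[[l]] %*% A + net$b[[l]]
    if (l < L) A <- pmax(A, 0)
  }
  P <- exp(sweep(A, 2, apply(A, 2, max)))
  t(sweep(P, 2, colSums(P), "/"))
}

#' Train the rare-phenotype enumeration head
#'
#' A small fully connected perceptron on frozen features. The `"two-layer"`
#' head (hidden width 64) follows the contrived-slide profile: 100 epochs,
#' learning rate 0.01; the `"three-layer"` head (128, 64) follows the
#' patient-slide profile: 50 epochs, learning rate 0.001, weight decay
#' 1e-4. Adam optimizer in both profiles.
#'
#' @param features n x d training features.
#' @param labels Factor of class labels (rare class(es) plus `"other"`).
#' @param head_spec `"two-layer"` or `"three-layer"`.
#' @param seed Seed.
#' @param epochs,lr,weight_decay,batch Optional overrides of the profile.
#' @return An `enumerator` model.
#' @export
train_enumerator <- function(features, labels,
                             head_spec = c("two-layer", "three-layer"),
                             seed = 1L, epochs = NULL, lr = NULL,
                             weight_decay = NULL, batch = 128L) {
  head_spec <- match.arg(head_spec)
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  prof <- if (head_spec == "two-layer") {
    list(hidden = 64L, epochs = 100L, lr = 0.01, wd = 0)
  } else {
    list(hidden = c(128L, 64L), epochs = 50L, lr = 0.001, wd = 1e-4)
  }
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv < 1e-12] <- 1
  net <- .mlp_train(sweep(sweep(X, 2, mu), 2, sdv, "/"), y,
                    hidden = prof$hidden,
                    epochs = epochs %||% prof$epochs, lr = lr %||% prof$lr,
                    wd = weight_decay %||% prof$wd, batch = batch,
                    seed = seed)
  structure(list(net = net, levels = levels(y), mu = mu, sd = sdv,
                 head_spec = head_spec), class = "enumerator")
}

#' Predict classes with an enumeration head
#'
#' @param object An `enumerator`.
#' @param features Feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a probability matrix.
#' @export
predict.enumerator <- function(object, features, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  X <- sweep(sweep(as.matrix(features), 2, object$mu), 2, object$sd, "/")
  P <- .mlp_prob(object$net, X)
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P)], levels = object$levels)
}

#' Per-slide rare-phenotype enumeration report
#'
#' Applies a trained enumeration head to held-out slides and reports
#' precision, recall and F1 per rare class: per slide, pooled from summed
#' confusion counts (micro), and as the mean of per-slide values (macro).
#' Slides that contain no cell of a class contribute no per-slide row for
#' it. Undefined precision (no predicted positives) is reported as 0.
#'
#' @param classifier An `enumerator`.
#' @param slide_features Named list of per-slide feature matrices.
#' @param slide_truth Named list of per-slide true label vectors.
#' @param rare_classes Classes to report (defaults to every non-"other"
#'   level of the classifier).
#' @return An `enumeration_report`: `per_slide` and `pooled` data.frames.
#' @export
enumerate_slides <- function(classifier, slide_features, slide_truth,
                             rare_classes = NULL) {
  stopifnot(inherits(classifier, "enumerator"),
            identical(names(slide_features), names(slide_truth)))
  rare_classes <- rare_classes %||%
    setdiff(classifier$levels, "other")
  per <- list(); counts <- list()
  for (s in names(slide_features)) {
    truth <- factor(slide_truth[[s]], levels = classifier$levels)
    if (nrow(slide_features[[s]]) != length(truth))
      stop("slide ", s, ": features and truth differ in length")
    pred <- predict(classifier, slide_features[[s]])
    for (cl in rare_classes) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      counts[[paste(s, cl)]] <- data.frame(slide = s, class = cl, tp = tp,
                                           fp = fp, fn = fn)
      if (tp + fn > 0) {
        m <- prf_counts(tp, fp, fn)
        per[[paste(s, cl)]] <- data.frame(slide = s, class = cl,
                                          n_true = tp + fn,
                                          precision = m["precision"],
                                          recall = m["recall"], f1 = m["f1"])
      }
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  cts <- do.call(rbind, counts)
  pooled <- do.call(rbind, lapply(rare_classes, function(cl) {
    cc <- cts[cts$class == cl, ]
    m <- prf_counts(sum(cc$tp), sum(cc$fp), sum(cc$fn))
    sl <- per[per$class == cl, ]
    data.frame(class = cl, micro_precision = m["precision"],
               micro_recall = m["recall"], micro_f1 = m["f1"],
               macro_f1 = if (nrow(sl)) mean(sl$f1) else NA_real_,
               n_true = sum(cc$tp) + sum(cc$fn))
  }))
  rownames(pooled) <- NULL
  structure(list(per_slide = per, pooled = pooled, counts = cts),
            class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat("<enumeration_report>\n")
  print(x$pooled)
  invisible(x)
}
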