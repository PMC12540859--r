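# Independent oracles used across the suite. Each re-derives a quantity from
# first principles (double loops, exhaustive pair counting, longhand entropy
# sums) without touching the implementation under test.

# NT-Xent by naive double loop over all 2N anchors
oracle_nt_xent <- function(z1, z2, tau) {
  Z <- rbind(z1, z2)
  n2 <- nrow(Z)
  N <- n2 / 2
  cossim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  total <- 0
  for (i in seq_len(n2)) {
    j <- if (i <= N) i + N else i - N
    num <- exp(cossim(Z[i, ], Z[j, ]) / tau)
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(cossim(Z[i, ], Z[k, ]) / tau)
    total <- total - log(num / den)
  }
  total / n2
}

# all-pairs IoU by brute-force pixel counting
oracle_iou_table <- function(gt, pred) {
  gids <- setdiff(sort(unique(as.vector(gt))), 0)
  pids <- setdiff(sort(unique(as.vector(pred))), 0)
  out <- list()
  for (g in gids) for (p in pids) {
    inter <- sum(gt == g & pred == p)
    if (inter > 0) {
      un <- sum(gt == g | pred == p)
      out[[length(out) + 1L]] <- data.frame(gt = g, pred = p, iou = inter / un)
    }
  }
  if (!length(out)) return(data.frame(gt = integer(0), pred = integer(0),
                                      iou = numeric(0)))
  do.call(rbind, out)
}

# maximum-cardinality one-to-one matching above a threshold, via igraph
oracle_match_counts <- function(gt, pred, thr) {
  tab <- oracle_iou_table(gt, pred)
  gids <- setdiff(sort(unique(as.vector(gt))), 0)
  pids <- setdiff(sort(unique(as.vector(pred))), 0)
  cand <- tab[tab$iou >= thr, , drop = FALSE]
  tp <- 0
  if (nrow(cand)) {
    vg <- paste0("g", cand$gt); vp <- paste0("p", cand$pred)
    verts <- unique(c(vg, vp))
    g <- igraph::make_bipartite_graph(
      types = grepl("^p", verts),
      edges = as.vector(rbind(match(vg, verts), match(vp, verts))))
    tp <- igraph::max_bipartite_match(g)$matching_size
  }
  list(TP = tp, FP = length(pids) - tp, FN = length(gids) - tp)
}

# ARI by exhaustive pair counting over all n(n-1)/2 point pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# entropy-based clustering scores written out longhand
oracle_info_scores <- function(pred, truth) {
  n <- length(pred)
  H <- function(x) {
    p <- table(x) / n
    p <- p[p > 0]
    -sum(p * log(p))
  }
  Hcond <- function(x, given) {
    # H(x | given)
    tot <- 0
    for (g in unique(given)) {
      sel <- given == g
      pg <- sum(sel) / n
      px <- table(x[sel]) / sum(sel)
      px <- px[px > 0]
      tot <- tot - pg * sum(px * log(px))
    }
    tot
  }
  Hc <- H(truth); Hk <- H(pred)
  mi <- Hc - Hcond(truth, pred)
  list(
    nmi = if (Hc + Hk < 1e-12) 1 else if (mi <= 0) 0 else mi / ((Hc + Hk) / 2),
    homogeneity = if (Hc < 1e-12) 1 else 1 - Hcond(truth, pred) / Hc,
    completeness = if (Hk < 1e-12) 1 else 1 - Hcond(pred, truth) / Hk)
}

# ROC AUC by comparing every (positive, negative) pair
oracle_roc_auc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# average precision from the explicit step curve, walking unique thresholds
oracle_pr_auc <- function(score, truth) {
  th <- sort(unique(score), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in th) {
    sel <- score >= t
    prec <- sum(truth[sel]) / sum(sel)
    rec <- sum(truth[sel]) / sum(truth)
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

# draw a toy scene of labelled rectangles and a perturbed copy
random_scene <- function(seed, n_max = 12, dim = c(60, 60)) {
  set.seed(seed)
  gt <- matrix(0L, dim[1], dim[2])
  pred <- matrix(0L, dim[1], dim[2])
  n <- sample(2:n_max, 1)
  placed <- 0
  for (i in seq_len(n)) {
    h <- sample(4:8, 1); w <- sample(4:8, 1)
    r <- sample(2:(dim[1] - h - 2), 1); cc <- sample(2:(dim[2] - w - 2), 1)
    if (any(gt[r:(r + h), cc:(cc + w)] != 0)) next
    placed <- placed + 1
    gt[r:(r + h), cc:(cc + w)] <- placed
    if (runif(1) < 0.85) {   # predicted copy, jittered; else a miss
      dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
      rr <- pmax(1, pmin(dim[1], r + dr)):pmax(1, pmin(dim[1], r + h + dr))
      ccc <- pmax(1, pmin(dim[2], cc + dc)):pmax(1, pmin(dim[2], cc + w + dc))
      pred[rr, ccc] <- placed
    }
  }
  # spurious prediction
  if (runif(1) < 0.5) {
    r <- sample(2:(dim[1] - 5), 1); cc <- sample(2:(dim[2] - 5), 1)
    sq <- pred[r:(r + 3), cc:(cc + 3)]
    if (all(sq == 0) && all(gt[r:(r + 3), cc:(cc + 3)] == 0))
      pred[r:(r + 3), cc:(cc + 3)] <- max(pred) + 1L
  }
  list(gt = instance_mask(gt), pred = instance_mask(pred))
}
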