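# Evaluation metrics implemented from their contingency-table / step-curve
# definitions. Each is validated in the test suite against longhand oracles
# (exhaustive pair counting, explicit entropy sums, rank statistics).

#' Clustering agreement metrics
#'
#' Adjusted Rand Index, Normalized Mutual Information (arithmetic-mean
#' normalization), homogeneity and completeness between a predicted
#' clustering and reference labels. Conventions at degenerate partitions:
#' a single predicted cluster over several classes has homogeneity 0 and
#' completeness 1; ARI of two identical trivial partitions is 1.
#'
#' @param pred,truth Equal-length label vectors (any type coercible to
#'   factor).
#' @return Named list: `ari`, `nmi`, `homogeneity`, `completeness`.
#' @export
clustering_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  n <- length(pred)
  if (n < 2) stop("need at least two points")
  tab <- table(factor(pred), factor(truth))
  # ARI by pair counting
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  expected <- a * b / comb2(n)
  mx <- (a + b) / 2
  ari <- if (abs(mx - expected) < 1e-12) 1 else (sum_ij - expected) / (mx - expected)
  # entropies (natural log)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Hk <- H(pr); Hc <- H(pc)
  Hck <- -sum(p[p > 0] * log((p / pr[row(tab)])[p > 0]))  # H(C|K)
  Hkc <- -sum(p[p > 0] * log((p / rep(pc, each = nrow(tab)))[p > 0]))
  mi <- Hc - Hck
  nmi <- if (Hk + Hc < 1e-12) 1 else if (mi <= 0) 0 else mi / ((Hk + Hc) / 2)
  homogeneity <- if (Hc < 1e-12) 1 else 1 - Hck / Hc
  completeness <- if (Hk < 1e-12) 1 else 1 - Hkc / Hk
  list(ari = ari, nmi = nmi, homogeneity = max(0, homogeneity),
       completeness = max(0, completeness))
}

# precision/recall/F1 from confusion counts; undefined precision (no
# predicted positives) is reported as 0, flagged via attribute
prf_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' ROC AUC of a score against a binary truth
#'
#' Rank statistic (Mann-Whitney) with midrank tie handling; equals the area
#' under the exact step ROC curve.
#'
#' @param score Numeric scores, higher = more positive.
#' @param truth Logical (or 0/1) labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need both classes for ROC AUC")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall step curve)
#'
#' `AP = sum_k (R_k - R_{k-1}) P_k` over descending score order, with tied
#' scores collapsed into single steps.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
pr_auc <- function(score, truth) {
  truth <- as.logical(truth)
  if (!any(truth)) stop("need positive examples for PR AUC")
  o <- order(-score)
  s <- score[o]; y <- truth[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(truth)
  sum(diff(c(0, rec)) * prec)
}

#' Top-K outlier recovery curve and normalized AUC
#'
#' Walks the first K entries of an outlier ranking, accumulating the
#' fraction of the positives found within the prefix. The area under
#' recall-vs-rank (relative to the positives present in the prefix) is
#' normalized by the ideal curve that packs those positives at the front,
#' so a ranking placing all rare cells first scores exactly 1; a prefix
#' containing no positives scores 0.
#'
#' @param ranking An `outlier_ranking` from [detect_outliers()], or a
#'   numeric score vector (higher = more outlying).
#' @param truth Logical vector marking the rare cells.
#' @param K Prefix size (defaults to 0.1% of n, at least 1).
#' @return List with `curve` (data.frame `rank`, `found`, `recall`) and
#'   `auc`.
#' @export
topk_recovery <- function(ranking, truth, K = max(1L, round(0.001 * length(truth)))) {
  score <- if (inherits(ranking, "outlier_ranking")) ranking$score else ranking
  truth <- as.logical(truth)
  if (length(score) != length(truth)) stop("ranking and truth differ in length")
  if (!any(truth)) stop("no positives in truth")
  if (K > length(truth)) stop("K exceeds the number of cells")
  ord <- order(-score)
  hits <- truth[ord][seq_len(K)]
  found <- cumsum(hits)
  pk <- found[K]
  if (pk == 0) {
    return(list(curve = data.frame(rank = seq_len(K), found = found,
                                   recall = rep(0, K)), auc = 0))
  }
  recall <- found / pk
  ideal <- pmin(seq_len(K), pk) / pk
  list(curve = data.frame(rank = seq_len(K), found = found, recall = recall),
       auc = sum(recall) / sum(ideal))
}
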